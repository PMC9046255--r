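# Shared fixtures and independent brute-force oracles used across tests.

# central finite-difference gradient of f: R^n -> R
num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# uniform random proper rotation (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# independent dihedral implementation: angle between the two plane normals,
# signed by the scalar triple product with the central bond
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang)))
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# exhaustive all-pairs k-NN edge oracle; matches the documented semantics:
# distances compared after rounding at 1e-9 A, ties broken by smaller index
oracle_knn <- function(ca, k) {
  L <- nrow(ca)
  out <- NULL
  for (i in seq_len(L)) {
    d <- round(sqrt(colSums((t(ca) - ca[i, ])^2)), 9L)
    d[i] <- Inf
    ord <- order(d, seq_len(L))
    nb <- ord[seq_len(min(k, L - 1L))]
    out <- rbind(out, cbind(src = nb, dst = i))
  }
  as.data.frame(out)
}

# threshold-sweep oracles for PR metrics
oracle_aupr <- function(scores, labels) {
  taus <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(taus, function(t) {
    sel <- scores >= t
    c(p = sum(labels[sel]) / sum(sel), r = sum(labels[sel]) / sum(labels))
  }, numeric(2L)))
  sum(diff(c(0, pts[, "r"])) * pts[, "p"])
}

oracle_fmax <- function(pred, labels) {
  best <- 0
  for (tau in sort(unique(c(0, 1, as.numeric(pred))))) {
    dec <- pred >= tau
    covered <- rowSums(dec) > 0
    if (!any(covered)) next
    prec <- mean((rowSums(dec & labels == 1) / rowSums(dec))[covered])
    rec <- mean((rowSums(dec & labels == 1) / rowSums(labels))[rowSums(labels) > 0])
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    best <- max(best, f)
  }
  best
}

# pairwise-enumeration AUROC (probability a positive outranks a negative,
# ties counting 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# numeric GVP transform replicated with explicit per-row loops
oracle_gvp <- function(s, Vx, Vy, Vz, p) {
  n <- nrow(s)
  d <- p$dims
  sout <- matrix(0, n, d$sout)
  Vox <- matrix(0, n, max(d$vout, 1L)); Voy <- Vox; Voz <- Vox
  for (i in seq_len(n)) {
    V <- rbind(Vx[i, ], Vy[i, ], Vz[i, ])        # 3 x vin spatial rows
    Vh <- V %*% t(p$Wh$value)                    # 3 x hv
    norms <- sqrt(colSums(Vh^2))
    sh <- c(s[i, ], norms)
    sm <- as.numeric(p$Ws$value %*% sh + t(p$bs$value))
    so <- pmax(sm, 0)
    sout[i, ] <- so
    if (d$vout > 0L) {
      Vmu <- Vh %*% t(p$Wv$value)                # 3 x vout
      gate <- 1 / (1 + exp(-(as.numeric(p$Wg$value %*% so + t(p$bg$value)))))
      Vg <- sweep(Vmu, 2L, gate, "*")
      Vox[i, ] <- Vg[1L, ]; Voy[i, ] <- Vg[2L, ]; Voz[i, ] <- Vg[3L, ]
    }
  }
  list(s = sout, Vx = Vox, Vy = Voy, Vz = Voz)
}

# dense per-edge loop implementation of one GVP convolution (dropout off)
oracle_gvp_conv <- function(graph, s, Vx, Vy, Vz, p) {
  n <- graph$n_nodes
  ev <- graph$edge_vector
  E <- nrow(graph$edges)
  ms <- matrix(0, E, ncol(s) + ncol(graph$edge_scalar))
  mVx <- matrix(0, E, ncol(Vx) + 1L); mVy <- mVx; mVz <- mVx
  for (e in seq_len(E)) {
    j <- graph$edges$src[e]
    ms[e, ] <- c(s[j, ], graph$edge_scalar[e, ])
    mVx[e, ] <- c(Vx[j, ], ev[e, 1L])
    mVy[e, ] <- c(Vy[j, ], ev[e, 2L])
    mVz[e, ] <- c(Vz[j, ], ev[e, 3L])
  }
  msg <- oracle_gvp(ms, mVx, mVy, mVz, p$msg)
  d <- p$dims
  as_ <- matrix(0, n, d$s_h); aVx <- matrix(0, n, d$v_h); aVy <- aVx; aVz <- aVx
  for (i in seq_len(n)) {
    ei <- which(graph$edges$dst == i)
    as_[i, ] <- colMeans(msg$s[ei, , drop = FALSE])
    aVx[i, ] <- colMeans(msg$Vx[ei, , drop = FALSE])
    aVy[i, ] <- colMeans(msg$Vy[ei, , drop = FALSE])
    aVz[i, ] <- colMeans(msg$Vz[ei, , drop = FALSE])
  }
  sr <- s + as_
  g <- as.numeric(p$ln_gamma$value); b <- as.numeric(p$ln_beta$value)
  sn <- t(apply(sr, 1L, function(row) {
    g * (row - mean(row)) / sqrt(mean((row - mean(row))^2) + 1e-5) + b
  }))
  Vrx <- Vx + aVx; Vry <- Vy + aVy; Vrz <- Vz + aVz
  nrm <- sqrt(Vrx^2 + Vry^2 + Vrz^2)
  tau <- rowMeans(nrm) + 1e-6
  list(s = sn, Vx = Vrx / tau, Vy = Vry / tau, Vz = Vrz / tau)
}

# dense-adjacency GAT oracle (single head, ELU output, softmax incl. self)
oracle_gat <- function(graph, x, hp) {
  n <- graph$n_nodes
  W <- hp$heads[[1L]]$W$value
  a_s <- as.numeric(hp$heads[[1L]]$a_src$value)
  a_d <- as.numeric(hp$heads[[1L]]$a_dst$value)
  Wh <- x %*% t(W)
  out <- matrix(0, n, nrow(W))
  lrelu <- function(v) ifelse(v > 0, v, 0.2 * v)
  for (i in seq_len(n)) {
    nb <- c(graph$edges$src[graph$edges$dst == i], i)
    logits <- vapply(nb, function(j)
      lrelu(sum(a_s * Wh[j, ]) + sum(a_d * Wh[i, ])), numeric(1L))
    al <- exp(logits - max(logits)); al <- al / sum(al)
    acc <- numeric(nrow(W))
    for (t in seq_along(nb)) acc <- acc + al[t] * Wh[nb[t], ]
    out[i, ] <- ifelse(acc > 0, acc, exp(pmin(acc, 0)) - 1)
  }
  out
}

# small shared fixtures
toy_structure <- function(L = 10L, seed = 7L) build_chain(chain_spec(L, seed = seed))

# a chain whose CA trace is a compact 3.8 A random walk: unlike extended
# idealized chains it has a contact-rich map, which the probe tests need
compact_structure <- function(L = 30L, seed = 1L) {
  st <- build_chain(chain_spec(L, seed = seed))
  set.seed(seed + 1000L)
  steps <- matrix(stats::rnorm(3L * (L - 1L)), ncol = 3L)
  steps <- 3.8 * steps / sqrt(rowSums(steps^2))
  # bias steps back toward the origin to keep the walk compact
  ca <- matrix(0, L, 3L)
  for (i in 2:L) {
    pull <- -0.05 * ca[i - 1L, ]
    dir <- steps[i - 1L, ] + pull
    ca[i, ] <- ca[i - 1L, ] + 3.8 * dir / sqrt(sum(dir^2))
  }
  st$coords_CA <- ca
  st
}

toy_pdb <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
  "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      7  CA  GLY A   2       3.984   2.830   0.000  1.00  0.00           C",
  "ATOM      8  C   GLY A   2       5.496   2.696   0.000  1.00  0.00           C",
  "ATOM      9  O   GLY A   2       6.070   1.610   0.000  1.00  0.00           O",
  "ATOM     10  N   ALA A   3       6.148   3.851   0.000  1.00  0.00           N",
  "ATOM     11  CA  ALA A   3       7.601   3.905   0.000  1.00  0.00           C",
  "ATOM     12  C   ALA A   3       8.150   5.320   0.000  1.00  0.00           C",
  "ATOM     13  O   ALA A   3       7.409   6.305   0.000  1.00  0.00           O",
  "ATOM     14  CB  ALA A   3       8.152   3.133   1.199  1.00  0.00           C",
  "END")
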