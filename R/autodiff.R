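# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is an "adnode": an environment holding $value
# (a numeric matrix), $grad (accumulated cotangent, NULL until backward) and
# $track (whether gradients should flow into it). Operations evaluate eagerly
# and push a backward closure onto a tape; ad_backward() replays the tape in
# reverse. Parameters live off-tape (they have no inputs) but receive
# gradients because they are captured by the closures of their consumers.

#' Create an empty autodiff tape
#'
#' A tape records every differentiable operation of one forward pass so
#' [ad_backward()] can replay it in reverse. Build one per forward pass.
#' @return a tape environment.
#' @export
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$stack <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$stack)) {
    tape$stack <- c(tape$stack, vector("list", length(tape$stack)))
  }
  tape$stack[[n]] <- node
  tape$n <- n
  node
}

ad_new <- function(value, track = TRUE, bw = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$track <- track
  e$bw <- bw
  class(e) <- "adnode"
  e
}

is_adnode <- function(x) inherits(x, "adnode")

# Wrap plain numerics as untracked constants; pass adnodes through.
ad_wrap <- function(x) {
  if (is_adnode(x)) return(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  ad_new(x, track = FALSE)
}

#' Create a trainable parameter node
#'
#' Parameter nodes live off-tape and accumulate gradients across backward
#' passes until [ad_zero_grad()] clears them.
#' @param value numeric matrix (or vector, promoted to a column matrix).
#' @return an `adnode` with `$value` and `$grad`.
#' @export
ad_param <- function(value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_new(value, track = TRUE)
}

ad_accum <- function(node, g) {
  if (!isTRUE(node$track)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Clear accumulated gradients on a list of parameter nodes
#' @param params list of `adnode` parameters.
#' @export
ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' Run backward from an output node
#'
#' Seeds the output gradient (every element set to `seed`) and replays the
#' tape in reverse, accumulating gradients into every tracked node.
#' @param tape the tape the forward pass was recorded on.
#' @param node output `adnode` (typically scalar).
#' @param seed gradient seed value (default 1).
#' @export
ad_backward <- function(tape, node, seed = 1) {
  node$grad <- matrix(seed, nrow(node$value), ncol(node$value))
  i <- tape$n
  while (i >= 1L) {
    s <- tape$stack[[i]]
    if (!is.null(s$grad) && !is.null(s$bw)) s$bw(s$grad)
    i <- i - 1L
  }
  invisible(NULL)
}

# ---- primitive operations ---------------------------------------------------

ad_matmul <- function(tape, a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  out <- ad_new(a$value %*% b$value, bw = function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, t(a$value) %*% g)
  })
  ad_push(tape, out)
}

# a %*% t(b): convenient for row-major layouts (rows = items)
ad_matmul_t <- function(tape, a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  out <- ad_new(tcrossprod(a$value, b$value), bw = function(g) {
    ad_accum(a, g %*% b$value)
    ad_accum(b, crossprod(g, a$value))
  })
  ad_push(tape, out)
}

ad_add <- function(tape, a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  out <- ad_new(a$value + b$value, bw = function(g) {
    ad_accum(a, g); ad_accum(b, g)
  })
  ad_push(tape, out)
}

ad_sub <- function(tape, a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  out <- ad_new(a$value - b$value, bw = function(g) {
    ad_accum(a, g); ad_accum(b, -g)
  })
  ad_push(tape, out)
}

ad_emul <- function(tape, a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  out <- ad_new(a$value * b$value, bw = function(g) {
    ad_accum(a, g * b$value); ad_accum(b, g * a$value)
  })
  ad_push(tape, out)
}

ad_scale <- function(tape, a, s) {
  a <- ad_wrap(a)
  out <- ad_new(a$value * s, bw = function(g) ad_accum(a, g * s))
  ad_push(tape, out)
}

ad_add_scalar <- function(tape, a, s) {
  a <- ad_wrap(a)
  out <- ad_new(a$value + s, bw = function(g) ad_accum(a, g))
  ad_push(tape, out)
}

# add a length-k row vector to every row of an n x k matrix (bias)
ad_add_rowvec <- function(tape, a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  bv <- as.numeric(b$value)
  out <- ad_new(sweep(a$value, 2L, bv, "+"), bw = function(g) {
    ad_accum(a, g)
    ad_accum(b, matrix(colSums(g), nrow(b$value), ncol(b$value)))
  })
  ad_push(tape, out)
}

# multiply every row of a by a length-k row vector
ad_mul_rowvec <- function(tape, a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  bv <- as.numeric(b$value)
  out <- ad_new(sweep(a$value, 2L, bv, "*"), bw = function(g) {
    ad_accum(a, sweep(g, 2L, bv, "*"))
    ad_accum(b, matrix(colSums(g * a$value), nrow(b$value), ncol(b$value)))
  })
  ad_push(tape, out)
}

# multiply row i of a by v[i] (v an n x 1 node)
ad_mul_colvec <- function(tape, a, v) {
  a <- ad_wrap(a); v <- ad_wrap(v)
  vv <- as.numeric(v$value)
  out <- ad_new(a$value * vv, bw = function(g) {
    ad_accum(a, g * vv)
    ad_accum(v, matrix(rowSums(g * a$value), ncol = 1L))
  })
  ad_push(tape, out)
}

ad_relu <- function(tape, a) {
  a <- ad_wrap(a)
  m <- a$value > 0
  out <- ad_new(a$value * m, bw = function(g) ad_accum(a, g * m))
  ad_push(tape, out)
}

ad_leaky_relu <- function(tape, a, slope = 0.2) {
  a <- ad_wrap(a)
  m <- ifelse(a$value > 0, 1, slope)
  out <- ad_new(a$value * m, bw = function(g) ad_accum(a, g * m))
  ad_push(tape, out)
}

ad_elu <- function(tape, a, alpha = 1) {
  a <- ad_wrap(a)
  pos <- a$value > 0
  ex <- alpha * (exp(pmin(a$value, 0)) - 1)
  val <- ifelse(pos, a$value, ex)
  out <- ad_new(val, bw = function(g) ad_accum(a, g * ifelse(pos, 1, ex + alpha)))
  ad_push(tape, out)
}

ad_sigmoid <- function(tape, a) {
  a <- ad_wrap(a)
  y <- 1 / (1 + exp(-a$value))
  out <- ad_new(y, bw = function(g) ad_accum(a, g * y * (1 - y)))
  ad_push(tape, out)
}

ad_tanh <- function(tape, a) {
  a <- ad_wrap(a)
  y <- tanh(a$value)
  out <- ad_new(y, bw = function(g) ad_accum(a, g * (1 - y^2)))
  ad_push(tape, out)
}

ad_exp <- function(tape, a) {
  a <- ad_wrap(a)
  y <- exp(a$value)
  out <- ad_new(y, bw = function(g) ad_accum(a, g * y))
  ad_push(tape, out)
}

ad_log <- function(tape, a) {
  a <- ad_wrap(a)
  out <- ad_new(log(a$value), bw = function(g) ad_accum(a, g / a$value))
  ad_push(tape, out)
}

ad_sum <- function(tape, a) {
  a <- ad_wrap(a)
  d <- dim(a$value)
  out <- ad_new(matrix(sum(a$value), 1L, 1L), bw = function(g) {
    ad_accum(a, matrix(g[1L], d[1L], d[2L]))
  })
  ad_push(tape, out)
}

ad_mean <- function(tape, a) {
  a <- ad_wrap(a)
  d <- dim(a$value); n <- d[1L] * d[2L]
  out <- ad_new(matrix(mean(a$value), 1L, 1L), bw = function(g) {
    ad_accum(a, matrix(g[1L] / n, d[1L], d[2L]))
  })
  ad_push(tape, out)
}

# column means as a 1 x k matrix
ad_colmeans <- function(tape, a) {
  a <- ad_wrap(a)
  n <- nrow(a$value)
  out <- ad_new(matrix(colMeans(a$value), 1L), bw = function(g) {
    ad_accum(a, matrix(g, n, ncol(a$value), byrow = TRUE) / n)
  })
  ad_push(tape, out)
}

ad_colsums <- function(tape, a) {
  a <- ad_wrap(a)
  n <- nrow(a$value)
  out <- ad_new(matrix(colSums(a$value), 1L), bw = function(g) {
    ad_accum(a, matrix(g, n, ncol(a$value), byrow = TRUE))
  })
  ad_push(tape, out)
}

# row means as an n x 1 matrix
ad_rowmeans <- function(tape, a) {
  a <- ad_wrap(a)
  k <- ncol(a$value)
  out <- ad_new(matrix(rowMeans(a$value), ncol = 1L), bw = function(g) {
    ad_accum(a, matrix(g / k, nrow(a$value), k))
  })
  ad_push(tape, out)
}

ad_recip <- function(tape, a) {
  a <- ad_wrap(a)
  y <- 1 / a$value
  out <- ad_new(y, bw = function(g) ad_accum(a, -g * y * y))
  ad_push(tape, out)
}

ad_concat_cols <- function(tape, nodes) {
  nodes <- lapply(nodes, ad_wrap)
  widths <- vapply(nodes, function(x) ncol(x$value), integer(1L))
  out <- ad_new(do.call(cbind, lapply(nodes, function(x) x$value)), bw = function(g) {
    at <- 0L
    for (j in seq_along(nodes)) {
      ad_accum(nodes[[j]], g[, at + seq_len(widths[j]), drop = FALSE])
      at <- at + widths[j]
    }
  })
  ad_push(tape, out)
}

ad_cols <- function(tape, a, idx) {
  a <- ad_wrap(a)
  out <- ad_new(a$value[, idx, drop = FALSE], bw = function(g) {
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    ga[, idx] <- g
    ad_accum(a, ga)
  })
  ad_push(tape, out)
}

# gather rows (with repetition); backward is scatter-add
ad_rows <- function(tape, a, idx) {
  a <- ad_wrap(a)
  out <- ad_new(a$value[idx, , drop = FALSE], bw = function(g) {
    rs <- rowsum(g, group = idx, reorder = FALSE)
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    ga[as.integer(rownames(rs)), ] <- rs
    ad_accum(a, ga)
  })
  ad_push(tape, out)
}

# group-wise sum of rows: rows of a grouped by `group` (values in 1..ngroups)
ad_group_sum <- function(tape, a, group, ngroups) {
  a <- ad_wrap(a)
  val <- matrix(0, ngroups, ncol(a$value))
  rs <- rowsum(a$value, group = group, reorder = FALSE)
  val[as.integer(rownames(rs)), ] <- rs
  out <- ad_new(val, bw = function(g) ad_accum(a, g[group, , drop = FALSE]))
  ad_push(tape, out)
}

ad_group_mean <- function(tape, a, group, ngroups) {
  a <- ad_wrap(a)
  cnt <- tabulate(group, nbins = ngroups)
  cnt_safe <- pmax(cnt, 1L)
  val <- matrix(0, ngroups, ncol(a$value))
  rs <- rowsum(a$value, group = group, reorder = FALSE)
  val[as.integer(rownames(rs)), ] <- rs
  val <- val / cnt_safe
  out <- ad_new(val, bw = function(g) {
    ad_accum(a, (g / cnt_safe)[group, , drop = FALSE])
  })
  ad_push(tape, out)
}

# row-wise softmax with detached max-shift stabilization (shift-invariant)
ad_softmax_rows <- function(tape, a) {
  a <- ad_wrap(a)
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  y <- e / rowSums(e)
  out <- ad_new(y, bw = function(g) {
    ad_accum(a, (g - rowSums(g * y)) * y)
  })
  ad_push(tape, out)
}

# row-wise layer norm with learned gain/bias (1 x k nodes)
ad_layernorm_rows <- function(tape, a, gamma, beta, eps = 1e-5) {
  a <- ad_wrap(a); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  k <- ncol(a$value)
  mu <- rowMeans(a$value)
  xc <- a$value - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value)
  val <- sweep(xhat, 2L, gv, "*")
  val <- sweep(val, 2L, as.numeric(beta$value), "+")
  out <- ad_new(val, bw = function(g) {
    ad_accum(gamma, matrix(colSums(g * xhat), 1L))
    ad_accum(beta, matrix(colSums(g), 1L))
    gx <- sweep(g, 2L, gv, "*")
    # d/dx of (x - mu) * inv with mu, inv functions of the row
    s1 <- rowSums(gx)
    s2 <- rowSums(gx * xhat)
    ad_accum(a, inv * (gx - s1 / k - xhat * s2 / k))
  })
  ad_push(tape, out)
}

# Euclidean norm across three aligned matrices (the x/y/z components of a
# vector channel); value is exact at 0, backward clamps the denominator.
ad_norm3 <- function(tape, x, y, z, eps = 1e-8) {
  x <- ad_wrap(x); y <- ad_wrap(y); z <- ad_wrap(z)
  n <- sqrt(x$value^2 + y$value^2 + z$value^2)
  dn <- pmax(n, eps)
  out <- ad_new(n, bw = function(g) {
    ad_accum(x, g * x$value / dn)
    ad_accum(y, g * y$value / dn)
    ad_accum(z, g * z$value / dn)
  })
  ad_push(tape, out)
}

# inverted dropout; draws its mask from the current RNG stream
ad_dropout <- function(tape, a, rate, train) {
  a <- ad_wrap(a)
  if (!train || rate <= 0) return(a)
  keep <- matrix(stats::runif(length(a$value)) >= rate,
                 nrow(a$value), ncol(a$value)) / (1 - rate)
  out <- ad_new(a$value * keep, bw = function(g) ad_accum(a, g * keep))
  ad_push(tape, out)
}

# numerically stable binary cross-entropy with logits, optionally label-weighted;
# returns the mean over all entries (matching an n x l logit/target layout)
ad_bce_logits <- function(tape, z, y, w = NULL) {
  z <- ad_wrap(z)
  n <- length(z$value)
  wmat <- if (is.null(w)) 1 else matrix(w, nrow(z$value), ncol(z$value), byrow = TRUE)
  elem <- pmax(z$value, 0) - z$value * y + log1p(exp(-abs(z$value)))
  out <- ad_new(matrix(sum(wmat * elem) / n, 1L, 1L), bw = function(g) {
    sig <- 1 / (1 + exp(-z$value))
    ad_accum(z, g[1L] * wmat * (sig - y) / n)
  })
  ad_push(tape, out)
}

ad_mse <- function(tape, pred, y) {
  pred <- ad_wrap(pred)
  n <- length(pred$value)
  d <- pred$value - y
  out <- ad_new(matrix(sum(d^2) / n, 1L, 1L), bw = function(g) {
    ad_accum(pred, g[1L] * 2 * d / n)
  })
  ad_push(tape, out)
}

# treat a node as a constant from here on (cut the graph)
ad_detach <- function(a) ad_new(a$value, track = FALSE)

#' Extract the numeric value of an adnode (identity on plain matrices)
#' @param a an `adnode` or numeric matrix.
#' @return numeric matrix.
#' @export
ad_value <- function(a) if (is_adnode(a)) a$value else a
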