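# Conversion of a backbone structure (optionally plus per-residue language
# model embeddings) into the attributed k-NN residue graph consumed by the
# graph networks: scalar and vector features on nodes and directed edges.

#' Backbone dihedral angles phi/psi/omega
#'
#' @param struct a `backbone_structure`.
#' @return list with `angles` (L x 3 matrix, radians, columns phi/psi/omega;
#'   NA where undefined) and `defined` (L x 3 logical). phi is undefined at
#'   the first residue; psi and omega at the last.
#' @export
compute_dihedrals <- function(struct) {
  L <- length(struct$aa)
  ang <- matrix(NA_real_, L, 3L, dimnames = list(NULL, c("phi", "psi", "omega")))
  if (L >= 2L) {
    N <- struct$coords_N; CA <- struct$coords_CA; C <- struct$coords_C
    for (i in seq_len(L)) {
      if (i > 1L)
        ang[i, 1L] <- dihedral_angle(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
      if (i < L) {
        ang[i, 2L] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
        ang[i, 3L] <- dihedral_angle(CA[i, ], C[i, ], N[i + 1L, ], CA[i + 1L, ])
      }
    }
  }
  list(angles = ang, defined = !is.na(ang))
}

#' Directed k-nearest-neighbour edges from C-alpha coordinates
#'
#' Each node i receives edges j -> i from its min(k, L-1) nearest other
#' residues by C-alpha Euclidean distance; ties are broken by the smaller
#' residue index. No self-edges.
#' @param ca L x 3 C-alpha coordinates (Angstrom).
#' @param k positive neighbour count (default 30).
#' @return data.frame with integer columns `src` (j) and `dst` (i).
#' @export
build_knn_edges <- function(ca, k = 30L) {
  L <- nrow(ca)
  stopifnot(L >= 2L, k >= 1L)
  d2 <- as.matrix(stats::dist(ca))
  # distances rounded to 1e-9 A before sorting so the index tie-break (and
  # hence the edge ordering) is stable under rigid motions of the input
  dr <- round(d2, 9L)
  kk <- min(k, L - 1L)
  src <- integer(L * kk); dst <- integer(L * kk)
  at <- 0L
  for (i in seq_len(L)) {
    cand <- setdiff(seq_len(L), i)
    nb <- cand[order(dr[i, cand], cand)][seq_len(kk)]
    src[at + seq_len(kk)] <- nb
    dst[at + seq_len(kk)] <- i
    at <- at + kk
  }
  data.frame(src = src, dst = dst)
}

#' Gaussian radial basis encoding of a distance
#'
#' 16 Gaussian units with centers evenly spaced between 0 and 20 Angstrom;
#' the width equals the center spacing (20/15 A).
#' @param d distance(s) in Angstrom (>= 0).
#' @param n_centers number of basis units (default 16).
#' @param d_max largest center (default 20 A).
#' @return length(d) x `n_centers` matrix with entries in (0, 1].
#' @export
rbf_encode <- function(d, n_centers = 16L, d_max = 20) {
  centers <- seq(0, d_max, length.out = n_centers)
  sigma <- centers[2L] - centers[1L]
  outer(d, centers, function(x, c) exp(-((x - c) / sigma)^2))
}

#' Sinusoidal positional encoding of a signed sequence offset
#'
#' The Transformer recipe applied to the signed offset j - i, 16 dimensions
#' (8 sine/cosine pairs with geometric frequencies).
#' @param offset integer offset(s), may be negative.
#' @param dim encoding width (even; default 16).
#' @return length(offset) x dim matrix; columns alternate sin, cos.
#' @export
positional_encode <- function(offset, dim = 16L) {
  stopifnot(dim %% 2L == 0L)
  half <- dim %/% 2L
  freq <- 1 / (10000^((2 * (seq_len(half) - 1L)) / dim))
  arg <- outer(offset, freq)
  out <- matrix(0, length(offset), dim)
  out[, 2L * seq_len(half) - 1L] <- sin(arg)
  out[, 2L * seq_len(half)] <- cos(arg)
  out
}

onehot_aa <- function(aa) {
  m <- matrix(0, length(aa), length(AA_ALPHABET),
              dimnames = list(NULL, AA_ALPHABET))
  aa[!aa %in% AA_ALPHABET] <- "X"
  m[cbind(seq_along(aa), match(aa, AA_ALPHABET))] <- 1
  m
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  bad <- n < 1e-9
  n[bad] <- 1
  out <- m / n
  out[bad, ] <- 0
  out
}

#' Build the attributed residue graph
#'
#' Node scalars: sines and cosines of phi/psi/omega (6; undefined angles
#' encoded as (0,0)) and, depending on `mode`, the 21-way one-hot residue
#' identity and/or per-residue embeddings. Node vectors (3 per node): unit
#' vectors to the next and previous C-alpha (zero and flagged at the chain
#' termini) and the unit C-alpha -> C-beta direction. Edge scalars: 16 RBF
#' distance units and a 16-dim positional encoding of j - i. Edge vector:
#' the unit vector from the receiving residue i to the source j.
#'
#' @param struct a `backbone_structure`.
#' @param embeddings optional L x h embedding matrix (required for modes
#'   "lm_only" and "lm_concat").
#' @param mode "onehot" (6+21 scalars), "lm_only" (h) or "lm_concat" (6+21+h).
#' @param k neighbour count for [build_knn_edges()].
#' @return a `protein_graph`: list(n_nodes, edges, node_scalar, node_vector
#'   (list of L x 3 matrices `fwd`, `rev`, `cb`), node_vector_defined,
#'   edge_scalar, edge_vector (E x 3), feature_mode, embed_cols).
#' @export
featurize_graph <- function(struct, embeddings = NULL,
                            mode = c("onehot", "lm_only", "lm_concat"),
                            k = 30L) {
  mode <- match.arg(mode)
  L <- length(struct$aa)
  if (mode != "onehot") {
    if (is.null(embeddings)) stop("mode '", mode, "' requires embeddings")
    if (nrow(embeddings) != L) stop("sequence/structure length mismatch")
  }
  dih <- compute_dihedrals(struct)
  sc <- cbind(sin(dih$angles), cos(dih$angles))
  sc[is.na(sc)] <- 0
  colnames(sc) <- c(paste0("sin_", colnames(dih$angles)),
                    paste0("cos_", colnames(dih$angles)))

  base_scalar <- cbind(sc, onehot_aa(struct$aa))
  embed_cols <- integer(0L)
  node_scalar <- switch(mode,
    onehot = base_scalar,
    lm_only = embeddings,
    lm_concat = cbind(embeddings, base_scalar))
  if (mode == "lm_only") embed_cols <- seq_len(ncol(embeddings))
  if (mode == "lm_concat") embed_cols <- seq_len(ncol(embeddings))

  ca <- struct$coords_CA
  fwd <- matrix(0, L, 3L); rev <- matrix(0, L, 3L)
  if (L >= 2L) {
    fwd[-L, ] <- unit_rows(ca[-1L, , drop = FALSE] - ca[-L, , drop = FALSE])
    rev[-1L, ] <- unit_rows(ca[-L, , drop = FALSE] - ca[-1L, , drop = FALSE])
  }
  cbdir <- unit_rows(struct$coords_CB - ca)
  nv_defined <- cbind(fwd = c(rep(TRUE, max(L - 1L, 0L)), FALSE),
                      rev = c(FALSE, rep(TRUE, max(L - 1L, 0L))),
                      cb = rowSums(cbdir^2) > 0)

  edges <- build_knn_edges(ca, k)
  dvec <- ca[edges$src, , drop = FALSE] - ca[edges$dst, , drop = FALSE]
  dist <- sqrt(rowSums(dvec^2))
  edge_scalar <- cbind(rbf_encode(dist), positional_encode(edges$src - edges$dst))
  edge_vector <- unit_rows(dvec)

  structure(list(
    n_nodes = L,
    edges = edges,
    node_scalar = node_scalar,
    node_vector = list(fwd = fwd, rev = rev, cb = cbdir),
    node_vector_defined = nv_defined,
    edge_scalar = edge_scalar,
    edge_vector = edge_vector,
    feature_mode = mode,
    embed_cols = embed_cols), class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf("<protein_graph> %d nodes, %d edges, mode %s, %d node scalars\n",
              x$n_nodes, nrow(x$edges), x$feature_mode, ncol(x$node_scalar)))
  invisible(x)
}
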