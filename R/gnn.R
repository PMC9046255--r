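# Geometric network cores. A node state is a pair (scalar channel, vector
# channel). On the autodiff tape the scalar channel is one n x a matrix and
# the vector channel is held as three aligned n x nu matrices (the x/y/z
# components), so a linear map over the vector-count axis is one matrix
# multiply per component and never mixes spatial coordinates -- which is
# what makes scalars rotation-invariant and vectors equivariant by
# construction.

glorot <- function(nout, nin) {
  matrix(stats::runif(nout * nin, -1, 1) * sqrt(6 / (nin + nout)), nout, nin)
}

#' Parameters for one geometric vector perceptron transform
#'
#' @param sin,vin input scalar width / vector count.
#' @param sout,vout output scalar width / vector count.
#' @param hv hidden vector count (defaults to max(vin, vout)).
#' @return list of parameter nodes.
#' @export
gvp_params <- function(sin, vin, sout, vout, hv = max(vin, vout)) {
  p <- list(dims = list(sin = sin, vin = vin, sout = sout, vout = vout, hv = hv))
  if (vin > 0L) p$Wh <- ad_param(glorot(hv, vin))
  p$Ws <- ad_param(glorot(sout, sin + if (vin > 0L) hv else 0L))
  p$bs <- ad_param(matrix(0, 1L, sout))
  if (vout > 0L) {
    p$Wv <- ad_param(glorot(vout, hv))
    p$Wg <- ad_param(glorot(vout, sout))
    p$bg <- ad_param(matrix(0, 1L, vout))
  }
  p
}

# vector channel helpers: V is list(x=, y=, z=) of n x nu adnodes/matrices
vec_wrap <- function(V) lapply(V, ad_wrap)

vec_linear <- function(tape, V, W) lapply(V, function(cm) ad_matmul_t(tape, cm, W))

vec_concat <- function(tape, Vs) {
  list(x = ad_concat_cols(tape, lapply(Vs, `[[`, "x")),
       y = ad_concat_cols(tape, lapply(Vs, `[[`, "y")),
       z = ad_concat_cols(tape, lapply(Vs, `[[`, "z")))
}

vec_rows <- function(tape, V, idx) lapply(V, function(cm) ad_rows(tape, cm, idx))

vec_add <- function(tape, A, B) {
  list(x = ad_add(tape, A$x, B$x), y = ad_add(tape, A$y, B$y),
       z = ad_add(tape, A$z, B$z))
}

vec_norms <- function(tape, V) ad_norm3(tape, V$x, V$y, V$z)

# graph vector features -> component layout (n x 3 matrices per named vector)
graph_node_vectors <- function(graph) {
  vs <- graph$node_vector
  list(x = do.call(cbind, lapply(vs, function(m) m[, 1L])),
       y = do.call(cbind, lapply(vs, function(m) m[, 2L])),
       z = do.call(cbind, lapply(vs, function(m) m[, 3L])))
}

graph_edge_vectors <- function(graph) {
  ev <- graph$edge_vector
  list(x = ev[, 1L, drop = FALSE], y = ev[, 2L, drop = FALSE],
       z = ev[, 3L, drop = FALSE])
}

act_fn <- function(name) {
  switch(name,
         relu = ad_relu,
         tanh = ad_tanh,
         sigmoid = ad_sigmoid,
         elu = ad_elu,
         identity = function(tape, a) a,
         stop("unknown nonlinearity: ", name))
}

#' Apply one GVP transform to a (scalar, vector) state
#'
#' Row-norm formulation: the vector channel passes through a learned linear
#' map over the vector-count axis; the row norms of the mapped vectors are
#' concatenated to the scalar channel, which gets an affine map and a
#' pointwise nonlinearity; the vector output is a second linear map gated by
#' a sigmoid factor derived from the scalar channel.
#' @param tape autodiff tape.
#' @param s n x sin scalar node (or matrix).
#' @param V vector channel: list(x, y, z) of n x vin nodes, or NULL if vin=0.
#' @param p parameters from [gvp_params()].
#' @param act scalar nonlinearity name (default "relu").
#' @return list(s = scalar node, V = vector channel or NULL).
#' @export
gvp_transform <- function(tape, s, V, p, act = "relu") {
  s <- ad_wrap(s)
  d <- p$dims
  if (ncol(s$value) != d$sin) stop("scalar width mismatch")
  if (d$vin > 0L) {
    V <- vec_wrap(V)
    if (ncol(V$x$value) != d$vin) stop("vector count mismatch")
    Vh <- vec_linear(tape, V, p$Wh)
    sh <- ad_concat_cols(tape, list(s, vec_norms(tape, Vh)))
  } else {
    Vh <- NULL
    sh <- s
  }
  sm <- ad_add_rowvec(tape, ad_matmul_t(tape, sh, p$Ws), p$bs)
  sout <- act_fn(act)(tape, sm)
  Vout <- NULL
  if (d$vout > 0L) {
    Vmu <- vec_linear(tape, Vh, p$Wv)
    gate <- ad_sigmoid(tape, ad_add_rowvec(tape, ad_matmul_t(tape, sout, p$Wg),
                                           p$bg))
    Vout <- lapply(Vmu, function(cm) ad_emul(tape, cm, gate))
  }
  list(s = sout, V = Vout)
}

#' Parameters for one GVP graph-convolution layer
#' @param s_h,v_h node hidden scalar width / vector count.
#' @param es,ev edge scalar width / vector count.
#' @param dropout dropout rate in [0, 1).
#' @export
gvp_conv_params <- function(s_h, v_h, es = 32L, ev = 1L, dropout = 0.1) {
  list(msg = gvp_params(s_h + es, v_h + ev, s_h, v_h),
       ln_gamma = ad_param(matrix(1, 1L, s_h)),
       ln_beta = ad_param(matrix(0, 1L, s_h)),
       dropout = dropout,
       dims = list(s_h = s_h, v_h = v_h))
}

#' One GVP graph-convolution layer
#'
#' Messages are one GVP transform of the concatenation (scalar-wise and
#' vector-wise) of the source-node state and the edge features, averaged over
#' each node's incoming edges, passed through dropout (train mode only),
#' added residually and normalized: LayerNorm on the scalar channel; the
#' vector channel is scaled by the reciprocal of its mean row norm.
#' @param tape autodiff tape.
#' @param graph a `protein_graph` (supplies edges and edge features).
#' @param s,V node state (n x s_h scalar node; vector channel list).
#' @param p parameters from [gvp_conv_params()].
#' @param train logical; enables dropout.
#' @param act scalar nonlinearity for the message GVP (default "relu").
#' @return updated list(s, V).
#' @export
gvp_conv_layer <- function(tape, graph, s, V, p, train = FALSE, act = "relu") {
  s <- ad_wrap(s); V <- vec_wrap(V)
  n <- graph$n_nodes
  src <- graph$edges$src; dst <- graph$edges$dst
  if (!length(src)) warning("graph has no edges; update is normalization only")

  ms <- ad_concat_cols(tape, list(ad_rows(tape, s, src), graph$edge_scalar))
  mV <- vec_concat(tape, list(vec_rows(tape, V, src),
                              vec_wrap(graph_edge_vectors(graph))))
  msg <- gvp_transform(tape, ms, mV, p$msg, act = act)

  as <- ad_group_mean(tape, msg$s, dst, n)
  aV <- lapply(msg$V, function(cm) ad_group_mean(tape, cm, dst, n))

  if (train && p$dropout > 0) {
    keep_s <- matrix(stats::runif(n * p$dims$s_h) >= p$dropout,
                     n, p$dims$s_h) / (1 - p$dropout)
    keep_v <- matrix(stats::runif(n * p$dims$v_h) >= p$dropout,
                     n, p$dims$v_h) / (1 - p$dropout)
    as <- ad_emul(tape, as, keep_s)
    aV <- lapply(aV, function(cm) ad_emul(tape, cm, keep_v))
  }

  s_new <- ad_layernorm_rows(tape, ad_add(tape, s, as), p$ln_gamma, p$ln_beta)
  V_res <- vec_add(tape, V, aV)
  tau <- ad_add_scalar(tape, ad_rowmeans(tape, vec_norms(tape, V_res)), 1e-6)
  inv <- ad_recip(tape, tau)
  V_new <- lapply(V_res, function(cm) ad_mul_colvec(tape, cm, inv))
  list(s = s_new, V = V_new)
}

#' Parameters for one GAT layer
#' @param nin,nout input/output width.
#' @param heads attention head count (default 1).
#' @export
gat_params <- function(nin, nout, heads = 1L) {
  stopifnot(nout %% heads == 0L)
  dh <- nout %/% heads
  list(heads = lapply(seq_len(heads), function(h) {
    list(W = ad_param(glorot(dh, nin)),
         a_src = ad_param(glorot(1L, dh)),
         a_dst = ad_param(glorot(1L, dh)))
  }), dims = list(nin = nin, nout = nout, nheads = heads))
}

#' One graph-attention layer
#'
#' The original GAT recipe: a shared linear map W, pairwise LeakyReLU
#' attention logits, softmax over each node's in-neighbourhood plus itself,
#' and an attention-weighted sum (the self term alpha_ii W h_i plus the
#' aggregated messages alpha_ij W h_j).
#' @param tape autodiff tape.
#' @param graph a `protein_graph` (only the edge list is used).
#' @param x n x nin node features (scalar only).
#' @param p parameters from [gat_params()].
#' @param act output nonlinearity (default "elu"; "identity" to disable).
#' @return n x nout node features.
#' @export
gat_layer <- function(tape, graph, x, p, act = "elu") {
  x <- ad_wrap(x)
  n <- graph$n_nodes
  src <- c(graph$edges$src, seq_len(n))
  dst <- c(graph$edges$dst, seq_len(n))
  outs <- lapply(p$heads, function(hp) {
    Wh <- ad_matmul_t(tape, x, hp$W)
    f_src <- ad_matmul_t(tape, Wh, hp$a_src)
    f_dst <- ad_matmul_t(tape, Wh, hp$a_dst)
    logits <- ad_leaky_relu(tape, ad_add(tape, ad_rows(tape, f_src, src),
                                         ad_rows(tape, f_dst, dst)), 0.2)
    # softmax per destination group (shift by detached per-group max)
    gmax <- vapply(split(as.numeric(logits$value), dst), max, numeric(1L))
    shift <- gmax[match(dst, as.integer(names(gmax)))]
    ex <- ad_exp(tape, ad_add(tape, logits, matrix(-shift, ncol = 1L)))
    denom <- ad_group_sum(tape, ex, dst, n)
    alpha <- ad_emul(tape, ex, ad_recip(tape, ad_rows(tape, denom, dst)))
    m <- ad_mul_colvec(tape, ad_rows(tape, Wh, src), alpha)
    ad_group_sum(tape, m, dst, n)
  })
  out <- if (length(outs) > 1L) ad_concat_cols(tape, outs) else outs[[1L]]
  act_fn(act)(tape, out)
}

#' Concatenate per-layer node features and pool over residues
#'
#' @param layer_outputs list of n x w matrices (or adnodes), one per layer.
#' @param pool "sum" or "mean".
#' @param mask logical valid-node flags (default all TRUE).
#' @return 1 x (sum of widths) matrix.
#' @export
readout <- function(layer_outputs, pool = c("mean", "sum"), mask = NULL) {
  pool <- match.arg(pool)
  mats <- lapply(layer_outputs, ad_value)
  n <- nrow(mats[[1L]])
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!any(mask)) stop("empty mask")
  h <- do.call(cbind, mats)[mask, , drop = FALSE]
  matrix(if (pool == "sum") colSums(h) else colMeans(h), nrow = 1L)
}

# tape version of readout for scalar channels
ad_readout <- function(tape, layer_outputs, pool = "mean", mask = NULL) {
  h <- ad_concat_cols(tape, layer_outputs)
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty mask")
    h <- ad_rows(tape, h, which(mask))
  }
  if (pool == "sum") ad_colsums(tape, h) else ad_colmeans(tape, h)
}
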