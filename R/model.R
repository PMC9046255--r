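# Model assembly for the four families: sequence-only ([CLS] head),
# structure-only GNNs (GVP or GAT), and the sequence+structure hybrids
# (two-stage with a frozen LM, or end-to-end). Also the losses and the
# class-imbalance label weights.

#' Model dimension settings
#'
#' @param s_h,v_h GVP hidden scalar width and vector count per node.
#' @param gat_width GAT hidden width.
#' @param n_layers number of graph-convolution layers.
#' @param penultimate width of the dense layer between readout and task head.
#' @param k neighbour count for graph construction.
#' @param dropout message dropout rate.
#' @param act scalar nonlinearity used throughout the model ("tanh" by
#'   default: a smooth activation keeps integrated-gradients quadrature
#'   convergent; "relu" and others are accepted).
#' @return list of dimensions.
#' @export
model_dims <- function(s_h = 100L, v_h = 16L, gat_width = 100L, n_layers = 3L,
                       penultimate = 400L, k = 30L, dropout = 0.1,
                       act = "tanh") {
  list(s_h = s_h, v_h = v_h, gat_width = gat_width, n_layers = n_layers,
       penultimate = penultimate, k = k, dropout = dropout, act = act)
}

NODE_SCALAR_BASE <- 27L  # 6 dihedral terms + 21-way one-hot

#' Assemble a property-prediction model
#'
#' Families: `seq_only` (linear head on the pooled [CLS] token), `gat` /
#' `gvp` (structure-only graph networks; GAT consumes the one-hot residue
#' identity, GVP the full 27-wide scalar channel plus vector features),
#' `hybrid_gat` (LM embeddings replace the one-hot features) and
#' `hybrid_gvp` (LM embeddings concatenated to the scalar channel). Hybrids
#' take `mode` "two_stage" (LM permanently frozen) or "end_to_end" (LM
#' transformer layers unfrozen in the second training phase). Two-stage and
#' end-to-end hybrids have identical parameter sets; they differ only in
#' which parameters are trainable.
#'
#' @param family one of "seq_only", "gat", "gvp", "hybrid_gat", "hybrid_gvp".
#' @param mode "two_stage" or "end_to_end" (hybrids only).
#' @param task "multilabel" or "regression".
#' @param n_outputs number of labels (1 for regression).
#' @param dims from [model_dims()].
#' @param lm a `stub_lm` (required for seq_only and hybrids).
#' @param seed parameter-initialization seed.
#' @return object of class `geoprot_model`.
#' @export
build_model <- function(family = c("seq_only", "gat", "gvp", "hybrid_gat",
                                   "hybrid_gvp"),
                        mode = c("end_to_end", "two_stage"),
                        task = c("multilabel", "regression"),
                        n_outputs = 1L, dims = model_dims(), lm = NULL,
                        seed = 1L) {
  family <- match.arg(family)
  task <- match.arg(task)
  hybrid <- family %in% c("hybrid_gat", "hybrid_gvp")
  if (!hybrid && !missing(mode) && mode[1L] == "two_stage") {
    stop("mode 'two_stage' is only valid for hybrid families")
  }
  mode <- if (hybrid) match.arg(mode) else "none"
  needs_lm <- hybrid || family == "seq_only"
  if (needs_lm && is.null(lm)) lm <- stub_lm()
  h <- if (needs_lm) lm$h else 0L

  params <- local_seed(seed, {
    switch(family,
      seq_only = list(
        W_out = ad_param(glorot(n_outputs, h)),
        b_out = ad_param(matrix(0, 1L, n_outputs))),
      gat = ,
      hybrid_gat = {
        nin <- if (family == "gat") 21L else h  # one-hot replaced by embeddings
        w <- dims$gat_width
        list(layers = c(list(gat_params(nin, w)),
                        lapply(seq_len(dims$n_layers - 1L),
                               function(i) gat_params(w, w))),
             W_pen = ad_param(glorot(dims$penultimate, dims$n_layers * w)),
             b_pen = ad_param(matrix(0, 1L, dims$penultimate)),
             W_out = ad_param(glorot(n_outputs, dims$penultimate)),
             b_out = ad_param(matrix(0, 1L, n_outputs)))
      },
      gvp = ,
      hybrid_gvp = {
        a_in <- NODE_SCALAR_BASE + if (family == "hybrid_gvp") h else 0L
        ro <- dims$n_layers * (dims$s_h + dims$v_h)
        list(in_proj = gvp_params(a_in, 3L, dims$s_h, dims$v_h),
             layers = lapply(seq_len(dims$n_layers), function(i)
               gvp_conv_params(dims$s_h, dims$v_h, dropout = dims$dropout)),
             W_pen = ad_param(glorot(dims$penultimate, ro)),
             b_pen = ad_param(matrix(0, 1L, dims$penultimate)),
             W_out = ad_param(glorot(n_outputs, dims$penultimate)),
             b_out = ad_param(matrix(0, 1L, n_outputs)))
      })
  })
  structure(list(family = family, mode = mode, task = task,
                 n_outputs = n_outputs, dims = dims, lm = lm,
                 params = params, seed = seed),
            class = "geoprot_model")
}

#' @export
print.geoprot_model <- function(x, ...) {
  cat(sprintf("<geoprot_model> family=%s mode=%s task=%s outputs=%d\n",
              x$family, x$mode, x$task, x$n_outputs))
  np <- sum(vapply(flatten_params(model_struct_params(x)),
                   function(p) length(p$value), numeric(1L)))
  cat(sprintf("  %d head/GNN parameters%s\n", np,
              if (!is.null(x$lm)) sprintf(" + LM (h=%d)", x$lm$h) else ""))
  invisible(x)
}

flatten_params <- function(x, prefix = "") {
  if (is_adnode(x)) {
    out <- list(x); names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    nms[nms == ""] <- as.character(which(nms == ""))
    for (i in seq_along(x)) {
      if (nms[i] %in% c("dims", "dropout")) next
      out <- c(out, flatten_params(x[[i]],
                                   if (prefix == "") nms[i]
                                   else paste0(prefix, ".", nms[i])))
    }
    return(out)
  }
  list()
}

model_struct_params <- function(model) flatten_params(model$params)

# trainable parameters for a training phase: LM parameters join only when the
# LM is unfrozen (seq_only always fine-tunes the LM; hybrids only in
# end-to-end phase 2)
model_trainable <- function(model, lm_unfrozen = FALSE) {
  ps <- model_struct_params(model)
  if (!is.null(model$lm) && (lm_unfrozen || model$family == "seq_only")) {
    lmp <- lm_trainable_params(model$lm)
    names(lmp) <- paste0("lm.", seq_along(lmp))
    ps <- c(ps, lmp)
  }
  ps
}

# geometry-only graph for one structure (embeddings enter on the tape)
model_featurize <- function(model, struct) {
  featurize_graph(struct, mode = "onehot", k = model$dims$k)
}

#' Forward pass of a model on one protein
#'
#' Returns the 1 x n_outputs logit node for a single example on the given
#' tape (so gradients can be taken through it).
#' @param tape autodiff tape from [ad_tape()].
#' @param model a `geoprot_model`.
#' @param graph `protein_graph` of the protein (geometry features; not used
#'   by seq_only models).
#' @param aa sequence string (needed when the LM runs on the tape).
#' @param embeddings precomputed L x h embedding matrix for hybrids (frozen
#'   LM); NULL to run the LM on the tape.
#' @param train logical; enables dropout.
#' @return an `adnode` of logits.
#' @export
model_forward <- function(tape, model, graph, aa = NULL, embeddings = NULL,
                          train = FALSE) {
  fam <- model$family
  if (fam == "seq_only") {
    pooled <- lm_pooled_ad(tape, model$lm, aa_tokens(aa))
    return(ad_add_rowvec(tape, ad_matmul_t(tape, pooled, model$params$W_out),
                         model$params$b_out))
  }
  emb_node <- NULL
  if (fam %in% c("hybrid_gat", "hybrid_gvp")) {
    emb_node <- if (is.null(embeddings)) lm_embed_ad(tape, model$lm, aa)
                else ad_wrap(embeddings)
  }
  p <- model$params
  if (fam %in% c("gat", "hybrid_gat")) {
    x <- if (fam == "gat") graph$node_scalar[, 7:27, drop = FALSE] else emb_node
    outs <- vector("list", length(p$layers))
    for (i in seq_along(p$layers)) {
      x <- gat_layer(tape, graph, x, p$layers[[i]])
      outs[[i]] <- x
    }
    pooled <- ad_readout(tape, outs, pool = "sum")
  } else {
    s <- if (fam == "hybrid_gvp")
      ad_concat_cols(tape, list(emb_node, graph$node_scalar))
    else ad_wrap(graph$node_scalar)
    V <- vec_wrap(graph_node_vectors(graph))
    act <- model_act(model)
    st <- gvp_transform(tape, s, V, p$in_proj, act = act)
    ss <- vector("list", length(p$layers)); Vs <- vector("list", length(p$layers))
    for (i in seq_along(p$layers)) {
      st <- gvp_conv_layer(tape, graph, st$s, st$V, p$layers[[i]],
                           train = train, act = act)
      ss[[i]] <- st$s; Vs[[i]] <- st$V
    }
    s_pool <- ad_readout(tape, ss, pool = "mean")
    Vcat <- vec_concat(tape, Vs)
    Vpool <- lapply(Vcat, function(cm) ad_colmeans(tape, cm))
    pooled <- ad_concat_cols(tape, list(s_pool,
                                        vec_norms(tape, Vpool)))
  }
  pen <- act_fn(model_act(model))(
    tape, ad_add_rowvec(tape, ad_matmul_t(tape, pooled, p$W_pen), p$b_pen))
  ad_add_rowvec(tape, ad_matmul_t(tape, pen, p$W_out), p$b_out)
}

# model-wide scalar nonlinearity (older dims lists may lack the field)
model_act <- function(model) {
  if (is.null(model$dims$act)) "tanh" else model$dims$act
}

#' Class-imbalance label weights
#'
#' w_j = max(1, min(10, sum_i N_i+ / (l * N_j+))): the inverse positive
#' frequency of label j relative to the average, clamped to [1, 10]. Labels
#' with no positives get the clamp limit 10 with a warning.
#' @param labels N x l binary matrix.
#' @return length-l numeric weight vector.
#' @export
compute_label_weights <- function(labels) {
  labels <- as.matrix(labels)
  npos <- colSums(labels)
  l <- ncol(labels)
  if (any(npos == 0)) warning("label(s) with no positive instances: weight clamped to 10")
  w <- sum(npos) / (l * npos)
  w[!is.finite(w)] <- 10
  pmin(10, pmax(1, w))
}

#' Training loss
#'
#' Regression: mean squared error. Multi-label: binary cross-entropy on
#' logits, label j weighted by w_j (both its positive and negative terms),
#' averaged over labels and batch.
#' @param predictions n x l logits (multilabel) or numeric predictions
#'   (regression).
#' @param targets matching targets.
#' @param task_kind "multilabel" or "regression".
#' @param weights optional length-l label weights (multilabel).
#' @return non-negative scalar.
#' @export
loss <- function(predictions, targets, task_kind = c("multilabel",
                                                     "regression"),
                 weights = NULL) {
  task_kind <- match.arg(task_kind)
  predictions <- as.matrix(predictions); targets <- as.matrix(targets)
  if (any(!is.finite(predictions))) stop("non-finite predictions")
  stopifnot(all(dim(predictions) == dim(targets)))
  if (task_kind == "regression") {
    return(mean((predictions - targets)^2))
  }
  w <- if (is.null(weights)) rep(1, ncol(targets)) else weights
  wmat <- matrix(w, nrow(targets), ncol(targets), byrow = TRUE)
  z <- predictions
  elem <- pmax(z, 0) - z * targets + log1p(exp(-abs(z)))
  mean(wmat * elem)
}

ad_loss <- function(tape, logits, target, task_kind, weights = NULL) {
  if (task_kind == "regression") ad_mse(tape, logits, target)
  else ad_bce_logits(tape, logits, target, weights)
}

#' Predict from a model
#'
#' @param object a `geoprot_model`.
#' @param structures list of `backbone_structure` (ignored by seq_only when
#'   `sequences` given).
#' @param sequences optional character vector of sequences (defaults to the
#'   structures' sequences).
#' @param type "response" (probabilities for multilabel) or "link" (logits).
#' @param ... unused.
#' @return n x n_outputs matrix.
#' @export
predict.geoprot_model <- function(object, structures = NULL, sequences = NULL,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(sequences)) sequences <- vapply(structures, aa_sequence, character(1L))
  n <- max(length(structures), length(sequences))
  out <- matrix(NA_real_, n, object$n_outputs)
  needs_emb <- object$family %in% c("hybrid_gat", "hybrid_gvp")
  for (i in seq_len(n)) {
    tape <- ad_tape()
    graph <- if (object$family != "seq_only")
      model_featurize(object, structures[[i]]) else NULL
    emb <- if (needs_emb) embed_sequence(object$lm, sequences[i]) else NULL
    z <- model_forward(tape, object, graph, aa = sequences[i],
                       embeddings = emb, train = FALSE)
    out[i, ] <- ad_value(z)
  }
  if (type == "response" && object$task == "multilabel") out <- stats::plogis(out)
  out
}

#' Save / load model parameters as a JSON archive
#'
#' The archive is a JSON object mapping parameter paths to their values with
#' an explicit shape manifest; the model skeleton (family, dims, LM seed) is
#' stored alongside so [load_model_params()] can validate shapes.
#' @param model a `geoprot_model`.
#' @param path output file.
#' @export
save_model_params <- function(model, path) {
  ps <- model_trainable(model, lm_unfrozen = TRUE)
  obj <- list(
    family = model$family, mode = model$mode, task = model$task,
    n_outputs = model$n_outputs, dims = model$dims,
    shapes = lapply(ps, function(p) dim(p$value)),
    values = lapply(ps, function(p) as.numeric(p$value)))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model_params
#' @export
load_model_params <- function(model, path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ps <- model_trainable(model, lm_unfrozen = TRUE)
  stopifnot(setequal(names(ps), names(obj$shapes)))
  for (nm in names(ps)) {
    sh <- as.integer(obj$shapes[[nm]])
    if (!all(dim(ps[[nm]]$value) == sh)) stop("shape mismatch for ", nm)
    ps[[nm]]$value <- matrix(obj$values[[nm]], sh[1L], sh[2L])
  }
  invisible(model)
}
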