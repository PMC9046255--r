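# Training: Adam optimization with early stopping, hyper-parameter grid
# search, and the gradual-unfreezing schedule for end-to-end hybrids
# (phase 1 trains the GNN/head with the LM frozen until the validation loss
# stops improving; phase 2 unfreezes the LM transformer layers and
# re-initializes the optimizer state).

#' Training configuration
#'
#' Defaults: Adam with beta1 = 0.9,
#' beta2 = 0.999; early stopping with patience 10; at most 200 epochs;
#' learning-rate grid {1e-4, 1e-5, 1e-6} x batch-size grid {16, 32} selected
#' by validation loss.
#' @param lr_grid learning rates to search.
#' @param batch_grid batch sizes to search.
#' @param beta1,beta2 Adam moment decays.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs cap on epochs per phase.
#' @param phase2_max_epochs cap for the unfrozen phase (0 disables phase 2,
#'   making end-to-end training identical to two-stage).
#' @param seed RNG seed for shuffling, dropout and initialization.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr_grid = c(1e-4, 1e-5, 1e-6), batch_grid = c(16L, 32L),
                         beta1 = 0.9, beta2 = 0.999, patience = 10L,
                         max_epochs = 200L, phase2_max_epochs = NULL,
                         seed = 1L) {
  stopifnot(length(lr_grid) >= 1L, length(batch_grid) >= 1L, patience >= 1L)
  structure(list(lr_grid = lr_grid, batch_grid = batch_grid, beta1 = beta1,
                 beta2 = beta2, patience = patience,
                 max_epochs = as.integer(max_epochs),
                 phase2_max_epochs = if (is.null(phase2_max_epochs))
                   as.integer(max_epochs) else as.integer(phase2_max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p$value * 0, v = p$value * 0))
}

adam_step <- function(params, state, lr, beta1, beta2, t, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * p$grad
    st$v <- beta2 * st$v + (1 - beta2) * p$grad^2
    p$value <- p$value - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    state[[i]] <- st
  }
  state
}

snapshot_params <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}

# mean loss over a set of examples; when `grad_scale` is non-NULL the scaled
# gradient of each example's loss is accumulated into the parameters
run_examples <- function(model, cache, idx, weights, train = FALSE,
                         grad_scale = NULL, lm_on_tape = FALSE) {
  tot <- 0
  for (i in idx) {
    ex <- cache[[i]]
    tape <- ad_tape()
    emb <- if (ex$needs_emb && !lm_on_tape) ex$embeddings else NULL
    z <- model_forward(tape, model, ex$graph, aa = ex$aa, embeddings = emb,
                       train = train)
    l <- ad_loss(tape, z, ex$target, model$task, weights)
    tot <- tot + l$value[1L]
    if (!is.null(grad_scale)) ad_backward(tape, l, seed = grad_scale)
  }
  tot / length(idx)
}

train_phase <- function(model, cache, train_idx, val_idx, weights, config,
                        lr, batch_size, phase, lm_unfrozen, max_epochs,
                        epoch_offset = 0L) {
  params <- model_trainable(model, lm_unfrozen = lm_unfrozen)
  state <- adam_init(params)
  t_step <- 0L
  best_val <- Inf
  best_snap <- snapshot_params(params)
  since_best <- 0L
  hist <- NULL
  lm_on_tape <- lm_unfrozen || model$family == "seq_only"
  for (epoch in seq_len(max_epochs)) {
    ord <- train_idx[sample.int(length(train_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0
    for (b in batches) {
      ad_zero_grad(params)
      ep_loss <- ep_loss + length(b) * run_examples(
        model, cache, b, weights, train = TRUE, grad_scale = 1 / length(b),
        lm_on_tape = lm_on_tape)
      if (any(vapply(params, function(p)
        !is.null(p$grad) && any(!is.finite(p$grad)), logical(1L)))) {
        stop("training diverged: non-finite gradient")
      }
      t_step <- t_step + 1L
      state <- adam_step(params, state, lr, config$beta1, config$beta2, t_step)
    }
    train_loss <- ep_loss / length(train_idx)
    if (!is.finite(train_loss)) stop("training diverged: non-finite loss")
    val_loss <- run_examples(model, cache, val_idx, weights,
                             lm_on_tape = lm_on_tape)
    hist <- rbind(hist, data.frame(epoch = epoch_offset + epoch, phase = phase,
                                   train_loss = train_loss,
                                   val_loss = val_loss, lr = lr,
                                   batch_size = batch_size))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_snap <- snapshot_params(params)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  restore_params(params, best_snap)
  list(history = hist, best_val = best_val)
}

#' Fit a protein property model
#'
#' The central fitting function: builds (or reuses) a model of the requested
#' family, runs the training protocol over the hyper-parameter grid and
#' returns the best fit. Hybrids with `mode = "end_to_end"` use gradual
#' unfreezing: phase 1 trains the GNN and head with the LM frozen until the
#' validation loss stops improving (the stated early-stopping criterion);
#' phase 2 unfreezes the LM transformer layers, re-initializes the Adam
#' state, and continues. The best-validation-loss weights are restored at
#' every stage, so the end-to-end fit can never end with a worse validation
#' loss than the corresponding two-stage fit at the same seed.
#'
#' @param structures list of `backbone_structure` training inputs.
#' @param labels numeric vector (regression) or n x l binary matrix
#'   (multilabel).
#' @param task_kind "multilabel" or "regression".
#' @param family,mode,dims,lm,n_outputs passed to [build_model()].
#' @param config a [train_config()].
#' @param val_fraction held-out fraction when `val_idx` is not given.
#' @param val_idx optional explicit validation indices.
#' @return object of class `geoprot_fit`: the fitted `model`, per-epoch
#'   `history` (with phase boundaries), the selected grid point, label
#'   weights, and the data split.
#' @export
geoprot_fit <- function(structures, labels, task_kind = c("multilabel",
                                                          "regression"),
                        family = "gvp", mode = "end_to_end",
                        dims = model_dims(), lm = NULL,
                        config = train_config(), val_fraction = 0.2,
                        val_idx = NULL) {
  task_kind <- match.arg(task_kind)
  labels <- if (task_kind == "multilabel") as.matrix(labels)
            else matrix(as.numeric(labels), ncol = 1L)
  n <- length(structures)
  stopifnot(n == nrow(labels), n >= 2L)
  n_outputs <- ncol(labels)
  weights <- if (task_kind == "multilabel") compute_label_weights(labels)
             else NULL

  set.seed(config$seed)
  if (is.null(val_idx)) {
    val_idx <- sample.int(n, max(1L, round(val_fraction * n)))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  stopifnot(length(train_idx) >= 1L)

  base <- build_model(family = family, mode = mode, task = task_kind,
                      n_outputs = n_outputs, dims = dims, lm = lm,
                      seed = config$seed)
  needs_graph <- family != "seq_only"
  needs_emb <- family %in% c("hybrid_gat", "hybrid_gvp")
  cache <- lapply(seq_len(n), function(i) {
    s <- structures[[i]]
    aa <- aa_sequence(s)
    list(aa = aa,
         graph = if (needs_graph) model_featurize(base, s) else NULL,
         embeddings = if (needs_emb) embed_sequence(base$lm, aa) else NULL,
         needs_emb = needs_emb,
         target = labels[i, , drop = FALSE])
  })

  best <- NULL
  for (lr in config$lr_grid) for (bs in config$batch_grid) {
    set.seed(config$seed)
    model <- build_model(family = family, mode = mode, task = task_kind,
                         n_outputs = n_outputs, dims = dims,
                         lm = if (is.null(lm)) base$lm else lm,
                         seed = config$seed)
    ph1 <- train_phase(model, cache, train_idx, val_idx, weights, config,
                       lr = lr, batch_size = bs, phase = 1L,
                       lm_unfrozen = FALSE, max_epochs = config$max_epochs)
    history <- ph1$history
    best_val <- ph1$best_val
    if (needs_emb && model$mode == "end_to_end" &&
        config$phase2_max_epochs > 0L) {
      snap_all <- snapshot_params(model_trainable(model, lm_unfrozen = TRUE))
      ph2 <- train_phase(model, cache, train_idx, val_idx, weights, config,
                         lr = lr, batch_size = bs, phase = 2L,
                         lm_unfrozen = TRUE,
                         max_epochs = config$phase2_max_epochs,
                         epoch_offset = max(history$epoch))
      history <- rbind(history, ph2$history)
      if (ph2$best_val <= best_val) {
        best_val <- ph2$best_val
      } else {
        restore_params(model_trainable(model, lm_unfrozen = TRUE), snap_all)
      }
    }
    if (is.null(best) || best_val < best$val_loss) {
      best <- list(model = model, history = history, val_loss = best_val,
                   lr = lr, batch_size = bs)
    }
  }

  structure(list(model = best$model, history = best$history,
                 val_loss = best$val_loss,
                 lr = best$lr, batch_size = best$batch_size,
                 label_weights = weights, config = config,
                 train_idx = train_idx, val_idx = val_idx,
                 task_kind = task_kind),
            class = "geoprot_fit")
}

#' @export
print.geoprot_fit <- function(x, ...) {
  cat(sprintf("<geoprot_fit> %s (%s), %s task\n", x$model$family,
              x$model$mode, x$task_kind))
  cat(sprintf("  selected lr=%g batch=%d; best validation loss %.6g\n",
              x$lr, x$batch_size, x$val_loss))
  cat(sprintf("  %d epoch(s) over %d phase(s)\n", nrow(x$history),
              length(unique(x$history$phase))))
  invisible(x)
}

#' @export
summary.geoprot_fit <- function(object, ...) {
  print(object)
  ph <- split(object$history, object$history$phase)
  for (p in ph) {
    cat(sprintf("  phase %d: epochs %d-%d, final val loss %.6g\n",
                p$phase[1L], min(p$epoch), max(p$epoch),
                p$val_loss[nrow(p)]))
  }
  invisible(object)
}

#' @export
predict.geoprot_fit <- function(object, structures = NULL, sequences = NULL,
                                type = c("response", "link"), ...) {
  predict(object$model, structures = structures, sequences = sequences,
          type = type, ...)
}

#' @export
plot.geoprot_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  for (b in which(diff(h$phase) != 0)) graphics::abline(v = h$epoch[b] + 0.5,
                                                        lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.geoprot_fit <- function(object, structures, labels, ...) {
  if (object$task_kind != "regression")
    stop("residuals are defined for regression fits")
  as.numeric(labels) - as.numeric(predict(object, structures))
}
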