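# Evaluation metrics: micro / per-label area under the precision-recall
# curve, protein-centric Fmax (CAFA convention), and Spearman rank
# correlation for regression tasks.

aupr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels)
  if (npos == 0L) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  r_prev <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    p <- tp / sum(sel)
    r <- tp / npos
    area <- area + (r - r_prev) * p
    r_prev <- r
  }
  area
}

#' Protein-centric Fmax
#'
#' CAFA-style maximum F1 over score thresholds: at each threshold tau,
#' precision is averaged over proteins with at least one predicted label and
#' recall over all proteins; Fmax is the maximum harmonic mean. The
#' threshold grid is all distinct predicted scores plus {0, 1}.
#' @param pred n x l matrix of scores in [0, 1].
#' @param labels n x l binary matrix.
#' @return list(fmax, tau) with the maximizing threshold.
#' @export
fmax_protein_centric <- function(pred, labels) {
  stopifnot(all(dim(pred) == dim(labels)))
  has_true <- rowSums(labels) > 0
  taus <- sort(unique(c(0, 1, as.numeric(pred))))
  best <- 0; best_tau <- 0
  for (tau in taus) {
    dec <- pred >= tau
    npred <- rowSums(dec)
    tp <- rowSums(dec & labels == 1)
    covered <- npred > 0
    if (!any(covered)) next
    prec <- mean(tp[covered] / npred[covered])
    rec_terms <- tp[has_true] / rowSums(labels)[has_true]
    rec <- if (any(has_true)) mean(rec_terms) else 0
    if (prec + rec > 0) {
      f <- 2 * prec * rec / (prec + rec)
      if (f > best) { best <- f; best_tau <- tau }
    }
  }
  list(fmax = best, tau = best_tau)
}

#' Evaluate predictions against labels
#'
#' Multi-label tasks: micro-AUPR pooling all (protein, label) decisions,
#' per-label AUPR, and protein-centric Fmax. Regression tasks: Spearman rank
#' correlation (average ranks on ties); NA with a warning when either side
#' is constant.
#' @param predictions n x l score matrix (probabilities for multilabel) or
#'   numeric vector (regression).
#' @param labels matching binary matrix or numeric vector.
#' @param task_kind "multilabel" or "regression".
#' @return named list of metrics.
#' @export
evaluate <- function(predictions, labels, task_kind = c("multilabel",
                                                        "regression")) {
  task_kind <- match.arg(task_kind)
  if (task_kind == "regression") {
    x <- as.numeric(predictions); y <- as.numeric(labels)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("Spearman rho undefined for constant input")
      return(list(spearman = NA_real_))
    }
    return(list(spearman = stats::cor(x, y, method = "spearman")))
  }
  pred <- as.matrix(predictions); lab <- as.matrix(labels)
  stopifnot(all(dim(pred) == dim(lab)))
  if (any(pred < 0 | pred > 1)) stop("multilabel predictions must be in [0,1]")
  per_label <- vapply(seq_len(ncol(pred)), function(j)
    aupr_curve(pred[, j], lab[, j]), numeric(1L))
  list(micro_aupr = aupr_curve(as.numeric(pred), as.numeric(lab)),
       per_label_aupr = per_label,
       fmax = fmax_protein_centric(pred, lab)$fmax)
}

#' Spearman rank correlation between variant scores and assay values
#'
#' @param scores,assay numeric vectors of equal length (>= 3 records).
#' @return rho in [-1, 1]; NA with a warning for constant input.
#' @export
scan_correlation <- function(scores, assay) {
  stopifnot(length(scores) == length(assay), length(scores) >= 3L)
  if (stats::sd(scores) == 0 || stats::sd(assay) == 0) {
    warning("Spearman rho undefined for constant input")
    return(NA_real_)
  }
  stats::cor(scores, assay, method = "spearman")
}

#' Rank-based AUROC with average-rank tie handling
#'
#' Mann-Whitney formulation: the probability that a random positive outranks
#' a random negative.
#' @param scores numeric vector.
#' @param labels binary vector with at least one positive and one negative.
#' @return AUROC in [0, 1].
#' @export
rank_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  n1 <- sum(labels); n0 <- sum(1 - labels)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: degenerate labels")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
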