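# Contact-map probing: ground-truth contacts from structure, per-pair
# attention features from the language model, an L1-penalized logistic
# probe, and precision-at-L evaluation.

#' Ground-truth contact map from C-alpha distances
#'
#' Entry (i, j) is 1 iff the C-alpha distance is <= `threshold` Angstrom and
#' |i - j| >= `min_sep` (local contacts ignored). Symmetric, zero diagonal.
#' @param struct a `backbone_structure`.
#' @param threshold distance cutoff (default 10 A).
#' @param min_sep minimum sequence separation (default 6).
#' @return L x L binary matrix with attributes `threshold` and `min_sep`.
#' @export
true_contacts <- function(struct, threshold = 10, min_sep = 6L) {
  d <- as.matrix(stats::dist(struct$coords_CA))
  L <- nrow(d)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  cm <- (d <= threshold & sep >= min_sep) * 1L
  attr(cm, "threshold") <- threshold
  attr(cm, "min_sep") <- min_sep
  cm
}

#' Per-pair attention features
#'
#' One row per unordered residue pair (i < j, j - i >= `min_sep`); one
#' feature per (layer, head): the symmetrized attention (A[i,j] + A[j,i]) / 2.
#' @param maps attention maps from [attention_maps()].
#' @param min_sep minimum sequence separation (default 6, matching
#'   [true_contacts()]).
#' @param contacts optional contact map supplying per-pair labels.
#' @return list: `features` (n_pairs x n_layer*n_head matrix), `pairs`
#'   (n_pairs x 2), `labels` (or NULL).
#' @export
attention_pair_features <- function(maps, min_sep = 6L, contacts = NULL) {
  L <- nrow(maps[[1L]][[1L]])
  if (!is.null(contacts) && nrow(contacts) != L)
    stop("contact map size does not match attention maps")
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  keep <- idx[, 2L] - idx[, 1L] >= min_sep
  pairs <- idx[keep, , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  feats <- do.call(cbind, lapply(seq_along(maps), function(l)
    do.call(cbind, lapply(seq_along(maps[[l]]), function(h) {
      A <- maps[[l]][[h]]
      (A[pairs] + A[pairs[, c(2L, 1L), drop = FALSE]]) / 2
    }))))
  colnames(feats) <- unlist(lapply(seq_along(maps), function(l)
    paste0("l", l, "h", seq_along(maps[[l]]))))
  labels <- if (!is.null(contacts)) contacts[pairs] else NULL
  list(features = feats, pairs = pairs, labels = labels)
}

#' Fit the L1-penalized logistic contact probe
#'
#' Pools pair rows across proteins and fits an L1-penalized logistic
#' regression (per-sample-averaged loss, so duplicating rows leaves the
#' solution unchanged). The penalty strength is selected from `lambda_grid`
#' by log-loss on an internal held-out split.
#' @param tables list of tables from [attention_pair_features()] (each must
#'   carry `labels`), or a single table.
#' @param lambda_grid L1 strengths to try (default a small geometric grid).
#' @param holdout fraction of rows held out for lambda selection.
#' @param seed seed for the selection split.
#' @return a `contact_probe`: list(weights, intercept, lambda, feature_names).
#' @export
fit_contact_probe <- function(tables, lambda_grid = 10^seq(-1, -4),
                              holdout = 0.2, seed = 1L) {
  if (!is.null(tables$features)) tables <- list(tables)
  X <- do.call(rbind, lapply(tables, `[[`, "features"))
  y <- unlist(lapply(tables, `[[`, "labels"))
  if (is.null(y)) stop("tables must carry contact labels")
  if (length(unique(y)) < 2L) stop("single-class training data")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  sel <- local_seed(seed, sample.int(nrow(X), max(1L, round(holdout * nrow(X)))))
  fit <- glmnet::glmnet(X[-sel, , drop = FALSE], y[-sel], family = "binomial",
                        alpha = 1, lambda = lambda_grid, standardize = TRUE,
                        thresh = 1e-6)
  pv <- stats::predict(fit, X[sel, , drop = FALSE], type = "response")
  eps <- 1e-12
  ll <- apply(pv, 2L, function(p)
    -mean(y[sel] * log(pmax(p, eps)) + (1 - y[sel]) * log(pmax(1 - p, eps))))
  best <- fit$lambda[which.min(ll)]
  # refit on all rows at the selected strength
  fit2 <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                         lambda = lambda_grid, standardize = TRUE,
                         thresh = 1e-6)
  co <- as.numeric(stats::coef(fit2, s = best))
  structure(list(weights = stats::setNames(co[-1L], colnames(X)),
                 intercept = co[1L], lambda = best,
                 feature_names = colnames(X)),
            class = "contact_probe")
}

#' @export
print.contact_probe <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf("<contact_probe> lambda=%.3g, %d/%d nonzero weights\n",
              x$lambda, nz, length(x$weights)))
  invisible(x)
}

#' Predicted contact probabilities for a pair-feature table
#' @param object a `contact_probe`.
#' @param table output of [attention_pair_features()].
#' @param ... unused.
#' @return numeric vector of probabilities, one per pair row.
#' @export
predict.contact_probe <- function(object, table, ...) {
  eta <- as.numeric(table$features %*% object$weights) + object$intercept
  stats::plogis(eta)
}

#' Contact precision at L
#'
#' Ranks pairs by predicted probability and reports the fraction of true
#' contacts among the top-L pairs (L = protein length). When fewer than L
#' eligible pairs exist, all pairs are used and the result is flagged.
#' @param probe a `contact_probe`, or a numeric vector of scores aligned
#'   with `table` rows.
#' @param table pair-feature table with `labels`.
#' @param L protein length.
#' @return precision in [0, 1], with attribute `flagged_all_pairs` when the
#'   pair list was shorter than L. Empty contact maps give 0 with a warning.
#' @export
probe_precision <- function(probe, table, L) {
  scores <- if (inherits(probe, "contact_probe")) predict(probe, table)
            else as.numeric(probe)
  y <- table$labels
  if (sum(y) == 0L) {
    warning("contact map is empty; precision is 0")
    return(structure(0, flagged_all_pairs = FALSE))
  }
  flagged <- length(scores) < L
  top <- order(scores, decreasing = TRUE)[seq_len(min(L, length(scores)))]
  structure(mean(y[top]), flagged_all_pairs = flagged)
}

#' Serialize a contact map as a TSV edge list
#' @param cm contact map from [true_contacts()].
#' @param path output file.
#' @export
write_contact_map <- function(cm, path) {
  idx <- which(cm == 1L & upper.tri(cm), arr.ind = TRUE)
  utils::write.table(data.frame(i = idx[, 1L], j = idx[, 2L]), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
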