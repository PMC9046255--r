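# Integrated-gradients residue saliency. Attribution surface: the L x h
# per-residue embedding matrix feeding the network (language-model output
# for hybrids and seq-only models; the residue-identity block of the scalar
# channel for structure-only models). The baseline is the embedding of a
# same-length all-[SEP] sequence; coordinates are never interpolated.

#' Integrated gradients of a differentiable functional
#'
#' Midpoint-rule approximation of the path integral
#' (x - x') * mean over alpha of dF/dx evaluated at x' + alpha (x - x'),
#' with alpha at the midpoints of `steps` equal subintervals. Exact for
#' linear F at any step count.
#'
#' @param F a function(tape, x_node) returning a scalar adnode: the model
#'   output being explained as a function of the attribution surface.
#' @param x original input matrix.
#' @param x_baseline baseline matrix (same shape).
#' @param steps number of interpolation points (>= 1).
#' @return list: `attribution` (same shape as x), `completeness_gap`
#'   (relative gap |sum(attr) - (F(x) - F(x'))| / |F(x) - F(x')|), `steps`,
#'   and the endpoint values `f_x`, `f_baseline`.
#' @export
integrated_gradients <- function(F, x, x_baseline, steps = 64L) {
  stopifnot(steps >= 1L, all(dim(x) == dim(x_baseline)))
  dx <- x - x_baseline
  gsum <- 0 * x
  for (t in seq_len(steps)) {
    alpha <- (t - 0.5) / steps
    tape <- ad_tape()
    xn <- ad_new(x_baseline + alpha * dx, track = TRUE)
    out <- F(tape, xn)
    ad_backward(tape, out)
    if (is.null(xn$grad) || any(!is.finite(xn$grad))) {
      stop(sprintf("non-finite gradient at interpolation step %d", t))
    }
    gsum <- gsum + xn$grad
  }
  attribution <- dx * gsum / steps
  ev <- function(xm) {
    tape <- ad_tape()
    ad_value(F(tape, ad_wrap(xm)))[1L]
  }
  f_x <- ev(x); f_b <- ev(x_baseline)
  denom <- abs(f_x - f_b)
  gap <- if (denom < 1e-12) 0 else abs(sum(attribution) - (f_x - f_b)) / denom
  list(attribution = attribution, completeness_gap = gap, steps = steps,
       f_x = f_x, f_baseline = f_b)
}

# output functional (target logit) over the embedding surface for one model
model_output_functional <- function(model, graph, target) {
  if (target < 1L || target > model$n_outputs) stop("target index out of range")
  fam <- model$family
  if (fam %in% c("hybrid_gat", "hybrid_gvp")) {
    function(tape, xn) {
      z <- model_forward(tape, model, graph, embeddings = xn)
      ad_cols(tape, z, target)
    }
  } else if (fam == "seq_only") {
    function(tape, xn) {
      pooled <- lm_pooled_ad(tape, model$lm, tokens = NULL, embed_input = xn)
      z <- ad_add_rowvec(tape, ad_matmul_t(tape, pooled, model$params$W_out),
                         model$params$b_out)
      ad_cols(tape, z, target)
    }
  } else {
    # structure-only: attribute over the residue-identity block of the
    # scalar channel, holding the dihedral block fixed
    function(tape, xn) {
      s_fixed <- graph$node_scalar[, 1:6, drop = FALSE]
      g2 <- graph
      sc <- ad_concat_cols(tape, list(ad_wrap(s_fixed), xn))
      z <- model_forward_scalar_override(tape, model, g2, sc)
      ad_cols(tape, z, target)
    }
  }
}

# gvp/gat forward with an explicit scalar-channel node (used by IG for
# structure-only families)
model_forward_scalar_override <- function(tape, model, graph, s_node) {
  p <- model$params
  if (model$family == "gat") {
    x <- ad_cols(tape, s_node, 7:27)
    outs <- vector("list", length(p$layers))
    for (i in seq_along(p$layers)) {
      x <- gat_layer(tape, graph, x, p$layers[[i]])
      outs[[i]] <- x
    }
    pooled <- ad_readout(tape, outs, pool = "sum")
  } else {
    V <- vec_wrap(graph_node_vectors(graph))
    act <- model_act(model)
    st <- gvp_transform(tape, s_node, V, p$in_proj, act = act)
    ss <- vector("list", length(p$layers)); Vs <- vector("list", length(p$layers))
    for (i in seq_along(p$layers)) {
      st <- gvp_conv_layer(tape, graph, st$s, st$V, p$layers[[i]], act = act)
      ss[[i]] <- st$s; Vs[[i]] <- st$V
    }
    Vcat <- vec_concat(tape, Vs)
    Vpool <- lapply(Vcat, function(cm) ad_colmeans(tape, cm))
    pooled <- ad_concat_cols(tape, list(ad_readout(tape, ss, pool = "mean"),
                                        vec_norms(tape, Vpool)))
  }
  pen <- act_fn(model_act(model))(
    tape, ad_add_rowvec(tape, ad_matmul_t(tape, pooled, p$W_pen), p$b_pen))
  ad_add_rowvec(tape, ad_matmul_t(tape, pen, p$W_out), p$b_out)
}

#' Per-residue saliency profile via integrated gradients
#'
#' Embeds the sequence and an all-[SEP] baseline of the same length, runs
#' [integrated_gradients()] on the explained output (the target logit), and
#' sums attributions over the embedding width: ig(i) = sum_j ig(i, j).
#'
#' @param model a `geoprot_model` (or the model of a `geoprot_fit`).
#' @param struct `backbone_structure` of the protein (used for the graph and
#'   the sequence; seq_only models may instead pass `sequence`).
#' @param target output index to explain (default 1).
#' @param steps interpolation steps (default 64).
#' @param sequence optional explicit sequence.
#' @return a `saliency_profile`: list(score: length-L numeric, target, steps,
#'   completeness_gap, aa).
#' @export
residue_saliency <- function(model, struct = NULL, target = 1L, steps = 64L,
                             sequence = NULL) {
  if (inherits(model, "geoprot_fit")) model <- model$model
  if (is.null(sequence)) sequence <- aa_sequence(struct)
  L <- nchar(sequence)
  fam <- model$family
  graph <- if (fam != "seq_only") model_featurize(model, struct) else NULL
  if (fam %in% c("hybrid_gat", "hybrid_gvp")) {
    x <- embed_sequence(model$lm, sequence)
    x_base <- lm_sep_embedding(model$lm, L)
  } else if (fam == "seq_only") {
    x <- lm_input_embedding(model$lm, aa_tokens(sequence))
    x_base <- lm_input_embedding(model$lm, rep(LM_SEP, L + 2L))
  } else {
    x <- onehot_aa(strsplit(sequence, "")[[1L]])
    x_base <- matrix(0, L, ncol(x))
  }
  F <- model_output_functional(model, graph, target)
  ig <- integrated_gradients(F, x, x_base, steps = steps)
  score <- rowSums(ig$attribution)
  if (fam == "seq_only") score <- score[seq(2L, L + 1L)]  # strip [CLS]/[SEP]
  structure(list(score = score, target = target, steps = steps,
                 completeness_gap = ig$completeness_gap,
                 aa = strsplit(sequence, "")[[1L]]),
            class = "saliency_profile")
}

# embeddings of an all-[SEP] sequence of length L (residue rows)
lm_sep_embedding <- function(lm, L) {
  tape <- ad_tape()
  toks <- c(LM_CLS, rep(LM_SEP, L), LM_SEP)
  fw <- lm_forward(tape, lm, toks)
  ad_value(fw$H)[seq(2L, L + 1L), , drop = FALSE]
}

# embedding-layer output (token + positional) for a token vector
lm_input_embedding <- function(lm, tokens) {
  lm$E_tok$value[tokens, , drop = FALSE] +
    positional_encode(seq_along(tokens), dim = lm$h)
}

#' @export
print.saliency_profile <- function(x, ...) {
  cat(sprintf("<saliency_profile> L=%d, target %d, %d steps, completeness gap %.3g\n",
              length(x$score), x$target, x$steps, x$completeness_gap))
  invisible(x)
}

#' AUROC between a saliency profile and binding-site labels
#'
#' Rank-based AUROC (average ranks on ties) measuring how well saliency
#' scores separate annotated binding-site residues from the rest.
#' @param profile a `saliency_profile` or numeric score vector.
#' @param annotation binary per-residue labels (1 = binding site).
#' @return AUROC in [0, 1].
#' @export
saliency_auroc <- function(profile, annotation) {
  score <- if (inherits(profile, "saliency_profile")) profile$score else profile
  if (length(score) != length(annotation)) stop("length mismatch")
  rank_auroc(score, annotation)
}

#' Read binding-site annotations from TSV
#'
#' Expects columns `protein_id` and `positions` (comma-separated 1-based
#' residue positions).
#' @param path TSV file.
#' @param protein_id which protein to extract.
#' @param L protein length.
#' @return binary vector of length L.
#' @export
read_binding_sites <- function(path, protein_id, L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  row <- tab[tab$protein_id == protein_id, , drop = FALSE]
  if (!nrow(row)) stop("protein_id not found: ", protein_id)
  pos <- as.integer(strsplit(as.character(row$positions[1L]), ",")[[1L]])
  out <- integer(L)
  out[pos[pos >= 1L & pos <= L]] <- 1L
  out
}

#' Derive binding sites from ligand proximity in a PDB file
#'
#' Fallback annotation rule: a residue is a binding site when any of its
#' sidechain atoms (non-backbone) lies within `radius` Angstrom of any
#' ligand (non-water HETATM) atom.
#' @param pdb_text PDB text (string or lines).
#' @param chain protein chain id or "first".
#' @param radius cutoff in Angstrom (default 5.0).
#' @return binary vector aligned with [parse_backbone()]'s residues.
#' @export
binding_sites_from_ligand <- function(pdb_text, chain = "first", radius = 5.0) {
  struct <- parse_backbone(pdb_text, chain)
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1L]] else pdb_text
  rec <- trimws(substr(lines, 1L, 6L))
  resname <- pdb_field(lines, 18L, 20L)
  is_lig <- rec == "HETATM" & !(resname %in% c("HOH", "WAT")) &
    !(resname %in% names(AA_THREE_TO_ONE))
  if (!any(is_lig)) return(integer(length(struct$aa)))
  lig <- cbind(as.numeric(pdb_field(lines[is_lig], 31L, 38L)),
               as.numeric(pdb_field(lines[is_lig], 39L, 46L)),
               as.numeric(pdb_field(lines[is_lig], 47L, 54L)))
  # sidechain atoms of the selected chain
  if (identical(chain, "first")) chain <- struct$residue_ids$chain[1L]
  is_prot <- rec %in% c("ATOM", "HETATM") & substr(lines, 22L, 22L) == chain &
    (resname %in% names(AA_THREE_TO_ONE) | rec == "ATOM")
  atom <- pdb_field(lines[is_prot], 13L, 16L)
  side <- !(atom %in% c("N", "CA", "C", "O", "OXT"))
  resno <- as.integer(pdb_field(lines[is_prot], 23L, 26L))[side]
  xyz <- cbind(as.numeric(pdb_field(lines[is_prot], 31L, 38L)),
               as.numeric(pdb_field(lines[is_prot], 39L, 46L)),
               as.numeric(pdb_field(lines[is_prot], 47L, 54L)))[side, ,
                                                                drop = FALSE]
  out <- integer(length(struct$aa))
  if (nrow(xyz)) {
    for (a in seq_len(nrow(xyz))) {
      d <- sqrt(colSums((t(lig) - xyz[a, ])^2))
      if (any(d <= radius)) {
        r <- match(resno[a], struct$residue_ids$resno)
        if (!is.na(r)) out[r] <- 1L
      }
    }
  }
  out
}
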