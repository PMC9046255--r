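# Per-residue embedder contract: a deterministic small transformer ("stub")
# providing embeddings, a [CLS]-pooled vector, masked-token amino-acid
# distributions, and per-(layer, head) attention maps. The stub exists so
# that every downstream module (hybrid models, integrated gradients, variant
# scoring, contact probing) is testable offline; an adapter for a large
# pretrained protein LM only needs to honour the same interface.

LM_VOCAB <- c(AA_ALPHABET, "[CLS]", "[SEP]", "[MASK]")
LM_CLS <- length(AA_ALPHABET) + 1L
LM_SEP <- length(AA_ALPHABET) + 2L
LM_MASK <- length(AA_ALPHABET) + 3L

#' Build the deterministic stub language model
#'
#' A 2-layer, 2-head post-norm transformer over single amino-acid tokens
#' ([CLS] seq [SEP]), with a masked-LM head over the 21-letter alphabet and a
#' tanh-pooled [CLS] head. All parameters are drawn under `seed`, so the
#' model is reproducible; the token-embedding table is excluded from the
#' trainable set (fine-tuning never updates it).
#' @param h hidden width (default 16).
#' @param n_layers,n_heads transformer depth and head count.
#' @param ffn feed-forward width.
#' @param seed parameter seed.
#' @return an object of class `stub_lm`.
#' @export
stub_lm <- function(h = 16L, n_layers = 2L, n_heads = 2L, ffn = 32L,
                    seed = 42L) {
  stopifnot(h %% n_heads == 0L)
  dh <- h %/% n_heads
  local_seed(seed, {
    lm <- list(
      h = h, n_layers = n_layers, n_heads = n_heads, dh = dh, ffn = ffn,
      seed = seed, provenance = "stub",
      # token embeddings: frozen (excluded from fine-tuning gradient flow)
      E_tok = ad_new(matrix(stats::rnorm(length(LM_VOCAB) * h, 0, 1), ncol = h),
                     track = FALSE),
      layers = lapply(seq_len(n_layers), function(l) {
        list(
          heads = lapply(seq_len(n_heads), function(hh) list(
            Wq = ad_param(glorot(dh, h)), Wk = ad_param(glorot(dh, h)),
            Wv = ad_param(glorot(dh, h)))),
          Wo = ad_param(glorot(h, h)),
          ln1_g = ad_param(matrix(1, 1L, h)), ln1_b = ad_param(matrix(0, 1L, h)),
          W1 = ad_param(glorot(ffn, h)), b1 = ad_param(matrix(0, 1L, ffn)),
          W2 = ad_param(glorot(h, ffn)), b2 = ad_param(matrix(0, 1L, h)),
          ln2_g = ad_param(matrix(1, 1L, h)), ln2_b = ad_param(matrix(0, 1L, h)))
      }),
      Wp = ad_param(glorot(h, h)), bp = ad_param(matrix(0, 1L, h)),
      # masked-LM head; init scale chosen so token distributions are far from
      # uniform (the stub must yield non-degenerate zero-shot scores)
      Wm = ad_param(matrix(stats::rnorm(length(AA_ALPHABET) * h, 0, 0.6),
                           ncol = h)),
      bm = ad_param(matrix(0, 1L, length(AA_ALPHABET))))
    class(lm) <- "stub_lm"
    lm
  })
}

#' @export
print.stub_lm <- function(x, ...) {
  cat(sprintf("<stub_lm> h=%d, %d layers x %d heads, seed %d\n",
              x$h, x$n_layers, x$n_heads, x$seed))
  invisible(x)
}

lm_trainable_params <- function(lm) {
  ps <- list()
  for (l in lm$layers) {
    for (hd in l$heads) ps <- c(ps, hd[c("Wq", "Wk", "Wv")])
    ps <- c(ps, l[c("Wo", "ln1_g", "ln1_b", "W1", "b1", "W2", "b2",
                    "ln2_g", "ln2_b")])
  }
  c(ps, lm[c("Wp", "bp", "Wm", "bm")])
}

aa_tokens <- function(aa) {
  ch <- strsplit(aa, "")[[1L]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx)) {
    stop(sprintf("invalid character '%s' at position %d",
                 ch[which(is.na(idx))[1L]], which(is.na(idx))[1L]))
  }
  c(LM_CLS, idx, LM_SEP)
}

# full transformer forward; returns hidden-state node, embedding-layer node
# and attention maps (plain matrices, one per layer x head, special tokens
# included)
lm_forward <- function(tape, lm, tokens, embed_input = NULL) {
  Lt <- if (is.null(embed_input)) length(tokens) else nrow(ad_value(embed_input))
  if (is.null(embed_input)) {
    emb <- ad_rows(tape, lm$E_tok, tokens)
    x0 <- ad_add(tape, emb, positional_encode(seq_len(Lt), dim = lm$h))
  } else {
    x0 <- ad_wrap(embed_input)
  }
  x <- x0
  attn <- vector("list", lm$n_layers)
  inv_sqrt <- 1 / sqrt(lm$dh)
  for (li in seq_len(lm$n_layers)) {
    lp <- lm$layers[[li]]
    heads_out <- vector("list", lm$n_heads)
    attn[[li]] <- vector("list", lm$n_heads)
    for (hi in seq_len(lm$n_heads)) {
      hp <- lp$heads[[hi]]
      Q <- ad_matmul_t(tape, x, hp$Wq)
      K <- ad_matmul_t(tape, x, hp$Wk)
      Vv <- ad_matmul_t(tape, x, hp$Wv)
      A <- ad_softmax_rows(tape, ad_scale(tape, ad_matmul_t(tape, Q, K),
                                          inv_sqrt))
      attn[[li]][[hi]] <- A$value
      heads_out[[hi]] <- ad_matmul(tape, A, Vv)
    }
    mha <- ad_matmul_t(tape, ad_concat_cols(tape, heads_out), lp$Wo)
    x <- ad_layernorm_rows(tape, ad_add(tape, x, mha), lp$ln1_g, lp$ln1_b)
    ff <- ad_add_rowvec(tape, ad_matmul_t(
      tape, ad_relu(tape, ad_add_rowvec(tape, ad_matmul_t(tape, x, lp$W1),
                                        lp$b1)), lp$W2), lp$b2)
    x <- ad_layernorm_rows(tape, ad_add(tape, x, ff), lp$ln2_g, lp$ln2_b)
  }
  list(H = x, x0 = x0, attn = attn, Lt = Lt)
}

# tape-level per-residue embeddings (special-token rows stripped): the
# differentiable surface hybrids train through
lm_embed_ad <- function(tape, lm, aa) {
  toks <- aa_tokens(aa)
  fw <- lm_forward(tape, lm, toks)
  ad_rows(tape, fw$H, seq(2L, fw$Lt - 1L))
}

#' Per-residue embeddings from the language model
#'
#' Last-layer hidden states with the [CLS]/[SEP] rows stripped.
#' @param lm a `stub_lm`.
#' @param aa one-letter amino-acid string.
#' @return L x h numeric matrix with attributes `provenance` and `layer`.
#' @export
embed_sequence <- function(lm, aa) {
  tape <- ad_tape()
  out <- ad_value(lm_embed_ad(tape, lm, aa))
  attr(out, "provenance") <- lm$provenance
  attr(out, "layer") <- "last"
  out
}

#' Pooled [CLS] representation
#'
#' tanh of an affine map of the last-layer [CLS] hidden state, the standard
#' sequence-level pooling for a classification head.
#' @inheritParams embed_sequence
#' @return 1 x h numeric matrix.
#' @export
pooled_cls <- function(lm, aa) {
  tape <- ad_tape()
  ad_value(lm_pooled_ad(tape, lm, aa_tokens(aa)))
}

lm_pooled_ad <- function(tape, lm, tokens, embed_input = NULL) {
  fw <- lm_forward(tape, lm, tokens, embed_input = embed_input)
  cls <- ad_rows(tape, fw$H, 1L)
  ad_tanh(tape, ad_add_rowvec(tape, ad_matmul_t(tape, cls, lm$Wp), lm$bp))
}

#' Amino-acid distributions at masked positions
#'
#' Replaces the listed residue positions with [MASK] (all of them in a single
#' forward pass) and returns the model's 21-way amino-acid distribution at
#' each, conditioned on the unmasked context.
#' @param lm a `stub_lm`.
#' @param aa one-letter amino-acid string.
#' @param positions 1-based residue positions to mask (non-empty).
#' @return length(positions) x 21 matrix of probabilities (rows sum to 1),
#'   columns named by amino acid, rows named by position.
#' @export
masked_logprobs <- function(lm, aa, positions) {
  L <- nchar(aa)
  if (!length(positions)) stop("empty position set")
  if (any(positions < 1L | positions > L)) stop("positions out of [1, L]")
  toks <- aa_tokens(aa)
  toks[positions + 1L] <- LM_MASK
  tape <- ad_tape()
  fw <- lm_forward(tape, lm, toks)
  hid <- ad_value(fw$H)[positions + 1L, , drop = FALSE]
  logits <- tcrossprod(hid, lm$Wm$value) +
    matrix(as.numeric(lm$bm$value), length(positions), nrow(lm$Wm$value),
           byrow = TRUE)
  z <- logits - apply(logits, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  dimnames(p) <- list(positions, AA_ALPHABET)
  p
}

#' Self-attention maps with special tokens stripped
#'
#' @inheritParams embed_sequence
#' @return list over layers, each a list over heads of L x L row-stochastic
#'   matrices ([CLS]/[SEP] rows and columns removed and rows renormalized).
#' @export
attention_maps <- function(lm, aa) {
  tape <- ad_tape()
  fw <- lm_forward(tape, lm, aa_tokens(aa))
  keep <- seq(2L, fw$Lt - 1L)
  lapply(fw$attn, function(layer) lapply(layer, function(A) {
    B <- A[keep, keep, drop = FALSE]
    B / rowSums(B)
  }))
}
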