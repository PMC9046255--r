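# Zero-shot mutational-effect scoring: the masked marginal probability
# score. All mutated positions are masked jointly in a single forward pass
# and the score is the sum over mutated positions of
# log p(mutant AA) - log p(wildtype AA) under that joint-mask distribution.

#' Parse mutation notation
#'
#' "A123G" = wildtype A at 1-based position 123 mutated to G; multi-mutants
#' are semicolon-separated ("A123G;C5W"). Substitutions only.
#' @param spec notation string, or an already-built data.frame with columns
#'   pos/wt/mt.
#' @return data.frame with columns `pos`, `wt`, `mt`.
#' @export
parse_mutations <- function(spec) {
  if (is.data.frame(spec)) return(spec)
  parts <- trimws(strsplit(spec, ";", fixed = TRUE)[[1L]])
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) stop("malformed mutation notation: ", parts[bad][1L])
  data.frame(pos = as.integer(vapply(m, `[`, "", 3L)),
             wt = vapply(m, `[`, "", 2L),
             mt = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Masked marginal mutational-effect score
#'
#' @param lm a `stub_lm` (or any embedder honouring its interface).
#' @param wt_sequence wildtype one-letter sequence.
#' @param mutations mutation notation string or data.frame (see
#'   [parse_mutations()]); the listed wildtype residues must match
#'   `wt_sequence`.
#' @return numeric score; 0 when every mutant equals the wildtype.
#' @export
masked_marginal_score <- function(lm, wt_sequence, mutations) {
  muts <- parse_mutations(mutations)
  if (!nrow(muts)) stop("empty mutation set")
  wt_vec <- strsplit(wt_sequence, "")[[1L]]
  for (r in seq_len(nrow(muts))) {
    p <- muts$pos[r]
    if (p < 1L || p > length(wt_vec)) stop("position out of range: ", p)
    if (wt_vec[p] != muts$wt[r]) {
      stop(sprintf("wildtype mismatch at position %d: sequence has %s, record says %s",
                   p, wt_vec[p], muts$wt[r]))
    }
  }
  probs <- masked_logprobs(lm, wt_sequence, sort(unique(muts$pos)))
  lp <- log(probs)
  sum(vapply(seq_len(nrow(muts)), function(r) {
    row <- match(as.character(muts$pos[r]), rownames(lp))
    lp[row, muts$mt[r]] - lp[row, muts$wt[r]]
  }, numeric(1L)))
}

#' Score every record of a mutational scan
#'
#' @param lm embedder.
#' @param scan a `mutscan_table` (see [make_mutscan()] / [read_mutscan()]).
#' @return data.frame with per-record `score` and `assay`.
#' @export
score_mutscan <- function(lm, scan) {
  data.frame(
    score = vapply(scan$records, function(r)
      masked_marginal_score(lm, scan$wildtype, r$mutations), numeric(1L)),
    assay = vapply(scan$records, function(r) r$assay, numeric(1L)))
}

#' Read a mutational scan table from TSV
#'
#' Expects columns `mutations` (notation, semicolon-separated) and `assay`;
#' the wildtype sequence is given separately.
#' @param path TSV file.
#' @param wildtype wildtype sequence.
#' @return a `mutscan_table`.
#' @export
read_mutscan <- function(path, wildtype) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(tab)), function(i)
    list(mutations = parse_mutations(tab$mutations[i]), assay = tab$assay[i]))
  structure(list(wildtype = wildtype, records = records,
                 meta = list(source = path)),
            class = "mutscan_table")
}

#' Write a mutational scan table to TSV
#' @param scan a `mutscan_table`.
#' @param path output file.
#' @export
write_mutscan <- function(scan, path) {
  notation <- vapply(scan$records, function(r)
    paste(sprintf("%s%d%s", r$mutations$wt, r$mutations$pos, r$mutations$mt),
          collapse = ";"), character(1L))
  utils::write.table(
    data.frame(mutations = notation,
               assay = vapply(scan$records, function(r) r$assay, numeric(1L))),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
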