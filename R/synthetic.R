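# Deterministic generators for idealized backbones, labelled toy tasks and
# toy mutational scans. These emulate desk-scale stand-ins for the real
# benchmark datasets so every downstream component is testable offline.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify an idealized chain by its backbone torsions
#'
#' @param length number of residues (>= 2).
#' @param phi,psi,omega backbone torsions in degrees, each a scalar (recycled)
#'   or a length-`length` vector; values in (-180, 180].
#' @param sequence optional one-letter sequence; sampled under `seed` if NULL.
#' @param seed seed for sequence sampling.
#' @return a `chain_spec` list.
#' @export
chain_spec <- function(length, phi = -57, psi = -47, omega = 180,
                       sequence = NULL, seed = 1L) {
  stopifnot(length >= 2L)
  spec <- list(length = as.integer(length),
               phi = rep_len(phi, length), psi = rep_len(psi, length),
               omega = rep_len(omega, length), seed = as.integer(seed))
  if (is.null(sequence)) {
    sequence <- local_seed(seed, paste(
      sample(AA_ALPHABET[1:20], length, replace = TRUE), collapse = ""))
  }
  stopifnot(nchar(sequence) == length)
  spec$sequence <- sequence
  structure(spec, class = "chain_spec")
}

#' Build an idealized backbone from internal coordinates
#'
#' Places atoms sequentially (NeRF) with ideal bond lengths (N-CA 1.458 A,
#' CA-C 1.525 A, C-N 1.329 A) and angles, honouring the spec's per-residue
#' phi/psi/omega. The construction round-trips through [compute_dihedrals()].
#' @param spec a [chain_spec()].
#' @return a `backbone_structure`.
#' @export
build_chain <- function(spec) {
  L <- spec$length
  phi <- spec$phi * pi / 180; psi <- spec$psi * pi / 180
  omega <- spec$omega * pi / 180
  N <- matrix(0, L, 3L); CA <- N; C <- N; O <- N
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(.ideal$b_n_ca, 0, 0)
  th <- pi - .ideal$a_n_ca_c
  C[1L, ] <- CA[1L, ] + .ideal$b_ca_c * c(cos(th), sin(th), 0)
  for (r in seq_len(L)) {
    if (r < L) {
      N[r + 1L, ] <- place_atom(N[r, ], CA[r, ], C[r, ],
                                .ideal$b_c_n, .ideal$a_ca_c_n, psi[r])
      CA[r + 1L, ] <- place_atom(CA[r, ], C[r, ], N[r + 1L, ],
                                 .ideal$b_n_ca, .ideal$a_c_n_ca, omega[r])
      C[r + 1L, ] <- place_atom(C[r, ], N[r + 1L, ], CA[r + 1L, ],
                                .ideal$b_ca_c, .ideal$a_n_ca_c, phi[r + 1L])
      O[r, ] <- place_atom(N[r, ], CA[r, ], C[r, ],
                           .ideal$b_c_o, .ideal$a_ca_c_o, psi[r] - pi)
    } else {
      O[r, ] <- place_atom(N[r, ], CA[r, ], C[r, ],
                           .ideal$b_c_o, .ideal$a_ca_c_o, psi[r] - pi)
    }
  }
  aa <- strsplit(spec$sequence, "")[[1L]]
  CB <- matrix(0, L, 3L)
  for (r in seq_len(L)) CB[r, ] <- impute_cbeta(N[r, ], CA[r, ], C[r, ])
  ids <- data.frame(chain = "A", resno = seq_len(L), icode = "",
                    stringsAsFactors = FALSE)
  new_backbone_structure(ids, aa, N, CA, C, O, CB,
                         cb_imputed = rep(TRUE, L))
}

# canonical torsion sets used by the task generator
.torsions <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135)
)

#' Generate a labelled toy structure task
#'
#' Each protein is a chain of random helix/strand/coil segments; the label is
#' a deterministic function of the generated structure. Rule
#' `helix_fraction_threshold` gives a binary label (1 when the fraction of
#' helix residues is >= `threshold`); rule `radius_label` gives a regression
#' target (radius of gyration of the C-alpha trace, Angstrom).
#'
#' @param n_proteins number of proteins (>= 4).
#' @param rule "helix_fraction_threshold" or "radius_label".
#' @param seed RNG seed; the dataset is a deterministic function of it.
#' @param length_range residue-count range to sample from.
#' @param threshold helix-fraction cutoff for the binary rule.
#' @return list with `structures` (list of `backbone_structure`), `labels`
#'   (numeric vector, or one-column matrix for the binary rule), `task_kind`,
#'   and `meta` (generation parameters, seed, content hash).
#' @export
make_structure_task <- function(n_proteins, rule = c("helix_fraction_threshold",
                                                     "radius_label"),
                                seed = 1L, length_range = c(25L, 35L),
                                threshold = 0.5) {
  rule <- match.arg(rule)
  stopifnot(n_proteins >= 4L)
  out <- local_seed(seed, {
    structures <- vector("list", n_proteins)
    helix_frac <- numeric(n_proteins)
    for (i in seq_len(n_proteins)) {
      L <- sample(length_range[1L]:length_range[2L], 1L)
      # per-protein helix propensity spans (0,1) so labels stay balanced
      prop <- stats::runif(1L)
      phi <- numeric(L); psi <- numeric(L); is_helix <- logical(L)
      pos <- 1L
      while (pos <= L) {
        seg <- min(L - pos + 1L, sample(4:8, 1L))
        kind <- if (stats::runif(1L) < prop) "helix"
                else if (stats::runif(1L) < 0.7) "strand" else "coil"
        if (kind == "coil") {
          phi[pos:(pos + seg - 1L)] <- stats::runif(seg, -150, -60)
          psi[pos:(pos + seg - 1L)] <- stats::runif(seg, -60, 160)
        } else {
          phi[pos:(pos + seg - 1L)] <- .torsions[[kind]]["phi"] +
            stats::rnorm(seg, 0, 3)
          psi[pos:(pos + seg - 1L)] <- .torsions[[kind]]["psi"] +
            stats::rnorm(seg, 0, 3)
          if (kind == "helix") is_helix[pos:(pos + seg - 1L)] <- TRUE
        }
        pos <- pos + seg
      }
      spec <- chain_spec(L, phi = phi, psi = psi, omega = 180,
                         seed = sample.int(1e6, 1L))
      structures[[i]] <- build_chain(spec)
      helix_frac[i] <- mean(is_helix)
    }
    list(structures = structures, helix_frac = helix_frac)
  })
  labels <- switch(rule,
    helix_fraction_threshold = matrix(as.numeric(out$helix_frac >= threshold),
                                      ncol = 1L),
    radius_label = vapply(out$structures, function(s) {
      ca <- s$coords_CA
      sqrt(mean(rowSums(sweep(ca, 2L, colMeans(ca))^2)))
    }, numeric(1L)))
  task_kind <- if (rule == "helix_fraction_threshold") "multilabel" else "regression"
  meta <- list(rule = rule, seed = seed, n = n_proteins,
               length_range = length_range, threshold = threshold,
               content_hash = content_hash(lapply(out$structures, `[[`, "coords_CA")))
  list(structures = out$structures, labels = labels,
       task_kind = task_kind, meta = meta)
}

#' Generate a toy mutational scan against the stub language model
#'
#' Samples random single/double substitutions on a random wildtype and sets
#' the assay value to the stub model's masked-marginal score plus Gaussian
#' noise, so the attainable rank correlation is known by construction.
#' @param wt_length wildtype length.
#' @param n_records number of mutation records (>= 3).
#' @param sigma assay noise standard deviation (default 0.1).
#' @param seed RNG seed.
#' @param lm optional embedder (defaults to [stub_lm()] with its own seed).
#' @return a `mutscan_table`: list(wildtype, records, meta); each record has
#'   `mutations` (data.frame pos/wt/mt), `assay`, and the noise-free `score`.
#' @export
make_mutscan <- function(wt_length, n_records, sigma = 0.1, seed = 1L,
                         lm = NULL) {
  stopifnot(n_records >= 3L)
  if (is.null(lm)) lm <- stub_lm()
  local_seed(seed, {
    wt <- paste(sample(AA_ALPHABET[1:20], wt_length, replace = TRUE),
                collapse = "")
    wt_vec <- strsplit(wt, "")[[1L]]
    records <- vector("list", n_records)
    for (i in seq_len(n_records)) {
      nmut <- sample(1:2, 1L)
      pos <- sort(sample.int(wt_length, nmut))
      mt <- vapply(pos, function(p)
        sample(setdiff(AA_ALPHABET[1:20], wt_vec[p]), 1L), character(1L))
      muts <- data.frame(pos = pos, wt = wt_vec[pos], mt = mt,
                         stringsAsFactors = FALSE)
      score <- masked_marginal_score(lm, wt, muts)
      records[[i]] <- list(mutations = muts, assay = score + stats::rnorm(1L, 0, sigma),
                           score = score)
    }
    meta <- list(wt_length = wt_length, n_records = n_records, sigma = sigma,
                 seed = seed, content_hash = content_hash(records))
    structure(list(wildtype = wt, records = records, meta = meta),
              class = "mutscan_table")
  })
}

# md5 of the serialized object (via a temp file; tools::md5sum is file-based)
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}
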