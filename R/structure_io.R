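# Parsing backbone atoms out of PDB text into a validated per-residue
# structure (class "backbone_structure"), plus JSON sidecar serialization
# and a minimal PDB writer for synthetic chains.

new_backbone_structure <- function(residue_ids, aa, N, CA, C, O, CB, cb_imputed) {
  L <- length(aa)
  stopifnot(L >= 1L, nrow(N) == L, nrow(CA) == L, nrow(C) == L,
            nrow(O) == L, nrow(CB) == L, length(cb_imputed) == L)
  coords <- list(N = N, CA = CA, C = C, O = O, CB = CB)
  for (m in coords) if (anyNA(m)) stop("coordinates contain NA")
  structure(
    list(residue_ids = residue_ids,
         aa = aa,
         coords_N = N, coords_CA = CA, coords_C = C, coords_O = O,
         coords_CB = CB, cb_imputed = cb_imputed),
    class = "backbone_structure")
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> %d residues, chain %s\n",
              length(x$aa), paste(unique(x$residue_ids$chain), collapse = ",")))
  cat("  sequence:", paste(x$aa, collapse = ""), "\n")
  cat(sprintf("  C-beta imputed at %d residue(s)\n", sum(x$cb_imputed)))
  invisible(x)
}

#' @export
length.backbone_structure <- function(x) length(x$aa)

#' One-letter sequence of a backbone structure
#' @param struct a `backbone_structure`.
#' @return single string of one-letter codes (21-letter alphabet, X for
#'   non-standard residues).
#' @export
aa_sequence <- function(struct) paste(struct$aa, collapse = "")

pdb_field <- function(lines, from, to) trimws(substr(lines, from, to))

#' Parse backbone atoms from PDB text
#'
#' Reads ATOM (and amino-acid HETATM, e.g. MSE) records of one chain from
#' fixed-column PDB text and returns the per-residue backbone. Only the first
#' model of a multi-model file is read. Alternate locations are resolved by
#' highest occupancy, ties by first occurrence. Residues missing any of
#' N/CA/C are dropped with a warning; a missing O is imputed from the local
#' frame (it is not used by any downstream feature). C-beta is taken from the
#' file when present, otherwise imputed with [impute_cbeta()].
#'
#' @param pdb_text PDB content: a single string or a character vector of lines.
#' @param chain chain identifier, or "first" (default) for the chain of the
#'   first ATOM record.
#' @return a `backbone_structure`.
#' @export
parse_backbone <- function(pdb_text, chain = "first") {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1L]] else pdb_text
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  rec <- substr(lines, 1L, 6L)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM/HETATM records found")

  resname <- pdb_field(lines, 18L, 20L)
  is_aa <- resname %in% names(AA_THREE_TO_ONE) | trimws(substr(lines, 1L, 6L)) == "ATOM"
  lines <- lines[is_aa]; resname <- resname[is_aa]
  chains <- substr(lines, 22L, 22L)
  if (identical(chain, "first")) chain <- chains[1L]
  sel <- chains == chain
  if (!any(sel)) stop(sprintf("chain '%s' not found", chain))
  lines <- lines[sel]; resname <- resname[sel]

  atom <- pdb_field(lines, 13L, 16L)
  resno <- as.integer(pdb_field(lines, 23L, 26L))
  icode <- sub(" ", "", substr(lines, 27L, 27L), fixed = TRUE)
  x <- as.numeric(pdb_field(lines, 31L, 38L))
  y <- as.numeric(pdb_field(lines, 39L, 46L))
  z <- as.numeric(pdb_field(lines, 47L, 54L))
  occ <- suppressWarnings(as.numeric(pdb_field(lines, 55L, 60L)))
  occ[is.na(occ)] <- 1

  res_key <- paste(resno, icode, sep = "|")
  res_order <- unique(res_key)
  want <- c("N", "CA", "C", "O", "CB")

  L0 <- length(res_order)
  getmat <- function() matrix(NA_real_, L0, 3L)
  cm <- list(N = getmat(), CA = getmat(), C = getmat(), O = getmat(), CB = getmat())
  aa <- character(L0)
  for (r in seq_len(L0)) {
    ri <- which(res_key == res_order[r])
    rn <- resname[ri[1L]]
    aa[r] <- if (rn %in% names(AA_THREE_TO_ONE)) AA_THREE_TO_ONE[[rn]] else "X"
    for (at in want) {
      ai <- ri[atom[ri] == at]
      if (!length(ai)) next
      # altloc: highest occupancy, then first listed
      ai <- ai[order(-occ[ai], seq_along(ai))][1L]
      cm[[at]][r, ] <- c(x[ai], y[ai], z[ai])
    }
  }

  complete <- !apply(is.na(cm$N) | is.na(cm$CA) | is.na(cm$C), 1L, any)
  if (!any(complete)) stop("no complete residues")
  if (any(!complete)) {
    warning(sprintf("dropping %d residue(s) missing N/CA/C backbone atoms",
                    sum(!complete)))
  }
  idx <- which(complete)
  ids <- data.frame(
    chain = chain,
    resno = as.integer(sub("\\|.*", "", res_order[idx])),
    icode = sub(".*\\|", "", res_order[idx]),
    stringsAsFactors = FALSE)

  N <- cm$N[idx, , drop = FALSE]; CA <- cm$CA[idx, , drop = FALSE]
  C <- cm$C[idx, , drop = FALSE]; O <- cm$O[idx, , drop = FALSE]
  CB <- cm$CB[idx, , drop = FALSE]
  aa <- aa[idx]
  Lf <- length(idx)

  # impute missing O from the local frame (trans to the next N when known)
  for (r in seq_len(Lf)) {
    if (anyNA(O[r, ])) {
      tor <- if (r < Lf) {
        psi <- dihedral_angle(N[r, ], CA[r, ], C[r, ], N[r + 1L, ])
        if (is.na(psi)) 0 else psi - pi
      } else 0
      O[r, ] <- place_atom(N[r, ], CA[r, ], C[r, ],
                           .ideal$b_c_o, .ideal$a_ca_c_o, tor)
    }
  }
  cb_imputed <- apply(is.na(CB), 1L, any)
  for (r in which(cb_imputed)) {
    CB[r, ] <- impute_cbeta(N[r, ], CA[r, ], C[r, ])
  }
  new_backbone_structure(ids, aa, N, CA, C, O, CB, cb_imputed)
}

#' Serialize a backbone structure to JSON
#'
#' The sidecar layout is a JSON object with fields `residue_ids` (chain,
#' resno, icode), `aa` (one-letter codes), `coords` (named N/CA/C/O/CB, each
#' an L x 3 array) and `cb_imputed`. [structure_from_json()] inverts it.
#' @param struct a `backbone_structure`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
structure_to_json <- function(struct, path = NULL) {
  obj <- list(
    residue_ids = struct$residue_ids,
    aa = struct$aa,
    coords = list(N = struct$coords_N, CA = struct$coords_CA,
                  C = struct$coords_C, O = struct$coords_O,
                  CB = struct$coords_CB),
    cb_imputed = struct$cb_imputed)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname structure_to_json
#' @param json JSON string or file path produced by [structure_to_json()].
#' @export
structure_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  new_backbone_structure(
    residue_ids = as.data.frame(obj$residue_ids),
    aa = as.character(obj$aa),
    N = matrix(obj$coords$N, ncol = 3L), CA = matrix(obj$coords$CA, ncol = 3L),
    C = matrix(obj$coords$C, ncol = 3L), O = matrix(obj$coords$O, ncol = 3L),
    CB = matrix(obj$coords$CB, ncol = 3L),
    cb_imputed = as.logical(obj$cb_imputed))
}

#' Write a backbone structure as minimal PDB text
#' @param struct a `backbone_structure`.
#' @param path optional output file.
#' @return character vector of PDB lines (invisibly when written to file).
#' @export
write_pdb <- function(struct, path = NULL) {
  L <- length(struct$aa)
  lines <- character(0L)
  serial <- 0L
  for (r in seq_len(L)) {
    res3 <- AA_ONE_TO_THREE[[struct$aa[r]]]
    atoms <- list(N = struct$coords_N[r, ], CA = struct$coords_CA[r, ],
                  C = struct$coords_C[r, ], O = struct$coords_O[r, ])
    if (!struct$cb_imputed[r]) atoms$CB <- struct$coords_CB[r, ]
    for (an in names(atoms)) {
      serial <- serial + 1L
      p <- atoms[[an]]
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, sprintf(" %-3s", an), res3, struct$residue_ids$chain[r],
        struct$residue_ids$resno[r], struct$residue_ids$icode[r],
        p[1L], p[2L], p[3L], 1, 0, substr(an, 1L, 1L)))
    }
  }
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Apply a rigid (or general linear) transform to all coordinates
#' @param struct a `backbone_structure`.
#' @param R 3 x 3 matrix applied on the right as `X %*% t(R)`.
#' @param t length-3 translation.
#' @return transformed `backbone_structure` (C-beta kept as stored).
#' @export
transform_structure <- function(struct, R = diag(3), t = c(0, 0, 0)) {
  tr <- function(m) sweep(m %*% t(R), 2L, t, "+")
  new_backbone_structure(struct$residue_ids, struct$aa,
                         tr(struct$coords_N), tr(struct$coords_CA),
                         tr(struct$coords_C), tr(struct$coords_O),
                         tr(struct$coords_CB), struct$cb_imputed)
}
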