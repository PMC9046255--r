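# Integrated gradients: linear exactness, completeness, rigged-model
# localization, and saliency/binding-site agreement.

test_that("IG is exact on linear functionals at any step count", {
  set.seed(51)
  w <- matrix(rnorm(20), 4L, 5L)
  F_lin <- function(tape, xn) ad_sum(tape, ad_emul(tape, xn, w))
  x <- matrix(rnorm(20), 4L, 5L)
  xb <- matrix(rnorm(20), 4L, 5L)
  for (steps in c(1L, 3L, 64L)) {
    ig <- integrated_gradients(F_lin, x, xb, steps = steps)
    expect_equal(ig$attribution, w * (x - xb), tolerance = 1e-10)
    expect_lt(ig$completeness_gap, 1e-10)
  }
})

test_that("identical baseline gives all-zero attributions", {
  F_any <- function(tape, xn) ad_mean(tape, ad_tanh(tape, xn))
  x <- matrix(rnorm(12), 3L, 4L)
  ig <- integrated_gradients(F_any, x, x, steps = 8L)
  expect_true(all(ig$attribution == 0))
})

test_that("completeness gap is small at 256 steps and non-increasing in steps", {
  set.seed(52)
  st <- toy_structure(10L, seed = 52L)
  lm <- stub_lm(h = 8L)
  model <- build_model("hybrid_gvp", "two_stage", "multilabel", 2L,
                       model_dims(s_h = 8L, v_h = 2L, penultimate = 12L,
                                  k = 6L),
                       lm = lm, seed = 9L)
  graph <- model_featurize(model, st)
  F <- model_output_functional(model, graph, 1L)
  x <- embed_sequence(lm, aa_sequence(st))
  xb <- lm_sep_embedding(lm, 10L)
  gaps <- vapply(c(16L, 64L, 256L), function(s)
    integrated_gradients(F, x, xb, steps = s)$completeness_gap, numeric(1L))
  expect_lte(gaps[3L], 0.01)
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("a head reading only residue 4 concentrates saliency on residue 4", {
  lm <- stub_lm(h = 8L)
  st <- toy_structure(7L, seed = 53L)
  model <- build_model("hybrid_gvp", "two_stage", "multilabel", 1L,
                       model_dims(s_h = 8L, v_h = 2L, penultimate = 12L,
                                  k = 4L),
                       lm = lm, seed = 3L)
  # rig: bypass the GNN with a functional that depends on row 4 only
  graph <- model_featurize(model, st)
  set.seed(6)
  w4 <- matrix(rnorm(8), 1L, 8L)
  F_rigged <- function(tape, xn) {
    r4 <- ad_rows(tape, xn, 4L)
    ad_sum(tape, ad_tanh(tape, ad_emul(tape, r4, w4)))
  }
  x <- embed_sequence(lm, aa_sequence(st))
  xb <- lm_sep_embedding(lm, 7L)
  ig <- integrated_gradients(F_rigged, x, xb, steps = 32L)
  score <- rowSums(ig$attribution)
  expect_equal(which.max(abs(score)), 4L)
  expect_true(all(abs(score[-4L]) < 1e-12))
})

test_that("saliency profiles have length L for every model family", {
  st <- toy_structure(9L, seed = 54L)
  lm <- stub_lm(h = 8L)
  dims <- model_dims(s_h = 8L, v_h = 2L, gat_width = 8L, penultimate = 12L,
                     k = 5L)
  for (fam in c("hybrid_gvp", "gvp", "seq_only")) {
    model <- if (fam == "hybrid_gvp")
      build_model(fam, "two_stage", "multilabel", 2L, dims, lm = lm, seed = 4L)
    else build_model(fam, task = "multilabel", n_outputs = 2L, dims = dims,
                     lm = lm, seed = 4L)
    prof <- residue_saliency(model, st, target = 2L, steps = 8L)
    expect_length(prof$score, 9L)
    expect_true(all(is.finite(prof$score)))
  }
  model <- build_model("hybrid_gvp", "two_stage", "multilabel", 2L, dims,
                       lm = lm)
  expect_error(residue_saliency(model, st, target = 5L), "out of range")
})

test_that("doubling steps moves scores by no more than the completeness gaps", {
  st <- toy_structure(8L, seed = 55L)
  lm <- stub_lm(h = 8L)
  model <- build_model("hybrid_gvp", "two_stage", "regression", 1L,
                       model_dims(s_h = 8L, v_h = 2L, penultimate = 12L,
                                  k = 5L), lm = lm, seed = 8L)
  p64 <- residue_saliency(model, st, steps = 64L)
  p128 <- residue_saliency(model, st, steps = 128L)
  delta <- max(abs(p64$score - p128$score))
  scale <- max(abs(p64$score))
  expect_lt(delta / max(scale, 1e-12),
            max(p64$completeness_gap, 1e-3) * 10)
})

test_that("saliency AUROC reproduces the stated toys and the pair oracle", {
  lab <- c(1, 0, 1, 0, 0, 0)
  expect_equal(saliency_auroc(lab, lab), 1.0)
  expect_equal(saliency_auroc(1 - lab, lab), 0.0)
  sc <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1)
  expect_equal(saliency_auroc(sc, lab), oracle_auroc(sc, lab))
  expect_error(saliency_auroc(sc, rep(0, 6)), "degenerate")
  expect_error(saliency_auroc(sc, lab[1:3]), "length mismatch")
})

test_that("ligand-proximity fallback marks residues with close sidechain atoms", {
  st <- build_chain(chain_spec(6L, seed = 56L))
  st$cb_imputed[] <- FALSE          # write C-beta atoms as observed sidechains
  pdb <- write_pdb(st)
  # ligand atom 3 A from residue 2's C-beta
  cb2 <- st$coords_CB[2L, ] + c(0, 0, 3)
  lig <- sprintf("HETATM  999  C1  LIG A 900    %8.3f%8.3f%8.3f  1.00  0.00           C",
                 cb2[1L], cb2[2L], cb2[3L])
  # default 5 A radius reaches several neighbouring sidechains of the
  # compact helix; at 3.1 A only residues 2 and 3 (C-betas at 3.00 and
  # 2.81 A from the ligand) remain
  ann5 <- binding_sites_from_ligand(c(pdb[-length(pdb)], lig, "END"))
  expect_true(ann5[2L] == 1L)
  ann <- binding_sites_from_ligand(c(pdb[-length(pdb)], lig, "END"),
                                   radius = 3.1)
  expect_equal(which(ann == 1L), c(2L, 3L))
  # far ligand marks nothing
  lig_far <- sub("C1  LIG", "C1  LIG", sprintf(
    "HETATM  999  C1  LIG A 900    %8.3f%8.3f%8.3f  1.00  0.00           C",
    500, 500, 500))
  ann2 <- binding_sites_from_ligand(c(pdb[-length(pdb)], lig_far, "END"))
  expect_true(all(ann2 == 0L))
  # waters are not ligands
  wat <- sprintf("HETATM  998  O   HOH A 901    %8.3f%8.3f%8.3f  1.00  0.00           O",
                 cb2[1L], cb2[2L], cb2[3L])
  ann3 <- binding_sites_from_ligand(c(pdb[-length(pdb)], wat, "END"))
  expect_true(all(ann3 == 0L))
})

test_that("binding-site TSV reader builds the binary profile", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tpositions", "p1\t2,5,6", "p2\t1"), f)
  expect_equal(read_binding_sites(f, "p1", 8L),
               c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 0L))
  expect_error(read_binding_sites(f, "zz", 8L), "not found")
  unlink(f)
})
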