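# GVP transform, GVP convolution, GAT layer and readouts, checked against
# dense brute-force oracles and for their geometric symmetry properties.

rand_state <- function(n, a, v, seed = 1L) {
  set.seed(seed)
  list(s = matrix(rnorm(n * a), n, a),
       Vx = matrix(rnorm(n * v), n, v),
       Vy = matrix(rnorm(n * v), n, v),
       Vz = matrix(rnorm(n * v), n, v))
}

rotate_state <- function(st, R) {
  out <- st
  for (i in seq_len(nrow(st$Vx))) for (j in seq_len(ncol(st$Vx))) {
    v <- R %*% c(st$Vx[i, j], st$Vy[i, j], st$Vz[i, j])
    out$Vx[i, j] <- v[1L]; out$Vy[i, j] <- v[2L]; out$Vz[i, j] <- v[3L]
  }
  out
}

test_that("gvp_transform reshapes as configured and matches the dense oracle", {
  set.seed(3)
  p <- gvp_params(4L, 2L, 3L, 5L)
  st <- rand_state(6L, 4L, 2L, seed = 8L)
  tape <- ad_tape()
  out <- gvp_transform(tape, st$s, list(x = st$Vx, y = st$Vy, z = st$Vz), p)
  expect_equal(dim(ad_value(out$s)), c(6L, 3L))
  expect_equal(dim(ad_value(out$V$x)), c(6L, 5L))
  ref <- oracle_gvp(st$s, st$Vx, st$Vy, st$Vz, p)
  expect_lt(max(abs(ad_value(out$s) - ref$s)), 1e-10)
  expect_lt(max(abs(ad_value(out$V$x) - ref$Vx)), 1e-10)
  expect_lt(max(abs(ad_value(out$V$z) - ref$Vz)), 1e-10)
  expect_error(gvp_transform(tape, st$s[, 1:3], list(x = st$Vx, y = st$Vy,
                                                     z = st$Vz), p),
               "width mismatch")
})

test_that("zero vector channel passes through as zeros, scalars see zero norms", {
  set.seed(4)
  p <- gvp_params(4L, 2L, 3L, 2L)
  s <- matrix(rnorm(8), 2L, 4L)
  z <- matrix(0, 2L, 2L)
  tape <- ad_tape()
  out <- gvp_transform(tape, s, list(x = z, y = z, z = z), p)
  expect_true(all(ad_value(out$V$x) == 0))
  expect_true(all(ad_value(out$V$y) == 0))
  # scalar path equals an explicit affine + relu on (s || zero norms)
  manual <- pmax(cbind(s, z) %*% t(p$Ws$value) +
                   matrix(p$bs$value, 2L, 3L, byrow = TRUE), 0)
  expect_equal(ad_value(out$s), manual)
})

test_that("gvp_transform is O(3)-equivariant: scalars invariant, vectors rotate", {
  set.seed(5)
  p <- gvp_params(5L, 3L, 4L, 3L)
  st <- rand_state(7L, 5L, 3L, seed = 9L)
  V <- list(x = st$Vx, y = st$Vy, z = st$Vz)
  tape <- ad_tape()
  base <- gvp_transform(tape, st$s, V, p)
  refl <- diag(c(-1, 1, 1))
  for (M in list(random_rotation(), random_rotation() %*% refl)) {
    str_ <- rotate_state(st, M)
    tape2 <- ad_tape()
    out <- gvp_transform(tape2, str_$s, list(x = str_$Vx, y = str_$Vy,
                                             z = str_$Vz), p)
    expect_lt(max(abs(ad_value(out$s) - ad_value(base$s))) /
                max(abs(ad_value(base$s))), 1e-10)
    rot_base <- rotate_state(list(Vx = ad_value(base$V$x),
                                  Vy = ad_value(base$V$y),
                                  Vz = ad_value(base$V$z)), M)
    expect_lt(max(abs(ad_value(out$V$x) - rot_base$Vx)), 1e-10)
    expect_lt(max(abs(ad_value(out$V$y) - rot_base$Vy)), 1e-10)
  }
})

test_that("gvp_conv_layer matches a dense per-edge loop oracle", {
  set.seed(6)
  st <- toy_structure(4L, seed = 6L)
  g <- featurize_graph(st, k = 2L)
  p <- gvp_conv_params(5L, 3L, dropout = 0)
  ns <- rand_state(4L, 5L, 3L, seed = 10L)
  tape <- ad_tape()
  out <- gvp_conv_layer(tape, g, ns$s, list(x = ns$Vx, y = ns$Vy, z = ns$Vz), p)
  ref <- oracle_gvp_conv(g, ns$s, ns$Vx, ns$Vy, ns$Vz, p)
  expect_lt(max(abs(ad_value(out$s) - ref$s)), 1e-6)
  expect_lt(max(abs(ad_value(out$V$x) - ref$Vx)), 1e-6)
  expect_lt(max(abs(ad_value(out$V$y) - ref$Vy)), 1e-6)
  expect_lt(max(abs(ad_value(out$V$z) - ref$Vz)), 1e-6)
})

test_that("zero-weight messages leave only the residual/normalization path", {
  st <- toy_structure(5L, seed = 2L)
  g <- featurize_graph(st, k = 2L)
  p <- gvp_conv_params(4L, 2L, dropout = 0)
  for (nm in c("Wh", "Ws", "Wv", "Wg")) p$msg[[nm]]$value[] <- 0
  p$msg$bs$value[] <- 0; p$msg$bg$value[] <- 0
  ns <- rand_state(5L, 4L, 2L, seed = 3L)
  tape <- ad_tape()
  out <- gvp_conv_layer(tape, g, ns$s, list(x = ns$Vx, y = ns$Vy, z = ns$Vz), p)
  # scalar: LayerNorm of the input state itself
  g_ <- as.numeric(p$ln_gamma$value); b_ <- as.numeric(p$ln_beta$value)
  manual <- t(apply(ns$s, 1L, function(r)
    g_ * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) + b_))
  expect_equal(ad_value(out$s), manual, tolerance = 1e-12)
  # vectors: input scaled by the reciprocal mean norm
  nrm <- sqrt(ns$Vx^2 + ns$Vy^2 + ns$Vz^2)
  expect_equal(ad_value(out$V$x), ns$Vx / (rowMeans(nrm) + 1e-6),
               tolerance = 1e-12)
})

test_that("gat_layer gives uniform attention for identical features and matches dense oracle", {
  set.seed(7)
  st <- toy_structure(5L, seed = 4L)
  g <- featurize_graph(st, k = 2L)
  p <- gat_params(6L, 4L)
  # identical node features -> alpha uniform -> output = elu(W h)
  x_same <- matrix(rep(rnorm(6L), each = 5L), 5L, 6L)
  tape <- ad_tape()
  out <- gat_layer(tape, g, x_same, p)
  wh <- as.numeric(p$heads[[1L]]$W$value %*% x_same[1L, ])
  manual <- ifelse(wh > 0, wh, exp(pmin(wh, 0)) - 1)
  for (i in 1:5) expect_equal(ad_value(out)[i, ], manual, tolerance = 1e-10)
  # random features vs dense-adjacency oracle
  x <- matrix(rnorm(30), 5L, 6L)
  tape2 <- ad_tape()
  out2 <- gat_layer(tape2, g, x, p)
  expect_lt(max(abs(ad_value(out2) - oracle_gat(g, x, p))), 1e-6)
})

test_that("an isolated node attends only to itself", {
  p <- gat_params(3L, 3L)
  # hand-built graph: node 3 has no incoming edges
  g <- list(n_nodes = 3L, edges = data.frame(src = c(1L, 2L), dst = c(2L, 1L)))
  x <- matrix(rnorm(9), 3L, 3L)
  tape <- ad_tape()
  out <- gat_layer(tape, g, x, p, act = "identity")
  expect_equal(ad_value(out)[3L, ],
               as.numeric(p$heads[[1L]]$W$value %*% x[3L, ]),
               tolerance = 1e-10)
})

test_that("multi-head GAT concatenates head outputs", {
  st <- toy_structure(6L, seed = 5L)
  g <- featurize_graph(st, k = 3L)
  p <- gat_params(5L, 6L, heads = 2L)
  tape <- ad_tape()
  out <- gat_layer(tape, g, matrix(rnorm(30), 6L, 5L), p)
  expect_equal(dim(ad_value(out)), c(6L, 6L))
})

test_that("readout pooling is additive (sum) / intensive (mean) and concatenates layers", {
  set.seed(8)
  layer1 <- matrix(rnorm(12), 4L, 3L)
  layer2 <- matrix(rnorm(8), 4L, 2L)
  ro <- readout(list(layer1, layer2), pool = "sum")
  expect_equal(ncol(ro), 5L)
  # duplicated graph: sum doubles, mean is unchanged
  dup <- list(rbind(layer1, layer1), rbind(layer2, layer2))
  expect_equal(readout(dup, pool = "sum"), 2 * ro)
  expect_equal(readout(dup, pool = "mean"),
               readout(list(layer1, layer2), pool = "mean"))
  # masked pooling honors the mask
  expect_equal(readout(list(layer1), pool = "mean", mask = c(TRUE, FALSE, FALSE, FALSE)),
               layer1[1L, , drop = FALSE], ignore_attr = TRUE)
  expect_error(readout(list(layer1), mask = rep(FALSE, 4L)), "empty mask")
  # 3 layers of width 100 -> width-300 readout
  wide <- replicate(3L, matrix(0, 5L, 100L), simplify = FALSE)
  expect_equal(ncol(readout(wide)), 300L)
})

test_that("full GVP network output is invariant to rigid motions of the coordinates", {
  set.seed(9)
  st <- toy_structure(12L, seed = 12L)
  m <- build_model("gvp", task = "multilabel", n_outputs = 3L,
                   dims = model_dims(s_h = 12L, v_h = 4L, penultimate = 20L,
                                     k = 8L),
                   seed = 31L)
  g <- featurize_graph(st, k = 8L)
  tape <- ad_tape()
  z0 <- ad_value(model_forward(tape, m, g))
  for (rep in 1:3) {
    R <- random_rotation(); tr <- rnorm(3, sd = 30)
    g2 <- featurize_graph(transform_structure(st, R, tr), k = 8L)
    tape2 <- ad_tape()
    z <- ad_value(model_forward(tape2, m, g2))
    expect_lt(max(abs(z - z0)) / max(abs(z0)), 1e-4)
  }
})

test_that("network scalars are invariant under improper transforms of the vector features", {
  # reflections applied to the graph's vector channel (the network level at
  # which O(3) invariance holds; the featurization itself is chirality-aware)
  set.seed(10)
  st <- toy_structure(10L, seed = 13L)
  m <- build_model("gvp", task = "regression", n_outputs = 1L,
                   dims = model_dims(s_h = 10L, v_h = 3L, penultimate = 16L,
                                     k = 6L),
                   seed = 5L)
  g <- featurize_graph(st, k = 6L)
  tape <- ad_tape()
  z0 <- ad_value(model_forward(tape, m, g))
  M <- random_rotation() %*% diag(c(1, 1, -1))
  g2 <- g
  for (nm in names(g2$node_vector)) g2$node_vector[[nm]] <-
    g2$node_vector[[nm]] %*% t(M)
  g2$edge_vector <- g2$edge_vector %*% t(M)
  tape2 <- ad_tape()
  expect_lt(abs(ad_value(model_forward(tape2, m, g2)) - z0) / abs(z0), 1e-10)
})

test_that("forward passes are bitwise deterministic with dropout off", {
  st <- toy_structure(8L, seed = 3L)
  m <- build_model("gvp", task = "regression",
                   dims = model_dims(s_h = 8L, v_h = 2L, penultimate = 12L,
                                     k = 5L), seed = 2L)
  g <- featurize_graph(st, k = 5L)
  t1 <- ad_tape(); z1 <- ad_value(model_forward(t1, m, g))
  t2 <- ad_tape(); z2 <- ad_value(model_forward(t2, m, g))
  expect_identical(z1, z2)
})
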