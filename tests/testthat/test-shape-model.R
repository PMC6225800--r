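test_that("Procrustes alignment removes similarity transforms exactly", {
  base <- knee_template("PA")$points
  tf <- list(scale = 1.7, rotation = 0.4, translation = c(3, -2))
  al <- procrustes_align(list(base, apply_similarity(base, tf)))
  expect_lt(sum((al$aligned[[1]] - al$aligned[[2]])^2), 1e-10)

  # a single shape repeated: the mean is that shape, normalized
  al2 <- procrustes_align(list(base, base, base))
  expect_lt(max(abs(al2$mean_shape - kneestudy:::normalize_shape(base))), 1e-10)

  expect_error(procrustes_align(list(base)), "at least 2")
  expect_error(procrustes_align(list(base, base[1:50, ])), "topolog")
  degenerate <- matrix(1, 74, 2)
  expect_error(procrustes_align(list(degenerate, degenerate)), "degenerate")
})

test_that("the Procrustes mean matches a naive alternating-minimization oracle", {
  set.seed(14)
  shapes <- lapply(1:20, function(i) {
    s <- knee_template("PA")$points + matrix(rnorm(148, 0, 0.01), ncol = 2)
    tf <- list(scale = exp(rnorm(1, 0, 0.1)), rotation = rnorm(1, 0, 0.2),
               translation = rnorm(2, 0, 5))
    apply_similarity(s, tf)
  })
  m_pkg <- procrustes_align(shapes)$mean_shape
  m_orc <- procrustes_oracle(shapes)
  # resolve the rotation gauge freedom before comparing
  tf <- kneestudy:::similarity_fit(m_orc, m_pkg)
  expect_lt(sqrt(mean((apply_similarity(m_orc, tf) - m_pkg)^2)), 1e-6)
})

test_that("shape-model PCA satisfies its algebraic invariants", {
  set.seed(15)
  shapes <- lapply(rnorm(60), function(s) instantiate_shape(s, "PA")$points)
  al <- procrustes_align(shapes)
  m <- build_shape_model(al, 0.95, view = "PA")
  G <- crossprod(m$modes)
  expect_lt(max(abs(G - diag(ncol(m$modes)))), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_lte(ncol(m$modes), min(59, 148))
  # eigenvalue sum equals the total variance of the aligned data
  X <- t(vapply(al$aligned, as.vector, numeric(148)))
  expect_equal(sum(m$all_eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-8)

  # alignment invariance: a common similarity transform changes nothing
  tf <- list(scale = 2.5, rotation = 1.1, translation = c(40, -7))
  m2 <- build_shape_model(procrustes_align(lapply(shapes, apply_similarity, tf = tf)),
                          0.95, view = "PA")
  expect_equal(m$eigenvalues, m2$eigenvalues, tolerance = 1e-6)

  # degenerate case: identical shapes give a mean-only model
  m0 <- build_shape_model(list(shapes[[1]], shapes[[1]], shapes[[1]]), 0.95)
  expect_identical(ncol(m0$modes), 0L)

  expect_error(build_shape_model(al, 1.5), "variance_retained")
  expect_error(build_shape_model(al$aligned[1:2]), "at least 3")
})

test_that("a known two-mode generator is recovered from sampled shapes", {
  gen <- two_mode_shapes(500, eig = c(9, 1), seed = 16)
  m <- build_shape_model(gen$shapes, 0.99)
  expect_gte(ncol(m$modes), 2L)
  rel_err <- abs(m$all_eigenvalues[1:2] - gen$eigenvalues) / gen$eigenvalues
  expect_true(all(rel_err < 0.15))
  ang <- principal_angles_deg(m$modes[, 1:2], gen$modes)
  expect_true(all(ang < 5))
})

test_that("shape parameterization round-trips and clamps correctly", {
  set.seed(17)
  shapes <- lapply(rnorm(40), function(s) instantiate_shape(s, "PA")$points)
  al <- procrustes_align(shapes)
  m <- build_shape_model(al, 1.0, view = "PA")

  # b = 0 with identity pose gives the mean shape
  expect_equal(params_to_shape(numeric(ncol(m$modes)), NULL, m, view = NULL),
               m$mean_shape, tolerance = 1e-12, ignore_attr = TRUE)

  # full-variance round trip on a training shape
  p <- shape_to_params(shapes[[5]], m)
  rec <- params_to_shape(p$b, p$pose, m)
  expect_lt(max(abs(rec$points - shapes[[5]])), 1e-6)

  # synthesizing from random b and re-fitting reconstructs the shape exactly;
  # b itself is recovered up to the pose-shape gauge coupling (no tangent
  # projection), which the alternating fit reduces to well below mode scale
  set.seed(18)
  for (i in 1:5) {
    b <- rnorm(ncol(m$modes), 0, sqrt(m$eigenvalues))
    s <- params_to_shape(b, list(scale = 2, rotation = 0.3, translation = c(9, 4)), m)
    p2 <- shape_to_params(s, m)
    expect_lt(point_to_point_error(params_to_shape(p2$b, p2$pose, m), s), 1e-8)
    expect_lt(max(abs(p2$b - b)), 0.05 * max(sqrt(m$eigenvalues)))
  }
  # at a fixed (identity) pose the projection identity is exact
  b0 <- rnorm(ncol(m$modes), 0, sqrt(m$eigenvalues))
  s0 <- params_to_shape(b0, NULL, m, view = NULL)
  b0_rec <- drop(crossprod(m$modes, as.vector(s0) - as.vector(m$mean_shape)))
  expect_lt(max(abs(b0_rec - b0)), 1e-10)

  expect_error(params_to_shape(numeric(2 + ncol(m$modes)), NULL, m), "retained modes")

  # clamp equals the element-wise oracle
  set.seed(19)
  for (i in 1:10) {
    b <- rnorm(ncol(m$modes), 0, 4 * sqrt(m$eigenvalues))
    lim <- 3 * sqrt(m$eigenvalues)
    oracle <- mapply(function(bj, lj) max(min(bj, lj), -lj), b, lim)
    expect_equal(constrain_params(b, m, k = 3), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  b_in <- rnorm(ncol(m$modes), 0, 0.1 * sqrt(m$eigenvalues))
  expect_identical(constrain_params(b_in, m), b_in)
})

test_that("reconstruction error is monotone non-increasing in retained modes", {
  set.seed(20)
  shapes <- lapply(rnorm(30), function(s) instantiate_shape(s, "PA")$points)
  m <- build_shape_model(procrustes_align(shapes), 1.0, view = "PA")
  target <- shapes[[3]]
  p <- shape_to_params(target, m)
  errs <- vapply(0:ncol(m$modes), function(j) {
    bj <- p$b; if (j < length(bj)) bj[(j + 1):length(bj)] <- 0
    rec <- params_to_shape(bj, p$pose, m)$points
    sqrt(sum((rec - target)^2))          # L2 norm of the residual vector
  }, 0)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("models survive a serialization round trip", {
  set.seed(22)
  shapes <- lapply(rnorm(20), function(s) instantiate_shape(s, "PA")$points)
  m <- build_shape_model(procrustes_align(shapes), 0.95, view = "PA")
  path <- file.path(tempdir(), "model.shm")
  save_model(m, path)
  m2 <- load_model(path)
  expect_s3_class(m2, "shape_model")
  expect_equal(m$modes, m2$modes, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m$eigenvalues, m2$eigenvalues, tolerance = 1e-12)
  expect_equal(m$mean_shape, m2$mean_shape, tolerance = 1e-12, ignore_attr = TRUE)
})
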