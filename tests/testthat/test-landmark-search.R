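# One shared PA fixture for the whole file: 25 rendered training knees.
fixture <- render_set(25, seed = 31, image_size = 160)
regressors <- train_point_regressors(fixture$images, fixture$landmarks, seed = 32)
pdm <- build_shape_model(procrustes_align(fixture$landmarks), 0.95, view = "PA")

test_that("the detector localizes a fixed scene and is total on noise", {
  # constant location/scale: rendered without shape variation
  cfg <- cohort_config(n_subjects = 1, image_size = 128)
  set.seed(33)
  fixed <- lapply(1:12, function(i) render_knee(0, "PA", cfg, shape_noise_sd = 0))
  det <- train_detector(lapply(fixed, `[[`, "image"),
                        lapply(fixed, `[[`, "landmarks"), seed = 34)
  set.seed(35)
  probe <- render_knee(0, "PA", cfg, shape_noise_sd = 0)
  box <- detect_box(probe$image, det)
  truth <- kneestudy:::landmark_bbox(probe$landmarks)
  expect_lt(sqrt(sum((box$center - truth[c("cx", "cy")])^2)), 2)

  # pure-noise input still yields one box (flagged by its confidence score)
  set.seed(36)
  noise_box <- detect_box(matrix(runif(128 * 128), 128, 128), det)
  expect_true(is.finite(noise_box$width) && noise_box$width > 0)
  expect_true(noise_box$confidence > 0 && noise_box$confidence <= 1)
  expect_error(train_detector(fixture$images[1:5], fixture$landmarks[1:5]),
               "at least 10")
})

test_that("the detector tracks randomized translations of a fixed scene", {
  canvas <- 224; inner <- 128
  cfg <- cohort_config(n_subjects = 1, image_size = inner)
  set.seed(37)
  scene <- render_knee(0.5, "PA", cfg)
  make_shifted <- function(n) {
    lapply(1:n, function(i) {
      ox <- sample(0:(canvas - inner), 1); oy <- sample(0:(canvas - inner), 1)
      img <- matrix(stats::rnorm(canvas^2, 0.15, 0.05), canvas, canvas)
      img[oy + seq_len(inner), ox + seq_len(inner)] <- scene$image
      list(image = pmin(pmax(img, 0), 1),
           landmarks = landmark_set(sweep(scene$landmarks$points, 2, c(ox, oy), `+`), "PA"))
    })
  }
  train <- make_shifted(200)
  test <- make_shifted(50)
  det <- train_detector(lapply(train, `[[`, "image"),
                        lapply(train, `[[`, "landmarks"),
                        n_trees = 50, grid = 16, seed = 38)
  errs <- vapply(test, function(ex) {
    box <- detect_box(ex$image, det)
    truth <- kneestudy:::landmark_bbox(ex$landmarks)
    sqrt(sum((box$center - truth[c("cx", "cy")])^2))
  }, 0)
  expect_lt(median(errs), 5)
})

test_that("patch regressors predict near-zero displacement at zero sampling range", {
  reg0 <- train_point_regressors(fixture$images[1:10], fixture$landmarks[1:10],
                                 sampling_range = 1e-9, patches_per_image = 4,
                                 seed = 39)
  truth <- fixture$landmarks[[1]]$points
  P <- kneestudy:::extract_patches(fixture$images[[1]], truth[1:8, , drop = FALSE], 15)
  colnames(P) <- kneestudy:::patch_feature_names(15)
  for (j in 1:8) {
    row <- as.data.frame(P[j, , drop = FALSE])
    dx <- predict(reg0$regressors[[j]]$dx, row, num.threads = 1)$predictions
    dy <- predict(reg0$regressors[[j]]$dy, row, num.threads = 1)$predictions
    expect_lt(abs(dx), 0.1); expect_lt(abs(dy), 0.1)
  }
})

test_that("response maps conserve votes, peak near the truth, and flatten on blank input", {
  set.seed(40)
  probe <- render_knee(0.3, "PA", fixture$config)
  truth <- probe$landmarks$points
  maps <- compute_response_maps(probe$image, truth, regressors,
                                search_radius = 12, grid_step = 3)
  n_grid <- length(seq(-12, 12, by = 3))^2
  # peaks localize the bone contour; along-contour position is ambiguous for
  # outline points (resolved only by the shape constraint), so measure the
  # distance from each peak to the true outline
  topo <- probe$landmarks$topology
  dense <- do.call(rbind, lapply(names(topo$subshapes), function(nm) {
    kneestudy:::densify_polyline(truth[topo$subshapes[[nm]], , drop = FALSE],
                                 step = 0.25, closed = (nm == "patella"))
  }))
  contour_err <- vapply(seq_along(maps), function(j) {
    pk <- kneestudy:::response_peak(maps[[j]])
    sqrt(min((dense[, 1] - pk[1])^2 + (dense[, 2] - pk[2])^2))
  }, 0)
  expect_gt(mean(contour_err < 2), 0.9)
  point_err <- vapply(seq_along(maps), function(j) {
    pk <- kneestudy:::response_peak(maps[[j]])
    sqrt(sum((pk - truth[j, ])^2))
  }, 0)
  expect_lt(median(point_err), 4)
  for (m in maps[1:10]) {
    expect_lte(m$n_votes, n_grid)
    expect_equal(sum(m$map), m$n_votes)
    expect_true(all(m$map >= 0))
  }
  # constant image: identical patches, identical votes, no informative peak
  flat <- compute_response_maps(matrix(0, 160, 160), truth, regressors)
  expect_lte(max(flat[[1]]$map), 1)
})

test_that("the constrained fit stays near truth, respects the PDM box, and is deterministic", {
  img <- fixture$images[[2]]; truth <- fixture$landmarks[[2]]
  fit <- clm_fit(img, NULL, regressors, pdm, init = truth$points, truth = truth)
  # the fit equilibrates within the system's accuracy floor
  expect_lt(fit$mean_point_error_vs_truth, 3)
  expect_true(all(abs(fit$b) <= 3 * sqrt(pdm$eigenvalues) + 1e-9))
  fit2 <- clm_fit(img, NULL, regressors, pdm, init = truth$points, truth = truth)
  expect_identical(fit$landmarks$points, fit2$landmarks$points)
  expect_s3_class(fit$landmarks, "landmark_set")
  expect_true(validate_landmarks(fit$landmarks))
})

test_that("fitting reduces a deliberate initialization error on unseen images", {
  set.seed(41)
  improved <- logical(6)
  for (i in 1:6) {
    rk <- render_knee(rnorm(1), "PA", fixture$config)
    init <- rk$landmarks$points +
      matrix(rep(c(10.6, -10.6), each = 74), ncol = 2)
    e0 <- point_to_point_error(init, rk$landmarks)
    fit <- clm_fit(rk$image, NULL, regressors, pdm, init = init, truth = rk$landmarks)
    improved[i] <- fit$mean_point_error_vs_truth < 0.5 * e0
  }
  expect_gte(sum(improved), 5)
})

test_that("point-to-point error matches its definition", {
  a <- knee_template("PA", 128)
  expect_identical(point_to_point_error(a, a), 0)
  shifted <- landmark_set(sweep(a$points, 2, c(3, 0), `+`), "PA")
  expect_equal(point_to_point_error(shifted, a), 3, tolerance = 1e-12)
  set.seed(42)
  p1 <- matrix(rnorm(40), 20); p2 <- matrix(rnorm(40), 20)
  expect_equal(point_to_point_error(p1, p2),
               mean(sqrt(rowSums((p1 - p2)^2))), tolerance = 1e-12)
  expect_error(point_to_point_error(p1, p2[1:10, ]), "differ in size")
})
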