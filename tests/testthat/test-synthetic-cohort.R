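test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(transient_flip_prob = 0.6), "transient_flip_prob")
  expect_error(cohort_config(severity_grade_loadings = rep(0.5, 10)),
               "severity_grade_loadings")
  expect_error(cohort_config(severity_grade_loadings = rep(1.5, 36)),
               "severity_grade_loadings")
  expect_error(cohort_config(widespread_fraction = 1.2), "widespread_fraction")
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(grade_noise_sd = -1), "grade_noise_sd")
})

test_that("latent sampling is deterministic and follows the logistic-normal link", {
  cfg <- cohort_config(n_subjects = 200, seed = 11)
  expect_identical(sample_latent(cfg), sample_latent(cfg))

  # zero slope and no widespread subgroup: pain independent of severity
  cfg0 <- cohort_config(n_subjects = 10000, seed = 3, pain_slope = 0,
                        widespread_fraction = 0, bmi_pain_coef = 0,
                        sex_pain_coef = 0)
  lat0 <- sample_latent(cfg0)
  expect_lt(abs(cor(lat0$severity, lat0$persistent_pain)), 0.03)

  # prevalence at intercept 0, slope 1 matches the normal-logistic integral
  oracle <- integrate(function(z) plogis(z) * dnorm(z), -Inf, Inf)$value
  cfg1 <- cohort_config(n_subjects = 50000, seed = 5, pain_intercept = 0,
                        pain_slope = 1, widespread_fraction = 0,
                        bmi_pain_coef = 0, sex_pain_coef = 0)
  lat1 <- sample_latent(cfg1)
  expect_lt(abs(mean(lat1$persistent_pain) - oracle), 0.01)
})

test_that("grades respect their scales and track severity as configured", {
  ft <- knee_feature_table()
  expect_identical(nrow(ft), 36L)
  cfg <- cohort_config(n_subjects = 2000, seed = 8)
  lat <- sample_latent(cfg)
  g <- grades_from_severity(lat$severity, cfg)
  expect_identical(colnames(g), ft$name)
  for (k in seq_len(36)) {
    expect_true(all(g[, k] >= 0 & g[, k] <= ft$max_grade[k]))
  }

  # zero noise and full loading: grade is a monotone function of severity
  cfg_m <- cohort_config(n_subjects = 500, seed = 9, grade_noise_sd = 0,
                         severity_grade_loadings = rep(1, 36))
  lat_m <- sample_latent(cfg_m)
  set.seed(1)
  gm <- grades_from_severity(lat_m$severity, cfg_m)
  ord <- order(lat_m$severity)
  for (k in c(1, 7, 19)) {
    expect_true(all(diff(gm[ord, k]) >= 0))
  }
})

test_that("grade-severity rank correlation matches a direct Monte-Carlo oracle", {
  w <- 0.8
  loadings <- rep(0, 36); loadings[7] <- w   # the 0-4 global grade slot
  cfg <- cohort_config(n_subjects = 20000, seed = 13,
                       severity_grade_loadings = loadings)
  lat <- sample_latent(cfg)
  g <- grades_from_severity(lat$severity, cfg)
  rho_pkg <- cor(g[, 7], lat$severity, method = "spearman")

  # oracle: direct simulation with 1e6 draws using plain arithmetic
  set.seed(99)
  z <- rnorm(1e6)
  latent <- w * z + rnorm(1e6, 0, cfg$grade_noise_sd)
  thr <- qnorm(c(0.35, 0.60, 0.80, 0.93), 0, sqrt(w^2 + cfg$grade_noise_sd^2))
  rho_mc <- cor(findInterval(latent, thr), z, method = "spearman")
  expect_lt(abs(rho_pkg - rho_mc), 0.02)
})

test_that("pain reports are flip-noised copies of the persistent state", {
  cfg0 <- cohort_config(n_subjects = 100, transient_flip_prob = 0)
  persistent <- rbinom(100, 1, 0.5)
  set.seed(2)
  r0 <- pain_reports(persistent, cfg0)
  expect_identical(r0$tscreen, persistent)
  expect_identical(r0$saq, persistent)
  expect_identical(r0$clinic, persistent)

  # closed form: P(all three stay 1) = (1 - flip)^3 = 0.85^3
  cfg <- cohort_config(n_subjects = 1e5, transient_flip_prob = 0.15)
  set.seed(3)
  r <- pain_reports(rep(1L, 1e5), cfg)
  p_all <- mean(r$tscreen == 1 & r$saq == 1 & r$clinic == 1)
  expect_lt(abs(p_all - 0.85^3), 0.01)
})

test_that("rendered knees follow the view topologies and the template geometry", {
  cfg <- cohort_config(n_subjects = 1, image_size = 128)
  set.seed(4)
  pa <- render_knee(0.5, "PA", cfg)
  la <- render_knee(0.5, "LATERAL", cfg)
  expect_identical(nrow(pa$landmarks$points), 74L)
  expect_identical(nrow(la$landmarks$points), 102L)
  expect_true(validate_landmarks(pa$landmarks))
  expect_true(validate_landmarks(la$landmarks))
  expect_true(all(pa$image >= 0 & pa$image <= 1))

  # zero severity with shape noise off reproduces the template exactly
  set.seed(4)
  rk0 <- render_knee(0, "PA", cfg, shape_noise_sd = 0)
  tmpl <- knee_template("PA", image_size = 128)
  expect_lt(max(abs(rk0$landmarks$points - tmpl$points)), 1e-10)

  expect_error(render_knee(0, "PA", cohort_config(image_size = 48)), NA)
  expect_error(cohort_config(image_size = 20), "image_size")
})

test_that("severity narrows the tibiofemoral gap by the generator's own formula", {
  cfg <- cohort_config(n_subjects = 1, image_size = 160)
  set.seed(6)
  hi <- render_knee(2, "PA", cfg, shape_noise_sd = 0)
  lo <- render_knee(-2, "PA", cfg, shape_noise_sd = 0)
  g_hi <- tibiofemoral_gap(hi$landmarks)
  g_lo <- tibiofemoral_gap(lo$landmarks)
  expect_lt(g_hi, g_lo)
  # whole-tibia translation: the gap difference is exactly 4 * rate * scale
  expect_equal(g_lo - g_hi, 4 * kneestudy:::severity_gap_per_sd * (160 - 1),
               tolerance = 1e-9)
})

test_that("cohort artifacts are byte-identical across reruns and counts are sane", {
  cfg <- cohort_config(n_subjects = 6, seed = 21, image_size = 96)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "cohort.csv"))),
                   unname(tools::md5sum(file.path(d2, "cohort.csv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "images/knee_00001.png"))),
                   unname(tools::md5sum(file.path(d2, "images/knee_00001.png"))))
  pts <- read_points(file.path(d1, "points/knee_00001.pts"), "PA")
  expect_identical(nrow(pts$points), 74L)

  co <- generate_cohort(cohort_config(n_subjects = 2000, seed = 31,
                                      widespread_fraction = 0.5),
                        render = FALSE)$table
  n_ws <- sum(co$widespread)
  expect_gte(n_ws, qbinom(0.005, 2000, 0.5))
  expect_lte(n_ws, qbinom(0.995, 2000, 0.5))
})
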