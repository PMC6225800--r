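#' Radiographic feature catalogue
#'
#' The 36 individually graded radiographic features scored on the PA and
#' lateral views: per-feature ordinal grades (mostly OARSI-style 0-1 or 0-3
#' scales) plus the global Kellgren-Lawrence grade (0-4). Column order is
#' fixed and used everywhere a grade matrix is assembled.
#'
#' Default severity loadings encode how strongly each synthetic grade tracks
#' the latent disease severity: the global severity grade loads highest,
#' osteophytes / joint space narrowing / sclerosis load moderately, and
#' features known to carry no signal (chondrocalcinosis, cysts, attrition,
#' patellar-tendon ossification) load zero, so downstream single-feature
#' classifiers sit at chance for them.
#'
#' @return data.frame with columns `name` (snake-case column name),
#'   `description`, `max_grade` (grades run 0..max_grade) and
#'   `default_loading`.
#' @export
knee_feature_table <- function() {
  f <- function(name, desc, g, w) data.frame(name = name, description = desc,
                                             max_grade = g, default_loading = w,
                                             stringsAsFactors = FALSE)
  rbind(
    f("chondro_pf_la",          "Chondrocalcinosis (0-1), PF joint, lateral view", 1L, 0.00),
    f("ost_fem_ant_pf_la",      "Osteophytes (0-3), femur anterior PF joint, lateral view", 3L, 0.50),
    f("ost_fem_post_pf_la",     "Osteophytes (0-3), femur posterior PF joint, lateral view", 3L, 0.55),
    f("jsn_lat_tf_la",          "Joint space narrowing (0-3), lateral TF compartment, lateral view", 3L, 0.30),
    f("jsn_med_tf_la",          "Joint space narrowing (0-3), medial TF compartment, lateral view", 3L, 0.50),
    f("effusion_pf_la",         "Effusion (0-1), PF joint, lateral view", 1L, 0.35),
    f("kl_pa",                  "Kellgren-Lawrence grade (0-4), PA view", 4L, 0.85),
    f("chondro_lat_tf_pa",      "Chondrocalcinosis (0-1), lateral TF compartment, PA view", 1L, 0.00),
    f("cyst_fem_lat_tf_pa",     "Cyst (0-3), femur lateral TF compartment, PA view", 3L, 0.00),
    f("ost_fem_lat_tf_pa",      "Osteophytes (0-3), femur lateral TF compartment, PA view", 3L, 0.55),
    f("scl_fem_lat_tf_pa",      "Sclerosis (0-3), femur lateral TF compartment, PA view", 3L, 0.25),
    f("jsn_lat_tf_pa",          "Joint space narrowing (0-3), lateral TF compartment, PA view", 3L, 0.28),
    f("attr_lat_tf_pa",         "Attrition (0-1), lateral TF compartment, PA view", 1L, 0.00),
    f("cyst_tib_lat_tf_pa",     "Cyst (0-3), tibia lateral TF compartment, PA view", 3L, 0.00),
    f("ost_tib_lat_tf_pa",      "Osteophytes (0-3), tibia lateral TF compartment, PA view", 3L, 0.55),
    f("scl_tib_lat_tf_pa",      "Sclerosis (0-3), tibia lateral TF compartment, PA view", 3L, 0.25),
    f("chondro_med_tf_pa",      "Chondrocalcinosis (0-1), medial TF compartment, PA view", 1L, 0.00),
    f("cyst_fem_med_tf_pa",     "Cyst (0-3), femur medial TF compartment, PA view", 3L, 0.00),
    f("ost_fem_med_tf_pa",      "Osteophytes (0-3), femur medial TF compartment, PA view", 3L, 0.60),
    f("scl_fem_med_tf_pa",      "Sclerosis (0-3), femur medial TF compartment, PA view", 3L, 0.45),
    f("jsn_med_tf_pa",          "Joint space narrowing (0-3), medial TF compartment, PA view", 3L, 0.45),
    f("attr_med_tf_pa",         "Attrition (0-1), medial TF compartment, PA view", 1L, 0.10),
    f("cyst_tib_med_tf_pa",     "Cyst (0-3), tibia medial TF compartment, PA view", 3L, 0.08),
    f("ost_tib_med_tf_pa",      "Osteophytes (0-3), tibia medial TF compartment, PA view", 3L, 0.55),
    f("scl_tib_med_tf_pa",      "Sclerosis (0-3), tibia medial TF compartment, PA view", 3L, 0.45),
    f("ossif_pat_tend_low_pf_la", "Ossification (0-3), patellar tendon lower PF joint, lateral view", 3L, 0.00),
    f("ossif_pat_tend_up_pf_la",  "Ossification (0-3), patellar tendon upper PF joint, lateral view", 3L, 0.00),
    f("loose_body_fem_post_pf_la", "Ossified loose body (0-1), femur posterior PF joint, lateral view", 1L, 0.10),
    f("ossif_quad_ins_pf_la",   "Ossification (0-3), quadriceps femoris insertion PF joint, lateral view", 3L, 0.05),
    f("cyst_pf_la",             "Cyst (0-3), PF joint, lateral view", 3L, 0.05),
    f("jsn_pf_la",              "Joint space narrowing (0-3), PF joint, lateral view", 3L, 0.20),
    f("scl_pf_la",              "Sclerosis (0-3), PF joint, lateral view", 3L, 0.20),
    f("ost_pat_inf_pf_la",      "Osteophytes (0-3), patella inferior PF joint, lateral view", 3L, 0.50),
    f("ost_pat_sup_pf_la",      "Osteophytes (0-3), patella superior PF joint, lateral view", 3L, 0.55),
    f("ost_tib_ant_pf_la",      "Osteophytes (0-3), tibia anterior PF joint, lateral view", 3L, 0.30),
    f("ost_tib_post_pf_la",     "Osteophytes (0-3), tibia posterior PF joint, lateral view", 3L, 0.50)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' A one-dimensional standard-normal latent osteoarthritis severity per knee
#' drives (a) joint geometry and texture, (b) the 36 ordinal reader-style
#' grades with per-feature signal strength, and (c) the propensity for
#' persistent frequent knee pain through a logistic link. Three binary pain
#' reports are the persistent state observed through independent symmetric
#' flip noise. A widespread-pain subgroup has pain independent of severity.
#'
#' @param n_subjects number of knees.
#' @param view `"PA"` or `"LATERAL"`.
#' @param image_size square image side in pixels.
#' @param severity_grade_loadings 36 loadings in `[0,1]`, ordered as
#'   [knee_feature_table()].
#' @param grade_noise_sd SD of the per-feature reader noise added to the
#'   loading-weighted severity before ordinal binning.
#' @param pain_intercept,pain_slope logistic-link coefficients of persistent
#'   pain on severity (non-widespread subjects).
#' @param bmi_pain_coef,sex_pain_coef additional logit contributions of
#'   standardized BMI and female sex to persistent pain.
#' @param transient_flip_prob probability, per report, that the observed
#'   binary pain answer flips from the persistent state; must be `< 0.5`.
#' @param widespread_fraction fraction of subjects in the widespread-pain
#'   subgroup.
#' @param widespread_pain_prob persistent-pain probability in that subgroup
#'   (independent of severity).
#' @param demo_params list with `age_mean`, `age_sd`, `bmi_mean`, `bmi_sd`,
#'   `prop_female`.
#' @param grade_quantiles list of cumulative marginal probabilities of the
#'   ordinal bins by scale length, emulating the sparsity of reader grading
#'   (most knees grade 0).
#' @param seed integer RNG seed.
#' @return a validated `cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 2756,
                          view = "PA",
                          image_size = 192,
                          severity_grade_loadings = knee_feature_table()$default_loading,
                          grade_noise_sd = 0.6,
                          pain_intercept = -0.85,
                          pain_slope = 1.0,
                          bmi_pain_coef = 0.4,
                          sex_pain_coef = 0.3,
                          transient_flip_prob = 0.15,
                          widespread_fraction = 0.5,
                          widespread_pain_prob = 0.35,
                          demo_params = list(age_mean = 62.3, age_sd = 8,
                                             bmi_mean = 30.7, bmi_sd = 5.9,
                                             prop_female = 0.6),
                          grade_quantiles = list(`1` = 0.80,
                                                 `3` = c(0.60, 0.85, 0.95),
                                                 `4` = c(0.35, 0.60, 0.80, 0.93)),
                          seed = 1L) {
  cfg <- list(n_subjects = n_subjects, view = toupper(view),
              image_size = image_size,
              severity_grade_loadings = severity_grade_loadings,
              grade_noise_sd = grade_noise_sd,
              pain_intercept = pain_intercept, pain_slope = pain_slope,
              bmi_pain_coef = bmi_pain_coef, sex_pain_coef = sex_pain_coef,
              transient_flip_prob = transient_flip_prob,
              widespread_fraction = widespread_fraction,
              widespread_pain_prob = widespread_pain_prob,
              demo_params = demo_params, grade_quantiles = grade_quantiles,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!ok) stop(sprintf("invalid `%s`: %s", field, msg))
  chk(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 1, "n_subjects", "must be >= 1")
  chk(cfg$view %in% c("PA", "LATERAL"), "view", "must be PA or LATERAL")
  chk(cfg$image_size >= 48, "image_size", "must be >= 48 px")
  w <- cfg$severity_grade_loadings
  chk(length(w) == 36, "severity_grade_loadings", "exactly 36 loadings required")
  chk(all(w >= 0 & w <= 1), "severity_grade_loadings", "loadings must lie in [0,1]")
  chk(cfg$grade_noise_sd >= 0, "grade_noise_sd", "must be >= 0")
  chk(cfg$transient_flip_prob >= 0 && cfg$transient_flip_prob < 0.5,
      "transient_flip_prob", "must lie in [0, 0.5)")
  chk(cfg$widespread_fraction >= 0 && cfg$widespread_fraction <= 1,
      "widespread_fraction", "must lie in [0,1]")
  chk(cfg$widespread_pain_prob >= 0 && cfg$widespread_pain_prob <= 1,
      "widespread_pain_prob", "must lie in [0,1]")
  dp <- cfg$demo_params
  chk(all(c("age_mean", "age_sd", "bmi_mean", "bmi_sd", "prop_female") %in% names(dp)),
      "demo_params", "needs age_mean, age_sd, bmi_mean, bmi_sd, prop_female")
  chk(dp$prop_female >= 0 && dp$prop_female <= 1, "demo_params", "prop_female must lie in [0,1]")
  invisible(cfg)
}

#' Read a cohort configuration from YAML or JSON
#'
#' Scalar fields in the file override the defaults of [cohort_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(vals), names(formals(cohort_config)))
  do.call(cohort_config, vals[keep])
}

#' Sample latent subjects
#'
#' Draws latent disease severity (standard normal), the widespread-pain flag,
#' demographics and the persistent-pain state. For non-widespread subjects
#' the persistent-pain probability follows a logistic link on severity plus
#' standardized BMI and female sex; for widespread subjects it is a constant
#' independent of severity.
#'
#' @param config a `cohort_config`; `config$seed` makes the draw
#'   reproducible.
#' @return data.frame with columns `id`, `severity`, `widespread`, `age`,
#'   `bmi`, `sex` ("F"/"M"), `persistent_pain`.
#' @export
sample_latent <- function(config) {
  validate_cohort_config(config)
  n <- config$n_subjects
  dp <- config$demo_params
  set.seed(config$seed)
  severity <- stats::rnorm(n)
  widespread <- stats::rbinom(n, 1, config$widespread_fraction)
  age <- stats::rnorm(n, dp$age_mean, dp$age_sd)
  bmi <- stats::rnorm(n, dp$bmi_mean, dp$bmi_sd)
  sex <- ifelse(stats::runif(n) < dp$prop_female, "F", "M")
  z_bmi <- (bmi - dp$bmi_mean) / dp$bmi_sd
  eta <- config$pain_intercept + config$pain_slope * severity +
    config$bmi_pain_coef * z_bmi + config$sex_pain_coef * (sex == "F")
  p <- ifelse(widespread == 1, config$widespread_pain_prob, stats::plogis(eta))
  persistent_pain <- stats::rbinom(n, 1, p)
  data.frame(id = sprintf("knee_%05d", seq_len(n)), severity = severity,
             widespread = widespread, age = age, bmi = bmi, sex = sex,
             persistent_pain = persistent_pain, stringsAsFactors = FALSE)
}

# Ordinal bin thresholds for a feature: quantiles of the marginal
# distribution of w*severity + noise, which is N(0, sqrt(w^2 + sd^2)).
grade_thresholds <- function(w, config, max_grade) {
  q <- config$grade_quantiles[[as.character(max_grade)]]
  if (is.null(q)) stop("no grade quantiles configured for scale 0-", max_grade)
  stats::qnorm(q, mean = 0, sd = sqrt(w^2 + config$grade_noise_sd^2))
}

#' Generate ordinal reader-style grades from latent severity
#'
#' For feature k with loading `w_k` and scale 0..G_k, the grade is the
#' ordinal bin of `w_k * severity + noise` with thresholds at fixed marginal
#' quantiles; `w_k = 0` gives a grade independent of severity (a chance-level
#' feature). Uses the current RNG stream.
#'
#' @param severity numeric vector of latent severities.
#' @param config a `cohort_config`.
#' @return integer matrix `length(severity) x 36` with the feature-table
#'   column names.
#' @export
grades_from_severity <- function(severity, config) {
  ft <- knee_feature_table()
  w <- config$severity_grade_loadings
  n <- length(severity)
  out <- matrix(0L, n, nrow(ft), dimnames = list(NULL, ft$name))
  for (k in seq_len(nrow(ft))) {
    latent <- w[k] * severity + stats::rnorm(n, 0, config$grade_noise_sd)
    thr <- grade_thresholds(w[k], config, ft$max_grade[k])
    out[, k] <- as.integer(findInterval(latent, thr))
  }
  out
}

#' Generate the three binary pain reports
#'
#' Each of the telephone screen (tscreen), self-assessed questionnaire (saq)
#' and clinic-visit (clinic) answers equals the persistent-pain state flipped
#' independently with probability `transient_flip_prob`. Uses the current RNG
#' stream.
#'
#' @param persistent_pain 0/1 vector.
#' @param config a `cohort_config`.
#' @return data.frame with binary columns `tscreen`, `saq`, `clinic`.
#' @export
pain_reports <- function(persistent_pain, config) {
  n <- length(persistent_pain)
  flip <- function() stats::rbinom(n, 1, config$transient_flip_prob)
  data.frame(tscreen = as.integer(xor(persistent_pain, flip())),
             saq     = as.integer(xor(persistent_pain, flip())),
             clinic  = as.integer(xor(persistent_pain, flip())))
}

#' Generate a full synthetic cohort
#'
#' Composes [sample_latent()], [grades_from_severity()], [pain_reports()] and
#' (optionally) [render_knee()] into a cohort with known ground truth.
#' Outputs are byte-identical for identical config and seed.
#'
#' @param config a `cohort_config`.
#' @param out_dir if non-NULL, write `cohort.csv`, a `manifest.json`, and
#'   (when `render = TRUE`) one grayscale PNG and one plain-text points file
#'   per knee.
#' @param render generate images and ground-truth landmarks; disable for
#'   grades-and-pain-only cohorts, which is much faster.
#' @return list with `table` (the cohort data.frame), `images` and
#'   `landmarks` (lists, NULL when `render = FALSE`), and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL, render = TRUE) {
  validate_cohort_config(config)
  subj <- sample_latent(config)            # seeds the stream from config$seed
  grades <- grades_from_severity(subj$severity, config)
  pain <- pain_reports(subj$persistent_pain, config)
  n <- config$n_subjects
  images <- landmarks <- NULL
  img_paths <- rep(NA_character_, n)
  if (render) {
    images <- vector("list", n)
    landmarks <- vector("list", n)
    for (i in seq_len(n)) {
      rk <- render_knee(subj$severity[i], config$view, config)
      images[[i]] <- rk$image
      landmarks[[i]] <- rk$landmarks
    }
    img_paths <- sprintf("images/%s.png", subj$id)
  }
  tab <- cbind(data.frame(id = subj$id, view = config$view,
                          image = img_paths, stringsAsFactors = FALSE),
               as.data.frame(grades), pain,
               data.frame(widespread = subj$widespread, age = subj$age,
                          bmi = subj$bmi, sex = subj$sex,
                          severity = subj$severity,
                          persistent_pain = subj$persistent_pain))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
      stop("cannot create output directory ", out_dir)
    }
    utils::write.csv(tab, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    if (render) {
      dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
      dir.create(file.path(out_dir, "points"), showWarnings = FALSE)
      for (i in seq_len(n)) {
        png::writePNG(images[[i]], file.path(out_dir, img_paths[i]))
        write_points(landmarks[[i]],
                     file.path(out_dir, sprintf("points/%s.pts", subj$id[i])))
      }
    }
    manifest <- list(package = "kneestudy", n_subjects = n, view = config$view,
                     image_size = config$image_size, seed = config$seed,
                     rendered = render)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(table = tab, images = images, landmarks = landmarks, config = config)
}
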