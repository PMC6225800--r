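#' Cross-validation configuration
#'
#' Defaults follow the evaluation protocol used throughout: a random forest
#' with 40 trees under stratified 5-fold cross-validation repeated five
#' times, reporting the mean and SD of the AUC over the five repeats.
#'
#' @param n_trees trees in the random forest.
#' @param n_folds folds per repeat.
#' @param n_repeats independent fold splits.
#' @param stratified stratify folds by class.
#' @param seed base RNG seed; repeat r uses `seed + r`.
#' @return a `cv_config` object.
#' @export
cv_config <- function(n_trees = 40, n_folds = 5, n_repeats = 5,
                      stratified = TRUE, seed = 1) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(n_trees = n_trees, n_folds = n_folds, n_repeats = n_repeats,
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_config")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie handling:
#' `P(score+ > score-) + 0.5 P(score+ = score-)`.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment; returns an integer fold id per row.
# Deterministic given the seed; tie-break by row order. The caller's RNG
# state is left untouched.
make_folds <- function(labels, n_folds, stratified, seed) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(seed)
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < n_folds) {
        stop(sprintf("class %s has only %d rows; need at least %d to stratify",
                     cls, length(idx), n_folds))
      }
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold <- rep_len(seq_len(n_folds), n)[sample.int(n)]
  }
  fold
}

#' Repeated cross-validated random-forest evaluation
#'
#' For each repeat, a fresh stratified fold split (seeded from the config
#' seed plus the repeat index) is drawn; the forest is trained on the other
#' folds and the held-out fold is scored with class-probability outputs. All
#' out-of-fold scores of a repeat are pooled into a single AUC, giving
#' exactly `n_repeats` AUCs whose mean and SD are reported.
#'
#' @param x numeric feature matrix (rows = knees).
#' @param y 0/1 labels.
#' @param config a [cv_config()].
#' @param ids optional row ids, stored to support paired comparisons.
#' @return an object of class `roc_result`: `auc_per_repeat`, `auc_mean`,
#'   `auc_sd`, `scores` (n x n_repeats pooled out-of-fold scores), `labels`,
#'   `ids`, `config`.
#' @export
run_repeated_cv <- function(x, y, config = cv_config(), ids = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) < 2 * config$n_folds) stop("need at least 2 * n_folds rows")
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(x)
  xdf <- as.data.frame(x)
  names(xdf) <- sprintf("x%03d", seq_len(ncol(x)))
  yf <- factor(y, levels = c(0, 1))
  scores <- matrix(NA_real_, n, config$n_repeats)
  aucs <- numeric(config$n_repeats)
  for (rep_i in seq_len(config$n_repeats)) {
    fold <- make_folds(y, config$n_folds, config$stratified,
                       seed = config$seed + rep_i)
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      rf <- ranger::ranger(x = xdf[tr, , drop = FALSE], y = yf[tr],
                           num.trees = config$n_trees, probability = TRUE,
                           seed = config$seed * 1000L + rep_i * 10L + f,
                           num.threads = 1)
      p <- stats::predict(rf, xdf[!tr, , drop = FALSE],
                          num.threads = 1)$predictions[, "1"]
      scores[!tr, rep_i] <- p
    }
    aucs[rep_i] <- auc(scores[, rep_i], y)
  }
  structure(list(auc_per_repeat = aucs, auc_mean = mean(aucs),
                 auc_sd = stats::sd(aucs), scores = scores, labels = y,
                 ids = ids, config = config),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.1f%% +/- %.1f (%d repeats, %d-fold, %d trees, n=%d)\n",
              100 * x$auc_mean, 100 * x$auc_sd, x$config$n_repeats,
              x$config$n_folds, x$config$n_trees, length(x$labels)))
  invisible(x)
}

# DeLong structural components of one classifier's pooled scores.
# Returns V10 (per positive), V01 (per negative) and the AUC.
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = sum(v10) / m)
}

# Paired DeLong variance of auc1 - auc2 on common rows.
delong_paired_var <- function(s1, s2, labels) {
  c1 <- delong_components(s1, labels)
  c2 <- delong_components(s2, labels)
  m <- length(c1$v10); n <- length(c1$v01)
  s10 <- stats::var(c1$v10 - c2$v10)
  s01 <- stats::var(c1$v01 - c2$v01)
  list(diff = c1$auc - c2$auc, var = s10 / m + s01 / n)
}

delong_unpaired_var <- function(s, labels) {
  cc <- delong_components(s, labels)
  stats::var(cc$v10) / length(cc$v10) + stats::var(cc$v01) / length(cc$v01)
}

#' Chi-square comparison of two cross-validated AUCs
#'
#' Per repeat, the difference between the two pooled out-of-fold AUCs and
#' its DeLong variance (covariance-based in paired mode, sum of the two
#' variances in unpaired mode) are computed; the mean difference over
#' repeats is then standardized by the total variance -- the mean
#' within-repeat DeLong variance plus the between-repeat variance of the
#' differences divided by the repeat count -- and the squared standardized
#' difference is referred to a chi-square distribution with 1 degree of
#' freedom.
#'
#' The between-repeat term matters: out-of-fold scores come from refitted
#' classifiers, so the cross-validated AUC carries model-level variance that
#' the per-realization DeLong variance cannot see, and omitting it (or
#' summing per-repeat squared z values over repeats, which additionally
#' treats the highly correlated repeats as independent) anti-conservatively
#' inflates the test. The within-plus-between combination is calibrated
#' under the null.
#'
#' @param result_a,result_b `roc_result` objects.
#' @param paired paired mode requires both results to share rows, labels and
#'   fold structure (same CV seed and repeat count).
#' @param alpha significance level (default 0.05).
#' @return an object of class `auc_comparison` with `statistic`, `df`,
#'   `p_value`, `method`, `significant`, `auc_diff_per_repeat`.
#' @export
compare_auc <- function(result_a, result_b, paired = TRUE, alpha = 0.05) {
  ka <- result_a$config$n_repeats
  if (ka != result_b$config$n_repeats) stop("results differ in repeat count")
  vars <- numeric(ka); diffs <- numeric(ka)
  if (paired) {
    same_rows <- length(result_a$labels) == length(result_b$labels) &&
      all(result_a$labels == result_b$labels) &&
      (is.null(result_a$ids) || is.null(result_b$ids) ||
         identical(result_a$ids, result_b$ids))
    if (!same_rows) stop("paired comparison requires identical rows and labels")
    if (result_a$config$seed != result_b$config$seed) {
      stop("paired comparison requires identical fold structure (same CV seed)")
    }
    for (k in seq_len(ka)) {
      d <- delong_paired_var(result_a$scores[, k], result_b$scores[, k],
                             result_a$labels)
      diffs[k] <- d$diff
      vars[k] <- d$var
    }
    method <- "paired DeLong with between-repeat variance, chi-square (df=1)"
  } else {
    for (k in seq_len(ka)) {
      va <- delong_unpaired_var(result_a$scores[, k], result_a$labels)
      vb <- delong_unpaired_var(result_b$scores[, k], result_b$labels)
      diffs[k] <- result_a$auc_per_repeat[k] - result_b$auc_per_repeat[k]
      vars[k] <- va + vb
    }
    method <- "unpaired DeLong with between-repeat variance, chi-square (df=1)"
  }
  between <- if (ka > 1) stats::var(diffs) / ka else 0
  v_total <- mean(vars) + between
  stat <- if (v_total <= 0) 0 else mean(diffs)^2 / v_total
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(statistic = stat, df = 1L, p_value = p, method = method,
                 significant = p <= alpha, auc_diff_per_repeat = diffs,
                 delong_var_per_repeat = vars),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("<auc_comparison> X2=%.2f df=%d p=%.4g (%s)%s\n", x$statistic,
              x$df, x$p_value, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Select the best automated feature set by inner cross-validation
#'
#' Runs the three automated variants (shape, texture, combined parameters)
#' through the same CV engine with an independent selection seed and returns
#' the variant with the highest mean AUC, so the reported "best automated"
#' result is not chosen on the evaluation folds themselves.
#'
#' @param cohort cohort table.
#' @param auto automated feature table.
#' @param mode outcome mode.
#' @param config evaluation [cv_config()]; the selection run uses
#'   `seed + 10000`.
#' @param exclude_widespread apply the widespread-pain exclusion.
#' @return list with `kind` (winning spec name) and `selection_auc` (named
#'   vector of the inner-CV mean AUCs).
#' @export
select_best_automated <- function(cohort, auto, mode, config = cv_config(),
                                  exclude_widespread = FALSE) {
  kinds <- c("AUTO_SHAPE", "AUTO_TEXTURE", "AUTO_COMBINED")
  sel_cfg <- cv_config(n_trees = config$n_trees, n_folds = config$n_folds,
                       n_repeats = config$n_repeats, stratified = config$stratified,
                       seed = config$seed + 10000L)
  aucs <- vapply(kinds, function(k) {
    ds <- build_analysis_set(cohort, auto, feature_set_spec(k), mode,
                             exclude_widespread)
    run_repeated_cv(ds$x, ds$y, sel_cfg, ids = ds$ids)$auc_mean
  }, 0)
  list(kind = kinds[which.max(aucs)], selection_auc = aucs)
}

#' Run a grid of outcome/feature-set evaluations
#'
#' Executes every requested (outcome mode, feature set, widespread-filter)
#' combination through the CV engine and reports AUC +/- SD with a
#' chi-square p-value against the referent of the same outcome (the MANUAL
#' feature set without the widespread exclusion). The comparison is paired
#' when both runs share the same rows, unpaired otherwise.
#'
#' @param cohort cohort table.
#' @param auto automated feature table or `NULL`.
#' @param grid data.frame with columns `mode`, `kind`, `exclude_widespread`
#'   (and optionally `feature` for SINGLE rows).
#' @param config a [cv_config()].
#' @return data.frame mirroring the requested grid with columns `mode`,
#'   `kind`, `exclude_widespread`, `n`, `auc_mean`, `auc_sd`, `p_vs_referent`
#'   (NA for the referent itself).
#' @export
table_runner <- function(cohort, auto = NULL, grid, config = cv_config()) {
  if (!all(c("mode", "kind", "exclude_widespread") %in% names(grid))) {
    stop("grid needs columns mode, kind, exclude_widespread")
  }
  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- feature_set_spec(grid$kind[i],
                           feature = if ("feature" %in% names(grid)) grid$feature[i] else NULL)
    ds <- build_analysis_set(cohort, auto, sp, grid$mode[i],
                             grid$exclude_widespread[i])
    runs[[i]] <- list(res = run_repeated_cv(ds$x, ds$y, config, ids = ds$ids),
                      n = length(ds$y))
  }
  out <- data.frame(mode = grid$mode, kind = grid$kind,
                    exclude_widespread = grid$exclude_widespread,
                    n = vapply(runs, `[[`, 0, "n"),
                    auc_mean = vapply(runs, function(r) r$res$auc_mean, 0),
                    auc_sd = vapply(runs, function(r) r$res$auc_sd, 0),
                    p_vs_referent = NA_real_, stringsAsFactors = FALSE)
  for (m in unique(grid$mode)) {
    ref_i <- which(grid$mode == m & grid$kind == "MANUAL" & !grid$exclude_widespread)
    if (!length(ref_i)) next
    ref <- runs[[ref_i[1]]]$res
    for (i in which(grid$mode == m)) {
      if (i == ref_i[1]) next
      paired <- !is.null(runs[[i]]$res$ids) && identical(runs[[i]]$res$ids, ref$ids)
      cmp <- compare_auc(runs[[i]]$res, ref, paired = paired)
      out$p_vs_referent[i] <- cmp$p_value
    }
  }
  out
}
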