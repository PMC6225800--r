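#' Derive a pain outcome label from the three binary reports
#'
#' Single-instrument modes (`TSCREEN`, `SAQ`, `CLINIC`) label a knee by that
#' report alone. `CONSISTENT` compares people who reported frequent knee
#' pain at all three time points (POSITIVE) with those who reported it at
#' none (NEGATIVE); everyone whose answers disagree is EXCLUDED.
#'
#' @param records data.frame with binary columns `tscreen`, `saq`, `clinic`
#'   (a cohort table works directly).
#' @param mode one of `"TSCREEN"`, `"SAQ"`, `"CLINIC"`, `"CONSISTENT"`.
#' @return character vector of `"POSITIVE"`, `"NEGATIVE"`, `"EXCLUDED"`.
#' @export
derive_outcome <- function(records, mode = c("CONSISTENT", "TSCREEN", "SAQ", "CLINIC")) {
  mode <- match.arg(toupper(mode[1]), c("CONSISTENT", "TSCREEN", "SAQ", "CLINIC"))
  need <- c("tscreen", "saq", "clinic")
  if (!all(need %in% names(records))) {
    stop("records must carry binary columns tscreen, saq, clinic")
  }
  r <- records[need]
  if (anyNA(r)) stop("missing pain reports; drop incomplete records first")
  if (mode == "CONSISTENT") {
    s <- r$tscreen + r$saq + r$clinic
    ifelse(s == 3, "POSITIVE", ifelse(s == 0, "NEGATIVE", "EXCLUDED"))
  } else {
    v <- r[[tolower(mode)]]
    ifelse(v == 1, "POSITIVE", "NEGATIVE")
  }
}

#' Remove knees with widespread pain
#'
#' Widespread pain (frequent pain above and below the waist, on both sides
#' of the body and axially) is assumed not to be of articular origin and is
#' applied as an exclusion.
#'
#' @param rows data.frame with a binary `widespread` column.
#' @return list with `kept` (the filtered data.frame) and `n_removed`.
#' @export
filter_widespread <- function(rows) {
  if (!"widespread" %in% names(rows)) stop("no `widespread` column present")
  keep <- rows$widespread == 0
  if (!any(keep)) warning("all rows flagged widespread; nothing left")
  list(kept = rows[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Feature-set specifications
#'
#' The feature sets compared by the evaluation engine:
#' `SINGLE` (one named radiographic grade), `MANUAL` (all 36 grades),
#' `MANUAL_DEMO` (grades + sex + BMI), `AUTO_SHAPE` / `AUTO_TEXTURE` /
#' `AUTO_COMBINED` (automated appearance-model parameter sets) and
#' `MANUAL_PLUS_AUTO` (grades + combined appearance parameters).
#'
#' @param kind one of the set names above.
#' @param feature for `SINGLE`, a feature name from [knee_feature_table()].
#' @param include_age include age alongside sex + BMI in `MANUAL_DEMO`
#'   (off by default).
#' @return a `feature_set_spec` object.
#' @export
feature_set_spec <- function(kind = c("MANUAL", "SINGLE", "MANUAL_DEMO",
                                      "AUTO_SHAPE", "AUTO_TEXTURE",
                                      "AUTO_COMBINED", "MANUAL_PLUS_AUTO"),
                             feature = NULL, include_age = FALSE) {
  kind <- match.arg(toupper(kind[1]), c("MANUAL", "SINGLE", "MANUAL_DEMO",
                                        "AUTO_SHAPE", "AUTO_TEXTURE",
                                        "AUTO_COMBINED", "MANUAL_PLUS_AUTO"))
  if (kind == "SINGLE") {
    if (is.null(feature) || !feature %in% knee_feature_table()$name) {
      stop("SINGLE requires a valid feature name from knee_feature_table()")
    }
  }
  structure(list(kind = kind, feature = feature, include_age = include_age),
            class = "feature_set_spec")
}

auto_block <- function(auto, stem) {
  cols <- grep(sprintf("^%s_\\d+$", stem), names(auto), value = TRUE)
  if (!length(cols)) stop("no automated columns with stem '", stem, "'")
  cols[order(as.integer(sub(sprintf("^%s_", stem), "", cols)))]
}

#' Assemble a feature matrix for one feature-set specification
#'
#' Joins the manual grade table with the automated feature table on `id` and
#' returns the numeric design matrix in deterministic column order (grade
#' columns in the fixed catalogue order, automated columns by index).
#' Ordinal grades are used as plain integers.
#'
#' @param grades data.frame carrying `id`, the 36 grade columns and `sex`,
#'   `bmi` (and `age`); a cohort table works directly.
#' @param auto data.frame of automated features (`id`, `c_*`, `bs_*`,
#'   `bg_*`) or `NULL` when the spec needs none.
#' @param spec a [feature_set_spec()].
#' @return numeric matrix, rows in `grades` order, with column names.
#' @export
assemble_features <- function(grades, auto = NULL, spec) {
  stopifnot(inherits(spec, "feature_set_spec"))
  ft <- knee_feature_table()
  grade_cols <- ft$name
  need_auto <- spec$kind %in% c("AUTO_SHAPE", "AUTO_TEXTURE", "AUTO_COMBINED",
                                "MANUAL_PLUS_AUTO")
  if (need_auto) {
    if (is.null(auto)) stop("spec requires automated features but none supplied")
    missing_ids <- setdiff(grades$id, auto$id)
    if (length(missing_ids)) {
      stop("ids missing from automated features: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           if (length(missing_ids) > 5) " ...")
    }
    auto <- auto[match(grades$id, auto$id), , drop = FALSE]
  }
  manual <- function() {
    miss <- setdiff(grade_cols, names(grades))
    if (length(miss)) stop("grade columns missing: ", paste(miss, collapse = ", "))
    as.matrix(grades[grade_cols])
  }
  demo <- function() {
    m <- cbind(sex = as.numeric(grades$sex == "F"), bmi = grades$bmi)
    if (spec$include_age) m <- cbind(m, age = grades$age)
    m
  }
  auto_mat <- function(stem) as.matrix(auto[auto_block(auto, stem)])
  out <- switch(spec$kind,
    SINGLE = {
      m <- as.matrix(grades[spec$feature]); colnames(m) <- spec$feature; m
    },
    MANUAL = manual(),
    MANUAL_DEMO = cbind(manual(), demo()),
    AUTO_SHAPE = auto_mat("bs"),
    AUTO_TEXTURE = auto_mat("bg"),
    AUTO_COMBINED = auto_mat("c"),
    MANUAL_PLUS_AUTO = cbind(manual(), auto_mat("c")))
  storage.mode(out) <- "double"
  out
}

#' Build an analysis-ready dataset for one outcome/feature-set combination
#'
#' Applies the outcome derivation, optionally the widespread-pain exclusion,
#' drops EXCLUDED rows, and assembles the feature matrix.
#'
#' @param cohort cohort table (from [generate_cohort()]).
#' @param auto automated feature table or `NULL`.
#' @param spec a [feature_set_spec()].
#' @param mode outcome mode for [derive_outcome()].
#' @param exclude_widespread apply [filter_widespread()] first.
#' @return list with `x` (feature matrix), `y` (0/1 labels), `ids`,
#'   `n_excluded_outcome`, `n_removed_widespread`.
#' @export
build_analysis_set <- function(cohort, auto = NULL, spec,
                               mode = "CLINIC", exclude_widespread = FALSE) {
  n_ws <- 0L
  if (exclude_widespread) {
    fw <- filter_widespread(cohort)
    cohort <- fw$kept
    n_ws <- fw$n_removed
  }
  lab <- derive_outcome(cohort, mode)
  keep <- lab != "EXCLUDED"
  cohort_kept <- cohort[keep, , drop = FALSE]
  x <- assemble_features(cohort_kept, auto, spec)
  list(x = x, y = as.integer(lab[keep] == "POSITIVE"), ids = cohort_kept$id,
       n_excluded_outcome = sum(!keep), n_removed_widespread = n_ws)
}
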