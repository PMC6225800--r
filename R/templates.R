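# Schematic knee outline templates in a unit frame ([0,1] x [0,1], y down).
# Control polygons are interpolated with natural (or periodic) cubic splines
# and resampled to the exact point count of each subshape.

resample_curve <- function(ctrl, n, closed = FALSE) {
  ctrl <- as.matrix(ctrl)
  if (closed) ctrl <- rbind(ctrl, ctrl[1, ])
  d <- sqrt(rowSums(diff(ctrl)^2))
  t0 <- c(0, cumsum(d))
  method <- if (closed) "periodic" else "natural"
  tt <- seq(0, max(t0), length.out = 512)
  xx <- stats::spline(t0, ctrl[, 1], xout = tt, method = method)$y
  yy <- stats::spline(t0, ctrl[, 2], xout = tt, method = method)$y
  dd <- c(0, cumsum(sqrt(diff(xx)^2 + diff(yy)^2)))
  # closed curves drop the duplicated endpoint
  s <- if (closed) seq(0, max(dd), length.out = n + 1)[-(n + 1)]
       else seq(0, max(dd), length.out = n)
  cbind(x = stats::approx(dd, xx, xout = s)$y,
        y = stats::approx(dd, yy, xout = s)$y)
}

template_pa <- function() {
  femur_ctrl <- rbind(
    c(0.30, 0.06), c(0.27, 0.18), c(0.22, 0.30), c(0.20, 0.38),
    c(0.24, 0.44), c(0.32, 0.47), c(0.40, 0.45), c(0.46, 0.40),
    c(0.50, 0.37), c(0.54, 0.40), c(0.60, 0.45), c(0.68, 0.47),
    c(0.76, 0.44), c(0.80, 0.38), c(0.78, 0.30), c(0.73, 0.18),
    c(0.70, 0.06))
  tibia_ctrl <- rbind(
    c(0.24, 0.94), c(0.22, 0.80), c(0.20, 0.66), c(0.18, 0.58),
    c(0.26, 0.545), c(0.34, 0.555), c(0.42, 0.545), c(0.47, 0.52),
    c(0.50, 0.50), c(0.53, 0.52), c(0.58, 0.545), c(0.66, 0.555),
    c(0.74, 0.545), c(0.82, 0.58), c(0.80, 0.66), c(0.78, 0.80),
    c(0.76, 0.94))
  rbind(resample_curve(femur_ctrl, 37), resample_curve(tibia_ctrl, 37))
}

template_lateral <- function() {
  patella_ctrl <- rbind(
    c(0.20, 0.24), c(0.15, 0.30), c(0.13, 0.38), c(0.15, 0.46),
    c(0.20, 0.51), c(0.25, 0.46), c(0.27, 0.38), c(0.25, 0.30))
  lat_condyle_ctrl <- rbind(           # open arc, anterior to posterior
    c(0.43, 0.22), c(0.35, 0.28), c(0.32, 0.38), c(0.36, 0.47),
    c(0.45, 0.52), c(0.55, 0.50), c(0.61, 0.42), c(0.60, 0.31))
  med_condyle_ctrl <- rbind(
    c(0.52, 0.24), c(0.46, 0.31), c(0.45, 0.41), c(0.50, 0.50),
    c(0.59, 0.535), c(0.68, 0.50), c(0.72, 0.40), c(0.69, 0.30))
  tibia_ctrl <- rbind(
    c(0.36, 0.94), c(0.34, 0.80), c(0.32, 0.68), c(0.30, 0.60),
    c(0.38, 0.575), c(0.47, 0.585), c(0.56, 0.575), c(0.65, 0.585),
    c(0.74, 0.60), c(0.72, 0.68), c(0.70, 0.80), c(0.68, 0.94))
  rbind(resample_curve(patella_ctrl, 21, closed = TRUE),
        resample_curve(lat_condyle_ctrl, 24),
        resample_curve(med_condyle_ctrl, 25),
        resample_curve(tibia_ctrl, 32))
}

#' Mean-shape template for a radiographic view
#'
#' Returns the schematic template outline of the knee joint for a view, in
#' unit coordinates (frame `[0,1] x [0,1]`, y downward). This is the
#' zero-severity, zero-noise shape from which synthetic knees are
#' instantiated.
#'
#' @param view `"PA"` or `"LATERAL"`.
#' @param image_size if given, coordinates are scaled to pixels of a square
#'   image of this side length.
#' @return a `landmark_set`.
#' @export
knee_template <- function(view, image_size = NULL) {
  view <- match.arg(toupper(view), c("PA", "LATERAL"))
  pts <- if (view == "PA") template_pa() else template_lateral()
  if (!is.null(image_size)) {
    if (image_size < 48) stop("image_size too small to contain template; minimum is 48 px")
    pts <- pts * (image_size - 1)
  }
  landmark_set(pts, view)
}

# Femur/tibia landmark index pairs spanning the tibiofemoral gap, computed
# once from the template: for each tibia plateau point in the central band,
# the femur point directly above it (nearest in x within the condyle region).
gap_pairs <- function(view) {
  tmpl <- knee_template(view)
  topo <- tmpl$topology
  fem_idx <- if (view == "PA") topo$subshapes$femur else topo$unions$femur
  tib_idx <- topo$subshapes$tibia
  pts <- tmpl$points
  # plateau: tibia points in the central x band near the top of the tibia
  band <- tib_idx[pts[tib_idx, 1] > 0.30 & pts[tib_idx, 1] < 0.70 &
                  pts[tib_idx, 2] < stats::quantile(pts[tib_idx, 2], 0.35)]
  # candidate femur points: lower third of the femur outline
  fem_low <- fem_idx[pts[fem_idx, 2] > stats::quantile(pts[fem_idx, 2], 0.6)]
  pairs <- t(vapply(band, function(i) {
    j <- fem_low[which.min(abs(pts[fem_low, 1] - pts[i, 1]))]
    c(femur = j, tibia = i)
  }, c(femur = 0, tibia = 0)))
  pairs
}

# Severity-driven landmark instantiation in the unit frame.
# Narrowing: the whole tibia translates toward the femur by gap_per_sd per
# severity SD, so gap(s) = gap(0) - gap_per_sd * s exactly.
# Osteophytes: outer marginal points displaced outward for positive severity.
# Secondary variation: low-frequency sinusoidal perturbation plus similarity
# jitter, drawn from the current RNG stream.
severity_gap_per_sd <- 0.010
severity_osteophyte_per_sd <- 0.012

instantiate_shape <- function(severity, view, noise_sd = 0.004, jitter = TRUE) {
  tmpl <- knee_template(view)
  pts <- tmpl$points
  topo <- tmpl$topology
  tib <- topo$subshapes$tibia
  pts[tib, 2] <- pts[tib, 2] - severity_gap_per_sd * severity
  # marginal osteophyte bumps: outermost points of femur and tibia
  margins <- outer_margin_points(tmpl)
  bump <- severity_osteophyte_per_sd * max(severity, 0)
  cx <- mean(pts[, 1])
  pts[margins, 1] <- pts[margins, 1] + bump * sign(pts[margins, 1] - cx)
  if (jitter && noise_sd > 0) {
    n <- nrow(pts)
    ph <- stats::runif(4, 0, 2 * pi)
    tt <- seq_len(n) / n
    pts[, 1] <- pts[, 1] + noise_sd * (sin(2 * pi * 2 * tt + ph[1]) +
                                       0.5 * sin(2 * pi * 5 * tt + ph[2]))
    pts[, 2] <- pts[, 2] + noise_sd * (cos(2 * pi * 2 * tt + ph[3]) +
                                       0.5 * sin(2 * pi * 4 * tt + ph[4]))
    ang <- stats::rnorm(1, 0, 0.015)
    sc <- exp(stats::rnorm(1, 0, 0.01))
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    ctr <- colMeans(pts)
    pts <- sweep(sweep(pts, 2, ctr) %*% t(R) * sc, 2, ctr, `+`)
    pts <- sweep(pts, 2, stats::rnorm(2, 0, 0.004), `+`)
  }
  landmark_set(pts, view)
}

# Outer margin points (lateral/medial extremes near the joint line), the
# sites that grow osteophyte-like bumps with severity.
outer_margin_points <- function(tmpl) {
  pts <- tmpl$points
  topo <- tmpl$topology
  fem <- if (tmpl$view == "PA") topo$subshapes$femur else topo$unions$femur
  tib <- topo$subshapes$tibia
  pick <- function(idx, k = 2) {
    ord <- idx[order(pts[idx, 1])]
    c(utils::head(ord, k), utils::tail(ord, k))
  }
  c(pick(fem), pick(tib))
}

#' Tibiofemoral joint-space width of a landmark set
#'
#' Mean vertical distance between designated femur/tibia landmark pairs that
#' span the joint line, in the units of the landmark coordinates.
#'
#' @param x a `landmark_set`.
#' @return mean gap (positive when the femur lies above the tibia).
#' @export
tibiofemoral_gap <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  prs <- gap_pairs(x$view)
  mean(x$points[prs[, "tibia"], 2] - x$points[prs[, "femur"], 2])
}
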