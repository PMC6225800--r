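# Schematic radiograph rendering: bone contours drawn as smooth bright
# ridges on a noisy background, with severity-scaled subchondral intensity
# (a sclerosis analogue). Deliberately not photorealistic -- the aim is
# enough edge structure for patch regressors and texture models to learn.

# Splat Gaussian blobs at (x, y) pixel positions onto an image matrix.
# img is indexed [row, col] = [y+1, x+1]; coordinates are 0-based.
splat_gaussian <- function(img, x, y, amplitude, sigma) {
  sz <- dim(img)
  r <- ceiling(3 * sigma)
  off <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
  wts <- exp(-(off[, "dx"]^2 + off[, "dy"]^2) / (2 * sigma^2))
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, length(x))
  cx <- round(x); cy <- round(y)
  n <- length(x); m <- nrow(off)
  rows <- rep(cy, each = m) + off[, "dy"] + 1L
  cols <- rep(cx, each = m) + off[, "dx"] + 1L
  amp <- rep(amplitude, each = m) * wts
  ok <- rows >= 1L & rows <= sz[1] & cols >= 1L & cols <= sz[2]
  idx <- (cols[ok] - 1L) * sz[1] + rows[ok]
  add <- tapply(amp[ok], idx, sum)
  img[as.integer(names(add))] <- img[as.integer(names(add))] + add
  img
}

# Dense points along an open or closed polyline, ~step px apart.
densify_polyline <- function(pts, step = 1, closed = FALSE) {
  if (closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, max(cum), by = step)
  cbind(stats::approx(cum, pts[, 1], xout = s)$y,
        stats::approx(cum, pts[, 2], xout = s)$y)
}

#' Render a synthetic knee radiograph
#'
#' Instantiates landmarks from the generative shape model -- the first mode
#' narrows the tibiofemoral gap and adds marginal osteophyte-like bumps in
#' proportion to severity, plus small random secondary modes -- and renders
#' the bone contours as smooth bright ridges over a noisy background.
#' Subchondral regions adjacent to the joint line brighten with severity
#' (sclerosis analogue). Uses the current RNG stream (seed from the caller
#' or via [generate_cohort()]).
#'
#' @param severity latent severity (standard-normal scale).
#' @param view `"PA"` or `"LATERAL"`.
#' @param config a `cohort_config` (supplies `image_size`).
#' @param shape_noise_sd SD of the secondary shape variation in unit-frame
#'   coordinates; 0 disables all random shape variation.
#' @param background_noise_sd pixel noise SD (intensity units, image in
#'   `[0,1]`).
#' @return list with `image` (matrix in `[0,1]`, `image_size` square) and
#'   `landmarks` (pixel-aligned ground-truth `landmark_set`).
#' @export
render_knee <- function(severity, view, config, shape_noise_sd = 0.004,
                        background_noise_sd = 0.05) {
  view <- match.arg(toupper(view), c("PA", "LATERAL"))
  sz <- config$image_size
  if (sz < 48) stop("image_size too small to contain template; minimum is 48 px")
  shp <- instantiate_shape(severity, view, noise_sd = shape_noise_sd,
                           jitter = shape_noise_sd > 0)
  pts <- shp$points * (sz - 1)
  img <- matrix(0.15, sz, sz)
  if (background_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(sz * sz, 0, background_noise_sd), sz, sz)
  }
  topo <- shp$topology
  lm <- landmark_set(pts, view)
  for (nm in names(topo$subshapes)) {
    sub <- pts[topo$subshapes[[nm]], , drop = FALSE]
    dense <- densify_polyline(sub, step = 0.75, closed = (nm == "patella"))
    img <- splat_gaussian(img, dense[, 1], dense[, 2],
                          amplitude = 0.16, sigma = 1.3)
  }
  # sclerosis analogue: brightening around the joint-line landmark pairs
  prs <- gap_pairs(view)
  sites <- rbind(pts[prs[, "femur"], , drop = FALSE],
                 pts[prs[, "tibia"], , drop = FALSE])
  img <- splat_gaussian(img, sites[, 1], sites[, 2],
                        amplitude = 0.05 * stats::plogis(severity), sigma = 3)
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, landmarks = lm)
}
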