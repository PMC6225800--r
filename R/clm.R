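# Fully automatic landmark localization: a global joint detector proposes a
# bounding box, then a constrained local model (CLM) refines landmark
# positions by regression-voting response maps under the shape-model
# constraint.

# Extract square patches centered at 0-based (x, y) positions; returns an
# n x patch_size^2 matrix of intensities with the patch mean subtracted
# (coarse photometric normalization). Positions are rounded to pixels and
# out-of-image samples clamp to the border.
extract_patches <- function(image, centers, patch_size) {
  if (patch_size %% 2 == 0) stop("patch_size must be odd")
  r <- (patch_size - 1) / 2
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r))
  h <- nrow(image); w <- ncol(image)
  cx <- round(centers[, 1]); cy <- round(centers[, 2])
  n <- nrow(centers); m <- nrow(off)
  cols <- pmin(pmax(rep(cx, each = m) + off[, "dx"], 0), w - 1) + 1L
  rows <- pmin(pmax(rep(cy, each = m) + off[, "dy"], 0), h - 1) + 1L
  vals <- matrix(image[(cols - 1L) * h + rows], nrow = n, ncol = m, byrow = TRUE)
  vals - rowMeans(vals)
}

patch_feature_names <- function(patch_size) sprintf("p%03d", seq_len(patch_size^2))

# Coarse whole-image features for the detector: block-mean intensity and
# block-mean gradient magnitude on a grid x grid partition.
detector_features <- function(image, grid = 12) {
  h <- nrow(image); w <- ncol(image)
  gx <- cbind(image[, -1] - image[, -w], 0)
  gy <- rbind(image[-1, ] - image[-h, ], 0)
  gm <- sqrt(gx^2 + gy^2)
  bin_r <- pmin(floor((seq_len(h) - 1) / h * grid), grid - 1)
  bin_c <- pmin(floor((seq_len(w) - 1) / w * grid), grid - 1)
  block_means <- function(m) {
    agg <- rowsum(m, bin_r)
    agg <- t(rowsum(t(agg), bin_c))
    cnt <- rowsum(matrix(1, h, w), bin_r)
    cnt <- t(rowsum(t(cnt), bin_c))
    as.vector(agg / cnt)
  }
  v <- c(block_means(image), block_means(gm))
  names(v) <- sprintf("f%03d", seq_along(v))
  v
}

landmark_bbox <- function(lm) {
  pts <- as_point_matrix(lm)
  c(cx = mean(range(pts[, 1])), cy = mean(range(pts[, 2])),
    width = diff(range(pts[, 1])))
}

# Crop a square window (side `win`) centered at 0-based (cx, cy), clamped
# to stay inside the image.
crop_window <- function(image, cx, cy, win) {
  h <- nrow(image); w <- ncol(image)
  x0 <- round(cx) - floor(win / 2)
  y0 <- round(cy) - floor(win / 2)
  x0 <- min(max(x0, 0), max(w - win, 0))
  y0 <- min(max(y0, 0), max(h - win, 0))
  cols <- pmin(x0 + seq_len(win), w)
  rows <- pmin(y0 + seq_len(win), h)
  list(img = image[rows, cols, drop = FALSE], origin = c(x0, y0))
}

#' Train the global joint detector
#'
#' A regressor ensemble on coarse block intensity/gradient features votes
#' for the joint bounding-box center and log-width. The detector always
#' returns a box; on images unlike its training data the prediction is
#' flagged low-confidence via the spread of the per-tree votes.
#'
#' @param images list of grayscale matrices.
#' @param truth list of `landmark_set`s (boxes are their bounding boxes) or
#'   a matrix/data.frame with columns `cx`, `cy`, `width`.
#' @param n_trees trees per coordinate regressor.
#' @param grid block grid size for the coarse features.
#' @param seed RNG seed for tree training.
#' @return an object of class `knee_detector`.
#' @export
train_detector <- function(images, truth, n_trees = 25, grid = 12, seed = 1) {
  if (length(images) < 10) stop("need at least 10 training examples")
  boxes <- if (is.list(truth) && inherits(truth[[1]], c("landmark_set", "matrix"))) {
    do.call(rbind, lapply(truth, landmark_bbox))
  } else as.matrix(truth)
  X <- do.call(rbind, lapply(images, detector_features, grid = grid))
  fit1 <- function(y, s) {
    ranger::ranger(x = as.data.frame(X), y = y, num.trees = n_trees,
                   seed = s, num.threads = 1)
  }
  shape_scale <- if (is.list(truth) && inherits(truth[[1]], c("landmark_set", "matrix"))) {
    mean(vapply(truth, function(lm) {
      pts <- as_point_matrix(lm)
      ctr <- sweep(pts, 2, colMeans(pts))
      sqrt(mean(rowSums(ctr^2)))
    }, 0) / boxes[, "width"])
  } else 0.35
  # second stage: regress the residual center offset from a window cropped
  # at a jittered center, emulating first-stage error
  win <- round(1.3 * mean(boxes[, "width"]))
  set.seed(seed + 3)
  X2 <- NULL; t2 <- NULL
  for (i in seq_along(images)) {
    for (rep_j in 1:3) {
      jit <- stats::runif(2, -12, 12)
      cw <- crop_window(images[[i]], boxes[i, "cx"] + jit[1],
                        boxes[i, "cy"] + jit[2], win)
      X2 <- rbind(X2, detector_features(cw$img, grid))
      ctr_in_win <- c(boxes[i, "cx"], boxes[i, "cy"]) - cw$origin
      t2 <- rbind(t2, ctr_in_win - win / 2)
    }
  }
  fit2 <- function(y, s) {
    ranger::ranger(x = as.data.frame(X2), y = y, num.trees = n_trees,
                   seed = s, num.threads = 1)
  }
  structure(list(rf_cx = fit1(boxes[, "cx"], seed),
                 rf_cy = fit1(boxes[, "cy"], seed + 1),
                 rf_logw = fit1(log(boxes[, "width"]), seed + 2),
                 rf_dx2 = fit2(t2[, 1], seed + 4),
                 rf_dy2 = fit2(t2[, 2], seed + 5),
                 refine_window = win,
                 grid = grid, shape_scale_per_box_width = shape_scale,
                 train_width_mean = mean(boxes[, "width"])),
            class = "knee_detector")
}

#' Detect the joint bounding box in an image
#'
#' @param image grayscale matrix.
#' @param detector a `knee_detector`.
#' @return list with `center` (x, y), `width`, `confidence` in (0, 1] (a
#'   monotone transform of the per-tree vote spread) and `low_confidence`
#'   flag.
#' @export
detect_box <- function(image, detector) {
  x <- as.data.frame(t(detector_features(image, detector$grid)))
  pr <- function(rf) {
    p <- stats::predict(rf, x, predict.all = TRUE, num.threads = 1)$predictions
    c(mean(p), stats::sd(p))
  }
  cx <- pr(detector$rf_cx); cy <- pr(detector$rf_cy); lw <- pr(detector$rf_logw)
  center <- c(cx[1], cy[1])
  if (!is.null(detector$rf_dx2)) {
    cw <- crop_window(image, center[1], center[2], detector$refine_window)
    v <- as.data.frame(t(detector_features(cw$img, detector$grid)))
    dx <- stats::predict(detector$rf_dx2, v, num.threads = 1)$predictions
    dy <- stats::predict(detector$rf_dy2, v, num.threads = 1)$predictions
    center <- cw$origin + detector$refine_window / 2 + c(dx, dy)
  }
  spread <- sqrt(cx[2]^2 + cy[2]^2) / detector$train_width_mean
  conf <- 1 / (1 + 10 * spread)
  list(center = center, width = exp(lw[1]),
       confidence = conf, low_confidence = conf < 0.5)
}

#' Train per-landmark patch displacement regressors
#'
#' For each landmark, patches are sampled at random offsets (uniform within
#' `sampling_range`) around the true position in every training image, and a
#' small tree ensemble learns the displacement from patch center back to the
#' landmark.
#'
#' @param images list of grayscale matrices.
#' @param landmarks paired list of true `landmark_set`s.
#' @param patch_size odd patch side in pixels.
#' @param sampling_range maximum training offset in pixels.
#' @param patches_per_image training patches per landmark per image.
#' @param n_trees trees per displacement regressor.
#' @param seed RNG seed (patch offsets and tree training).
#' @return an object of class `patch_regressor_set`.
#' @export
train_point_regressors <- function(images, landmarks, patch_size = 15,
                                   sampling_range = 10, patches_per_image = 12,
                                   n_trees = 10, seed = 1) {
  n_img <- length(images)
  if (length(landmarks) != n_img) stop("images and landmarks differ in length")
  n_lm <- nrow(as_point_matrix(landmarks[[1]]))
  set.seed(seed)
  per_image <- vector("list", n_img)
  offsets <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    truth <- as_point_matrix(landmarks[[i]])
    off <- matrix(stats::runif(n_lm * patches_per_image * 2,
                               -sampling_range, sampling_range),
                  ncol = 2)
    centers <- truth[rep(seq_len(n_lm), each = patches_per_image), ] + off
    per_image[[i]] <- extract_patches(images[[i]], centers, patch_size)
    offsets[[i]] <- off
  }
  feats <- patch_feature_names(patch_size)
  regressors <- vector("list", n_lm)
  for (j in seq_len(n_lm)) {
    rows <- (j - 1) * patches_per_image + seq_len(patches_per_image)
    Xj <- do.call(rbind, lapply(per_image, function(m) m[rows, , drop = FALSE]))
    dj <- -do.call(rbind, lapply(offsets, function(o) o[rows, , drop = FALSE]))
    colnames(Xj) <- feats
    Xj <- as.data.frame(Xj)
    regressors[[j]] <- list(
      dx = ranger::ranger(x = Xj, y = dj[, 1], num.trees = n_trees,
                          seed = seed + 2L * j, num.threads = 1),
      dy = ranger::ranger(x = Xj, y = dj[, 2], num.trees = n_trees,
                          seed = seed + 2L * j + 1L, num.threads = 1))
  }
  structure(list(regressors = regressors, patch_size = patch_size,
                 sampling_range = sampling_range, n_landmarks = n_lm,
                 n_trees = n_trees),
            class = "patch_regressor_set")
}

#' Regression-voting response maps
#'
#' For each landmark, patches on a regular grid within `search_radius` of
#' the current position each cast one vote at their predicted landmark
#' location; votes are accumulated on a 1-px map covering the search region
#' plus the regressor's sampling range.
#'
#' @param image grayscale matrix.
#' @param current 2-column matrix (or `landmark_set`) of current landmark
#'   positions.
#' @param regressors a `patch_regressor_set`.
#' @param search_radius grid half-width in pixels.
#' @param grid_step grid spacing in pixels.
#' @return list of response maps, each a list with `map` (matrix), `origin`
#'   (0-based x, y of the map's top-left pixel) and `n_votes`.
#' @export
compute_response_maps <- function(image, current, regressors,
                                  search_radius = 12, grid_step = 3) {
  cur <- as_point_matrix(current)
  n_lm <- nrow(cur)
  if (n_lm != regressors$n_landmarks) stop("landmark count does not match regressors")
  g <- seq(-search_radius, search_radius, by = grid_step)
  grid_off <- as.matrix(expand.grid(dx = g, dy = g))
  feats <- patch_feature_names(regressors$patch_size)
  margin <- search_radius + ceiling(regressors$sampling_range)
  side <- 2L * margin + 1L
  out <- vector("list", n_lm)
  for (j in seq_len(n_lm)) {
    centers <- sweep(grid_off, 2, cur[j, ], `+`)
    P <- extract_patches(image, centers, regressors$patch_size)
    colnames(P) <- feats
    Pd <- as.data.frame(P)
    dx <- stats::predict(regressors$regressors[[j]]$dx, Pd, num.threads = 1)$predictions
    dy <- stats::predict(regressors$regressors[[j]]$dy, Pd, num.threads = 1)$predictions
    votes_x <- round(centers[, 1] + dx) - round(cur[j, 1] - margin)
    votes_y <- round(centers[, 2] + dy) - round(cur[j, 2] - margin)
    ok <- votes_x >= 0 & votes_x < side & votes_y >= 0 & votes_y < side
    map <- matrix(0, side, side)
    if (any(ok)) {
      idx <- votes_x[ok] * side + votes_y[ok] + 1
      tab <- tabulate(idx, nbins = side * side)
      map <- matrix(tab, side, side)
    }
    out[[j]] <- list(map = map,
                     origin = c(round(cur[j, 1] - margin), round(cur[j, 2] - margin)),
                     n_votes = sum(ok))
  }
  out
}

# Deterministic peak of a response map: maximum vote count, ties broken by
# smallest (row, col), refined to sub-pixel precision by the vote centroid
# in a (2r+1)^2 window around the argmax; returns image-frame (x, y).
response_peak <- function(rm, refine_radius = 2) {
  m <- rm$map
  mx <- max(m)
  hits <- which(m == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  pr <- hits[1, 1]; pc <- hits[1, 2]
  rows <- max(1, pr - refine_radius):min(nrow(m), pr + refine_radius)
  cols <- max(1, pc - refine_radius):min(ncol(m), pc + refine_radius)
  w <- m[rows, cols, drop = FALSE]
  tot <- sum(w)
  if (tot > 0) {
    pr <- sum(rows * rowSums(w)) / tot
    pc <- sum(cols * colSums(w)) / tot
  }
  c(rm$origin[1] + pc - 1, rm$origin[2] + pr - 1)
}

#' Constrained-local-model landmark fitting
#'
#' Initializes the shape model's mean shape inside the detected (or given)
#' bounding box, then iterates: regression-voting response maps, per-map
#' argmax candidates, least-squares pose + shape parameter fit to the
#' candidates, parameter clamping to the plausible region (`k = 3`), and
#' landmark regeneration -- until the mean landmark movement falls below
#' `tol` or `max_iters` is reached. Deterministic given models and image.
#'
#' @param image grayscale matrix.
#' @param detector a `knee_detector`, or `NULL` when `init` is supplied.
#' @param regressors a `patch_regressor_set`.
#' @param shape_model a `shape_model` for the same view.
#' @param max_iters iteration cap.
#' @param tol convergence threshold on mean landmark movement (pixels).
#' @param search_radius,grid_step response-map search grid (pixels).
#' @param init optional 2-column matrix of initial landmark positions,
#'   bypassing the detector.
#' @param truth optional true `landmark_set`; when given, the mean
#'   point-to-point error is reported.
#' @return an object of class `clm_fit` with `landmarks`, `iterations`,
#'   `converged`, `b`, `pose`, `detection` and optional
#'   `mean_point_error_vs_truth`.
#' @export
clm_fit <- function(image, detector, regressors, shape_model,
                    max_iters = 20, tol = 0.5, search_radius = 12,
                    grid_step = 3, init = NULL, truth = NULL) {
  if (!is.null(shape_model$view) && !is.null(detector) &&
      !is.null(attr(detector, "view")) && attr(detector, "view") != shape_model$view) {
    stop("view mismatch between detector and shape model")
  }
  detection <- NULL
  if (is.null(init)) {
    if (is.null(detector)) stop("either a detector or an explicit init is required")
    detection <- detect_box(image, detector)
    s0 <- detection$width * detector$shape_scale_per_box_width
    pts <- sweep(shape_model$mean_shape * s0, 2, detection$center, `+`)
  } else {
    pts <- as_point_matrix(init)
  }
  b <- numeric(ncol(shape_model$modes))
  pose <- NULL
  converged <- FALSE
  prev_move <- Inf
  for (it in seq_len(max_iters)) {
    maps <- compute_response_maps(image, pts, regressors,
                                  search_radius = search_radius,
                                  grid_step = grid_step)
    cand <- do.call(rbind, lapply(maps, response_peak))
    model_pts <- params_to_shape(b, NULL, shape_model, view = NULL)
    for (k in 1:3) {
      pose <- similarity_fit(model_pts, cand)
      local <- apply_similarity(cand, invert_similarity(pose))
      b <- drop(crossprod(shape_model$modes,
                          as.vector(local) - as.vector(shape_model$mean_shape)))
      b <- constrain_params(b, shape_model, k = 3)
      model_pts <- params_to_shape(b, NULL, shape_model, view = NULL)
    }
    new_pts <- apply_similarity(model_pts, pose)
    move <- mean(sqrt(rowSums((new_pts - pts)^2)))
    pts <- new_pts
    if (move < tol) { converged <- TRUE; break }
    # equilibrium stop: once the descent stalls the fit is oscillating
    # within the response-map noise floor and further iterations only
    # re-sample that noise
    if (it >= 4 && move > 0.95 * prev_move) break
    prev_move <- move
  }
  lm <- if (!is.null(shape_model$view)) landmark_set(pts, shape_model$view) else pts
  err <- if (!is.null(truth)) point_to_point_error(pts, truth) else NULL
  structure(list(landmarks = lm, iterations = it, converged = converged,
                 b = b, pose = pose, detection = detection,
                 mean_point_error_vs_truth = err),
            class = "clm_fit")
}

#' @export
print.clm_fit <- function(x, ...) {
  cat(sprintf("<clm_fit> %d iterations, converged=%s%s\n", x$iterations,
              x$converged,
              if (is.null(x$mean_point_error_vs_truth)) "" else
                sprintf(", mean error %.2f px", x$mean_point_error_vs_truth)))
  invisible(x)
}
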