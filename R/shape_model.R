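#' @title Point-distribution shape modelling
#' @description Generalized Procrustes alignment, PCA shape models and the
#'   shape parameterization used by the landmark search and the appearance
#'   model.
#' @name shape-model
NULL

as_point_matrix <- function(s) {
  if (inherits(s, "landmark_set")) s$points else as.matrix(s)
}

# Optimal similarity transform (scale, rotation, translation) mapping
# `from` onto `to` in the least-squares sense (Umeyama / full Procrustes).
similarity_fit <- function(from, to) {
  mu_f <- colMeans(from); mu_t <- colMeans(to)
  A <- sweep(from, 2, mu_f); B <- sweep(to, 2, mu_t)
  # complex-number formulation for 2D similarity (rotation without reflection)
  zf <- complex(real = A[, 1], imaginary = A[, 2])
  zt <- complex(real = B[, 1], imaginary = B[, 2])
  denom <- sum(Mod(zf)^2)
  if (denom < 1e-24) stop("degenerate shape: all points coincident")
  w <- sum(Conj(zf) * zt) / denom
  scale <- Mod(w); angle <- Arg(w)
  if (scale <= 0) stop("degenerate similarity fit (zero scale)")
  trans <- c(mu_t) - scale * rotate2(mu_f, angle)
  list(scale = scale, rotation = angle, translation = trans)
}

rotate2 <- function(p, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  if (is.matrix(p)) p %*% t(R) else as.vector(R %*% p)
}

#' Apply or invert a similarity transform
#'
#' @param points 2-column matrix.
#' @param tf list with `scale`, `rotation`, `translation` as returned inside
#'   [procrustes_align()] results.
#' @return transformed 2-column matrix.
#' @export
apply_similarity <- function(points, tf) {
  sweep(rotate2(as_point_matrix(points), tf$rotation) * tf$scale,
        2, tf$translation, `+`)
}

#' @rdname apply_similarity
#' @export
invert_similarity <- function(tf) {
  inv_scale <- 1 / tf$scale
  inv_rot <- -tf$rotation
  list(scale = inv_scale, rotation = inv_rot,
       translation = -inv_scale * rotate2(tf$translation, inv_rot))
}

# Normalize a shape: centroid at origin, unit RMS scale.
normalize_shape <- function(pts) {
  pts <- sweep(pts, 2, colMeans(pts))
  rms <- sqrt(mean(rowSums(pts^2)))
  if (rms < 1e-12) stop("degenerate shape: all points coincident")
  pts / rms
}

#' Generalized Procrustes alignment
#'
#' Iteratively aligns each shape to the running mean by the least-squares
#' similarity transform, re-estimates and normalizes the mean (centroid at
#' origin, unit RMS scale), until the mean changes by less than `tol` in RMS
#' or `max_iters` iterations.
#'
#' @param shapes list of `landmark_set`s or 2-column matrices with identical
#'   topology.
#' @param tol convergence tolerance on the RMS change of the mean shape.
#' @param max_iters iteration cap.
#' @return list with `aligned` (list of matrices), `mean_shape` (matrix),
#'   `transforms` (the similarity mapping each original shape onto the final
#'   mean frame), and `view` when the input carried one.
#' @export
procrustes_align <- function(shapes, tol = 1e-8, max_iters = 100) {
  if (length(shapes) < 2) stop("need at least 2 shapes")
  view <- if (inherits(shapes[[1]], "landmark_set")) shapes[[1]]$view else NULL
  mats <- lapply(shapes, as_point_matrix)
  np <- vapply(mats, nrow, 0L)
  if (length(unique(np)) != 1) stop("mixed topologies: differing point counts")
  views <- unique(vapply(shapes, function(s)
    if (inherits(s, "landmark_set")) s$view else NA_character_, ""))
  if (length(views[!is.na(views)]) > 1) stop("mixed topologies: differing views")
  mean_shape <- normalize_shape(mats[[1]])
  aligned <- mats
  for (it in seq_len(max_iters)) {
    tfs <- lapply(mats, similarity_fit, to = mean_shape)
    aligned <- Map(apply_similarity, mats, tfs)
    new_mean <- normalize_shape(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  tfs <- lapply(mats, similarity_fit, to = mean_shape)
  aligned <- Map(apply_similarity, mats, tfs)
  list(aligned = aligned, mean_shape = mean_shape, transforms = tfs,
       view = view, iterations = it)
}

#' Build a PCA shape model from aligned shapes
#'
#' PCA of the aligned shape vectors (2N-dimensional, x-coordinates then
#' y-coordinates); retains the smallest number of modes whose cumulative
#' eigenvalue fraction reaches `variance_retained`.
#'
#' @param aligned list of aligned 2-column matrices (or the result of
#'   [procrustes_align()]).
#' @param variance_retained fraction of variance to retain, in `(0, 1]`.
#' @param view optional view tag carried into the model.
#' @return an object of class `shape_model` with `mean_shape` (matrix),
#'   `modes` (2N x t, orthonormal columns), `eigenvalues` (length t,
#'   non-increasing), `variance_retained`, `total_variance`, `n_points`.
#' @export
build_shape_model <- function(aligned, variance_retained = 0.95, view = NULL) {
  if (is.list(aligned) && !is.null(aligned$aligned)) {
    if (is.null(view)) view <- aligned$view
    aligned <- aligned$aligned
  }
  if (length(aligned) < 3) stop("need at least 3 shapes to build a model")
  if (variance_retained <= 0 || variance_retained > 1) {
    stop("variance_retained must lie in (0, 1]")
  }
  X <- t(vapply(aligned, function(m) as.vector(as_point_matrix(m)),
                numeric(2 * nrow(as_point_matrix(aligned[[1]])))))
  mean_vec <- colMeans(X)
  Xc <- sweep(X, 2, mean_vec)
  sv <- svd(Xc)
  n <- nrow(X)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  keep <- ev > total * 1e-12
  ev <- ev[keep]
  P <- sv$v[, keep, drop = FALSE]
  if (total <= 0 || length(ev) == 0) {         # all shapes identical
    t_keep <- 0L
  } else {
    cumfrac <- cumsum(ev) / total
    t_keep <- which(cumfrac >= variance_retained - 1e-12)[1]
  }
  structure(list(
    view = view,
    mean_shape = matrix(mean_vec, ncol = 2, dimnames = list(NULL, c("x", "y"))),
    modes = P[, seq_len(t_keep), drop = FALSE],
    eigenvalues = ev[seq_len(t_keep)],
    all_eigenvalues = ev,
    total_variance = total,
    variance_retained = variance_retained,
    n_points = length(mean_vec) / 2,
    n_train = n
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %s points=%d modes=%d (%.1f%% variance)\n",
              if (is.null(x$view)) "" else x$view, x$n_points,
              ncol(x$modes),
              if (x$total_variance > 0) 100 * sum(x$eigenvalues) / x$total_variance else 100))
  invisible(x)
}

#' Project a shape onto a shape model
#'
#' Finds the pose (similarity transform from the model frame to the shape's
#' frame) and the shape parameters `b` such that
#' `pose(mean + modes %*% b)` best reconstructs the shape, by alternating
#' pose estimation against the current reconstruction with projection onto
#' the modes. Tangent-space projection is not used, so pose and shape are
#' coupled at second order; the alternation resolves the coupling to
#' numerical precision for shapes in (or near) the model subspace.
#'
#' @param shape a `landmark_set` or 2-column matrix.
#' @param model a `shape_model`.
#' @param iters alternation steps (the joint fit typically settles in 2-3).
#' @return list with `b` (length-t parameter vector) and `pose`.
#' @export
shape_to_params <- function(shape, model, iters = 5) {
  pts <- as_point_matrix(shape)
  if (nrow(pts) != model$n_points) stop("point count does not match model")
  b <- numeric(ncol(model$modes))
  pose <- NULL
  for (i in seq_len(iters)) {
    recon <- matrix(as.vector(model$mean_shape) +
                      if (length(b)) drop(model$modes %*% b) else 0, ncol = 2)
    pose <- similarity_fit(recon, pts)
    local <- apply_similarity(pts, invert_similarity(pose))
    b_new <- drop(crossprod(model$modes,
                            as.vector(local) - as.vector(model$mean_shape)))
    if (length(b) && max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
    b <- b_new
  }
  list(b = as.numeric(b), pose = pose)
}

#' Reconstruct a shape from model parameters
#'
#' @param b shape parameter vector of length t (the retained mode count).
#' @param pose similarity transform from the model frame to image
#'   coordinates; identity (`NULL`) returns the model-frame shape.
#' @param model a `shape_model`.
#' @param view optional view; when the model carries one, the result is a
#'   `landmark_set`, otherwise a bare matrix.
#' @return `landmark_set` or matrix of points.
#' @export
params_to_shape <- function(b, pose = NULL, model, view = model$view) {
  if (length(b) != ncol(model$modes)) {
    stop(sprintf("parameter length %d does not match %d retained modes",
                 length(b), ncol(model$modes)))
  }
  vec <- as.vector(model$mean_shape) +
    if (length(b)) drop(model$modes %*% b) else 0
  pts <- matrix(vec, ncol = 2)
  if (!is.null(pose)) pts <- apply_similarity(pts, pose)
  if (!is.null(view)) landmark_set(pts, view) else pts
}

#' Clamp shape parameters to the plausible region
#'
#' Element-wise clamp of each parameter to `|b_j| <= k * sqrt(eigenvalue_j)`,
#' the standard point-distribution-model plausibility box.
#'
#' @param b parameter vector.
#' @param model a `shape_model`.
#' @param k box half-width in SDs of each mode (default 3).
#' @return clamped parameter vector.
#' @export
constrain_params <- function(b, model, k = 3) {
  lim <- k * sqrt(model$eigenvalues)
  pmin(pmax(b, -lim), lim)
}

#' Serialize and restore models
#'
#' Models are written as versioned JSON with full-precision numeric arrays,
#' a self-describing text container.
#'
#' @param model a `shape_model`, `texture_model` or `combined_model`.
#' @param path output path.
#' @return `save_model` the path invisibly; `load_model` the restored model.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$.class <- class(model)[1]
  obj$.format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL; obj$.format_version <- NULL
  for (nm in c("mean_shape", "modes", "combined_modes", "frame_pixels")) {
    if (!is.null(obj[[nm]]) && !is.matrix(obj[[nm]])) {
      obj[[nm]] <- as.matrix(obj[[nm]])
    }
  }
  # nested models
  for (nm in c("shape_model", "texture_model")) {
    if (!is.null(obj[[nm]])) {
      sub <- obj[[nm]]
      for (f in c("mean_shape", "modes")) {
        if (!is.null(sub[[f]]) && !is.matrix(sub[[f]])) sub[[f]] <- as.matrix(sub[[f]])
      }
      cls_sub <- if (nm == "shape_model") "shape_model" else "texture_model"
      obj[[nm]] <- structure(sub, class = cls_sub)
    }
  }
  structure(obj, class = cls)
}
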