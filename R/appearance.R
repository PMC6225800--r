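# Shape-normalized texture sampling and the combined shape+texture
# (appearance) model whose parameter vector is the automated feature set.

# --- Delaunay triangulation (Bowyer-Watson) -------------------------------
# Plain O(n^2) incremental insertion; adequate for landmark sets of ~100
# points and fully deterministic (insertion in index order).

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)   # center, squared radius
}

#' Delaunay triangulation of a 2D point set
#'
#' Incremental Bowyer-Watson triangulation, deterministic in the point
#' order. Used to define the piecewise-affine warp of the texture model on
#' the mean shape.
#'
#' @param pts 2-column matrix of points.
#' @return integer matrix with three vertex-index columns, one row per
#'   triangle; near-degenerate triangles (area < 1e-9) are dropped.
#' @export
delaunay_triangulate <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  rng <- apply(pts, 2, range)
  ctr <- colMeans(rng)
  d <- max(rng[2, ] - rng[1, ]) * 20 + 1
  sup <- rbind(ctr + c(0, -d), ctr + c(-d, d), ctr + c(d, d))
  allp <- rbind(pts, sup)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  ccs <- list(circumcircle(sup[1, ], sup[2, ], sup[3, ]))
  for (i in seq_len(n)) {
    p <- pts[i, ]
    bad <- vapply(ccs, function(cc) {
      !is.null(cc) && (p[1] - cc[1])^2 + (p[2] - cc[2])^2 <= cc[3] * (1 + 1e-12)
    }, logical(1))
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))
    }))
    tris <- tris[!bad]; ccs <- ccs[!bad]
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      tr <- c(boundary[e, ], i)
      cc <- circumcircle(allp[tr[1], ], allp[tr[2], ], allp[tr[3], ])
      if (is.null(cc)) next
      tris <- c(tris, list(tr))
      ccs <- c(ccs, list(cc))
    }
  }
  out <- do.call(rbind, tris)
  out <- out[apply(out, 1, function(tr) all(tr <= n)), , drop = FALSE]
  area <- abs((allp[out[, 2], 1] - allp[out[, 1], 1]) *
              (allp[out[, 3], 2] - allp[out[, 1], 2]) -
              (allp[out[, 3], 1] - allp[out[, 1], 1]) *
              (allp[out[, 2], 2] - allp[out[, 1], 2])) / 2
  out <- out[area > 1e-9, , drop = FALSE]
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# --- reference frame -------------------------------------------------------

#' Build the shape-normalized reference frame
#'
#' Scales the mean shape to span `frame_width` pixels, triangulates it
#' (Delaunay, frozen into the model), and enumerates the frame pixels inside
#' the triangulated region with their triangle assignment and barycentric
#' coordinates. Texture vectors are read at these pixels in row-major order.
#'
#' @param mean_shape 2-column matrix (any frame; typically the Procrustes
#'   mean).
#' @param frame_width target width of the mean shape in pixels.
#' @return list with `frame_shape` (mean shape in frame pixels), `width`,
#'   `height`, `triangles`, `pixels` (m x 2, 0-based), `tri_index` (m),
#'   `bary` (m x 3), `n_pixels`.
#' @export
build_reference_frame <- function(mean_shape, frame_width = 128) {
  ms <- as_point_matrix(mean_shape)
  rngx <- range(ms[, 1]); rngy <- range(ms[, 2])
  margin <- 2
  sc <- (frame_width - 1 - 2 * margin) / diff(rngx)
  fs <- cbind((ms[, 1] - rngx[1]) * sc + margin,
              (ms[, 2] - rngy[1]) * sc + margin)
  height <- ceiling(diff(rngy) * sc + 2 * margin) + 1
  tri <- delaunay_triangulate(fs)
  # rasterize: first triangle (in sorted order) owning a pixel wins
  width <- frame_width
  owner <- matrix(0L, height, width)
  b1m <- b2m <- b3m <- matrix(0, height, width)
  for (t in seq_len(nrow(tri))) {
    v <- fs[tri[t, ], ]
    xs <- max(0, floor(min(v[, 1]))):min(width - 1, ceiling(max(v[, 1])))
    ys <- max(0, floor(min(v[, 2]))):min(height - 1, ceiling(max(v[, 2])))
    if (!length(xs) || !length(ys)) next
    g <- expand.grid(x = xs, y = ys)
    det <- (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
           (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])
    b1 <- ((v[2, 1] - g$x) * (v[3, 2] - g$y) - (v[3, 1] - g$x) * (v[2, 2] - g$y)) / det
    b2 <- ((v[3, 1] - g$x) * (v[1, 2] - g$y) - (v[1, 1] - g$x) * (v[3, 2] - g$y)) / det
    b3 <- 1 - b1 - b2
    ok <- b1 >= -1e-9 & b2 >= -1e-9 & b3 >= -1e-9
    idx <- (g$x[ok]) * height + g$y[ok] + 1L        # column-major [y+1, x+1]
    free <- owner[idx] == 0L
    idx <- idx[free]
    owner[idx] <- t
    b1m[idx] <- b1[ok][free]; b2m[idx] <- b2[ok][free]; b3m[idx] <- b3[ok][free]
  }
  # row-major pixel order: scan rows (y) then columns (x)
  coords <- which(owner != 0L, arr.ind = TRUE)      # [row=y+1, col=x+1]
  ord <- order(coords[, 1], coords[, 2])            # row-major: y then x
  coords <- coords[ord, , drop = FALSE]
  lin <- (coords[, 2] - 1L) * height + coords[, 1]
  list(frame_shape = fs, width = width, height = height, triangles = tri,
       pixels = cbind(x = coords[, 2] - 1L, y = coords[, 1] - 1L),
       tri_index = owner[lin],
       bary = cbind(b1m[lin], b2m[lin], b3m[lin]),
       n_pixels = length(lin))
}

# Bilinear interpolation at 0-based (x, y); out-of-image positions clamp to
# the nearest valid pixel.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(x0, w - 2); y0 <- pmin(y0, h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]; i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]; i11 <- img[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Sample a shape-normalized texture vector
#'
#' Piecewise-affine warp from the image (under its landmarks) into the
#' reference frame: each frame pixel's barycentric coordinates, fixed by the
#' frozen triangulation of the mean shape, are applied to the corresponding
#' image landmarks, and the image is read there with bilinear interpolation.
#' Samples outside the image take the nearest valid pixel value.
#'
#' @param image grayscale matrix in `[0,1]`.
#' @param landmarks `landmark_set` or point matrix matching the frame's
#'   topology.
#' @param frame a reference frame from [build_reference_frame()].
#' @return numeric texture vector of length `frame$n_pixels` (row-major
#'   frame order).
#' @export
warp_to_reference <- function(image, landmarks, frame) {
  pts <- as_point_matrix(landmarks)
  if (nrow(pts) != nrow(frame$frame_shape)) {
    stop("landmark count does not match the reference frame")
  }
  tri <- frame$triangles
  v1 <- pts[tri[frame$tri_index, 1], , drop = FALSE]
  v2 <- pts[tri[frame$tri_index, 2], , drop = FALSE]
  v3 <- pts[tri[frame$tri_index, 3], , drop = FALSE]
  src <- frame$bary[, 1] * v1 + frame$bary[, 2] * v2 + frame$bary[, 3] * v3
  bilinear_sample(image, src[, 1], src[, 2])
}

# Zero-mean unit-variance normalization of a texture vector; constant
# textures map to the zero vector.
normalize_texture <- function(g) {
  g <- g - mean(g)
  s <- stats::sd(g)
  if (s < 1e-12) return(g * 0)
  g / s
}

pca_retain <- function(X, variance_retained) {
  if (variance_retained <= 0 || variance_retained > 1) {
    stop("variance_retained must lie in (0, 1]")
  }
  mean_vec <- colMeans(X)
  Xc <- sweep(X, 2, mean_vec)
  sv <- svd(Xc, nu = 0)
  n <- nrow(X)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  keep <- ev > total * 1e-12
  ev <- ev[keep]
  P <- sv$v[, keep, drop = FALSE]
  if (total <= 0 || length(ev) == 0) {
    t_keep <- 0L
  } else {
    t_keep <- which(cumsum(ev) / total >= variance_retained - 1e-12)[1]
  }
  list(mean = mean_vec, modes = P[, seq_len(t_keep), drop = FALSE],
       eigenvalues = ev[seq_len(t_keep)], all_eigenvalues = ev,
       total_variance = total)
}

#' Build a texture PCA model
#'
#' Normalizes each texture vector (zero mean, unit variance by default) then
#' applies PCA with the same variance-retention rule as the shape model.
#'
#' @param textures matrix (n x m) of raw texture vectors, or list of
#'   vectors.
#' @param variance_retained fraction of variance to retain, in `(0, 1]`.
#' @param frame the reference frame the textures were sampled in (stored for
#'   later feature extraction).
#' @param normalization `"zero-mean-unit-var"` (default) or `"none"`.
#' @return an object of class `texture_model`.
#' @export
build_texture_model <- function(textures, variance_retained = 0.95,
                                frame = NULL,
                                normalization = c("zero-mean-unit-var", "none")) {
  normalization <- match.arg(normalization)
  if (is.list(textures)) textures <- do.call(rbind, textures)
  if (normalization == "zero-mean-unit-var") {
    textures <- t(apply(textures, 1, normalize_texture))
  }
  p <- pca_retain(textures, variance_retained)
  structure(list(mean_texture = p$mean, modes = p$modes,
                 eigenvalues = p$eigenvalues,
                 all_eigenvalues = p$all_eigenvalues,
                 total_variance = p$total_variance,
                 normalization = normalization,
                 variance_retained = variance_retained,
                 frame = frame, n_train = nrow(textures)),
            class = "texture_model")
}

#' @export
print.texture_model <- function(x, ...) {
  cat(sprintf("<texture_model> %d pixels, %d modes\n",
              length(x$mean_texture), ncol(x$modes)))
  invisible(x)
}

#' Project a texture onto a texture model
#'
#' @param g raw texture vector.
#' @param model a `texture_model`.
#' @return parameter vector `b_g`.
#' @export
texture_to_params <- function(g, model) {
  if (model$normalization == "zero-mean-unit-var") g <- normalize_texture(g)
  drop(crossprod(model$modes, g - model$mean_texture))
}

#' Build the combined appearance model
#'
#' Concatenates the per-example shape parameters `b_s` (scaled by the
#' variance-balancing weight `W_s`) with the texture parameters `b_g`, and
#' applies PCA. `W_s = sqrt(sum(texture eigenvalues) / sum(shape
#' eigenvalues))` puts the two blocks on a common variance scale, so the
#' combined parameter vector `c` carries non-redundant shape and texture
#' information.
#'
#' @param shape_model a `shape_model`.
#' @param texture_model a `texture_model` carrying its reference frame.
#' @param b_s matrix (n x t) of per-example shape parameters.
#' @param b_g matrix (n x s) of per-example texture parameters, row-paired
#'   with `b_s`.
#' @param variance_retained retention fraction for the combined PCA.
#' @return an object of class `combined_model` with the appearance dimension
#'   `n_params`.
#' @export
build_combined_model <- function(shape_model, texture_model, b_s, b_g,
                                 variance_retained = 0.98) {
  b_s <- as.matrix(b_s); b_g <- as.matrix(b_g)
  if (nrow(b_s) != nrow(b_g)) stop("unpaired inputs: b_s and b_g row counts differ")
  ssum <- sum(shape_model$eigenvalues)
  tsum <- sum(texture_model$eigenvalues)
  W_s <- if (ssum > 0) sqrt(tsum / ssum) else 1
  if (W_s <= 0 || !is.finite(W_s)) W_s <- 1
  X <- cbind(b_s * W_s, b_g)
  p <- pca_retain(X, variance_retained)
  structure(list(shape_model = shape_model, texture_model = texture_model,
                 W_s = W_s, combined_mean = p$mean, combined_modes = p$modes,
                 combined_eigenvalues = p$eigenvalues,
                 all_eigenvalues = p$all_eigenvalues,
                 total_variance = p$total_variance,
                 n_shape_params = ncol(b_s), n_texture_params = ncol(b_g),
                 n_params = ncol(p$modes),
                 variance_retained = variance_retained),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat(sprintf("<combined_model> t=%d shape + s=%d texture -> %d appearance params (W_s=%.3f)\n",
              x$n_shape_params, x$n_texture_params, x$n_params, x$W_s))
  invisible(x)
}

#' Extract appearance features from an image and its landmarks
#'
#' Deterministically maps an (image, landmarks) pair to the appearance
#' parameter vector `c`: project the landmarks onto the shape model
#' (`b_s`), warp and normalize the texture and project onto the texture
#' model (`b_g`), then project the weighted concatenation onto the combined
#' modes. The shape-only and texture-only parameter vectors are returned
#' alongside so the classifier stage can select among the three automated
#' feature sets.
#'
#' @param image grayscale matrix in `[0,1]`.
#' @param landmarks `landmark_set` (fitted or ground truth).
#' @param model a `combined_model`.
#' @return list with `c`, `b_s`, `b_g`.
#' @export
extract_appearance_features <- function(image, landmarks, model) {
  sp <- shape_to_params(landmarks, model$shape_model)
  g <- warp_to_reference(image, landmarks, model$texture_model$frame)
  bg <- texture_to_params(g, model$texture_model)
  x <- c(sp$b * model$W_s, bg)
  cc <- drop(crossprod(model$combined_modes, x - model$combined_mean))
  list(c = as.numeric(cc), b_s = as.numeric(sp$b), b_g = as.numeric(bg))
}

#' Appearance feature matrix for a cohort
#'
#' Applies [extract_appearance_features()] to every knee and returns a
#' data.frame of id plus `c_*`, `bs_*` and `bg_*` columns.
#'
#' @param images list of grayscale matrices.
#' @param landmarks list of `landmark_set`s, paired with `images`.
#' @param model a `combined_model`.
#' @param ids character vector of knee ids.
#' @return data.frame, one row per knee.
#' @export
extract_cohort_features <- function(images, landmarks, model, ids = NULL) {
  n <- length(images)
  if (length(landmarks) != n) stop("images and landmarks differ in length")
  if (is.null(ids)) ids <- sprintf("knee_%05d", seq_len(n))
  feats <- lapply(seq_len(n), function(i)
    extract_appearance_features(images[[i]], landmarks[[i]], model))
  cmat <- do.call(rbind, lapply(feats, `[[`, "c"))
  smat <- do.call(rbind, lapply(feats, `[[`, "b_s"))
  gmat <- do.call(rbind, lapply(feats, `[[`, "b_g"))
  name_block <- function(m, stem) {
    if (is.null(m) || ncol(m) == 0) return(NULL)
    colnames(m) <- sprintf("%s_%d", stem, seq_len(ncol(m)))
    as.data.frame(m)
  }
  out <- cbind(data.frame(id = ids, stringsAsFactors = FALSE),
               name_block(cmat, "c"), name_block(smat, "bs"),
               name_block(gmat, "bg"))
  out
}
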