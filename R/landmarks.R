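#' Landmark topology for a radiographic view
#'
#' The two knee views use fixed point-distribution topologies. The lateral
#' model has four subshapes: patella (21 points), lateral femoral condyle
#' (24), medial femoral condyle (25) and tibia (32), 102 points in total;
#' the femur is the union of the two condyles (49 points). The PA model has
#' a femur and a tibia of 37 points each, 74 points in total.
#'
#' @param view `"PA"` or `"LATERAL"`.
#' @return A list with `view`, `n_points` and `subshapes`, a named list of
#'   integer index vectors into the point list. Index vectors partition
#'   `1:n_points`; derived unions (`femur` on the lateral view) are listed
#'   separately under `unions`.
#' @export
view_topology <- function(view) {
  view <- match.arg(toupper(view), c("PA", "LATERAL"))
  if (view == "PA") {
    subshapes <- list(femur = 1:37, tibia = 38:74)
    unions <- list()
    n <- 74L
  } else {
    subshapes <- list(
      patella = 1:21,
      lateral_femoral_condyle = 22:45,
      medial_femoral_condyle = 46:70,
      tibia = 71:102
    )
    unions <- list(femur = 22:70)
    n <- 102L
  }
  list(view = view, n_points = n, subshapes = subshapes, unions = unions)
}

#' Construct a landmark set
#'
#' @param points numeric matrix with two columns (x, y) in pixel coordinates;
#'   0-based pixel centers, x rightward, y downward.
#' @param view `"PA"` or `"LATERAL"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, view) {
  view <- match.arg(toupper(view), c("PA", "LATERAL"))
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  topo <- view_topology(view)
  if (nrow(points) != topo$n_points) {
    stop(sprintf("view %s requires %d points, got %d",
                 view, topo$n_points, nrow(points)))
  }
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, view = view, topology = topo),
            class = "landmark_set")
}

#' Validate a landmark set against its view topology
#'
#' @param x a `landmark_set`.
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_landmarks <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  topo <- view_topology(x$view)
  if (nrow(x$points) != topo$n_points) {
    stop(sprintf("expected %d points for view %s", topo$n_points, x$view))
  }
  idx <- sort(unlist(topo$subshapes, use.names = FALSE))
  if (!identical(idx, seq_len(topo$n_points))) {
    stop("subshape index ranges do not partition the point set")
  }
  if (!all(is.finite(x$points))) stop("non-finite landmark coordinates")
  invisible(TRUE)
}

#' Extract a named subshape
#'
#' @param x a `landmark_set`.
#' @param name subshape name (e.g. `"tibia"`, or `"femur"` which on the
#'   lateral view is the union of the two condyles).
#' @return matrix of the subshape's points.
#' @export
subshape_points <- function(x, name) {
  stopifnot(inherits(x, "landmark_set"))
  topo <- x$topology
  idx <- topo$subshapes[[name]]
  if (is.null(idx)) idx <- topo$unions[[name]]
  if (is.null(idx)) stop(sprintf("unknown subshape '%s' for view %s", name, x$view))
  x$points[idx, , drop = FALSE]
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> view=%s, %d points, subshapes: %s\n",
              x$view, nrow(x$points),
              paste(names(x$topology$subshapes), collapse = ", ")))
  invisible(x)
}

#' Read and write plain-text points files
#'
#' The format is: a first line `n_points: N`, an opening `{`, N lines of
#' `x y` (pixels, origin top-left, 0-based), and a closing `}`.
#'
#' @param path file path.
#' @param view view of the landmark set (needed on read to attach topology).
#' @return `read_points` returns a `landmark_set`; `write_points` returns the
#'   path invisibly.
#' @export
read_points <- function(path, view) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!grepl("^n_points:", lines[1])) stop("missing 'n_points:' header in ", path)
  n <- as.integer(sub("^n_points:\\s*", "", lines[1]))
  body <- lines[!(lines %in% c("{", "}"))][-1]
  if (length(body) != n) stop(sprintf("expected %d points, found %d in %s", n, length(body), path))
  xy <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  landmark_set(xy, view)
}

#' @rdname read_points
#' @param x a `landmark_set` to write.
#' @export
write_points <- function(x, path) {
  stopifnot(inherits(x, "landmark_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("n_points: %d", nrow(x$points)), con)
  writeLines("{", con)
  writeLines(sprintf("%.6f %.6f", x$points[, 1], x$points[, 2]), con)
  writeLines("}", con)
  invisible(path)
}

#' Mean point-to-point landmark error
#'
#' Mean Euclidean distance between corresponding landmarks of two sets with
#' the same topology, in pixels.
#'
#' @param fit,truth `landmark_set` objects (or bare 2-column matrices) with
#'   equal point counts.
#' @return mean distance in pixels.
#' @export
point_to_point_error <- function(fit, truth) {
  a <- if (inherits(fit, "landmark_set")) fit$points else as.matrix(fit)
  b <- if (inherits(truth, "landmark_set")) truth$points else as.matrix(truth)
  if (!identical(dim(a), dim(b))) stop("landmark sets differ in size")
  mean(sqrt(rowSums((a - b)^2)))
}
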