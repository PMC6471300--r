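#' Threshold a frequency grid into a point cloud
#'
#' Selects every voxel whose pocket frequency is strictly greater than
#' `cutoff` and returns its world coordinate (`origin + index * spacing`).
#' Thresholding is monotone: raising the cutoff never adds points.
#'
#' @param grid a [frequency_grid()].
#' @param cutoff frequency cutoff in `[0, 1]`; default 0.2, the
#'   conventional choice for pocket-frequency maps.
#' @return A numeric matrix with one row per surviving voxel and columns
#'   `x`, `y`, `z` (angstrom), of class `point_cloud`. The surviving
#'   frequencies are attached as attribute `"frequencies"` (used by the
#'   optional weighted axis mode). An empty cloud (0 rows) is valid.
#' @export
threshold_points <- function(grid, cutoff = 0.2) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1)
    stop("cutoff must be a single value in [0, 1]")
  keep <- which(grid$values > cutoff, arr.ind = TRUE)
  pts <- matrix(numeric(0), 0L, 3L)
  if (nrow(keep) > 0L) {
    pts <- sweep((keep - 1) %*% diag(grid$spacing), 2L, grid$origin, "+")
  }
  colnames(pts) <- c("x", "y", "z")
  structure(pts, frequencies = grid$values[keep], class = c("point_cloud", "matrix"))
}

#' Diffusion axes of a point cloud by covariance eigendecomposition
#'
#' Computes the sample covariance matrix of the point coordinates and its
#' eigendecomposition. The three orthonormal eigenvectors, sorted by
#' descending variance, are the principal axes of the cloud; the leading
#' one is the diffusion axis of a tunnel-shaped cavity. Each axis is
#' oriented so that its largest-magnitude component is positive, making
#' the output deterministic across eigensolvers.
#'
#' @param cloud a `point_cloud` from [threshold_points()], or any n x 3
#'   numeric matrix of coordinates.
#' @param weights optional non-negative per-point weights (e.g. the voxel
#'   frequencies). The default (`NULL`) is the unweighted decomposition.
#' @return An object of class `axis_set`: list with `axes` (3 x 3 matrix,
#'   one axis per column, descending variance), `variances` (length 3,
#'   angstrom squared), `degenerate` (logical: near-tied eigenvalues or a
#'   rank-deficient cloud), and `n_points`.
#' @export
diffusion_axes <- function(cloud, weights = NULL) {
  pts <- unclass(cloud)
  if (!is.matrix(pts) || ncol(pts) != 3L) stop("cloud must be an n x 3 matrix")
  n <- nrow(pts)
  if (n < 2L) stop("degenerate input: need at least 2 points for a covariance axis")
  if (is.null(weights)) {
    cv <- cov(pts)  # unbiased (n - 1) denominator
  } else {
    if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
      stop("weights must be non-negative with positive sum, one per point")
    w <- weights / sum(weights)
    mu <- colSums(pts * w)
    xc <- sweep(pts, 2L, mu)
    # frequency-weighted covariance with an effective (n - 1)-style correction
    cv <- crossprod(xc * sqrt(w), xc * sqrt(w)) / (1 - sum(w^2))
  }
  ed <- eigen(cv, symmetric = TRUE)
  vars <- pmax(ed$values, 0)
  axes <- ed$vectors
  for (j in 1:3) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  # near-ties among adjacent sorted eigenvalues (1% relative) or rank
  # deficiency leave the axis directions ill-determined
  rel_gap <- function(a, b) if (max(a, b) <= 0) 0 else (a - b) / max(a, b)
  degen <- n < 4L ||
    rel_gap(vars[1], vars[2]) < 0.01 ||
    rel_gap(vars[2], vars[3]) < 0.01
  if (degen)
    warning("degenerate point cloud: principal axes are not uniquely determined")
  structure(list(axes = axes, variances = vars, degenerate = degen,
                 n_points = n),
            class = "axis_set")
}

#' @export
print.axis_set <- function(x, ...) {
  cat(sprintf("axis_set from %d points%s\n", x$n_points,
              if (x$degenerate) " (degenerate)" else ""))
  for (j in 1:3)
    cat(sprintf("  axis %d: [%+.4f, %+.4f, %+.4f]  variance %.4g A^2\n",
                j, x$axes[1, j], x$axes[2, j], x$axes[3, j], x$variances[j]))
  invisible(x)
}

#' Write an axis set to JSON
#'
#' @param axes an `axis_set` from [diffusion_axes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_axis_json <- function(axes, path) {
  stopifnot(inherits(axes, "axis_set"))
  jsonlite::write_json(
    list(axes = t(axes$axes), variances = axes$variances,
         degenerate = axes$degenerate, n_points = axes$n_points),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an axis set from JSON
#'
#' @param path a file written by [write_axis_json()].
#' @return An `axis_set`.
#' @export
read_axis_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(axes = t(x$axes), variances = as.numeric(x$variances),
                 degenerate = isTRUE(x$degenerate),
                 n_points = as.integer(x$n_points)),
            class = "axis_set")
}
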