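#' Detect basins and barriers on a free-energy curve
#'
#' Local minima of the (optionally moving-average smoothed) curve,
#' separated by local maxima. Basins whose depth relative to their
#' lowest adjacent saddle is below `min_depth` are merged into the
#' deeper neighbour (persistence pruning). Basins are labelled by energy
#' rank, 0 for the deepest; the barrier between adjacent basins is the
#' highest point of the curve between their minima, with the height
#' reported relative to the shallower of the two.
#'
#' @param fes an `fes_curve` (data frame with `cv1`, `free_energy`) from
#'   [reconstruct_fes()] or [read_fes()].
#' @param smooth_window moving-average window in grid points (odd; 1 =
#'   no smoothing, the default since reconstructed curves are already
#'   smooth at hill-width resolution).
#' @param min_depth minimum basin depth, kcal/mol. Default 0.
#' @return List of class `basin_set` with data frames `basins` (`label`,
#'   `location`, `energy`, ordered along the grid) and `barriers`
#'   (`left`, `right` basin labels, `location`, `energy`, `height`).
#' @export
find_basins <- function(fes, smooth_window = 1, min_depth = 0) {
  x <- fes$cv1; f <- fes$free_energy
  if (length(x) < 3L) stop("curve must have at least 3 points")
  if (smooth_window > 1) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) w <- w + 1L
    k <- rep(1 / w, w)
    pad <- (w - 1L) %/% 2L
    fpad <- c(rep(f[1], pad), f, rep(f[length(f)], pad))
    f <- as.numeric(stats::filter(fpad, k, sides = 2))[(pad + 1L):(pad + length(x))]
  }
  n <- length(f)
  # interior local minima, plateau-tolerant (flat runs collapse to their
  # first point)
  mins <- integer(0)
  i <- 2L
  while (i < n) {
    if (f[i] < f[i - 1L]) {
      j <- i
      while (j < n && f[j + 1L] == f[i]) j <- j + 1L
      if (j < n && f[j + 1L] > f[i]) mins <- c(mins, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  # monotone edge case: a ramp has its basin at the low end
  if (!length(mins)) mins <- if (f[1] <= f[n]) 1L else n
  saddle_of <- function(a, b) {
    seg <- a:b
    seg[which.max(f[seg])]
  }
  # persistence pruning: drop the shallowest basin below min_depth
  if (min_depth > 0) {
    while (length(mins) >= 2L) {
      sads <- vapply(seq_len(length(mins) - 1L),
                     function(k) saddle_of(mins[k], mins[k + 1L]), integer(1))
      depth <- vapply(seq_along(mins), function(k) {
        adj <- c(if (k > 1L) f[sads[k - 1L]], if (k < length(mins)) f[sads[k]])
        min(adj) - f[mins[k]]
      }, numeric(1))
      worst <- which.min(depth)
      if (depth[worst] >= min_depth) break
      mins <- mins[-worst]
    }
  }
  ord <- rank(f[mins], ties.method = "first") - 1L
  basins <- data.frame(label = paste0("B", ord), location = x[mins],
                       energy = f[mins])
  barriers <- NULL
  if (length(mins) >= 2L) {
    ks <- seq_len(length(mins) - 1L)
    sads <- vapply(ks, function(k) saddle_of(mins[k], mins[k + 1L]), integer(1))
    barriers <- data.frame(
      left = basins$label[ks], right = basins$label[ks + 1L],
      location = x[sads], energy = f[sads],
      height = vapply(ks, function(k)
        f[sads[k]] - max(f[mins[k]], f[mins[k + 1L]]), numeric(1)))
  } else {
    barriers <- data.frame(left = character(0), right = character(0),
                           location = numeric(0), energy = numeric(0),
                           height = numeric(0))
  }
  structure(list(basins = basins, barriers = barriers), class = "basin_set")
}

#' @export
print.basin_set <- function(x, ...) {
  cat(sprintf("basin_set: %d basin(s)\n", nrow(x$basins)))
  print(x$basins, row.names = FALSE)
  if (nrow(x$barriers)) {
    cat("barriers:\n")
    print(x$barriers, row.names = FALSE)
  }
  invisible(x)
}

#' Mean-distance radius of gyration
#'
#' The mean distance between the atoms and their centroid — a linear
#' (not root-mean-square) spread measure, always less than or equal to
#' the RMS radius of gyration of the same atoms (Jensen's inequality).
#'
#' @param coords n x 3 coordinate matrix (angstrom).
#' @return Mean distance to the centroid, angstrom.
#' @seealso [radius_of_gyration_rms()] for the conventional definition.
#' @export
radius_of_gyration_mean <- function(coords) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("empty coordinate set")
  mu <- colMeans(coords)
  mean(sqrt(rowSums(sweep(coords, 2L, mu)^2)))
}

#' Root-mean-square radius of gyration
#'
#' The conventional definition, `sqrt(mean |r_i - centroid|^2)`.
#'
#' @param coords n x 3 coordinate matrix (angstrom).
#' @return RMS radius of gyration, angstrom.
#' @export
radius_of_gyration_rms <- function(coords) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("empty coordinate set")
  mu <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2L, mu)^2)))
}

#' Count inter-group atomic contacts in a frame
#'
#' Number of atom pairs (one from each group) strictly closer than
#' `cutoff`; symmetric in the two groups.
#'
#' @param frame n x 3 coordinate matrix.
#' @param group_a,group_b disjoint non-empty atom index vectors.
#' @param cutoff distance cutoff, angstrom. Default 4.5 (heavy-atom
#'   contact convention).
#' @return Integer pair count.
#' @export
count_contacts <- function(frame, group_a, group_b, cutoff = 4.5) {
  frame <- as.matrix(frame)
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  a <- frame[group_a, , drop = FALSE]
  b <- frame[group_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sum(d2 < cutoff^2)
}

#' Correlation between cavity volume and ligand position
#'
#' Pearson correlation between a cavity-volume series and the axial
#' collective variable CV1, optionally split by orientation (the sign of
#' the correlation is expected to flip between the two ligand poses).
#' Zero-variance inputs yield a flagged zero instead of NA.
#'
#' @param volumes cavity volumes, A^3.
#' @param cv1 CV1 series, angstrom (same length, >= 3).
#' @param orientation optional factor splitting the series (e.g. "A" /
#'   "B"); correlations are then reported per level.
#' @return Data frame with `orientation`, `r`, `sign`, `n`, `flagged`.
#' @export
volume_cv_correlation <- function(volumes, cv1, orientation = NULL) {
  if (length(volumes) != length(cv1)) stop("length mismatch")
  if (length(volumes) < 3L) stop("need at least 3 points")
  if (is.null(orientation)) orientation <- rep("all", length(cv1))
  one <- function(v, s) {
    if (sd(v) < 1e-12 || sd(s) < 1e-12)
      return(c(r = 0, flagged = 1))
    c(r = cor(v, s), flagged = 0)
  }
  levs <- unique(orientation)
  rows <- lapply(levs, function(l) {
    sel <- orientation == l
    res <- one(volumes[sel], cv1[sel])
    data.frame(orientation = l, r = res["r"],
               sign = sign(res["r"]), n = sum(sel),
               flagged = res["flagged"] > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
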