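#' Construct a pocket-frequency grid
#'
#' A `frequency_grid` holds a voxelized pocket-frequency map as produced by
#' pocket-detection tools run along a trajectory: for every voxel, the
#' fraction of frames in which that point of space was part of a detected
#' pocket.
#'
#' @param origin numeric 3-vector, world coordinate of voxel (0,0,0) in
#'   angstrom.
#' @param spacing numeric 3-vector, voxel edge lengths in angstrom (the
#'   diagonal of the DX delta records; only axis-aligned grids are
#'   supported).
#' @param values numeric 3D array of per-voxel frequencies, dimensions
#'   `c(nx, ny, nz)`. Values are expected in `[0, 1]`; small numeric
#'   overshoot triggers a warning, not an error.
#' @return An object of class `frequency_grid` with fields `origin`,
#'   `spacing`, `counts`, `values`.
#' @seealso [read_dx_grid()], [threshold_points()], [make_pocket_grid()]
#' @export
frequency_grid <- function(origin, spacing, values) {
  origin <- .check_vec3(origin, "origin")
  spacing <- .check_vec3(spacing, "spacing")
  if (any(spacing <= 0)) stop("spacing must be positive on every axis")
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (any(dim(values) < 1L)) stop("grid must have at least one voxel per axis")
  if (any(!is.finite(values))) stop("grid values must be finite")
  rng <- range(values)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    stop("grid values must lie in [0, 1]")
  if (rng[1] < 0 || rng[2] > 1)
    warning("grid values slightly outside [0, 1]; keeping as-is")
  structure(
    list(origin = origin, spacing = spacing,
         counts = as.integer(dim(values)), values = values),
    class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("frequency_grid: %d x %d x %d voxels\n",
              x$counts[1], x$counts[2], x$counts[3]))
  cat(sprintf("  origin  [%g, %g, %g] A\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  spacing [%g, %g, %g] A\n", x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Read an OpenDX scalar grid
#'
#' Parses the text OpenDX dialect written by the common pocket-mapping
#' tools: a `gridpositions counts` record, an `origin` record, three
#' axis-aligned `delta` records, and an `object 3 class array` data block
#' with values ordered with the last (z) index varying fastest. Comment
#' lines starting with `#` are ignored.
#'
#' @param path path to a DX file.
#' @return A [frequency_grid()].
#' @export
read_dx_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]

  cnt_i <- grep("class\\s+gridpositions\\s+counts", lines)
  if (length(cnt_i) != 1L) stop("malformed DX header: gridpositions record missing")
  counts <- suppressWarnings(as.integer(
    tail(strsplit(trimws(lines[cnt_i]), "\\s+")[[1]], 3L)))
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 1L))
    stop("malformed DX header: bad gridpositions counts")

  num_tail <- function(line, n, what) {
    v <- suppressWarnings(as.numeric(tail(strsplit(trimws(line), "\\s+")[[1]], n)))
    if (length(v) != n || any(is.na(v)))
      stop("malformed DX header: bad ", what, " record")
    v
  }
  org_i <- grep("^\\s*origin\\b", lines)
  if (length(org_i) != 1L) stop("malformed DX header: origin record missing")
  origin <- num_tail(lines[org_i], 3L, "origin")

  del_i <- grep("^\\s*delta\\b", lines)
  if (length(del_i) != 3L) stop("malformed DX header: expected 3 delta records")
  deltas <- t(vapply(lines[del_i], num_tail, numeric(3), n = 3L, what = "delta"))
  if (max(abs(deltas[upper.tri(deltas) | lower.tri(deltas)])) > 1e-10)
    stop("only axis-aligned (diagonal delta) DX grids are supported")
  spacing <- diag(deltas)

  arr_i <- grep("object\\s+3\\s+class\\s+array", lines)
  if (length(arr_i) != 1L) stop("malformed DX header: data array record missing")
  n_items <- prod(counts)
  m <- regmatches(lines[arr_i], regexec("items\\s+(\\d+)", lines[arr_i]))[[1]]
  if (length(m) == 2L && as.numeric(m[2]) != n_items)
    stop(sprintf("value count mismatch: header declares %s items for a %d x %d x %d grid",
                 m[2], counts[1], counts[2], counts[3]))

  body <- lines[(arr_i + 1L):length(lines)]
  body <- body[!grepl("^\\s*(object|attribute|component)\\b", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != n_items)
    stop(sprintf("value count mismatch: found %d values, expected %d",
                 length(vals), n_items))
  # DX stores z fastest; R arrays store the first index fastest
  arr <- aperm(array(vals, dim = rev(counts)), c(3L, 2L, 1L))
  frequency_grid(origin, spacing, arr)
}

#' Write an OpenDX scalar grid
#'
#' Inverse of [read_dx_grid()]: values round-trip exactly (full double
#' precision, z index varying fastest).
#'
#' @param grid a [frequency_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dx_grid <- function(grid, path) {
  stopifnot(inherits(grid, "frequency_grid"))
  n <- grid$counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by tunnelscape",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.10g %.10g %.10g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.10g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.10g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.10g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  vals <- as.vector(aperm(grid$values, c(3L, 2L, 1L)))  # z fastest
  starts <- seq(1L, length(vals), by = 3L)
  rows <- vapply(starts, function(i) {
    paste(sprintf("%.17g", vals[i:min(i + 2L, length(vals))]), collapse = " ")
  }, character(1))
  writeLines(rows, con)
  writeLines('object "pocket frequency" class field', con)
  invisible(path)
}
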