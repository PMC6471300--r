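#' Construct a trajectory
#'
#' A `trajectory` stores an ordered set of frames with identical atom
#' count and ordering, following the frames-by-rows layout of bio3d: the
#' coordinate matrix has one row per frame and `3 * n_atoms` columns
#' (`x1, y1, z1, x2, ...`), all in angstrom.
#'
#' @param xyz numeric matrix, `n_frames` x `3 * n_atoms`.
#' @param atoms data frame of per-atom metadata with at least columns
#'   `elety` (atom name), `resid` (residue name), `resno` (residue
#'   number); an `elesy` element-symbol column is added from `elety` when
#'   missing.
#' @param time optional numeric vector of frame times (ps).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(xyz, atoms, time = NULL) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) %% 3L != 0L) stop("xyz must have 3 columns per atom")
  n_atoms <- ncol(xyz) %/% 3L
  atoms <- as.data.frame(atoms)
  need <- c("elety", "resid", "resno")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (nrow(atoms) != n_atoms)
    stop(sprintf("atom table has %d rows but xyz implies %d atoms",
                 nrow(atoms), n_atoms))
  if (!is.null(time) && length(time) != nrow(xyz))
    stop("time must have one entry per frame")
  if (is.null(atoms$elesy))
    atoms$elesy <- toupper(substr(gsub("[0-9']", "", atoms$elety), 1L, 1L))
  structure(list(xyz = xyz, atoms = atoms, time = time), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms\n", n_frames(x), n_atoms(x)))
  cat(sprintf("  residues: %s\n",
              paste(unique(x$atoms$resid), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Number of atoms in a trajectory
#' @param traj a [trajectory()].
#' @return Integer atom count.
#' @export
n_atoms <- function(traj) ncol(traj$xyz) %/% 3L

#' Extract one frame as an n x 3 coordinate matrix
#'
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return Numeric matrix, `n_atoms` x 3, columns x/y/z (angstrom).
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  m <- matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Select atom indices by residue name, residue number, or atom name
#'
#' @param traj a [trajectory()].
#' @param resid optional residue name(s) to keep.
#' @param resno optional residue number(s) to keep.
#' @param elety optional atom name(s) to keep.
#' @return Integer vector of atom indices (1-based).
#' @export
select_atoms <- function(traj, resid = NULL, resno = NULL, elety = NULL) {
  keep <- rep(TRUE, n_atoms(traj))
  if (!is.null(resid)) keep <- keep & traj$atoms$resid %in% resid
  if (!is.null(resno)) keep <- keep & traj$atoms$resno %in% resno
  if (!is.null(elety)) keep <- keep & traj$atoms$elety %in% elety
  which(keep)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Uses bio3d's PDB reader with `multi = TRUE`; each MODEL becomes one
#' frame.
#'
#' @param path path to a PDB file.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  trajectory(xyz,
             data.frame(elety = pdb$atom$elety, resid = pdb$atom$resid,
                        resno = pdb$atom$resno,
                        elesy = pdb$atom$elesy,
                        stringsAsFactors = FALSE))
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    crd <- get_frame(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$elety) < 4L, paste0(" ", a$elety), a$elety),
      a$resid, a$resno, crd[, 1], crd[, 2], crd[, 3], a$elesy), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an XYZ-format trajectory
#'
#' Plain multi-frame XYZ: each frame is an atom count line, a comment
#' line, then `element x y z` records. Atom metadata is minimal (element
#' symbols as atom names, a single pseudo-residue).
#'
#' @param path path to an XYZ file.
#' @return A [trajectory()].
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  elems <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) stop("malformed XYZ: bad atom count at line ", i)
    if (i + 1L + nat > length(lines)) stop("malformed XYZ: truncated frame")
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    if (any(lengths(rec) < 4L)) stop("malformed XYZ: short atom record")
    el <- vapply(rec, `[`, character(1), 1L)
    crd <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(is.na(crd))) stop("malformed XYZ: non-numeric coordinate")
    if (is.null(elems)) elems <- el
    frames[[length(frames) + 1L]] <- as.vector(t(crd))
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("malformed XYZ: no frames")
  trajectory(do.call(rbind, frames),
             data.frame(elety = elems, resid = "MOL", resno = 1L,
                        elesy = elems, stringsAsFactors = FALSE))
}

#' Write a trajectory in XYZ format
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    crd <- get_frame(traj, f)
    writeLines(c(sprintf("%d", n_atoms(traj)), sprintf("frame %d", f)), con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f",
                       traj$atoms$elesy, crd[, 1], crd[, 2], crd[, 3]), con)
  }
  invisible(path)
}
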