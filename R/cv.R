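#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two paired point sets. Reflections are never returned: when the
#' optimal orthogonal map is improper, the best proper rotation is used
#' instead (determinant +1, with a nonzero residual).
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param reference n x 3 coordinate matrix to superpose onto.
#' @return A list of class `rigid_transform` with `rotation` (3 x 3,
#'   det +1), `translation` (length 3), and `rmsd` (angstrom, after the
#'   fit). The transform maps a row vector `x` to `x %*% rotation +
#'   translation`.
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for a rigid fit")
  mu_m <- colMeans(mobile); mu_r <- colMeans(reference)
  A <- sweep(mobile, 2L, mu_m); B <- sweep(reference, 2L, mu_r)
  H <- crossprod(A, B)                       # 3 x 3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30))
    stop("rank-deficient point sets: rigid fit is ill-determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)  # row-vector convention: x %*% R
  tr <- mu_r - as.vector(mu_m %*% R)
  fitted <- sweep(A %*% R, 2L, mu_r, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform a `rigid_transform` from [kabsch_fit()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(coords) %*% transform$rotation, 2L, transform$translation, "+")
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2). Unless `align = FALSE`,
#' every frame is first superposed onto the first frame on the requested
#' atoms (single alignment pass), so that global diffusion and tumbling
#' do not inflate the fluctuations.
#'
#' @param traj a [trajectory()].
#' @param atom_indices atoms over which to align and report; default all.
#' @param align superpose frames onto frame 1 before computing RMSF.
#' @return Named numeric vector of per-atom RMSF (angstrom), one entry
#'   per requested atom.
#' @export
compute_rmsf <- function(traj, atom_indices = seq_len(n_atoms(traj)),
                         align = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  ref <- get_frame(traj, 1L)[atom_indices, , drop = FALSE]
  na <- length(atom_indices)
  coords <- array(0, dim = c(na, 3L, nf))
  for (f in seq_len(nf)) {
    crd <- get_frame(traj, f)[atom_indices, , drop = FALSE]
    if (align && f > 1L) crd <- apply_transform(crd, kabsch_fit(crd, ref))
    coords[, , f] <- crd
  }
  mean_crd <- apply(coords, c(1L, 2L), mean)
  dev2 <- sweep(coords, c(1L, 2L), mean_crd)^2
  out <- sqrt(apply(dev2, 1L, sum) / nf)
  names(out) <- atom_indices
  out
}

#' Select rigid reference atoms by RMSF threshold
#'
#' Returns the atoms whose fluctuation is strictly below the threshold;
#' on helical proteins this criterion selects the helices and discards
#' mobile loops and termini, yielding a stable fitting frame.
#'
#' @param rmsf named per-atom RMSF from [compute_rmsf()].
#' @param threshold angstrom; default 1.0.
#' @return Integer vector of the selected atom indices.
#' @export
select_reference_atoms <- function(rmsf, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be positive")
  sel <- which(rmsf < threshold)
  if (!length(sel))
    stop("no atoms below the RMSF threshold: the fitting frame is undefined")
  idx <- if (!is.null(names(rmsf))) as.integer(names(rmsf)[sel]) else sel
  idx
}

#' Build the collective-variable reference state
#'
#' Packages everything needed to evaluate the two collective variables:
#' the reference coordinates, the low-RMSF fit atoms defining the
#' roto-translational frame, the ligand-tail atoms whose centroid is
#' tracked, the diffusion axis, and the origin (the tail centroid in the
#' reference structure, so the reference frame evaluates to CV = (0, 0)).
#'
#' @param traj a [trajectory()].
#' @param fit_atoms indices of the frame-fitting atoms (e.g. from
#'   [select_reference_atoms()] over the alpha-carbons).
#' @param ligand_atoms indices of the ligand aliphatic-chain carbons;
#'   bulky head groups should be excluded, their internal torsions would
#'   contaminate the centroid.
#' @param axis unit 3-vector (or an `axis_set`, whose leading axis is
#'   taken): the diffusion axis.
#' @param ref_frame frame index used as reference; default 1.
#' @param rmsf_threshold the threshold used for `fit_atoms` (recorded for
#'   provenance; not re-applied).
#' @return An object of class `reference_state`.
#' @export
reference_state <- function(traj, fit_atoms, ligand_atoms, axis,
                            ref_frame = 1L, rmsf_threshold = NA_real_) {
  stopifnot(inherits(traj, "trajectory"))
  if (inherits(axis, "axis_set")) axis <- axis$axes[, 1L]
  axis <- .unit(.check_vec3(axis, "axis"))
  fit_atoms <- as.integer(fit_atoms); ligand_atoms <- as.integer(ligand_atoms)
  if (!length(fit_atoms)) stop("fit_atoms must be non-empty")
  if (!length(ligand_atoms)) stop("ligand_atoms must be non-empty")
  if (length(intersect(fit_atoms, ligand_atoms)))
    stop("fit_atoms and ligand_atoms must be disjoint")
  ref_coords <- get_frame(traj, ref_frame)
  origin_com <- colMeans(ref_coords[ligand_atoms, , drop = FALSE])
  structure(list(coords = ref_coords, fit_atoms = fit_atoms,
                 ligand_atoms = ligand_atoms, axis = axis,
                 origin_com = origin_com, rmsf_threshold = rmsf_threshold),
            class = "reference_state")
}

#' @export
print.reference_state <- function(x, ...) {
  cat(sprintf("reference_state: %d fit atoms, %d ligand atoms\n",
              length(x$fit_atoms), length(x$ligand_atoms)))
  cat(sprintf("  axis [%+.4f, %+.4f, %+.4f], RMSF threshold %s A\n",
              x$axis[1], x$axis[2], x$axis[3], format(x$rmsf_threshold)))
  invisible(x)
}

#' Collective variables of one frame
#'
#' The frame is first mapped into the reference roto-translational frame
#' by a rigid fit of its fit atoms onto the reference fit atoms; the
#' displacement `d` of the ligand-tail centroid from its reference
#' position is then split into CV1 = d . axis (signed axial component,
#' angstrom) and CV2 = |d - (d . axis) axis| (non-negative radial
#' component). Both are invariant to any global rigid motion of the
#' frame.
#'
#' @param frame n x 3 coordinate matrix matching the reference atom
#'   ordering.
#' @param ref a [reference_state()].
#' @return Named numeric vector `c(cv1, cv2)` in angstrom.
#' @export
compute_cvs <- function(frame, ref) {
  stopifnot(inherits(ref, "reference_state"))
  frame <- as.matrix(frame)
  if (!all(dim(frame) == dim(ref$coords)))
    stop("frame dimensions do not match the reference")
  fit <- kabsch_fit(frame[ref$fit_atoms, , drop = FALSE],
                    ref$coords[ref$fit_atoms, , drop = FALSE])
  lig <- apply_transform(frame[ref$ligand_atoms, , drop = FALSE], fit)
  d <- colMeans(lig) - ref$origin_com
  cv1 <- sum(d * ref$axis)
  cv2 <- sqrt(max(sum((d - cv1 * ref$axis)^2), 0))
  c(cv1 = cv1, cv2 = cv2)
}

#' Collective-variable time series over a trajectory
#'
#' @param traj a [trajectory()].
#' @param ref a [reference_state()].
#' @return Data frame with columns `frame`, `time` (ps, when present),
#'   `cv1`, `cv2`.
#' @export
cv_timeseries <- function(traj, ref) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 1L) stop("empty trajectory")
  cvs <- t(vapply(seq_len(nf),
                  function(f) compute_cvs(get_frame(traj, f), ref),
                  numeric(2)))
  data.frame(frame = seq_len(nf),
             time = if (is.null(traj$time)) NA_real_ else traj$time,
             cv1 = cvs[, 1], cv2 = cvs[, 2])
}

#' Write a CV time series as TSV
#'
#' @param cvs data frame from [cv_timeseries()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_tsv <- function(cvs, path) {
  write.table(cvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
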