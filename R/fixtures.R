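# Synthetic-data generators: every stage of the protocol is testable
# against objects with known ground truth (analytic free-energy
# profiles, scripted collective-variable courses, grids with a declared
# principal axis).

# evaluate expr with a temporarily seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.polyval <- function(coefs, x) {
  v <- 0
  for (k in rev(seq_along(coefs))) v <- v * x + coefs[k]
  v
}

.polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

.polyderiv <- function(a) {
  if (length(a) < 2L) return(0)
  a[-1L] * seq_len(length(a) - 1L)
}

#' Construct a toy collective-variable potential
#'
#' Analytic model potentials used as desk-scale surrogates for the
#' all-atom system: energy in kcal/mol over a 1D or 3D CV space, with an
#' exact gradient and (when defined) an analytic free-energy profile
#' along the first coordinate.
#'
#' @param dims 1 or 3.
#' @param axial_coefs polynomial coefficients (constant first) of the
#'   axial energy w(x).
#' @param radial_k harmonic force constant of the radial term,
#'   kcal/(mol A^2) (3D only).
#' @param minima locations of the axial minima, angstrom (optional).
#' @param params free-form parameter record.
#' @return An object of class `toy_potential` with callable `energy(x)`
#'   and `gradient(x)` and `profile(s)` (the axial free-energy profile).
#' @export
toy_potential <- function(dims, axial_coefs, radial_k = 0, minima = NULL,
                          params = list()) {
  stopifnot(dims %in% c(1L, 3L))
  axial_coefs <- as.numeric(axial_coefs)
  dcoefs <- .polyderiv(axial_coefs)
  energy <- function(x) {
    e <- .polyval(axial_coefs, x[1])
    if (dims == 3L) e <- e + radial_k / 2 * (x[2]^2 + x[3]^2)
    e
  }
  gradient <- function(x) {
    g <- .polyval(dcoefs, x[1])
    if (dims == 3L) c(g, radial_k * x[2], radial_k * x[3]) else g
  }
  profile <- function(s) .polyval(axial_coefs, s)
  structure(list(dims = as.integer(dims), axial_coefs = axial_coefs,
                 radial_k = radial_k, energy = energy, gradient = gradient,
                 profile = profile, minima = minima, params = params),
            class = "toy_potential")
}

#' Symmetric-minima double-well potential
#'
#' Quartic `U(s) = b (s - s1)^2 (s - s2)^2` scaled so that the energy at
#' the midpoint exceeds the minima by exactly `barrier`; the analytic
#' profile is the oracle for free-energy reconstruction tests.
#'
#' @param barrier barrier height, kcal/mol (> 0).
#' @param minima locations `c(s1, s2)` of the two minima, angstrom,
#'   `s1 < s2`. Default `c(-2, 2)`.
#' @return A 1D [toy_potential()].
#' @export
make_double_well <- function(barrier, minima = c(-2, 2)) {
  if (barrier <= 0) stop("barrier must be positive")
  if (length(minima) != 2L || minima[1] >= minima[2])
    stop("minima must be c(s1, s2) with s1 < s2")
  a <- (minima[2] - minima[1]) / 2
  b <- barrier / a^4
  lin1 <- c(-minima[1], 1)
  lin2 <- c(-minima[2], 1)
  coefs <- b * .polymul(.polymul(lin1, lin1), .polymul(lin2, lin2))
  toy_potential(1L, coefs, minima = minima,
                params = list(barrier = barrier))
}

#' Tunnel potential: axial profile plus harmonic radial confinement
#'
#' `U(x, y, z) = w(x) + (radial_k / 2)(y^2 + z^2)`: the marginal free
#' energy along x equals w(x) up to an additive constant, emulating a
#' ligand free to move along a tunnel axis but confined radially.
#'
#' @param axial_profile a 1D [toy_potential()].
#' @param radial_k radial force constant, kcal/(mol A^2) (> 0).
#' @return A 3D [toy_potential()].
#' @export
make_tunnel_potential <- function(axial_profile, radial_k) {
  stopifnot(inherits(axial_profile, "toy_potential"), axial_profile$dims == 1L)
  if (radial_k <= 0) stop("radial_k must be positive")
  toy_potential(3L, axial_profile$axial_coefs, radial_k = radial_k,
                minima = axial_profile$minima,
                params = c(axial_profile$params, list(radial_k = radial_k)))
}

#' Synthetic scaffold-plus-ligand trajectory with known CV ground truth
#'
#' Builds a rigid pseudo-alpha-carbon scaffold (four helical arcs around
#' a tunnel plus mobile terminal loops), and a three-part ligand (head,
#' bridge, tail) whose tail is marched along the tunnel axis following a
#' scripted course. Optionally every frame after the first is hit with a
#' random global roto-translation (to exercise the fitting frame; the
#' first frame stays in the canonical pose since it defines the
#' reference and the axis coordinates) and per-atom Gaussian jitter. The
#' emitted ground truth is the pre-roto-translation CV course: CV1
#' equals the script, CV2 is 0.
#'
#' @param n_frames number of frames.
#' @param ligand_course numeric vector (recycled to `n_frames`) of the
#'   scripted CV1 displacement, angstrom.
#' @param jitter per-atom Gaussian jitter sd, angstrom. Default 0.
#' @param seed RNG seed.
#' @param global_motion apply a random rigid motion per frame. Default
#'   TRUE.
#' @param axis tunnel axis (unit 3-vector). Default x.
#' @param loop_amplitude oscillation amplitude of the mobile loop atoms,
#'   angstrom; chosen so their RMSF exceeds the default 1.0 A selection
#'   threshold while the helical atoms stay below it. Default 2.5.
#' @return List with `trajectory`, `cv1_truth`, `cv2_truth`, `parts` (a
#'   [ligand_parts()]), `helix_atoms`, `loop_atoms`, `axis`.
#' @export
make_toy_complex_trajectory <- function(n_frames, ligand_course = 0,
                                        jitter = 0, seed = 1,
                                        global_motion = TRUE,
                                        axis = c(1, 0, 0),
                                        loop_amplitude = 2.5) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (jitter < 0) stop("jitter must be non-negative")
  axis <- .unit(.check_vec3(axis, "axis"))
  course <- rep_len(as.numeric(ligand_course), n_frames)
  basis <- .complete_basis(axis)

  # scaffold: 4 helical arcs of 10 pseudo-CA each around the tunnel
  helix <- do.call(rbind, lapply(0:3, function(h) {
    j <- 0:9
    t(basis %*% rbind(-6.75 + 1.5 * j,
                      6 * cos(h * pi / 2 + 0.25 * j),
                      6 * sin(h * pi / 2 + 0.25 * j)))
  }))
  # terminal loops: 8 atoms past the helix ends, mobile
  loops <- do.call(rbind, lapply(0:7, function(i) {
    end <- if (i < 4L) -8.5 else 8.5
    as.vector(basis %*% c(end + 0.8 * (i %% 4), 7.5 * cos(i), 7.5 * sin(i)))
  }))
  # ligand along the axis: head (4), bridge (2), tail (8 carbons)
  lig_local <- rbind(
    t(basis %*% rbind(6.5 + 0.9 * (0:3), 0.9 * cos(1:4), 0.9 * sin(1:4))),
    t(basis %*% rbind(c(5.0, 5.8), 0, 0)),
    t(basis %*% rbind(seq(-4.55, 4.55, length.out = 8), 0, 0)))

  n_hel <- nrow(helix); n_loop <- nrow(loops); n_lig <- nrow(lig_local)
  base <- rbind(helix, loops, lig_local)
  n_at <- nrow(base)
  helix_atoms <- seq_len(n_hel)
  loop_atoms <- n_hel + seq_len(n_loop)
  head_idx <- n_hel + n_loop + 1:4
  bridge_idx <- n_hel + n_loop + 5:6
  tail_idx <- n_hel + n_loop + 7:14

  atoms <- data.frame(
    elety = c(rep("CA", n_hel + n_loop),
              paste0("CH", 1:4), paste0("CB", 1:2), paste0("CT", 1:8)),
    resid = c(rep("ALA", n_hel), rep("GLY", n_loop), rep("LIG", n_lig)),
    resno = c(seq_len(n_hel), n_hel + seq_len(n_loop), rep(999L, n_lig)),
    elesy = "C", stringsAsFactors = FALSE)

  .with_seed(seed, {
    loop_dir <- matrix(rnorm(n_loop * 3), n_loop, 3L)
    loop_dir <- loop_dir / sqrt(rowSums(loop_dir^2))
    loop_phase <- runif(n_loop, 0, 2 * pi)
    xyz <- matrix(0, n_frames, 3L * n_at)
    for (f in seq_len(n_frames)) {
      crd <- base
      crd[c(head_idx, bridge_idx, tail_idx), ] <-
        sweep(crd[c(head_idx, bridge_idx, tail_idx), , drop = FALSE],
              2L, course[f] * axis, "+")
      # loops oscillate with super-threshold amplitude
      ph <- sin(2 * pi * (f - 1) / max(n_frames - 1, 1) * 3 + loop_phase)
      crd[loop_atoms, ] <- crd[loop_atoms, ] + loop_amplitude * ph * loop_dir
      if (jitter > 0) crd <- crd + matrix(rnorm(n_at * 3, sd = jitter), n_at, 3L)
      # frame 1 stays in the canonical pose: it is the reference frame, and
      # the declared axis is expressed in its coordinates
      if (global_motion && f > 1L) {
        R <- .random_rotation()
        crd <- sweep(crd %*% R, 2L, runif(3, -10, 10), "+")
      }
      xyz[f, ] <- as.vector(t(crd))
    }
  })

  list(trajectory = trajectory(xyz, atoms),
       cv1_truth = course, cv2_truth = rep(0, n_frames),
       parts = ligand_parts(head = head_idx, tail = tail_idx,
                            bridge = bridge_idx),
       helix_atoms = helix_atoms, loop_atoms = loop_atoms, axis = axis)
}

# orthonormal basis (columns) with v as first column
.complete_basis <- function(v) {
  v <- .unit(v)
  aux <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- .unit(aux - sum(aux * v) * v)
  u3 <- c(v[2] * u2[3] - v[3] * u2[2],
          v[3] * u2[1] - v[1] * u2[3],
          v[1] * u2[2] - v[2] * u2[1])
  cbind(v, u2, u3, deparse.level = 0)
}

# uniform-ish random proper rotation from the current RNG stream
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Synthetic pocket-frequency grid with a known principal axis
#'
#' Voxel frequencies are high inside an ellipsoid elongated along `axis`
#' and seeded uniform background noise (strictly below the conventional
#' 0.2 cutoff) elsewhere, so thresholding recovers exactly the ellipsoid
#' interior and its covariance axes are known by construction.
#'
#' @param axis unit 3-vector: the ellipsoid's long axis.
#' @param half_lengths `c(a, b, c)` ellipsoid semi-axes, angstrom, with
#'   `a > b >= c > 0`. Default `c(8, 3, 2)`.
#' @param noise_level background frequency ceiling (< the threshold
#'   cutoff to be invisible). Default 0.05.
#' @param seed RNG seed.
#' @param spacing voxel edge, angstrom. Default 1.
#' @param inside_value frequency assigned inside the ellipsoid. Default
#'   0.9.
#' @return A [frequency_grid()].
#' @export
make_pocket_grid <- function(axis = c(1, 0, 0), half_lengths = c(8, 3, 2),
                             noise_level = 0.05, seed = 1, spacing = 1,
                             inside_value = 0.9) {
  axis <- .unit(.check_vec3(axis, "axis"))
  hl <- half_lengths
  if (length(hl) != 3L || !(hl[1] > hl[2] && hl[2] >= hl[3] && hl[3] > 0))
    stop("half_lengths must satisfy a > b >= c > 0")
  if (noise_level < 0 || noise_level >= 1) stop("noise_level must be in [0, 1)")
  basis <- .complete_basis(axis)
  ext <- ceiling(hl[1] + 2)
  coords1d <- seq(-ext, ext, by = spacing)
  n <- length(coords1d)
  origin <- rep(-ext, 3L)
  .with_seed(seed, {
    vals <- array(runif(n^3, 0, noise_level), dim = c(n, n, n))
    g <- as.matrix(expand.grid(x = coords1d, y = coords1d, z = coords1d))
    local <- g %*% basis          # coordinates in the ellipsoid frame
    inside <- (local[, 1] / hl[1])^2 + (local[, 2] / hl[2])^2 +
      (local[, 3] / hl[3])^2 <= 1
    vals[inside] <- inside_value
  })
  frequency_grid(origin, rep(spacing, 3L), vals)
}
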