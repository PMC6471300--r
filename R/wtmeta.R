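#' Well-tempered metadynamics parameters
#'
#' The bias schedule of well-tempered metadynamics: Gaussian hills of
#' initial height `H` and width `delta` are deposited every `tauG` of
#' simulated time, with heights tempered by the accumulated bias,
#' `h = H exp(-V_bias / kB deltaT)`.
#'
#' @param H initial hill height, kcal/mol. Default 0.1.
#' @param delta hill width (Gaussian sigma), angstrom. Default 0.05.
#' @param deltaT bias temperature, K: controls how fast hill heights
#'   decay and how far above the minima the landscape is explored.
#'   Default 4500.
#' @param tauG deposition period, fs. Default 1000.
#' @param temperature system temperature, K. Default 298.
#' @return A list of class `wt_params`.
#' @export
wt_params <- function(H = 0.1, delta = 0.05, deltaT = 4500, tauG = 1000,
                      temperature = 298) {
  if (H < 0) stop("H must be non-negative (0 disables the bias)")
  if (delta <= 0 || deltaT <= 0 || tauG <= 0 || temperature <= 0)
    stop("delta, deltaT, tauG and temperature must be positive")
  structure(list(H = H, delta = delta, deltaT = deltaT, tauG = tauG,
                 temperature = temperature), class = "wt_params")
}

#' Bias factor of a well-tempered run
#'
#' gamma = (T + deltaT) / T; the converged bias compensates the free
#' energy up to the factor (T + deltaT) / deltaT used in
#' [reconstruct_fes()].
#'
#' @param params a [wt_params()].
#' @return The dimensionless bias factor.
#' @export
bias_factor <- function(params) {
  (params$temperature + params$deltaT) / params$temperature
}

#' Harmonic wall parameters
#'
#' A half-harmonic restraint: zero inside `[s_lo, s_hi]`, quadratic
#' `(K/2)(s - bound)^2` outside. Used to confine the ligand collective
#' variables to the cavity region.
#'
#' @param K force constant, kcal/(mol A^2).
#' @param s_lo lower bound, angstrom (`-Inf` for no lower wall).
#' @param s_hi upper bound, angstrom (`Inf` for no upper wall).
#' @return A list of class `wall_params`.
#' @export
wall_params <- function(K = 40, s_lo = -Inf, s_hi = Inf) {
  if (K < 0) stop("wall force constant must be non-negative")
  if (!(s_lo < s_hi)) stop("s_lo must be below s_hi")
  structure(list(K = K, s_lo = s_lo, s_hi = s_hi), class = "wall_params")
}

#' Half-harmonic wall energy and gradient
#'
#' @param s CV value(s), angstrom.
#' @param wall a [wall_params()].
#' @return List with `energy` and `gradient`, each the length of `s`.
#' @export
wall_energy <- function(s, wall) {
  stopifnot(inherits(wall, "wall_params"))
  e <- g <- numeric(length(s))
  up <- s > wall$s_hi
  lo <- s < wall$s_lo
  e[up] <- 0.5 * wall$K * (s[up] - wall$s_hi)^2
  g[up] <- wall$K * (s[up] - wall$s_hi)
  e[lo] <- 0.5 * wall$K * (s[lo] - wall$s_lo)^2
  g[lo] <- wall$K * (s[lo] - wall$s_lo)
  list(energy = e, gradient = g)
}

#' Construct a hills log
#'
#' @param hills data frame with columns `time` (fs, strictly
#'   increasing), `center` (angstrom), `width` (angstrom), `height`
#'   (kcal/mol).
#' @param params the [wt_params()] of the run.
#' @param seed the RNG seed of the run, recorded for provenance.
#' @return A data frame of class `hills_log` with the parameters and
#'   seed as attributes.
#' @export
hills_log <- function(hills, params, seed = NA_integer_) {
  hills <- as.data.frame(hills)
  need <- c("time", "center", "width", "height")
  if (!all(need %in% names(hills)))
    stop("hills must have columns: ", paste(need, collapse = ", "))
  if (nrow(hills) > 1L && any(diff(hills$time) <= 0))
    stop("hill times must be strictly increasing")
  if (any(hills$width <= 0)) stop("hill widths must be positive")
  if (any(hills$height < 0)) stop("hill heights must be non-negative")
  structure(hills[need], params = params, seed = seed,
            class = c("hills_log", "data.frame"))
}

#' @export
print.hills_log <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("hills_log: %d hills over %.3g fs (seed %s)\n", nrow(x),
              if (nrow(x)) max(x$time) else 0, format(attr(x, "seed"))))
  if (!is.null(p))
    cat(sprintf("  H %g kcal/mol, delta %g A, deltaT %g K, tauG %g fs, T %g K\n",
                p$H, p$delta, p$deltaT, p$tauG, p$temperature))
  invisible(x)
}

#' Metadynamics bias energy by exact hill summation
#'
#' V(s) = sum_i h_i exp(-(s - c_i)^2 / (2 w_i^2)). This is the exact
#' reference evaluation used for free-energy reconstruction and for
#' validating the integrator's gridded bias.
#'
#' @param hills a [hills_log()] (an empty log gives 0 everywhere).
#' @param s CV value(s), angstrom.
#' @return Numeric vector of bias energies, kcal/mol.
#' @export
bias_energy <- function(hills, s) {
  if (!nrow(hills)) return(numeric(length(s)) + 0)
  out <- numeric(length(s))
  chunk <- 512L
  for (i0 in seq(1L, length(s), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(s))
    d <- outer(s[idx], hills$center, "-")
    out[idx] <- as.vector(exp(-(d * d) / (2 * rep(hills$width^2, each = length(idx)))) %*%
                            hills$height)
  }
  out
}

#' Tempered height of the next hill
#'
#' h = H exp(-V_bias / (kB deltaT)): hills shrink as the bias
#' accumulates, which is what makes the well-tempered scheme converge.
#'
#' @param params a [wt_params()].
#' @param V_bias_here accumulated bias at the deposition point, kcal/mol
#'   (non-negative).
#' @return Height in (0, H], kcal/mol.
#' @export
next_hill_height <- function(params, V_bias_here) {
  stopifnot(inherits(params, "wt_params"))
  if (any(V_bias_here < 0)) stop("bias energy must be non-negative")
  params$H * exp(-V_bias_here / (KB_KCAL * params$deltaT))
}

#' Run well-tempered metadynamics on a toy potential
#'
#' Integrates overdamped (Brownian) Langevin dynamics,
#' `s <- s - (D / kB T) grad(U + V_bias + V_walls) dt + sqrt(2 D dt) eta`,
#' on a [toy_potential()] (1D, or 3D with CV1 = x and CV2 = radial
#' distance), depositing a tempered Gaussian hill on CV1 every `tauG` of
#' simulated time. Identical seeds give bit-identical output.
#'
#' @param potential a [toy_potential()] with polynomial axial form (as
#'   built by [make_double_well()] / [make_tunnel_potential()]).
#' @param params a [wt_params()]; `H = 0` (or `NULL`) runs unbiased
#'   dynamics.
#' @param n_steps number of integration steps.
#' @param dt time step, fs. Default 0.1.
#' @param walls optional named list with elements `cv1` and/or `cv2`
#'   ([wall_params()]); the `cv2` wall acts on the radial coordinate and
#'   only its upper bound is meaningful (CV2 >= 0 by construction).
#' @param diffusion diffusion coefficient D, A^2/fs. Default 0.1.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param x0 initial CV-space position (length 1 or 3). Default: the
#'   potential's first minimum, or 0.
#' @param traj_stride record the CV trajectory every this many steps;
#'   default keeps at most ~1e6 samples.
#' @param sanity_bound abort with a diagnostic if any coordinate exceeds
#'   this magnitude (angstrom). Default 1000.
#' @param bias_range range of the internal bias grid (angstrom).
#' @return List with `time` (fs), `cv` (matrix of sampled CV1 and, in
#'   3D, CV2), and `hills` (a [hills_log()]).
#' @export
run_wt_metadynamics <- function(potential, params = wt_params(), n_steps,
                                dt = 0.1, walls = NULL, diffusion = 0.1,
                                seed, x0 = NULL, traj_stride = NULL,
                                sanity_bound = 1000,
                                bias_range = c(-30, 30)) {
  stopifnot(inherits(potential, "toy_potential"))
  if (is.null(params)) params <- wt_params(H = 0)
  stopifnot(inherits(params, "wt_params"))
  if (missing(seed) || is.na(seed)) stop("a seed is required")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (is.null(potential$axial_coefs))
    stop("the engine needs a polynomial axial form; see make_double_well()")
  if (is.null(x0))
    x0 <- if (!is.null(potential$minima)) potential$minima[1] else 0
  x0 <- rep(as.numeric(x0), length.out = if (potential$dims == 3L) 3L else 1L)
  if (is.null(traj_stride)) traj_stride <- max(1L, floor(n_steps / 1e6))

  w1 <- c(0, -Inf, Inf); w2 <- c(0, Inf)
  if (!is.null(walls$cv1)) {
    stopifnot(inherits(walls$cv1, "wall_params"))
    w1 <- c(walls$cv1$K, walls$cv1$s_lo, walls$cv1$s_hi)
  }
  if (!is.null(walls$cv2)) {
    stopifnot(inherits(walls$cv2, "wall_params"))
    w2 <- c(walls$cv2$K, walls$cv2$s_hi)
  }
  w1[!is.finite(w1)] <- sign(w1[!is.finite(w1)]) * 1e30
  w2[!is.finite(w2)] <- sign(w2[!is.finite(w2)]) * 1e30

  res <- wtmeta_run_cpp(
    axial_coefs = potential$axial_coefs,
    radial_k = if (is.null(potential$radial_k)) 0 else potential$radial_k,
    dims = potential$dims,
    H = params$H, delta = params$delta, deltaT = params$deltaT,
    tauG = params$tauG, temperature = params$temperature,
    wall1 = w1, wall2 = w2,
    n_steps_d = as.numeric(n_steps), dt = dt, D = diffusion,
    seed = as.numeric(seed), x0 = x0, stride = as.integer(traj_stride),
    sanity_bound = sanity_bound,
    grid_lo = bias_range[1], grid_hi = bias_range[2],
    grid_spacing = params$delta / 8)

  cv <- res$cv
  colnames(cv) <- if (ncol(cv) == 2L) c("cv1", "cv2") else "cv1"
  hills <- hills_log(
    data.frame(time = res$hill_time, center = res$hill_center,
               width = rep(params$delta, length(res$hill_time)),
               height = res$hill_height),
    params = params, seed = as.integer(seed))
  list(time = res$time, cv = cv, hills = hills)
}

#' Reconstruct the free-energy profile from a hills log
#'
#' In the long-time limit of well-tempered metadynamics the accumulated
#' bias compensates a fixed fraction of the free energy, so
#' `F(s) = -((T + deltaT) / deltaT) V_bias(s)`, shifted so the minimum
#' over the grid is zero.
#'
#' @param hills a [hills_log()] carrying its [wt_params()].
#' @param grid strictly increasing CV1 values, angstrom.
#' @return A data frame of class `fes_curve` with columns `cv1`,
#'   `free_energy` (kcal/mol, min 0).
#' @export
reconstruct_fes <- function(hills, grid) {
  if (!length(grid)) stop("empty grid")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  params <- attr(hills, "params")
  if (is.null(params)) stop("hills log carries no wt_params")
  scale <- (params$temperature + params$deltaT) / params$deltaT
  f <- -scale * bias_energy(hills, grid)
  f <- f - min(f)
  structure(data.frame(cv1 = grid, free_energy = f),
            params = params, class = c("fes_curve", "data.frame"))
}

#' Energy deposition per time window
#'
#' Sums deposited hill heights over consecutive windows of simulated
#' time. A converged well-tempered run deposits almost nothing late:
#' the profile decays toward zero.
#'
#' @param hills a [hills_log()].
#' @param window window length, fs.
#' @return Data frame with `t_start`, `t_end` (fs) and `energy`
#'   (kcal/mol deposited in the window); empty for an empty log.
#' @export
deposition_profile <- function(hills, window) {
  if (window <= 0) stop("window must be positive")
  if (!nrow(hills))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      energy = numeric(0)))
  # windows are (start, end]: a hill at exactly k*window belongs to
  # window k (robust at any time magnitude, unlike an absolute epsilon)
  bin <- ceiling(hills$time / window) - 1
  bin[bin < 0] <- 0
  agg <- tapply(hills$height, bin, sum)
  idx <- as.numeric(names(agg))
  ord <- order(idx)
  data.frame(t_start = idx[ord] * window, t_end = (idx[ord] + 1) * window,
             energy = as.numeric(agg)[ord])
}

#' Write a hills log as TSV
#'
#' Columns `time_fs`, `center_A`, `width_A`, `height_kcal`, full double
#' precision; run parameters and seed are recorded in `#`-comment header
#' lines so the log round-trips exactly.
#'
#' @param hills a [hills_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  p <- attr(hills, "params")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(p))
    writeLines(sprintf("# wt_params H=%.17g delta=%.17g deltaT=%.17g tauG=%.17g temperature=%.17g",
                       p$H, p$delta, p$deltaT, p$tauG, p$temperature), con)
  writeLines(sprintf("# seed %s", format(attr(hills, "seed"))), con)
  writeLines("time_fs\tcenter_A\twidth_A\theight_kcal", con)
  if (nrow(hills))
    writeLines(sprintf("%.17g\t%.17g\t%.17g\t%.17g", hills$time,
                       hills$center, hills$width, hills$height), con)
  invisible(path)
}

#' Read a hills log from TSV
#'
#' @param path a file written by [write_hills()] (or any TSV with the
#'   same columns). Non-monotone times are rejected.
#' @return A [hills_log()].
#' @export
read_hills <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  params <- NULL
  pm <- grep("wt_params", hdr, value = TRUE)
  if (length(pm)) {
    kv <- regmatches(pm[1], gregexpr("[A-Za-z]+=[-0-9.eE+]+", pm[1]))[[1]]
    vals <- as.list(as.numeric(sub(".*=", "", kv)))
    names(vals) <- sub("=.*", "", kv)
    params <- do.call(wt_params, vals)
  }
  seed <- NA_integer_
  sm <- grep("^# seed", hdr, value = TRUE)
  if (length(sm)) seed <- suppressWarnings(as.integer(sub("# seed\\s*", "", sm[1])))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("malformed hills file: no header row")
  df <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                   sep = "\t")
  need <- c("time_fs", "center_A", "width_A", "height_kcal")
  if (!all(need %in% names(df)))
    stop("malformed hills file: expected columns ", paste(need, collapse = ", "))
  if (any(!vapply(df[need], is.numeric, logical(1))))
    stop("malformed hills file: non-numeric values")
  hills_log(data.frame(time = df$time_fs, center = df$center_A,
                       width = df$width_A, height = df$height_kcal),
            params = params, seed = seed)
}

#' Write a free-energy curve as TSV
#'
#' @param fes an `fes_curve` from [reconstruct_fes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  out <- data.frame(cv1_A = fes$cv1, free_energy_kcal = fes$free_energy)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a free-energy curve from TSV
#'
#' @param path a file written by [write_fes()].
#' @return An `fes_curve` data frame.
#' @export
read_fes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  structure(data.frame(cv1 = df$cv1_A, free_energy = df$free_energy_kcal),
            class = c("fes_curve", "data.frame"))
}
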