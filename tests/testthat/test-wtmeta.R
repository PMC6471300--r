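test_that("harmonic walls are flat inside and quadratic outside", {
  w <- wall_params(K = 40, s_lo = -20, s_hi = 12.5)
  expect_equal(wall_energy(0, w)$energy, 0)
  expect_equal(wall_energy(c(-19.9, 12.49), w)$energy, c(0, 0))
  expect_equal(wall_energy(13.5, w)$energy, 20)          # (K/2) * 1^2
  expect_equal(wall_energy(-21, w)$energy, 20)
  expect_equal(wall_energy(13.5, w)$gradient, 40)

  set.seed(3)
  s <- runif(50, -30, 25)
  g_fd <- vapply(s, function(si)
    fd_gradient(function(x) wall_energy(x, w)$energy, si), numeric(1))
  expect_equal(wall_energy(s, w)$gradient, g_fd, tolerance = 1e-6)
  expect_error(wall_params(K = 40, s_lo = 3, s_hi = 3), "below")
})

test_that("bias energy equals explicit hill summation", {
  p <- wt_params()
  empty <- hills_log(data.frame(time = numeric(0), center = numeric(0),
                                width = numeric(0), height = numeric(0)), p)
  expect_equal(bias_energy(empty, c(-1, 0, 1)), c(0, 0, 0))

  one <- hills_log(data.frame(time = 1, center = 2.5, width = 0.05,
                              height = 0.07), p)
  expect_equal(bias_energy(one, 2.5), 0.07)

  set.seed(8)
  hl <- hills_log(data.frame(time = sort(runif(100, 0, 1e5)),
                             center = runif(100, -5, 5),
                             width = runif(100, 0.02, 0.4),
                             height = runif(100, 0.01, 0.1)), p)
  s <- runif(10, -6, 6)
  oracle <- vapply(s, function(si) {
    tot <- 0
    for (i in 1:100) tot <- tot + hl$height[i] *
        exp(-(si - hl$center[i])^2 / (2 * hl$width[i]^2))
    tot
  }, numeric(1))
  expect_equal(bias_energy(hl, s), oracle, tolerance = 1e-10)
})

test_that("tempered hill heights follow the well-tempered schedule", {
  p <- wt_params(H = 0.1, deltaT = 4500)
  expect_equal(next_hill_height(p, 0), 0.1)
  expect_equal(next_hill_height(p, KB_KCAL * 4500 * log(2)), 0.05)
  expect_error(next_hill_height(p, -1), "non-negative")
  expect_equal(bias_factor(wt_params(temperature = 298, deltaT = 4500)),
               (298 + 4500) / 298)
  expect_equal(bias_factor(wt_params()), 16.10, tolerance = 1e-3)
})

test_that("the engine is deterministic and tempering decays when pinned", {
  # stiff harmonic well pins the CV; rapid deposition for a short test
  pin <- toy_potential(1L, c(0, 0, 0.5 * 1e5))
  p <- wt_params(H = 0.1, delta = 0.05, deltaT = 4500, tauG = 0.1)
  r1 <- run_wt_metadynamics(pin, p, n_steps = 1.5e5, dt = 1e-4, seed = 99)
  r2 <- run_wt_metadynamics(pin, p, n_steps = 1.5e5, dt = 1e-4, seed = 99)
  expect_identical(r1$hills$center, r2$hills$center)
  expect_identical(r1$hills$height, r2$hills$height)
  expect_identical(r1$cv, r2$cv)

  h <- r1$hills$height
  expect_gt(length(h), 100)
  # non-increasing up to the residual sub-hill-width CV jitter
  expect_true(all(diff(h) <= 5e-3))
  expect_lt(h[length(h)] / h[1], 0.5)    # decays, not merely flat
})

test_that("bias accelerates barrier crossing on a double well", {
  pot <- make_double_well(3, c(-1.5, 1.5))
  count_crossings <- function(s) {
    side <- s[abs(s) > 1.0]
    sum(diff(sign(side)) != 0)
  }
  un <- run_wt_metadynamics(pot, wt_params(H = 0), n_steps = 2e6, dt = 0.1,
                            seed = 5, traj_stride = 10)
  bi <- run_wt_metadynamics(pot, wt_params(H = 0.1, tauG = 100),
                            n_steps = 2e6, dt = 0.1, seed = 5,
                            traj_stride = 10)
  expect_gt(count_crossings(bi$cv[, 1]), count_crossings(un$cv[, 1]))
})

test_that("the integrator aborts on divergence with a diagnostic", {
  steep <- toy_potential(1L, c(0, 0, -50))  # inverted well: expelled fast
  expect_error(
    run_wt_metadynamics(steep, wt_params(H = 0), n_steps = 1e5, dt = 0.1,
                        seed = 1, sanity_bound = 50),
    "diverged")
})

test_that("FES reconstruction inverts the accumulated bias exactly", {
  p <- wt_params()
  scale <- (p$temperature + p$deltaT) / p$deltaT
  empty <- hills_log(data.frame(time = numeric(0), center = numeric(0),
                                width = numeric(0), height = numeric(0)), p)
  fes0 <- reconstruct_fes(empty, seq(-2, 2, 0.1))
  expect_equal(fes0$free_energy, rep(0, length(fes0$cv1)))

  one <- hills_log(data.frame(time = 1, center = 0.5, width = 0.05,
                              height = 0.08), p)
  grid <- seq(-3, 3, 0.05)
  fes1 <- reconstruct_fes(one, grid)
  # the bias maximum maps to the free-energy minimum (0 after the shift),
  # and the flat tails sit at scale * height above it
  expect_equal(fes1$free_energy[which.min(abs(grid - 0.5))], 0,
               tolerance = 1e-12)
  expect_equal(max(fes1$free_energy), scale * 0.08, tolerance = 1e-6)

  set.seed(13)
  hl <- hills_log(data.frame(time = 1:50, center = runif(50, -2, 2),
                             width = 0.05 + runif(50, 0, 0.1),
                             height = runif(50, 0.01, 0.1)), p)
  fes <- reconstruct_fes(hl, grid)
  v <- bias_energy(hl, grid)
  resid <- fes$free_energy / scale + v
  expect_lt(diff(range(resid)), 1e-12)   # equal up to a constant
  expect_equal(min(fes$free_energy), 0)
  expect_error(reconstruct_fes(hl, numeric(0)), "empty grid")
  expect_error(reconstruct_fes(hl, c(1, 1, 2)), "strictly increasing")
})

test_that("the engine's gridded bias agrees with exact summation", {
  set.seed(17)
  n <- 400
  hl <- data.frame(time = 1:n, center = runif(n, -4, 4), width = 0.05,
                   height = runif(n, 0.01, 0.1))
  at <- runif(200, -5, 5)
  gridded <- tunnelscape:::bias_grid_eval_cpp(hl$center, hl$width, hl$height,
                                              at, -30, 30, 0.05 / 8)
  exact <- bias_energy(hills_log(hl, wt_params()), at)
  expect_lt(max(abs(gridded - exact)), 1e-6)
})

test_that("deposition profile aggregates hills per time window", {
  p <- wt_params()
  flat <- hills_log(data.frame(time = seq(100, 10000, by = 100),
                               center = 0, width = 0.05, height = 0.05), p)
  dp <- deposition_profile(flat, window = 1000)
  expect_equal(nrow(dp), 10L)
  expect_equal(dp$energy, rep(0.5, 10))

  empty <- hills_log(data.frame(time = numeric(0), center = numeric(0),
                                width = numeric(0), height = numeric(0)), p)
  expect_equal(nrow(deposition_profile(empty, 1000)), 0L)
  expect_error(deposition_profile(flat, 0), "positive")
})

test_that("hills logs round-trip through TSV and reject bad files", {
  set.seed(19)
  p <- wt_params(H = 0.2, delta = 0.07)
  hl <- hills_log(data.frame(time = sort(runif(25, 0, 1e4)),
                             center = rnorm(25), width = 0.07,
                             height = runif(25, 0, 0.2)), p, seed = 42L)
  f <- tempfile(fileext = ".tsv")
  write_hills(hl, f)
  back <- read_hills(f)
  expect_identical(back$time, hl$time)
  expect_identical(back$center, hl$center)
  expect_identical(back$height, hl$height)
  expect_equal(attr(back, "params")$H, 0.2)
  expect_equal(attr(back, "seed"), 42L)

  # shuffled times violate monotonicity
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("time_fs\tcenter_A\twidth_A\theight_kcal",
               "200\t0\t0.05\t0.1", "100\t1\t0.05\t0.1"), bad)
  expect_error(read_hills(bad), "strictly increasing")

  # hand-written log parses to exactly the authored values
  hand <- tempfile(fileext = ".tsv")
  writeLines(c("time_fs\tcenter_A\twidth_A\theight_kcal",
               "1000\t-1.25\t0.05\t0.1",
               "2000\t0.5\t0.05\t0.09",
               "3000\t2\t0.05\t0.085"), hand)
  hh <- read_hills(hand)
  expect_equal(hh$time, c(1000, 2000, 3000))
  expect_equal(hh$center, c(-1.25, 0.5, 2))
  expect_equal(hh$height, c(0.1, 0.09, 0.085))
})

test_that("the radial wall confines CV2 in three-dimensional runs", {
  tun <- make_tunnel_potential(toy_potential(1L, c(0, 0, 0.5)),
                               radial_k = 0.01)
  walls <- list(cv2 = wall_params(K = 40, s_lo = 0, s_hi = 2))
  res <- run_wt_metadynamics(tun, wt_params(H = 0), n_steps = 2e5,
                             dt = 0.1, walls = walls, seed = 31,
                             traj_stride = 2)
  # weak radial spring alone would wander to ~8 A; the wall holds it
  expect_lt(mean(res$cv[, 2] > 4), 1e-3)
  expect_true(all(res$cv[, 2] >= 0))
})

test_that("walls confine the sampled collective variable", {
  flat <- toy_potential(1L, c(0))
  walls <- list(cv1 = wall_params(K = 40, s_lo = -3, s_hi = 3))
  res <- run_wt_metadynamics(flat, wt_params(H = 0.1), n_steps = 1e6,
                             dt = 0.1, walls = walls, seed = 21,
                             traj_stride = 10)
  s <- res$cv[, 1]
  expect_lt(mean(s > 5 | s < -5), 1e-3)
})
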