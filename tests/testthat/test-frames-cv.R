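make_static_traj <- function(coords, n_frames = 4L) {
  xyz <- matrix(rep(as.vector(t(coords)), n_frames), nrow = n_frames,
                byrow = TRUE)
  trajectory(xyz, data.frame(elety = "CA", resid = "ALA",
                             resno = seq_len(nrow(coords))))
}

test_that("RMSF is zero for static atoms and matches simple motions", {
  crd <- matrix(rnorm(30), ncol = 3)
  traj <- make_static_traj(crd, 5L)
  expect_equal(unname(compute_rmsf(traj)), rep(0, 10), tolerance = 1e-12)

  # one atom alternating x = +/- a, others fixed: its RMSF equals a
  a <- 0.8
  nf <- 40L
  xyz <- matrix(rep(as.vector(t(crd)), nf), nrow = nf, byrow = TRUE)
  xyz[, 1] <- rep(c(a, -a), length.out = nf)
  traj2 <- trajectory(xyz, traj$atoms)
  r <- compute_rmsf(traj2, align = FALSE)
  expect_equal(unname(r[1]), a, tolerance = 1e-12)
  expect_equal(unname(r[-1]), rep(0, 9), tolerance = 1e-12)
})

test_that("RMSF matches a direct-formula loop on random walks", {
  set.seed(5)
  nf <- 20L; na <- 6L
  xyz <- matrix(0, nf, 3L * na)
  xyz[1L, ] <- rnorm(3L * na, sd = 4)
  for (f in 2:nf) xyz[f, ] <- xyz[f - 1L, ] + rnorm(3L * na, sd = 0.2)
  traj <- trajectory(xyz, data.frame(elety = "CA", resid = "ALA",
                                     resno = seq_len(na)))
  got <- compute_rmsf(traj, align = FALSE)
  # brute-force oracle straight from the definition
  for (i in seq_len(na)) {
    ri <- xyz[, (3 * i - 2):(3 * i)]
    mu <- colMeans(ri)
    want <- sqrt(mean(rowSums(sweep(ri, 2L, mu)^2)))
    expect_equal(unname(got[i]), want, tolerance = 1e-12)
  }
  expect_error(compute_rmsf(make_static_traj(matrix(rnorm(9), 3), 1L)),
               "at least 2 frames")
})

test_that("reference-atom selection filters strictly below the threshold", {
  r <- c(a1 = 0.2, a2 = 0.9, a3 = 1.0, a4 = 1.7)
  names(r) <- 1:4
  expect_equal(select_reference_atoms(r, 2.0), 1:4)
  expect_error(select_reference_atoms(r, 0.1), "no atoms below")
  expect_equal(select_reference_atoms(r, 1.0), 1:2)  # strict: 1.0 excluded
  set.seed(9)
  rr <- runif(50, 0, 2)
  names(rr) <- seq_len(50)
  expect_equal(select_reference_atoms(rr, 1.0), unname(which(rr < 1.0)))
})

test_that("Kabsch fit recovers constructed rigid transforms", {
  set.seed(14)
  A <- matrix(rnorm(45, sd = 3), ncol = 3)

  idf <- kabsch_fit(A, A)
  expect_equal(idf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(idf$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(idf$rmsd, 0, tolerance = 1e-10)

  rig <- random_rigid()
  B <- sweep(A %*% rig$R, 2L, rig$t, "+")
  fit <- kabsch_fit(A, B)
  expect_equal(fit$rotation, rig$R, tolerance = 1e-8)
  expect_equal(fit$translation, rig$t, tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(apply_transform(A, fit), B, tolerance = 1e-8)

  # mirrored set: proper rotation enforced, residual nonzero
  M <- A %*% diag(c(-1, 1, 1))
  fm <- kabsch_fit(A, M)
  expect_equal(det(fm$rotation), 1, tolerance = 1e-10)
  expect_gt(fm$rmsd, 0.1)

  expect_error(kabsch_fit(A[1:2, ], A[1:2, ]), "at least 3")
  degen <- cbind(seq_len(5), 0, 0)  # collinear
  expect_error(kabsch_fit(degen, degen), "rank-deficient")
})

test_that("Kabsch fit of a set onto itself is the identity (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(3 * (5 + seed)), ncol = 3)
    f <- kabsch_fit(A, A)
    expect_equal(f$rotation, diag(3), tolerance = 1e-9)
    expect_equal(f$translation, rep(0, 3), tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD agrees with an established reference implementation", {
  set.seed(23)
  A <- matrix(rnorm(60, sd = 2), ncol = 3)
  B <- A + matrix(rnorm(60, sd = 0.3), ncol = 3)
  fit <- kabsch_fit(A, B)
  ours <- fit$rmsd
  ref <- bio3d::rmsd(as.vector(t(B)), as.vector(t(A)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 5e-4)  # bio3d rounds to 3 decimals
})

test_that("collective variables have the defined geometry and invariances", {
  fx <- make_toy_complex_trajectory(n_frames = 3L, ligand_course = 0,
                                    jitter = 0, seed = 3,
                                    global_motion = FALSE)
  traj <- fx$trajectory
  ref <- reference_state(traj, fit_atoms = fx$helix_atoms,
                         ligand_atoms = fx$parts$tail, axis = fx$axis)
  # the reference frame itself sits at the CV origin
  expect_equal(unname(compute_cvs(get_frame(traj, 1L), ref)), c(0, 0),
               tolerance = 1e-10)

  # pure axial displacement of the ligand: (3, 0)
  frame <- get_frame(traj, 1L)
  frame[fx$parts$tail, ] <- sweep(frame[fx$parts$tail, ], 2L, 3 * fx$axis, "+")
  expect_equal(unname(compute_cvs(frame, ref)), c(3, 0), tolerance = 1e-8)

  # pure radial displacement: (0, 2), CV2 non-negative
  perp <- c(0, 1, 0)
  frame2 <- get_frame(traj, 1L)
  frame2[fx$parts$tail, ] <- sweep(frame2[fx$parts$tail, ], 2L, 2 * perp, "+")
  expect_equal(unname(compute_cvs(frame2, ref)), c(0, 2), tolerance = 1e-8)

  # global rigid motion leaves both CVs unchanged
  set.seed(77)
  rig <- random_rigid()
  moved <- sweep(frame %*% rig$R, 2L, rig$t, "+")
  expect_equal(compute_cvs(moved, ref), compute_cvs(frame, ref),
               tolerance = 1e-6)

  # axis sign: CV1 flips, CV2 unchanged
  ref_neg <- reference_state(traj, fx$helix_atoms, fx$parts$tail, -fx$axis)
  cv_pos <- compute_cvs(frame, ref)
  cv_neg <- compute_cvs(frame, ref_neg)
  expect_equal(unname(cv_neg["cv1"]), -unname(cv_pos["cv1"]), tolerance = 1e-8)
  expect_equal(unname(cv_neg["cv2"]), unname(cv_pos["cv2"]), tolerance = 1e-8)
})

test_that("reference_state validates its selections", {
  fx <- make_toy_complex_trajectory(3L, 0, seed = 4, global_motion = FALSE)
  expect_error(reference_state(fx$trajectory, integer(0), fx$parts$tail,
                               fx$axis), "non-empty")
  expect_error(reference_state(fx$trajectory, fx$helix_atoms,
                               c(fx$helix_atoms[1], fx$parts$tail), fx$axis),
               "disjoint")
})

test_that("CV time series tracks a scripted axial course", {
  course <- seq(0, 5, length.out = 25L)
  fx <- make_toy_complex_trajectory(25L, course, jitter = 0, seed = 8,
                                    global_motion = TRUE)
  ref <- reference_state(fx$trajectory, fx$helix_atoms, fx$parts$tail,
                         fx$axis)
  cvs <- cv_timeseries(fx$trajectory, ref)
  expect_equal(nrow(cvs), 25L)
  expect_equal(cvs$cv1, course, tolerance = 1e-6)
  expect_true(all(abs(cvs$cv2) < 1e-6))

  single <- make_toy_complex_trajectory(1L, 0, seed = 8, global_motion = FALSE)
  ref1 <- reference_state(single$trajectory, single$helix_atoms,
                          single$parts$tail, single$axis)
  expect_equal(nrow(cv_timeseries(single$trajectory, ref1)), 1L)
})

test_that("RMSF-based selection splits the fixture scaffold as intended", {
  fx <- make_toy_complex_trajectory(30L, 0, jitter = 0.2, seed = 15,
                                    global_motion = TRUE)
  ca <- select_atoms(fx$trajectory, elety = "CA")
  rmsf <- compute_rmsf(fx$trajectory, ca)
  sel <- select_reference_atoms(rmsf, 1.0)
  expect_setequal(sel, fx$helix_atoms)
})
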