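test_that("Kabsch superposition removes rigid motion exactly", {
  s <- make_toy_protein(6)
  fit0 <- kabsch_superpose(s$coords, s$coords)
  expect_equal(fit0$rmsd, 0)
  set.seed(21)
  for (k in 1:10) {
    R <- random_rotation(); tr <- stats::rnorm(3, 0, 10)
    moved <- sweep(s$coords %*% t(R), 2, tr, "+")
    fit <- kabsch_superpose(moved, s$coords)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_transform(moved, fit), s$coords, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("Kabsch RMSD matches the rotation-grid oracle on planar toys", {
  set.seed(31)
  for (k in 1:5) {
    n <- sample(4:6, 1)
    ref <- cbind(matrix(stats::rnorm(2 * n, 0, 2), ncol = 2), 0)
    mob <- ref + cbind(matrix(stats::rnorm(2 * n, 0, 0.3), ncol = 2), 0)
    kab <- kabsch_superpose(mob, ref)$rmsd
    grid <- grid_rmsd_planar(mob, ref, step_deg = 0.25)
    expect_lte(kab, grid + 1e-12)     # optimality lower bound
    expect_lt(grid - kab, 2e-3)       # grid resolution tolerance
  }
})

test_that("Kabsch RMSD never exceeds the unfitted RMSD", {
  set.seed(41)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    a <- matrix(stats::rnorm(3 * n, 0, 3), ncol = 3)
    b <- matrix(stats::rnorm(3 * n, 0, 3), ncol = 3)
    unfitted <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch_superpose(a, b)$rmsd, unfitted + 1e-12)
  }
})

test_that("degenerate fits are refused", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  a <- matrix(stats::rnorm(6), ncol = 3)
  expect_error(kabsch_superpose(a, a), "at least 3")
})

test_that("RMSD series is zero for static or rigidly rotated frames", {
  s <- make_toy_protein(5)
  static <- make_trajectory(s, 4, sigma = 0)
  expect_equal(rmsd_series(static)$rmsd, rep(0, 4), tolerance = 1e-9)
  set.seed(7)
  rot <- rigid_transform_traj(subset_frames(static, c(1, 2)),
                              random_rotation(), c(3, -1, 2))
  traj <- trajectory(s, array(c(static$xyz[, , 1], rot$xyz[, , 2]),
                              dim = c(nrow(s$atoms), 3, 2)))
  expect_equal(rmsd_series(traj)$rmsd[2], 0, tolerance = 1e-9)
})

test_that("RMSD of a single displaced Calpha matches the hand formula", {
  # 4 residues; displace one CA by 1 A after fitting on the others is not
  # rigid, so fit on all CAs: with three CAs fixed and one moved by delta,
  # the post-fit RMSD must match a direct Kabsch computation on the 4 CAs,
  # and be bounded by the unfitted value sqrt(delta^2 / n).
  s <- make_toy_protein(4)
  ca <- ca_indices(s)
  moved <- s$coords
  moved[ca[2], ] <- moved[ca[2], ] + c(0, 0, 1)
  traj <- trajectory(s, array(c(s$coords, moved), dim = c(nrow(s$atoms), 3, 2)))
  series <- rmsd_series(traj)
  direct <- kabsch_superpose(moved[ca, ], s$coords[ca, ])$rmsd
  expect_equal(series$rmsd[2], direct)
  expect_lte(series$rmsd[2], sqrt(1 / 4) + 1e-12)
  expect_gt(series$rmsd[2], 0.1)
})

test_that("equilibration window drops the head and samples equidistantly", {
  s <- make_toy_protein(3)
  traj <- make_trajectory(s, 150, sigma = 0.1, seed = 2)
  w <- equilibration_window(traj, 0.6, 60)
  expect_equal(n_frames(w), 60)
  expect_identical(w$xyz, traj$xyz[, , 91:150])   # frames 91..150
  # discard 0 with full snapshot count is the identity
  w0 <- equilibration_window(traj, 0, 150)
  expect_identical(w0$xyz, traj$xyz)
  # fewer frames than requested: all remaining, with a warning
  short <- make_trajectory(s, 10, sigma = 0.1)
  expect_warning(ws <- equilibration_window(short, 0, 1500), "returning all")
  expect_equal(n_frames(ws), 10)
  expect_error(equilibration_window(traj, 1, 10), "discard_fraction")
})

test_that("RMSF is zero for static trajectories and undefined for one frame", {
  s <- make_toy_protein(5)
  static <- make_trajectory(s, 3, sigma = 0)
  expect_equal(rmsf(static)$rmsf, rep(0, 5), tolerance = 1e-9)
  expect_error(rmsf(make_trajectory(s, 1)), "single frame")
})

test_that("RMSF profile is invariant under a global rigid motion of all frames", {
  s <- make_toy_protein(8)
  traj <- make_trajectory(s, 50, sigma = 0.3, seed = 17)
  set.seed(18)
  moved <- rigid_transform_traj(traj, random_rotation(), c(10, -4, 2))
  expect_equal(rmsf(moved)$rmsf, rmsf(traj)$rmsf, tolerance = 1e-9)
})

test_that("RMSF recovers the planted fluctuation amplitude", {
  # sigma per coordinate -> RMSF sigma*sqrt(3), corrected for the 6 rigid
  # degrees of freedom the mean-structure superposition absorbs:
  # E RMSF_i = sigma * sqrt(3 - tr(P_ii)).
  s <- make_toy_protein(16)
  sigma <- 0.5; n <- 2000
  traj <- make_trajectory(s, n, sigma = sigma, seed = 23)
  r <- rmsf(traj)
  lev <- rigid_leverage(s$coords[s$atoms$name == "CA", ])
  expected <- sigma * sqrt(3 - lev)
  se <- sqrt(6 / n) * sigma^2 / (2 * sigma * sqrt(3))
  expect_true(all(abs(r$rmsf - expected) < 3 * se))
})

test_that("sigma-hat = RMSF/sqrt(3) recovers the planted amplitude", {
  # long chain: the rigid-dof correction is < 2% so the naive estimator's
  # relative bias stays under 5% including sampling noise
  s <- make_toy_protein(100)
  sigma <- 0.5
  traj <- make_trajectory(s, 3000, sigma = sigma, seed = 24)
  r <- rmsf(traj)
  expect_lt(max(abs(r$rmsf / sqrt(3) / sigma - 1)), 0.05)
})

test_that("distance patterns follow the centre-of-geometry definition", {
  s <- make_toy_protein(6)
  traj <- make_trajectory(s, 3, sigma = 0)
  p <- distance_pattern(traj, 4)
  expect_equal(p$dist[p$resno == 4], 0)
  expect_true(all(p$dist >= 0))
  # hand computation from backbone (N, CA, C) centroids of the base
  bb <- function(r) colMeans(s$coords[atom_index(s, r, c("N", "CA", "C")), ])
  expect_equal(p$dist[p$resno == 1], sqrt(sum((bb(1) - bb(4))^2)))
  expect_error(distance_pattern(traj, 99), "not in the topology")
})

test_that("distance patterns average per-frame distances", {
  # frame distances 4 and 6 for the same pair must average to 5
  s <- make_toy_protein(2)
  base <- s$coords
  f2 <- base
  bb1 <- colMeans(base[atom_index(s, 1, c("N", "CA", "C")), ])
  bb2 <- colMeans(base[atom_index(s, 2, c("N", "CA", "C")), ])
  d0 <- sqrt(sum((bb1 - bb2)^2))
  rows2 <- s$atoms$resno == 2
  f1 <- base
  # place residue 2's centroid exactly 4 (then 6) Angstrom from residue 1's
  f1[rows2, ] <- sweep(f1[rows2, ], 2, bb1 + c(4, 0, 0) - bb2, "+")
  f2[rows2, ] <- sweep(f2[rows2, ], 2, bb1 + c(6, 0, 0) - bb2, "+")
  traj <- trajectory(s, array(c(f1, f2), dim = c(nrow(s$atoms), 3, 2)))
  p <- distance_pattern(traj, 1)
  expect_equal(p$dist[p$resno == 2], 5)
})

test_that("distance patterns are rigid-motion invariant", {
  s <- make_toy_protein(7)
  traj <- make_trajectory(s, 10, sigma = 0.2, seed = 31)
  p0 <- distance_pattern(traj, 3)
  set.seed(32)
  for (k in 1:5) {
    moved <- rigid_transform_traj(traj, random_rotation(), stats::rnorm(3, 0, 20))
    expect_equal(distance_pattern(moved, 3)$dist, p0$dist, tolerance = 1e-9)
  }
})

test_that("pattern differences are signed, antisymmetric and recover shifts", {
  s <- make_toy_protein(12)
  wt <- make_trajectory(s, 5, sigma = 0)
  mut <- make_trajectory(s, 5, sigma = 0,
                         shifts = list(planted_shift(c(8, 10), c(5, 0, 0))))
  pw <- distance_pattern(wt, 2); pm <- distance_pattern(mut, 2)
  d <- pattern_difference(pm, pw)
  expect_equal(pattern_difference(pw, pm)$delta, -d$delta)
  expect_equal(pattern_difference(pw, pw)$delta, rep(0, 12))
  in_range <- d$resno >= 8 & d$resno <= 10
  expect_true(all(abs(d$delta[in_range] - 5) < 0.05))
  expect_true(all(abs(d$delta[!in_range]) < 1e-9))
  # mismatched inputs are refused
  p_short <- distance_pattern(make_trajectory(make_toy_protein(5), 2), 2)
  expect_error(pattern_difference(pm, p_short), "residue sets")
  p_other_focal <- distance_pattern(wt, 3)
  expect_error(pattern_difference(pm, p_other_focal), "focal")
})
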