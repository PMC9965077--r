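test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  A <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  m <- random_rigid_motion()
  B <- apply_rigid(A, m)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(A %*% t(fit$rotation) +
                 matrix(fit$translation, nrow(A), 3, byrow = TRUE),
               B, tolerance = 1e-9)
  expect_error(kabsch_superpose(A, A[1:5, ]), "mismatch")
})

test_that("two-point stretched pair has the known 0.5 A optimum", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(0, 2, 0))
  expect_equal(rmsd_fit(a, b), 0.5, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the brute-force rotation-grid minimum", {
  set.seed(42)
  for (trial in 1:3) {
    n <- sample(4:6, 1)
    A <- matrix(rnorm(3 * n), ncol = 3)
    B <- matrix(rnorm(3 * n), ncol = 3)
    k <- rmsd_fit(A, B)
    g <- grid_rmsd_oracle(A, B)
    expect_lte(k, g + 1e-9)        # Kabsch is the true optimum
    expect_lt(g - k, 0.2)          # grid reaches it within its resolution
  }
})

test_that("Kabsch agrees with an independent superposition implementation", {
  set.seed(3)
  A <- matrix(rnorm(60), ncol = 3)
  B <- matrix(rnorm(60), ncol = 3)
  ours <- rmsd_fit(A, B)
  theirs <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 digits
})

test_that("rmsd_series starts at zero and ignores rigid motions", {
  set.seed(9)
  base <- matrix(rnorm(36), ncol = 3)
  frames <- c(list(base),
              lapply(1:5, function(i) apply_rigid(base,
                                                  random_rigid_motion())))
  tr <- toy_trajectory(frames)
  s <- rmsd_series(tr)
  expect_equal(s$rmsd[1], 0)
  expect_true(all(s$rmsd < 1e-6))
  expect_equal(s$times_ns, tr$times_ns)
})

test_that("a monotone unfolding trajectory gives a non-decreasing series", {
  base <- build_extended_chain(fg_sequence(strrep("GS", 6)), 3.8)
  frames <- lapply(seq(1, 2, by = 0.1), function(fac) {
    x <- base; x[, 1] <- x[, 1] * fac; x
  })
  s <- rmsd_series(toy_trajectory(frames))
  expect_true(all(diff(s$rmsd) >= -1e-9))
})

test_that("plateau classification separates flat, drifting and converged series", {
  mk <- function(vals, times) {
    structure(list(replica_id = 1L, times_ns = times, rmsd = vals),
              class = "rmsd_series")
  }
  t <- seq(0, 125, by = 0.5)
  flat <- mk(rep(5, length(t)), t)
  r <- classify_stability(flat)
  expect_true(r$stable)
  expect_equal(r$plateau_sd, 0)
  expect_equal(r$drift_slope, 0, tolerance = 1e-12)

  ramp <- mk(0.4 * t, t)  # 0 -> 50 A over 125 ns
  r <- classify_stability(ramp)
  expect_false(r$stable)
  expect_equal(r$drift_slope, 0.4, tolerance = 1e-9)

  set.seed(31)
  burn <- mk(c(60 * (1 - exp(-t[t <= 40] / 8)),
               rnorm(sum(t > 40), mean = 60, sd = 0.5)), t)
  r <- classify_stability(burn)
  expect_true(r$stable)
  expect_lt(r$plateau_sd, 1)

  expect_error(classify_stability(mk(c(0, 1), c(0, 1))), "too short")
})

test_that("stability classification is invariant to per-frame rigid motions", {
  set.seed(12)
  s <- random_fg_sequence(16, seed = 5)
  cfg <- sim_config(n_replicas = 1, n_sweeps = 600, seed = 6,
                    record_interval_ns = 0.015)
  tr <- simulate_replica(s, cfg, 1)
  moved <- tr
  for (i in seq_len(n_frames(tr)))
    moved$coords[i, , ] <- apply_rigid(traj_frame(tr, i),
                                       random_rigid_motion())
  a <- classify_stability(rmsd_series(tr), assessment_start_ns = 1,
                          sd_threshold = 6, slope_threshold = 1)
  b <- classify_stability(rmsd_series(moved), assessment_start_ns = 1,
                          sd_threshold = 6, slope_threshold = 1)
  expect_equal(a$plateau_mean_rmsd, b$plateau_mean_rmsd, tolerance = 1e-6)
  expect_equal(a$plateau_sd, b$plateau_sd, tolerance = 1e-6)
  expect_equal(a$stable, b$stable)
})

test_that("manual override lists force the stability call", {
  s <- random_fg_sequence(12, seed = 3)
  cfg <- sim_config(n_replicas = 2, n_sweeps = 400, seed = 4,
                    record_interval_ns = 0.05)
  ens <- simulate_ensemble(s, cfg)
  rep1 <- stability_report(ens, assessment_start_ns = 0.5,
                           sd_threshold = 100, slope_threshold = 100)
  expect_true(all(rep1$stable))
  rep2 <- stability_report(ens, assessment_start_ns = 0.5,
                           sd_threshold = 100, slope_threshold = 100,
                           force_unstable = 2L)
  expect_equal(rep2$stable, c(TRUE, FALSE))
})

test_that("representatives are the medoid of the largest cluster", {
  # two well-separated conformers at a 60/40 split
  set.seed(21)
  confA <- matrix(rnorm(30), ncol = 3)
  confB <- matrix(rnorm(30, sd = 5), ncol = 3)  # well-separated shape
  frames <- c(
    lapply(1:7, function(i) confA + matrix(rnorm(30, sd = 0.05), ncol = 3)),
    lapply(1:4, function(i) confB + matrix(rnorm(30, sd = 0.05), ncol = 3)))
  # 11 frames at 0..1 ns; the full-span window keeps all 7 + 4 frames
  tr <- toy_trajectory(frames, times_ns = seq(0, 1, by = 0.1))
  reps <- cluster_representatives(list(tr), analysis_window(1, 0.1),
                                  rmsd_cutoff = 3)
  expect_equal(reps[[1]]$cluster_size, 7L)
  expect_lt(rmsd_fit(reps[[1]]$coords, confA), 0.5)

  # frame-order invariance modulo the documented time tie-break
  rev_tr <- tr
  rev_tr$coords <- tr$coords[11:1, , , drop = FALSE]
  reps2 <- cluster_representatives(list(rev_tr), analysis_window(1, 0.1),
                                   rmsd_cutoff = 3)
  expect_lt(rmsd_fit(reps2[[1]]$coords, confA), 0.5)
})

test_that("degenerate windows behave as documented", {
  x <- matrix(rnorm(30), ncol = 3)
  tr <- toy_trajectory(rep(list(x), 5), times_ns = seq(0, 0.4, by = 0.1))
  reps <- cluster_representatives(list(tr), analysis_window(0.4, 0.1))
  expect_equal(reps[[1]]$cluster_size, 5L)
  expect_equal(reps[[1]]$coords, unname(x), ignore_attr = TRUE)

  one <- toy_trajectory(list(x, x, x), times_ns = c(0, 0.1, 0.2))
  reps1 <- cluster_representatives(list(one), analysis_window(0.1, 0.1))
  expect_equal(reps1[[1]]$n_frames, 1L)
})
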