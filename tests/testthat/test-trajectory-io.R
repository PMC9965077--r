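test_that("PDB round-trip preserves frame count and coordinates to PDB precision", {
  s <- random_fg_sequence(20, seed = 4)
  cfg <- sim_config(n_replicas = 1, n_sweeps = 200, seed = 8,
                    record_interval_ns = 0.1)
  tr <- simulate_replica(s, cfg, 1)
  f <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, f)
  back <- read_trajectory_pdb(f)
  expect_equal(n_frames(back), n_frames(tr))
  expect_equal(back$times_ns, tr$times_ns)
  expect_equal(back$replica_id, tr$replica_id)
  expect_equal(back$coords, tr$coords, tolerance = 1e-3)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3 + 1e-9)
  expect_equal(back$topology$residues, s$residues)

  # independent reader agrees on the coordinates
  b3 <- bio3d::read.pdb(f, multi = TRUE)
  expect_equal(dim(b3$xyz)[1], n_frames(tr))
  expect_equal(matrix(b3$xyz[1, ], ncol = 3, byrow = TRUE),
               unname(traj_frame(back, 1)), tolerance = 1e-9)
})

test_that("reader rejects malformed and inconsistent files with located errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_trajectory_pdb(f), "empty")

  writeLines(c("MODEL        1",
               "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
               "ATOM      2  CA  GLY A   2       3.800   0.000",
               "ENDMDL"), f)
  expect_error(read_trajectory_pdb(f), "shorter than 54")

  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       3.800   0.0x0   0.000  1.00  0.00",
    "ENDMDL"), f)
  expect_error(read_trajectory_pdb(f), "line 3")

  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ENDMDL"), f)
  expect_error(read_trajectory_pdb(f), "inconsistent atom counts")
})

test_that("a 2-model 3-atom file reads as 2 frames x 3 beads", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  PHE A   2       3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  PHE A   2       3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  GLY A   3       3.800   3.800   0.000  1.00  0.00",
    "ENDMDL", "END"), f)
  tr <- read_trajectory_pdb(f)
  expect_equal(dim(tr$coords), c(2, 3, 3))
  expect_equal(tr$topology$residues, c("G", "F", "G"))
  expect_equal(traj_frame(tr, 2)[3, ], c(x = 3.8, y = 3.8, z = 0))
})

test_that("ensemble directory round-trip preserves replica structure", {
  s <- random_fg_sequence(12, seed = 6)
  cfg <- sim_config(n_replicas = 3, n_sweeps = 100, seed = 2,
                    record_interval_ns = 0.1)
  ens <- simulate_ensemble(s, cfg)
  d <- tempfile()
  write_ensemble(ens, d, config = cfg)
  back <- read_ensemble(d)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$replica_id, ens[[k]]$replica_id)
    expect_equal(back[[k]]$coords, ens[[k]]$coords, tolerance = 1e-3)
  }
  meta <- jsonlite::read_json(file.path(d, "ensemble.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$n_replicas, 3)
  expect_equal(meta$config$seed, 2)
})

test_that("sample_window returns the trailing half-open window at the stride", {
  # 125 ns at 0.005 ns spacing; final 25 ns at 0.01 ns stride -> 2500 frames
  nfr <- 25001L
  tr <- toy_trajectory(
    rep(list(rbind(c(0, 0, 0), c(3.8, 0, 0))), 2),
    times_ns = c(0, 0.005))
  tr$coords <- array(0, dim = c(nfr, 2, 3))
  tr$times_ns <- (seq_len(nfr) - 1) * 0.005
  w <- sample_window(tr, analysis_window(25, 0.01))
  expect_equal(n_frames(w), 2500L)
  expect_equal(max(w$times_ns), 125)
  expect_gt(min(w$times_ns), 100)
  expect_equal(unique(round(diff(w$times_ns), 9)), 0.01)

  # idempotence at matched stride
  w2 <- sample_window(w, analysis_window(25, 0.01))
  expect_equal(w2$times_ns, w$times_ns)
  expect_equal(w2$coords, w$coords)
})

test_that("window equal to the full span with stride = spacing is the identity", {
  frames <- lapply(1:11, function(i) matrix(rnorm(9), 3, 3))
  tr <- toy_trajectory(frames, times_ns = seq(0, 1, by = 0.1))
  w <- sample_window(tr, analysis_window(1, 0.1))
  expect_equal(n_frames(w), 11L)
  expect_equal(w$coords, tr$coords)
})

test_that("window and stride misuse raise the documented errors", {
  frames <- lapply(1:11, function(i) matrix(rnorm(9), 3, 3))
  tr <- toy_trajectory(frames, times_ns = seq(0, 1, by = 0.1))
  expect_error(sample_window(tr, analysis_window(25, 0.01)), "window error")
  expect_error(sample_window(tr, analysis_window(1, 0.15)), "stride error")
  expect_error(analysis_window(25, 0), "stride")
  expect_error(analysis_window(25, 26), "stride")
})
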