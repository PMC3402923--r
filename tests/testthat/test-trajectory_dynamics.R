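test_that("subsampling keeps frames at multiples of the interval", {
  ref <- synth_helix(10)
  traj <- synth_trajectory(ref, 0.5, n_frames = 1000L,
                           frame_interval_ps = 1, seed = 1L)
  sub <- subsample_frames(traj, 25)
  expect_equal(dim(sub$xyz)[3], 41L)       # t = 0, 25, ..., 1000
  expect_equal(sub$frame_interval_ps, 25)
  expect_equal(sub$xyz[, , 2], traj$xyz[, , 26])

  same <- subsample_frames(traj, 1)
  expect_equal(same$xyz, traj$xyz)

  traj5 <- synth_trajectory(ref, 0.5, n_frames = 10L,
                            frame_interval_ps = 5, seed = 1L)
  expect_error(subsample_frames(traj5, 7), "not a multiple")
  expect_error(subsample_frames(traj5, -5), "positive")
})

test_that("a static trajectory has an all-zero profile", {
  ref <- synth_helix(12)
  traj <- synth_trajectory(ref, 0, n_frames = 5L, seed = 1L)
  for (fit in c("ca", "none"))
    expect_equal(per_residue_rmsd(traj, fit)$mean_rmsd, rep(0, 12))
})

test_that("two-frame displacement follows the d/sqrt(2) closed form", {
  ref <- synth_helix(10)
  arr <- array(rep(ref$xyz, 3), dim = c(10, 3, 3))
  d <- 1.8
  arr[4, 1, 3] <- arr[4, 1, 3] + d   # residue 4 moved by d in one frame
  traj <- ca_trajectory(arr, ref$resno, ref$resid, 25)
  prof <- per_residue_rmsd(traj, fit = "none")
  expect_equal(prof$mean_rmsd[4], d / sqrt(2), tolerance = 1e-12)
  expect_equal(prof$mean_rmsd[-4], rep(0, 9))
  expect_equal(attr(prof, "n_frames_used"), 2L)
})

test_that("Gaussian fluctuation recovery approaches sigma * sqrt(3)", {
  ref <- synth_helix(8)
  sigma <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.5, 2.0)
  traj <- synth_trajectory(ref, sigma, n_frames = 500L, seed = 101L)
  prof <- per_residue_rmsd(traj, fit = "none")
  expect_lt(max(abs(prof$mean_rmsd / (sigma * sqrt(3)) - 1)), 0.05)
})

test_that("rigid-body jitter is removed by all-CA fitting", {
  # a domain-sized chain: the 6 rigid degrees of freedom absorbed by the
  # fit are then a small fraction of the 3n coordinate noise
  ref <- synth_helix(40)
  sigma <- rep(1.0, 40)
  traj <- synth_trajectory(ref, sigma, n_frames = 500L,
                           jitter = list(max_rot_deg = 10, max_trans = 3),
                           seed = 102L)
  prof <- per_residue_rmsd(traj, fit = "ca")
  expect_lt(max(abs(prof$mean_rmsd / (sigma * sqrt(3)) - 1)), 0.07)
})

test_that("recovery bias shrinks as the frame count grows", {
  ref <- synth_helix(6)
  sigma <- rep(0.8, 6)
  tol <- c(`50` = 0.20, `200` = 0.12, `1000` = 0.06)
  for (nf in c(50L, 200L, 1000L)) {
    traj <- synth_trajectory(ref, sigma, n_frames = nf, seed = 7L + nf)
    prof <- per_residue_rmsd(traj, fit = "none")
    expect_lt(max(abs(prof$mean_rmsd / (sigma * sqrt(3)) - 1)),
              tol[[as.character(nf)]])
  }
})

test_that("the profile is invariant under a constant rigid move of all frames", {
  ref <- synth_helix(10)
  traj <- synth_trajectory(ref, 0.5, n_frames = 30L, seed = 4L)
  prof0 <- per_residue_rmsd(traj, fit = "ca")
  set.seed(99)
  R <- random_rotation(); tr <- stats::rnorm(3, sd = 10)
  moved <- traj
  for (k in seq_len(dim(traj$xyz)[3]))
    moved$xyz[, , k] <- sweep(traj$xyz[, , k] %*% R, 2, tr, `+`)
  prof1 <- per_residue_rmsd(moved, fit = "ca")
  expect_lt(max(abs(prof1$mean_rmsd - prof0$mean_rmsd)), 1e-6)
})

test_that("mean squared profile equals mean squared whole-structure deviation", {
  ref <- synth_helix(9)
  traj <- synth_trajectory(ref, 0.7, n_frames = 40L, seed = 12L)
  prof <- per_residue_rmsd(traj, fit = "none")
  nf <- dim(traj$xyz)[3]
  frame_msd <- vapply(2:nf, function(k)
    mean(rowSums((traj$xyz[, , k] - traj$xyz[, , 1])^2)), 0)
  expect_equal(mean(prof$mean_rmsd^2), mean(frame_msd), tolerance = 1e-12)
})

test_that("compare_dynamics contrasts wild-type and variant profiles", {
  ref <- synth_helix(20)
  sigma <- rep(0.5, 20)
  a <- per_residue_rmsd(synth_trajectory(ref, sigma, 300L, seed = 21L),
                        fit = "none")
  expect_equal(compare_dynamics(a, a)$delta, rep(0, 20))

  sigma_b <- sigma; sigma_b[16] <- 1.0   # variant doubles residue 16
  b <- per_residue_rmsd(synth_trajectory(ref, sigma_b, 300L, seed = 22L),
                        fit = "none")
  cmp <- compare_dynamics(a, b)
  expect_equal(cmp$resno[which.max(cmp$delta)], 16L)
  expect_gt(max(cmp$delta), 0)
  expect_true(16L %in% attr(cmp, "flagged"))

  short <- a[1:10, ]
  expect_error(compare_dynamics(a, short), "residue numbering")
})

test_that("annotation merges tiers and summarizes per-tier dynamics", {
  ref <- synth_helix(10)
  sigma <- c(0.3, 0.3, rep(1.0, 8))  # quiet at the conserved positions
  prof <- per_residue_rmsd(synth_trajectory(ref, sigma, 300L, seed = 31L),
                           fit = "none")
  tiers <- data.frame(position = c(1L, 2L, 5L),
                      tier = c("HMG_CONSERVED", "HMG_CONSERVED",
                               "SOX_CONSERVED"))
  ann <- annotate_dynamics(prof, tiers)
  expect_equal(ann$tier[1:2], rep("HMG_CONSERVED", 2))
  expect_equal(ann$tier[3], "NO_VARIANT")
  smry <- attr(ann, "tier_summary")
  expect_equal(smry$tier[1], "HMG_CONSERVED")  # lowest mean RMSD first

  ann0 <- annotate_dynamics(prof, NULL)
  expect_equal(unique(ann0$tier), "NO_VARIANT")
  expect_equal(nrow(attr(ann0, "tier_summary")), 1L)
  ann_empty <- annotate_dynamics(prof, data.frame(position = integer(),
                                                  tier = character()))
  expect_equal(unique(ann_empty$tier), "NO_VARIANT")
})

test_that("trajectories round-trip through multi-model PDB at PDB precision", {
  ref <- synth_helix(7)
  traj <- synth_trajectory(ref, 0.6, n_frames = 4L, seed = 41L)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, f)
  back <- read_trajectory_pdb(f, frame_interval_ps = 25)
  expect_equal(back$xyz, round(traj$xyz, 3), tolerance = 1e-9)
  expect_equal(back$resno, traj$resno)
  # write -> read -> write is a fixpoint
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("frame sets with mismatched residues are rejected at read time", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atom <- function(ser, resno, x)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            ser, resno, x, 0, 0)
  writeLines(c("MODEL        1", atom(1, 1, 1), atom(2, 2, 2), "ENDMDL",
               "MODEL        2", atom(1, 1, 1), "ENDMDL", "END"), f)
  expect_error(suppressWarnings(read_trajectory_pdb(f, 25)),
               "share|residue")
})
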