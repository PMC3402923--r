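apply_transform_pts <- function(xyz, fit)
  sweep(xyz %*% fit$rotation, 2, fit$translation, `+`)

test_that("kabsch_fit recovers identity on identical sets", {
  m <- synth_helix(8)$xyz
  fit <- kabsch_fit(m, m)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$n_pairs, 8L)
})

test_that("kabsch_fit exactly inverts an applied rigid transform", {
  m <- synth_helix(10)$xyz
  Rz90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  target <- sweep(m %*% t(Rz90), 2, c(1, 2, 3), `+`)
  fit <- kabsch_fit(m, target)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation %*% t(t(Rz90)), diag(3), tolerance = 1e-9)
  expect_equal(apply_transform_pts(m, fit), target, tolerance = 1e-9)
})

test_that("kabsch_fit matches the brute-force Euler-grid oracle", {
  # frozen value computed with grid_kabsch_rmsd on the canonical 3-point case
  mob <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  tar <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0))
  expect_equal(kabsch_fit(mob, tar)$rmsd, 0.4514759670, tolerance = 1e-6)
  expect_equal(grid_kabsch_rmsd(mob, tar), 0.4514759670, tolerance = 1e-6)

  set.seed(19)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    mob <- matrix(stats::rnorm(3 * n, sd = 2), ncol = 3)
    tar <- matrix(stats::rnorm(3 * n, sd = 2), ncol = 3)
    expect_equal(kabsch_fit(mob, tar)$rmsd, grid_kabsch_rmsd(mob, tar),
                 tolerance = 1e-3)
  }
})

test_that("kabsch rmsd agrees with the bio3d fitted rmsd", {
  set.seed(23)
  m <- matrix(stats::rnorm(18), ncol = 3)
  t2 <- matrix(stats::rnorm(18), ncol = 3)
  ours <- kabsch_fit(m, t2)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(t2)), as.numeric(t(m)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)  # bio3d prints 3 decimals
})

test_that("rmsd is symmetric and invariant under rigid moves of either set", {
  set.seed(31)
  for (i in 1:10) {
    a <- matrix(stats::rnorm(24), ncol = 3)
    b <- matrix(stats::rnorm(24), ncol = 3)
    r <- kabsch_fit(a, b)$rmsd
    expect_equal(kabsch_fit(b, a)$rmsd, r, tolerance = 1e-9)
    expect_equal(kabsch_fit(rigid_move(a), b)$rmsd, r, tolerance = 1e-9)
    expect_equal(kabsch_fit(a, rigid_move(b))$rmsd, r, tolerance = 1e-9)
  }
})

test_that("mirror images are not superposable to zero", {
  m <- synth_helix(12)$xyz
  mirror <- m %*% diag(c(1, 1, -1))
  fit <- kabsch_fit(m, mirror)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("degenerate geometry is rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "degenerate")
  expect_error(kabsch_fit(synth_helix(4)$xyz[1:2, ], synth_helix(4)$xyz[1:2, ]),
               "at least 3")
  point <- matrix(1, 4, 3)
  expect_error(kabsch_fit(point, point), "degenerate")
})

test_that("clean_structure strips DNA, waters and side-chain atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_mixed_pdb(f)
  m <- clean_structure(f, chain = "A")
  expect_s3_class(m, "structure_model")
  expect_equal(length(m$resno), 10L)
  expect_equal(m$resid[1], "MET")
  expect_true(all(diff(m$resno) > 0))
  expect_error(clean_structure(f, chain = "Z"), "chain 'Z'")
  expect_error(clean_structure(f, chain = "B"), "no protein C-alpha")
})

test_that("multi-model files default to the first reported member", {
  f <- withr::local_tempfile(fileext = ".pdb")
  make_mixed_pdb(f, n_models = 3L)
  m1 <- clean_structure(f, chain = "A")
  m2 <- clean_structure(f, chain = "A", model_index = 2L)
  expect_equal(m2$xyz[, 1] - m1$xyz[, 1], rep(1, 10))
  expect_error(clean_structure(f, chain = "A", model_index = 9L),
               "model 9")
})

test_that("superpose_ensemble gives zero rmsd for rigid copies of the reference", {
  ref <- synth_helix(20, id = "ref")
  copy <- ref; copy$id <- "copy"
  set.seed(5)
  copy$xyz <- rigid_move(ref$xyz)
  seq1 <- paste(rep("A", 20), collapse = "")
  corr <- aligned_set(c("ref", "copy"), c(seq1, seq1),
                      reference_id = "ref")
  fits <- superpose_ensemble(list(copy), ref, corr)
  expect_lt(fits$copy$rmsd, 1e-9)
  expect_equal(fits$copy$coords, ref$xyz, tolerance = 1e-9)
})

test_that("alignment-guided pairing handles gapped rows", {
  ref <- synth_helix(8, id = "ref")
  # mobile structure missing residues 3-4 relative to the reference
  mob <- structure_model("mob", 1:6, rep("ALA", 6),
                         ref$xyz[c(1, 2, 5, 6, 7, 8), ])
  corr <- aligned_set(c("ref", "mob"),
                      c("AAAAAAAA", "AA--AAAA"), reference_id = "ref")
  fits <- superpose_ensemble(list(mob), ref, corr)
  expect_equal(fits$mob$n_pairs, 6L)
  expect_lt(fits$mob$rmsd, 1e-9)
  expect_equal(fits$mob$ref_resno, c(1L, 2L, 5L, 6L, 7L, 8L))
})

test_that("a structure contradicting its alignment row is rejected", {
  ref <- synth_helix(8, id = "ref")
  mob <- structure_model("mob", 1:8, c(rep("ALA", 7), "GLY"), ref$xyz)
  corr <- aligned_set(c("ref", "mob"), c("AAAAAAAA", "AAAAAAAA"),
                      reference_id = "ref")
  expect_error(superpose_ensemble(list(mob), ref, corr),
               "does not match its alignment row")
  mob2 <- structure_model("other", 1:8, rep("ALA", 8), ref$xyz)
  expect_error(superpose_ensemble(list(mob2), ref, corr), "no row")
})

test_that("a locally displaced copy shows elevated deviation only in the window", {
  ref <- synth_helix(79, id = "ref")
  mob <- ref; mob$id <- "mob"
  win <- 30:50
  mob$xyz[win, ] <- mob$xyz[win, ] + matrix(rep(c(2, 0, 0), each = length(win)),
                                            ncol = 3)
  seqs <- strrep("A", 79)
  corr <- aligned_set(c("ref", "mob"), c(seqs, seqs), reference_id = "ref")
  fits <- superpose_ensemble(list(mob), ref, corr)
  dev <- fits$mob$per_residue_deviation
  expect_gt(mean(dev[win]), mean(dev[-win]))
  expect_gt(min(dev[win]), max(dev[setdiff(1:20, win)]))
})

test_that("ensemble superposition is independent of structure order", {
  ref <- synth_helix(15, id = "ref")
  set.seed(9)
  mk <- function(id) {
    m <- ref; m$id <- id
    m$xyz <- rigid_move(ref$xyz + matrix(stats::rnorm(45, sd = 0.3),
                                         ncol = 3))
    m
  }
  a <- mk("a"); b <- mk("b")
  s <- strrep("A", 15)
  corr <- aligned_set(c("ref", "a", "b"), c(s, s, s), reference_id = "ref")
  f1 <- superpose_ensemble(list(a, b), ref, corr)
  f2 <- superpose_ensemble(list(b, a), ref, corr)
  expect_equal(f1$a$rmsd, f2$a$rmsd, tolerance = 1e-12)
  expect_equal(f1$b$coords, f2$b$coords, tolerance = 1e-12)
})

test_that("trim_ensemble drops residues with high cross-member spread", {
  ref <- synth_helix(20, id = "ens")
  set.seed(2)
  members <- lapply(1:5, function(k) {
    m <- ref
    if (k > 1) m$xyz[15:20, ] <- m$xyz[15:20, ] +
        matrix(stats::rnorm(18, sd = 4), ncol = 3)
    m
  })
  trimmed <- trim_ensemble(members, spread_threshold = 2.0)
  expect_true(setequal(trimmed$resno, 1:14))
  expect_equal(trim_ensemble(members[1]), ref)
})
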