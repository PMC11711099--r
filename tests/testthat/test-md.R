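test_that("angular differences are wrap-aware and minimal", {
  expect_identical(angularDifference(10, 10), 0)
  expect_identical(angularDifference(170, -170), -20)
  expect_identical(abs(angularDifference(170, -170)), 20)
  expect_identical(angularDifference(-180, 180), 0)
  expect_identical(angularDifference(90, -90), 180)
  set.seed(1)
  a <- runif(200, -180, 179.9)
  b <- runif(200, -180, 179.9)
  d <- angularDifference(a, b)
  expect_true(all(d > -180 & d <= 180))
  expect_equal(d, oracle_ang_diff(a, b), tolerance = 1e-9)
})

test_that("the deviation statistic reproduces the hand example", {
  wt <- DihedralTrajectory(matrix(10, 1, 3))
  mut <- DihedralTrajectory(matrix(c(10, 20, 40), 1))
  expect_identical(fSim(wt, mut, 1), 500)
  # identical constant trajectories score zero at every admissible t'
  flat <- DihedralTrajectory(matrix(5, 2, 4))
  for (tp in 1:3) expect_identical(fSim(flat, flat, tp), 0)
  # quadratic homogeneity: doubling deviations quadruples the statistic
  mut2 <- DihedralTrajectory(matrix(c(10, 30, 70), 1))
  expect_identical(fSim(wt, mut2, 1), 2000)
  expect_error(fSim(wt, mut, 3), "tPrime")
})

test_that("both statistic variants match the naive double-loop oracle", {
  set.seed(19)
  for (rep in 1:60) {
    nres <- sample(1:5, 1)
    nsnap <- sample(3:10, 1)
    pair <- random_trajectory_pair(nres, nsnap, seed = 1000 + rep)
    wt <- DihedralTrajectory(pair$wt)
    mut <- DihedralTrajectory(pair$mut)
    tp <- sample(seq_len(nsnap - 1), 1)
    for (variant in c("printed", "time-matched")) {
      expect_equal(fSim(wt, mut, tp, variant),
                   oracle_fsim(pair$wt, pair$mut, tp, variant),
                   tolerance = 1e-9)
    }
  }
})

test_that("the statistic is invariant under a common rotation", {
  pair <- random_trajectory_pair(4, 8, seed = 5)
  rot <- function(m, deg) ((m + deg + 180) %% 360) - 180
  for (deg in c(37, 120, -90)) {
    expect_equal(
      fSim(DihedralTrajectory(pair$wt), DihedralTrajectory(pair$mut), 3),
      fSim(DihedralTrajectory(rot(pair$wt, deg)),
           DihedralTrajectory(rot(pair$mut, deg)), 3),
      tolerance = 1e-9)
  }
})

test_that("deviation profiles cover the admissible window", {
  spec <- trajectorySpec(nResidues = 5, nSnapshots = 50, seed = 4)
  pair <- makeTrajectoryPair(spec)
  prof <- fSimProfile(pair$wt, pair$mut, windowNs = 2)
  # 2 ns at 100 ps spacing = 20 admissible snapshots, minus the final one
  expect_identical(nrow(prof), 20L)
  expect_true(all(prof$f_sim >= 0))
  # a trajectory compared with itself is exactly zero under the
  # time-matched variant (the printed variant freezes the reference at
  # t', so it is nonzero for any time-varying series)
  profall <- fSimProfile(pair$wt, pair$wt, windowNs = Inf,
                         variant = "time-matched")
  expect_identical(nrow(profall), 49L)
  expect_true(all(profall$f_sim == 0))
  # a late perturbation inflates late-window deviations
  pert <- makeTrajectoryPair(trajectorySpec(nResidues = 5,
    nSnapshots = 50, perturbation = list(residues = 1:2,
                                         window = c(40, 50),
                                         amplitude = 80), seed = 4))
  expect_gt(mean(fSimProfile(pert$wt, pert$mut, windowNs = 1)$f_sim),
            mean(fSimProfile(pair$wt, pair$mut, windowNs = 1)$f_sim))
})

test_that("per-residue correlations behave on analytic cases", {
  t3 <- c(0, 10, 20)
  wt <- DihedralTrajectory(rbind(t3, t3 * 2))
  expect_identical(dihedralCorrelations(wt, wt)$pearson_r, c(1, 1))
  mirror <- DihedralTrajectory(rbind(-t3, -t3 * 2))
  expect_equal(dihedralCorrelations(wt, mirror)$pearson_r, c(-1, -1))
  scaled <- DihedralTrajectory(rbind(c(0, 20, 40), c(0, 40, 80)))
  expect_equal(dihedralCorrelations(wt, scaled)$pearson_r, c(1, 1))
  # zero-variance residues are skipped with a warning
  flat <- DihedralTrajectory(rbind(t3, c(7, 7, 7)))
  expect_warning(corr <- dihedralCorrelations(wt, flat), "zero-variance")
  expect_identical(corr$residue, 1L)
  expect_error(dihedralCorrelations(
    DihedralTrajectory(matrix(1:2, 1)),
    DihedralTrajectory(matrix(1:2, 1))), "3 snapshots")
  s <- correlationSummary(data.frame(residue = 1:3,
                                     pearson_r = c(0.2, 0.5, 0.9)))
  expect_identical(s$median, 0.5)
  expect_identical(s$n, 3L)
})

test_that("random controls mutate the best mutant's positions afresh", {
  wt <- ProteinSeq("wt", "MKTAYIAKQR")
  best <- MutantRecord("wt", list(parseMutation("K2A"),
                                  parseMutation("Y5W")),
                       applyMutations(wt, list(parseMutation("K2A"),
                                               parseMutation("Y5W"))))
  set.seed(6)
  ctls <- makeRandomControls(wt, best, n = 5)
  expect_length(ctls, 5)
  for (ctl in ctls) {
    pos <- vapply(ctl@mutations, function(m) m@position, integer(1))
    expect_identical(pos, c(2L, 5L))
    chars <- strsplit(residues(ctl), "")[[1]]
    expect_false(chars[2] %in% c("A", "K"))
    expect_false(chars[5] %in% c("W", "Y"))
  }
  set.seed(6)
  ctls2 <- makeRandomControls(wt, best, n = 5)
  expect_identical(vapply(ctls2, residues, character(1)),
                   vapply(ctls, residues, character(1)))
  expect_error(makeRandomControls(wt, MutantRecord("wt", list(), wt)),
               "no mutations")
})

test_that("the poly-proline control lands inside one helix", {
  wt <- randomProtein(40, seed = 8, id = "wt")
  hel <- HelixAnnotation(list(c(4, 12), c(20, 30)))
  set.seed(2)
  for (rep in 1:10) {
    ctl <- makeProlineControl(wt, hel)
    s <- residues(ctl)
    pos <- regexpr("PPPPP", s)[1]
    expect_gt(pos, 0)
    inside <- (pos >= 4 && pos + 4 <= 12) || (pos >= 20 && pos + 4 <= 30)
    expect_true(inside)
    expect_identical(nchar(s), 40L)
  }
  # a length-5 helix admits exactly one placement
  hel5 <- HelixAnnotation(list(c(7, 11)))
  ctl5 <- makeProlineControl(wt, hel5)
  expect_identical(substr(residues(ctl5), 7, 11), "PPPPP")
  expect_error(HelixAnnotation(list(c(3, 6))), "at least 5")
  expect_error(HelixAnnotation(list(c(1, 6), c(4, 10))), "overlap")
})

test_that("dihedral tables round-trip through TSV and CSV", {
  spec <- trajectorySpec(nResidues = 4, nSnapshots = 6, seed = 12)
  phi <- makeTrajectoryPair(spec, "phi")$wt
  psi <- makeTrajectoryPair(trajectorySpec(nResidues = 4, nSnapshots = 6,
                                           seed = 13), "psi")$wt
  for (ext in c(".tsv", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    writeDihedralTable(phi, psi, path)
    back <- readDihedralTable(path)
    expect_equal(angleMatrix(back$phi), unname(angleMatrix(phi)),
                 tolerance = 1e-9)
    expect_equal(angleMatrix(back$psi), unname(angleMatrix(psi)),
                 tolerance = 1e-9)
    expect_equal(snapshotTimes(back$phi), snapshotTimes(phi))
  }
})

test_that("the foldability stub demands a backend and validates it", {
  expect_error(predictFoldability("MKT"), "backend")
  good <- function(s) rep(80, nchar(s))
  expect_identical(predictFoldability("MKT", good), c(80, 80, 80))
  expect_error(predictFoldability("MKT", function(s) 1), "per residue")
})
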