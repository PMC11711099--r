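test_that("random proteins are canonical and seed-reproducible", {
  p <- randomProtein(30, seed = 1)
  expect_identical(seqLength(p), 30L)
  expect_identical(residues(randomProtein(30, seed = 1)), residues(p))
  expect_false(residues(randomProtein(100, seed = 2)) ==
                 residues(randomProtein(100, seed = 3)))
  expect_error(randomProtein(0), ">= 1")
})

test_that("synthetic alignments carry the requested conservation", {
  msa <- makeSyntheticMsa("MKTAYIAKQR", n = 50, conservation = 0.8,
                          seed = 4)
  expect_identical(dim(msa), c(50L, 10L))
  cons <- strsplit("MKTAYIAKQR", "")[[1]]
  frac <- mean(t(msa) == cons)
  # 0.8 direct retention plus 1/20 chance of redrawing the consensus
  expect_gt(frac, 0.75)
  expect_lt(frac, 0.9)
  expect_identical(makeSyntheticMsa("MKT", n = 5, seed = 9),
                   makeSyntheticMsa("MKT", n = 5, seed = 9))
})

test_that("target-match landscapes score the fraction of matches", {
  f <- makeLandscape(landscapeSpec("target_match", target = "MKT"))
  expect_identical(f("MKT"), 1)
  expect_equal(f("MAT"), 2 / 3)
  expect_identical(attr(f, "optimum"), 1)
  f10 <- makeLandscape(landscapeSpec("target_match",
                                     target = strrep("A", 10)))
  expect_identical(f10(paste0(strrep("A", 9), "C")), 0.9)
})

test_that("additive landscapes sum per-site weights", {
  W <- matrix(0, 20, 3, dimnames = list(AA_ALPHABET, NULL))
  f0 <- makeLandscape(landscapeSpec("additive", weights = W))
  expect_identical(f0("MKT"), 0)
  W["M", 1] <- 2; W["K", 2] <- 3; W["Y", 3] <- 5
  f <- makeLandscape(landscapeSpec("additive", weights = W))
  expect_identical(f("MKT"), 5)
  expect_identical(f("MKY"), 10)
  expect_identical(attr(f, "optimum"), 10)
})

test_that("reaction datasets expose their latent ground truth", {
  spec <- reactionSpec(nReported = 40, nRandom = 30, embedDim = 4,
                       delta = 2, noiseSd = 0, seed = 6)
  ds <- makeReactionDataset(spec)
  expect_identical(nrow(ds$records), 70L)
  expect_identical(sum(ds$records$label == "reported"), 40L)
  # strings are unique and the embedder reproduces the stored latents
  expect_identical(anyDuplicated(ds$records$substrate_smiles), 0L)
  expect_identical(anyDuplicated(ds$records$enzyme_seq), 0L)
  i <- 17
  expect_identical(ds$embedders$substrate(ds$records$substrate_smiles[i]),
                   unname(ds$latents$substrate[i, ]))
  expect_identical(ds$embedders$enzyme(ds$records$enzyme_seq[i]),
                   unname(ds$latents$enzyme[i, ]))
  # noiseless kcat is exactly the generator function of the latents
  expect_equal(log10(ds$records$kcat_s1[i]),
               unname(ds$latents$substrate[i, 1] +
                        0.5 * ds$latents$enzyme[i, 1]),
               tolerance = 1e-12)
  # byte-identical reruns
  ds2 <- makeReactionDataset(spec)
  expect_identical(ds2$records, ds$records)
  # class shift: reported minus random latent means differ by delta
  # along the shifted coordinates (total Euclidean size delta)
  sep <- vapply(ds$latents, function(z)
    mean(z[ds$records$label == "reported", 1]) -
      mean(z[ds$records$label == "random", 1]), numeric(1))
  expect_equal(unname(sep), rep(2 / sqrt(3), 3), tolerance = 0.5)
})

test_that("trajectory pairs honour spacing, wrap and perturbation", {
  spec <- trajectorySpec(nResidues = 8, nSnapshots = 20, seed = 3)
  pair <- makeTrajectoryPair(spec)
  expect_identical(snapshotTimes(pair$wt), (0:19) * 100)
  expect_true(all(angleMatrix(pair$mut) >= -180 &
                    angleMatrix(pair$mut) < 180))
  # zero noise and no perturbation: the pair is identical, and the
  # time-matched deviation is exactly zero
  quiet <- makeTrajectoryPair(trajectorySpec(nResidues = 4,
    nSnapshots = 10, thermalNoiseSd = 0, seed = 5))
  expect_identical(angleMatrix(quiet$wt), angleMatrix(quiet$mut))
  expect_identical(fSim(quiet$wt, quiet$mut, 2, "time-matched"), 0)
  # a localized perturbation inflates the deviation statistic
  pert <- makeTrajectoryPair(trajectorySpec(nResidues = 8,
    nSnapshots = 20, perturbation = list(residues = 5:7,
                                         window = c(10, 20),
                                         amplitude = 60), seed = 3))
  expect_gt(mean(fSimProfile(pert$wt, pert$mut, Inf)$f_sim),
            mean(fSimProfile(pair$wt, pair$mut, Inf)$f_sim))
  expect_error(trajectorySpec(nSnapshots = 10,
    perturbation = list(residues = 1, window = c(5, 12), amplitude = 10)),
    "outside")
  # pure functions of spec + seed
  expect_identical(angleMatrix(makeTrajectoryPair(spec)$wt),
                   angleMatrix(pair$wt))
})

test_that("generated objects satisfy their container invariants", {
  # generator output passes the S4 validity checks of its target types
  expect_true(validObject(makeTrajectoryPair(
    trajectorySpec(seed = 8))$mut))
  expect_true(validObject(randomProtein(12, seed = 8)))
  expect_silent(validateReactionTable(
    makeReactionDataset(reactionSpec(nReported = 10, nRandom = 10,
                                     seed = 1))$records,
    requireLabel = TRUE, requireKcat = TRUE))
})
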