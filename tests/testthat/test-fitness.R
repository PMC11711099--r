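test_that("reaction-table validation catches schema violations", {
  df <- tiny_reaction_table()
  expect_silent(validateReactionTable(df, requireLabel = TRUE,
                                      requireKcat = TRUE))
  expect_error(validateReactionTable(df[, -1]), "missing column")
  bad <- df; bad$kcat_s1[2] <- -1
  expect_error(validateReactionTable(bad, requireKcat = TRUE),
               "positive")
  bad2 <- df; bad2$label[1] <- "maybe"
  expect_error(validateReactionTable(bad2, requireLabel = TRUE),
               "label")
  path <- withr::local_tempfile(fileext = ".csv")
  writeReactionTable(df, path)
  expect_identical(readReactionTable(path)$enzyme_seq, df$enzyme_seq)
})

test_that("negative pairings never collide with reported triples", {
  df <- tiny_reaction_table(8)
  df$label <- "reported"
  set.seed(21)
  for (rep in 1:10) {
    neg <- makeNegativePairs(df)
    expect_identical(nrow(neg), 8L)
    expect_true(all(neg$label == "random"))
    key <- function(d) paste(d$substrate_smiles, d$product_smiles,
                             d$enzyme_seq)
    expect_length(intersect(key(neg), key(df)), 0)
    # permutations preserve the column multisets
    expect_setequal(neg$substrate_smiles, df$substrate_smiles)
  }
  set.seed(33); n1 <- makeNegativePairs(df)
  set.seed(33); n2 <- makeNegativePairs(df)
  expect_identical(n1, n2)
  expect_error(makeNegativePairs(df[1:2, ]), "at least 3")
})

test_that("embedders honour the declared-dimension contract", {
  e <- hashEmbedder(4)
  expect_identical(embedderDim(e), 4L)
  expect_length(e("CCO"), 4)
  expect_identical(e("CCO"), e("CCO"))
  expect_false(identical(e("CCO"), e("CCN")))
  tab <- matrix(1:6 / 10, 2, 3,
                dimnames = list(c("AAA", "BBB"), NULL))
  te <- tableEmbedder(tab)
  expect_identical(te("AAA"), c(0.1, 0.3, 0.5))
  expect_length(te("unknown-string"), 3)
})

test_that("featurization concatenates the three embeddings", {
  emb <- list(substrate = hashEmbedder(4, 1), product = hashEmbedder(4, 2),
              enzyme = hashEmbedder(8, 3))
  v <- featurizeReaction("CCO", "CCN", "MKTAY", emb)
  expect_length(v, 16)
  expect_identical(v, featurizeReaction("CCO", "CCN", "MKTAY", emb))
  zero <- function(d) {
    f <- function(x) numeric(d); attr(f, "embed_dim") <- d; f
  }
  vz <- featurizeReaction("a", "b", "MKT",
                          list(substrate = zero(2), product = zero(2),
                               enzyme = zero(3)))
  expect_identical(vz, numeric(7))
  bad <- function(x) 1:3
  attr(bad, "embed_dim") <- 5L
  expect_error(featurizeReaction("a", "b", "MKT",
    list(substrate = bad, product = zero(2), enzyme = zero(3))),
    "declared dimension")
})

test_that("the feasibility model recovers a separable latent class", {
  ds <- makeReactionDataset(reactionSpec(nReported = 150, nRandom = 150,
                                         delta = 3, seed = 5))
  model <- trainFeasibility(ds$records, ds$embedders, seed = 5)
  expect_length(model$cv_auc, 5)
  expect_gte(mean(model$cv_auc), 0.9)
  fs <- predictFeasibility(model, ds$records, ds$embedders)
  expect_true(all(fs >= 0 & fs <= 1))
  # training rows of the reported class sit above the boundary
  expect_gt(mean(fs[ds$records$label == "reported"]), 0.5)
  # label flip mirrors the scores around the boundary
  flipped <- ds$records
  flipped$label <- ifelse(flipped$label == "reported", "random",
                          "reported")
  mflip <- trainFeasibility(flipped, ds$embedders, seed = 5)
  fs_flip <- predictFeasibility(mflip, ds$records[1:20, ], ds$embedders)
  expect_lt(mean(fs_flip[ds$records$label[1:20] == "reported"]), 0.5)
  # single-class input is rejected
  one <- ds$records[ds$records$label == "reported", ]
  expect_error(trainFeasibility(one, ds$embedders), "both")
})

test_that("the kcat model recovers a noiseless monotone target", {
  ds <- makeReactionDataset(reactionSpec(nReported = 200, nRandom = 200,
                                         delta = 0, noiseSd = 0,
                                         seed = 9))
  model <- trainKcat(ds$records, ds$embedders, seed = 9)
  expect_gte(model$metrics$r2, 0.85)
  expect_gte(model$metrics$pearson, 0.9)
  pred <- predictKcat(model, ds$records[1:10, ], ds$embedders)
  expect_length(pred, 10)
  # the reference-protocol hyperparameters ride along
  expect_identical(model$hyperparams$eta, 0.09)
  bad <- ds$records; bad$kcat_s1[3] <- 0
  expect_error(trainKcat(bad, ds$embedders), "positive")
})

test_that("degenerate constant kcat is handled without crashing", {
  ds <- makeReactionDataset(reactionSpec(nReported = 30, nRandom = 30,
                                         seed = 2))
  ds$records$kcat_s1 <- 5
  model <- trainKcat(ds$records, ds$embedders, seed = 2)
  expect_identical(model$metrics$r2, 0)
  expect_lt(model$metrics$mse, 1e-6)
})

test_that("the log transform lowers held-out error on log-normal kcat", {
  ds <- makeReactionDataset(reactionSpec(nReported = 250, nRandom = 250,
                                         delta = 0, noiseSd = 0.2,
                                         seed = 31))
  with_log <- trainKcat(ds$records, ds$embedders, seed = 31)
  without <- trainKcat(ds$records, ds$embedders, seed = 31,
                       logTransform = FALSE)
  expect_lt(with_log$metrics$mse, without$metrics$mse)
})

test_that("fitness closures score enzymes for a fixed reaction", {
  ds <- makeReactionDataset(reactionSpec(nReported = 60, nRandom = 60,
                                         delta = 3, seed = 12))
  model <- trainFeasibility(ds$records, ds$embedders, seed = 12)
  row <- ds$records[1, ]
  f <- feasibilityFitness(model, row$substrate_smiles,
                          row$product_smiles, ds$embedders)
  val <- f(row$enzyme_seq)
  expect_true(val >= 0 && val <= 1)
  expect_identical(val, f(row$enzyme_seq))
})
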