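#' Reaction tables
#'
#' A reaction table is a data.frame with one biocatalytic reaction per row:
#' columns `substrate_smiles`, `product_smiles`, `enzyme_seq` (canonical
#' protein residues), `label` (`"reported"` for curated substrate-product-
#' enzyme associations, `"random"` for scrambled negatives), optional
#' `kcat_s1` (turnover number, 1/s, positive) and `ec_class`.
#' `validateReactionTable()` checks the schema and invariants and returns
#' the table invisibly.
#'
#' @param df a reaction data.frame.
#' @param requireLabel require the label column to be filled.
#' @param requireKcat require positive kcat on every row.
#' @return `df`, invisibly.
#' @export
validateReactionTable <- function(df, requireLabel = FALSE,
                                  requireKcat = FALSE) {
  need <- c("substrate_smiles", "product_smiles", "enzyme_seq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reaction table missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty reaction table")
  for (s in df$enzyme_seq) .check_residue_string(s, "enzyme_seq")
  if (requireLabel) {
    if (is.null(df$label) || anyNA(df$label) ||
        !all(df$label %in% c("reported", "random")))
      stop("label column must be 'reported' or 'random' on every row")
  }
  if (requireKcat) {
    if (is.null(df$kcat_s1) || anyNA(df$kcat_s1))
      stop("kcat_s1 column required on every row")
    if (any(df$kcat_s1 <= 0))
      stop("kcat_s1 must be positive (found ",
           sum(df$kcat_s1 <= 0), " non-positive value(s))")
  }
  invisible(df)
}

#' Read/write reaction tables as CSV
#' @param path CSV path.
#' @rdname validateReactionTable
#' @export
readReactionTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateReactionTable(df)
  df
}

#' @rdname validateReactionTable
#' @export
writeReactionTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate scrambled negative reaction pairings
#'
#' Augments a table of curated (`"reported"`) reactions with an equal number
#' of `"random"` rows, built by independently permuting the substrate,
#' product and enzyme columns. No generated triple may coincide with any
#' reported triple; colliding rows are re-permuted, with a bounded retry
#' budget for degenerate tiny inputs.
#'
#' @param reported reaction table of reported rows (>= 3 rows).
#' @param maxRetries retry budget for collision repair.
#' @return A reaction table of the same size, all labels `"random"`, kcat
#'   dropped.
#' @export
makeNegativePairs <- function(reported, maxRetries = 100L) {
  validateReactionTable(reported)
  n <- nrow(reported)
  if (n < 3L) stop("need at least 3 reported reactions to scramble")
  key <- function(s, p, e) paste(s, p, e, sep = "\r")
  reported_keys <- key(reported$substrate_smiles, reported$product_smiles,
                       reported$enzyme_seq)
  for (attempt in seq_len(maxRetries)) {
    s <- reported$substrate_smiles[sample.int(n)]
    p <- reported$product_smiles[sample.int(n)]
    e <- reported$enzyme_seq[sample.int(n)]
    if (!any(key(s, p, e) %in% reported_keys)) {
      return(data.frame(substrate_smiles = s, product_smiles = p,
                        enzyme_seq = e, label = "random",
                        kcat_s1 = NA_real_, ec_class = NA_character_,
                        stringsAsFactors = FALSE))
    }
  }
  stop("could not build collision-free random pairings after ", maxRetries,
       " attempts (degenerate input)")
}

#' Featurize a reaction as concatenated embeddings
#'
#' Builds the feature vector `[substrate || product || enzyme]` used by both
#' fitness models; total length is the sum of the three declared embedder
#' dimensions.
#'
#' @param substrate,product molecule strings.
#' @param enzyme protein residue string.
#' @param embedders named list with elements `substrate`, `product`,
#'   `enzyme`, each an embedder (see [hashEmbedder()]). `product` may be
#'   omitted for kcat features.
#' @return Numeric feature vector.
#' @export
featurizeReaction <- function(substrate, product = NULL, enzyme, embedders) {
  parts <- list(.embed_checked(embedders$substrate, substrate, "substrate"))
  if (!is.null(product) && !is.null(embedders$product))
    parts <- c(parts, list(.embed_checked(embedders$product, product,
                                          "product")))
  c(unlist(parts), .embed_checked(embedders$enzyme, enzyme, "enzyme"))
}

# feature matrix for a whole table; useProduct = FALSE for the kcat model
.feature_matrix <- function(df, embedders, useProduct = TRUE) {
  t(vapply(seq_len(nrow(df)), function(i)
    featurizeReaction(df$substrate_smiles[i],
                      if (useProduct) df$product_smiles[i] else NULL,
                      df$enzyme_seq[i], embedders),
    numeric(sum(vapply(
      embedders[c("substrate", if (useProduct) "product", "enzyme")],
      embedderDim, integer(1L))))))
}

# stratified fold assignment: each class spread evenly over folds
.stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Train the reaction-feasibility classifier
#'
#' A random forest of 100 trees (Gini impurity splitting) over concatenated
#' substrate/product/enzyme embeddings, distinguishing `"reported"` from
#' `"random"` reactions. Performance is estimated by stratified k-fold
#' cross-validation (per-fold held-out AUC); the returned model is refit on
#' all rows.
#'
#' @param df labeled reaction table (both labels present, at least `folds`
#'   rows per label).
#' @param embedders named list of `substrate`, `product`, `enzyme`
#'   embedders.
#' @param folds number of CV folds (default 5).
#' @param ntree forest size (default 100).
#' @param seed RNG seed for fold assignment and forest training.
#' @return A `FeasibilityModel` (list with the fitted forest, per-fold AUC
#'   in `$cv_auc`, and the embedder dimensions).
#' @export
trainFeasibility <- function(df, embedders, folds = 5L, ntree = 100L,
                             seed = 1L) {
  validateReactionTable(df, requireLabel = TRUE)
  y <- factor(df$label, levels = c("random", "reported"))
  if (nlevels(droplevels(y)) < 2L)
    stop("feasibility training needs both 'reported' and 'random' rows")
  if (min(table(y)) < folds)
    stop("need at least ", folds, " rows per label for ", folds,
         "-fold cross-validation")
  set.seed(seed)
  X <- .feature_matrix(df, embedders, useProduct = TRUE)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fold <- .stratified_folds(df$label, folds)
  cv_auc <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                     ntree = ntree)
    p <- stats::predict(rf, X[!tr, , drop = FALSE],
                        type = "prob")[, "reported"]
    as.numeric(pROC::auc(pROC::roc(response = y[!tr], predictor = p,
                                   levels = c("random", "reported"),
                                   direction = "<", quiet = TRUE)))
  }, numeric(1L))
  rf_full <- randomForest::randomForest(X, y, ntree = ntree)
  structure(list(forest = rf_full, cv_auc = cv_auc, folds = folds,
                 ntree = ntree, seed = seed,
                 dims = vapply(embedders[c("substrate", "product",
                                           "enzyme")],
                               embedderDim, integer(1L))),
            class = "FeasibilityModel")
}

#' @export
print.FeasibilityModel <- function(x, ...) {
  cat("FeasibilityModel: random forest,", x$ntree, "trees,",
      x$folds, "-fold CV mean AUC", round(mean(x$cv_auc), 4), "\n")
  invisible(x)
}

#' Score reaction feasibility
#'
#' The feasibility score F_s is the fraction of forest trees voting
#' `"reported"` — a probability in [0, 1] that the enzyme catalyzes the
#' substrate-to-product transformation; 0.5 is the reported/random decision
#' boundary.
#'
#' @param model a `FeasibilityModel` from [trainFeasibility()].
#' @param df reaction table rows to score.
#' @param embedders the embedders used at training time.
#' @return Numeric vector of F_s values in [0, 1].
#' @export
predictFeasibility <- function(model, df, embedders) {
  stopifnot(inherits(model, "FeasibilityModel"))
  X <- .feature_matrix(df, embedders, useProduct = TRUE)
  if (ncol(X) != sum(model$dims))
    stop("feature dimension ", ncol(X), " does not match the model's ",
         sum(model$dims))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  as.numeric(stats::predict(model$forest, X, type = "prob")[, "reported"])
}

#' Reference-protocol boosting hyperparameters for the kcat model
#' @return Named list of xgboost parameters.
#' @export
kcatHyperparams <- function() {
  list(eta = 0.09, max_delta_step = 1.19, min_child_weight = 2.82,
       alpha = 1.94, lambda = 4.95)
}

#' Train the turnover-number (kcat) regressor
#'
#' Gradient-boosted trees over concatenated substrate and enzyme embeddings
#' predicting log-transformed kcat (base-10 by default; the log transform
#' linearizes the target and damps outliers, and can be disabled for
#' comparison). Hyperparameters default to [kcatHyperparams()]. Metrics
#' (MSE, R-squared, Pearson r on the log scale) are computed on a random
#' 80/20 held-out split; the returned model is refit on all rows.
#'
#' @param df reaction table with positive `kcat_s1` on every row.
#' @param embedders named list with `substrate` and `enzyme` embedders.
#' @param hyperparams xgboost parameter list.
#' @param nrounds boosting rounds (default 300).
#' @param holdout held-out fraction for metrics (default 0.2).
#' @param logBase base of the log transform (default 10).
#' @param logTransform set `FALSE` to fit raw kcat (metrics are still
#'   reported on the log scale, for comparability).
#' @param seed RNG seed for the split and boosting.
#' @return A `KcatModel` (list with the booster and `$metrics`).
#' @export
trainKcat <- function(df, embedders, hyperparams = kcatHyperparams(),
                      nrounds = 300L, holdout = 0.2, logBase = 10,
                      logTransform = TRUE, seed = 1L) {
  validateReactionTable(df, requireKcat = TRUE)
  set.seed(seed)
  X <- .feature_matrix(df, embedders, useProduct = FALSE)
  y_log <- log(df$kcat_s1, base = logBase)
  y_fit <- if (logTransform) y_log else df$kcat_s1
  n <- nrow(df)
  test <- sample.int(n, max(1L, round(holdout * n)))
  params <- c(hyperparams, list(objective = "reg:squarederror"))
  fit <- function(rows) {
    xgboost::xgb.train(params = params,
      data = xgboost::xgb.DMatrix(X[rows, , drop = FALSE],
                                  label = y_fit[rows]),
      nrounds = nrounds, verbose = 0)
  }
  m_tr <- fit(setdiff(seq_len(n), test))
  pred_raw <- stats::predict(m_tr, xgboost::xgb.DMatrix(
    X[test, , drop = FALSE]))
  # metrics always on the log scale; raw-target fits are clamped at a
  # tiny positive value before the transform
  pred_log <- if (logTransform) pred_raw else
    log(pmax(pred_raw, .Machine$double.eps), base = logBase)
  obs <- y_log[test]
  mse <- mean((pred_log - obs)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum((pred_log - obs)^2) / ss_tot
  pearson <- if (stats::sd(obs) == 0 || stats::sd(pred_log) == 0)
    NA_real_ else stats::cor(obs, pred_log)
  booster <- fit(seq_len(n))
  structure(list(booster = booster, hyperparams = hyperparams,
                 nrounds = nrounds, logBase = logBase,
                 logTransform = logTransform, seed = seed,
                 dims = vapply(embedders[c("substrate", "enzyme")],
                               embedderDim, integer(1L)),
                 metrics = list(mse = mse, r2 = r2, pearson = pearson,
                                n_test = length(test))),
            class = "KcatModel")
}

#' @export
print.KcatModel <- function(x, ...) {
  cat("KcatModel: xgboost,", x$nrounds, "rounds, held-out log-scale R2",
      round(x$metrics$r2, 4), "MSE", round(x$metrics$mse, 4), "\n")
  invisible(x)
}

#' Predict log-kcat for reaction rows
#'
#' @param model a `KcatModel`.
#' @param df reaction table rows.
#' @param embedders the embedders used at training time.
#' @return Predicted kcat on the log scale (the model's `logBase`).
#' @export
predictKcat <- function(model, df, embedders) {
  stopifnot(inherits(model, "KcatModel"))
  X <- .feature_matrix(df, embedders, useProduct = FALSE)
  if (ncol(X) != sum(model$dims))
    stop("feature dimension ", ncol(X), " does not match the model's ",
         sum(model$dims))
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(X))
  if (model$logTransform) p else
    log(pmax(p, .Machine$double.eps), base = model$logBase)
}

#' Fitness closures over the trained models
#'
#' Freeze a reaction context (substrate, product) and return a function of
#' the enzyme residue string, suitable as the `fitness` argument of
#' [runGA()]: `feasibilityFitness` returns F_s, `kcatFitness` the predicted
#' log-kcat.
#'
#' @param model a `FeasibilityModel` or `KcatModel`.
#' @param substrate,product the fixed reaction molecules.
#' @param embedders embedders matching the model.
#' @return `function(enzyme_residues) -> numeric`.
#' @export
feasibilityFitness <- function(model, substrate, product, embedders) {
  function(enzyme) {
    predictFeasibility(model,
      data.frame(substrate_smiles = substrate, product_smiles = product,
                 enzyme_seq = enzyme, stringsAsFactors = FALSE), embedders)
  }
}

#' @rdname feasibilityFitness
#' @export
kcatFitness <- function(model, substrate, embedders) {
  function(enzyme) {
    predictKcat(model,
      data.frame(substrate_smiles = substrate, product_smiles = "",
                 enzyme_seq = enzyme, stringsAsFactors = FALSE), embedders)
  }
}
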