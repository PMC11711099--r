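#' GAConfig: parameters of the evolutionary loop
#'
#' Defaults follow the reference protocol: population 500, 30 generations,
#' top 80% retained each iteration. The crossover rate (probability that a
#' refill slot is produced by recombining two distinct survivors rather than
#' copying one) defaults to 0.5; single-point crossover is the default
#' operator, with uniform crossover available behind `crossoverType`.
#'
#' @slot populationSize individuals per generation (>= 2).
#' @slot generations iteration budget (>= 1).
#' @slot retainFraction fraction of top scorers retained, in (0, 1].
#' @slot crossoverRate probability a refill slot uses crossover, in [0, 1].
#' @slot crossoverType `"single_point"` or `"uniform"`.
#' @slot strategyConfig the [StrategyConfig-class] used for mutation.
#' @slot seed integer seed; all randomness in [runGA()] flows from it.
#' @slot stopOnScore optional early-stopping score (`NA` = generation
#'   budget only).
#' @slot clampPolicy how children exceeding the wild-type mutation budget
#'   are repaired: `"newest_first"` (default) reverts freshly introduced
#'   mutations before selection-vetted ones, `"uniform"` reverts uniformly
#'   among all differences.
#' @export
setClass("GAConfig",
  representation(populationSize = "integer", generations = "integer",
                 retainFraction = "numeric", crossoverRate = "numeric",
                 crossoverType = "character",
                 strategyConfig = "StrategyConfig", seed = "integer",
                 stopOnScore = "numeric", clampPolicy = "character"),
  prototype(populationSize = 500L, generations = 30L, retainFraction = 0.8,
            crossoverRate = 0.5, crossoverType = "single_point",
            seed = 1L, stopOnScore = NA_real_,
            clampPolicy = "newest_first"))

setValidity("GAConfig", function(object) {
  if (object@populationSize < 2L) return("populationSize must be >= 2")
  if (object@generations < 1L) return("generations must be >= 1")
  if (!(object@retainFraction > 0 && object@retainFraction <= 1))
    return("retainFraction must lie in (0, 1]")
  if (object@crossoverRate < 0 || object@crossoverRate > 1)
    return("crossoverRate must lie in [0, 1]")
  if (!object@crossoverType %in% c("single_point", "uniform"))
    return("crossoverType must be 'single_point' or 'uniform'")
  if (!object@clampPolicy %in% c("newest_first", "uniform"))
    return("clampPolicy must be 'newest_first' or 'uniform'")
  TRUE
})

#' @param populationSize,generations,retainFraction,crossoverRate
#'   see slot documentation.
#' @param crossoverType,strategyConfig,seed,stopOnScore see slots.
#' @rdname GAConfig-class
#' @export
GAConfig <- function(populationSize = 500L, generations = 30L,
                     retainFraction = 0.8, crossoverRate = 0.5,
                     crossoverType = "single_point",
                     strategyConfig = StrategyConfig(), seed = 1L,
                     stopOnScore = NA_real_,
                     clampPolicy = "newest_first") {
  new("GAConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      retainFraction = retainFraction, crossoverRate = crossoverRate,
      crossoverType = crossoverType, strategyConfig = strategyConfig,
      seed = as.integer(seed), stopOnScore = as.numeric(stopOnScore),
      clampPolicy = clampPolicy)
}

setMethod("show", "GAConfig", function(object) {
  cat("GAConfig: population ", object@populationSize, ", ",
      object@generations, " generations, retain ",
      object@retainFraction * 100, "%, crossover rate ",
      object@crossoverRate, " (", object@crossoverType, "), seed ",
      object@seed, "\n", sep = "")
})

#' Population: one GA generation
#'
#' Fixed-length design: all member sequences share one length. Members are
#' [MutantRecord-class] objects; a member is "scored" once its `scores`
#' vector carries a `fitness` entry.
#'
#' @slot generationIndex 1-based generation counter.
#' @slot members list of [MutantRecord-class].
#' @export
setClass("Population",
  representation(generationIndex = "integer", members = "list"))

setValidity("Population", function(object) {
  if (!length(object@members)) return("population must be non-empty")
  lens <- vapply(object@members, function(m) seqLength(m@sequence),
                 integer(1L))
  if (length(unique(lens)) != 1L)
    return("all member sequences must have identical length")
  TRUE
})

#' @param generationIndex,members see slot documentation.
#' @rdname Population-class
#' @export
Population <- function(members, generationIndex = 1L) {
  new("Population", generationIndex = as.integer(generationIndex),
      members = members)
}

#' @describeIn Population-class number of members
#' @param x a `Population`
#' @export
setGeneric("popSize", function(x) standardGeneric("popSize"))

#' @export
setMethod("popSize", "Population", function(x) length(x@members))

#' @describeIn Population-class members as a list of [MutantRecord-class]
#' @export
setGeneric("popMembers", function(x) standardGeneric("popMembers"))

#' @export
setMethod("popMembers", "Population", function(x) x@members)

setMethod("show", "Population", function(object) {
  sc <- .pop_scores(object)
  cat("Population generation ", object@generationIndex, ": ",
      length(object@members), " members", sep = "")
  if (!all(is.na(sc)))
    cat(", best fitness ", format(max(sc, na.rm = TRUE), digits = 6),
        sep = "")
  cat("\n")
})

.pop_scores <- function(pop) {
  vapply(pop@members, function(m) {
    s <- m@scores
    if ("fitness" %in% names(s)) unname(s[["fitness"]]) else NA_real_
  }, numeric(1L))
}

.pop_strings <- function(pop) {
  vapply(pop@members, function(m) m@sequence@residues, character(1L))
}

#' Score every member of a population
#'
#' Applies the fitness function to each unscored member (already-scored
#' members are left untouched, making the operation idempotent for a
#' deterministic fitness). Members whose evaluation fails or returns a
#' non-finite value are discarded with a warning.
#'
#' @param pop a [Population-class].
#' @param fitness `function(residue_string) -> finite numeric`.
#' @return The scored [Population-class], in input order.
#' @export
evaluatePopulation <- function(pop, fitness) {
  members <- pop@members
  keep <- rep(TRUE, length(members))
  for (i in seq_along(members)) {
    if ("fitness" %in% names(members[[i]]@scores)) next
    val <- tryCatch(fitness(members[[i]]@sequence@residues),
                    error = function(e) {
                      warning("fitness evaluation failed for member ", i,
                              ": ", conditionMessage(e),
                              "; member discarded")
                      NULL
                    })
    if (is.null(val)) {
      keep[i] <- FALSE
      next
    }
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      warning("non-finite fitness for member ", i, "; member discarded")
      keep[i] <- FALSE
      next
    }
    members[[i]]@scores["fitness"] <- val
  }
  Population(members[keep], pop@generationIndex)
}

#' Retain the top-scoring fraction of a population
#'
#' Keeps exactly `ceiling(fraction * n)` members with the highest fitness.
#' Ties are broken deterministically by (score descending, residue string
#' ascending) so identical runs select identical survivors on every
#' platform.
#'
#' @param pop a scored [Population-class].
#' @param fraction fraction to retain, in (0, 1].
#' @return The surviving [Population-class], sorted best-first.
#' @export
selectTopFraction <- function(pop, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  sc <- .pop_scores(pop)
  if (anyNA(sc)) stop("all members must be scored before selection")
  n_keep <- as.integer(ceiling(fraction * length(sc)))
  ord <- order(-sc, .pop_strings(pop), method = "radix")
  Population(pop@members[ord[seq_len(n_keep)]], pop@generationIndex)
}

#' Recombine two equal-length sequences
#'
#' Single-point crossover: a cut point `c` uniform in `[1, L-1]`; the child
#' takes positions `1..c` from `a` and `c+1..L` from `b`. `cut` can be fixed
#' for deterministic use. `uniform = TRUE` instead draws each position
#' independently from `a` or `b` with equal probability.
#'
#' @param a,b residue strings or [ProteinSeq-class] objects of equal length
#'   (length >= 2).
#' @param cut optional fixed cut point in `[1, L-1]`.
#' @param uniform use uniform crossover instead of single-point.
#' @return The child residue string.
#' @examples
#' crossoverSeqs("AAAA", "TTTT", cut = 2)  # "AATT"
#' @export
crossoverSeqs <- function(a, b, cut = NULL, uniform = FALSE) {
  sa <- if (is(a, "ProteinSeq")) a@residues else a
  sb <- if (is(b, "ProteinSeq")) b@residues else b
  L <- nchar(sa)
  if (nchar(sb) != L) stop("crossover parents differ in length")
  if (L < 2L) stop("crossover needs length >= 2")
  if (uniform) {
    pick <- sample.int(2L, L, replace = TRUE) == 1L
    ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
    cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
    return(paste(ifelse(pick, ca, cb), collapse = ""))
  }
  if (is.null(cut)) cut <- sample.int(L - 1L, 1L)
  if (cut < 1L || cut > L - 1L) stop("cut point must lie in [1, L-1]")
  paste0(substr(sa, 1L, cut), substr(sb, cut + 1L, L))
}

# revert excess differences so hamming(wt, seq) <= max. "newest_first"
# reverts freshly introduced mutations (in `new_idx`) before touching
# older, selection-vetted ones; "uniform" reverts uniformly among all
# differing positions.
.clamp_to_budget <- function(wt_chars, chars, max_mut, new_idx = integer(),
                             policy = "newest_first") {
  diffs <- which(chars != wt_chars)
  excess <- length(diffs) - max_mut
  if (excess <= 0L) return(chars)
  if (policy == "newest_first") {
    fresh <- intersect(diffs, new_idx)
    old <- setdiff(diffs, fresh)
    revert_pool <- c(fresh[sample.int(length(fresh))],
                     old[sample.int(length(old))])
    revert <- revert_pool[seq_len(excess)]
  } else {
    revert <- diffs[sample.int(length(diffs), excess)]
  }
  chars[revert] <- wt_chars[revert]
  chars
}

# build a MutantRecord for a residue-character vector relative to WT
.record_vs_wt <- function(wt_id, wt_chars, chars, tag,
                          score = NULL) {
  idx <- which(chars != wt_chars)
  muts <- lapply(idx, function(i) Mutation(i, wt_chars[i], chars[i]))
  MutantRecord(wt_id, muts,
               ProteinSeq(tag, paste(chars, collapse = "")),
               scores = if (is.null(score)) numeric(0L) else
                 c(fitness = score))
}

# --- fast internal GA state: plain string/score vectors ----------------
# The inner loop never touches S4; Population/MutantRecord objects are
# materialized only at the exported-API boundaries.

.fast_evaluate <- function(strings, scores, fitness) {
  keep <- rep(TRUE, length(strings))
  for (i in seq_along(strings)) {
    if (!is.na(scores[i])) next
    val <- tryCatch(fitness(strings[i]), error = function(e) {
      warning("fitness evaluation failed for member ", i, ": ",
              conditionMessage(e), "; member discarded")
      NULL
    })
    if (is.null(val)) {
      keep[i] <- FALSE
      next
    }
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      warning("non-finite fitness for member ", i, "; member discarded")
      keep[i] <- FALSE
      next
    }
    scores[i] <- val
  }
  list(strings = strings[keep], scores = scores[keep])
}

# one generation on the fast state; returns the survivor ordering so the
# exported wrapper can carry original member objects over
.fast_step <- function(strings, scores, fitness, cfg, backend, wt_chars) {
  n <- length(strings)
  ord <- order(-scores, strings, method = "radix")
  n_keep <- as.integer(ceiling(cfg@retainFraction * n))
  surv_str <- strings[ord[seq_len(n_keep)]]
  surv_sc <- scores[ord[seq_len(n_keep)]]
  n_new <- cfg@populationSize - n_keep
  scfg <- cfg@strategyConfig
  region <- .resolve_region(scfg, length(wt_chars))
  new_str <- character(0L)
  if (n_new > 0L) {
    new_str <- character(n_new)
    for (i in seq_len(n_new)) {
      do_cross <- stats::runif(1L) < cfg@crossoverRate && n_keep >= 2L
      if (do_cross) {
        pick <- sample.int(n_keep, 2L)
        child <- crossoverSeqs(surv_str[pick[1L]], surv_str[pick[2L]],
                               uniform = cfg@crossoverType == "uniform")
      } else {
        child <- surv_str[sample.int(n_keep, 1L)]
      }
      child_chars <- strsplit(child, "", fixed = TRUE)[[1L]]
      mut <- .mutate_chars(child_chars, child, scfg, backend, region)
      chars <- .clamp_to_budget(wt_chars, mut$chars, scfg@maxMutations,
                                mut$new_idx, cfg@clampPolicy)
      new_str[i] <- paste(chars, collapse = "")
    }
  }
  ev <- .fast_evaluate(new_str, rep(NA_real_, length(new_str)), fitness)
  list(strings = c(surv_str, ev$strings),
       scores = c(surv_sc, ev$scores),
       n_surv = n_keep, ord = ord)
}

#' Advance one GA generation
#'
#' Selection, recombination and mutation, refilled to a fixed population
#' size: the top `retainFraction` survivors are carried over unmodified
#' (which includes the single best member — elitism, so the best score
#' never decreases); each remaining slot takes either the crossover of two
#' distinct survivors (with probability `crossoverRate`) or a copy of one
#' survivor, then passes through the mutation operator of the configured
#' strategy. Mutation budgets are always enforced against the original wild
#' type: if recombination plus mutation leaves a child with more than
#' `maxMutations` differences from the wild type, randomly chosen excess
#' differences are reverted, which also lets the search move within the
#' maximum-distance shell instead of freezing at it.
#'
#' @param pop scored [Population-class].
#' @param fitness fitness function (used to score the new generation).
#' @param cfg a [GAConfig-class].
#' @param backend mutation backend (predictor function or
#'   [TransitionMatrix-class], matching `cfg@strategyConfig`).
#' @param wildType the original wild-type [ProteinSeq-class].
#' @return The next scored [Population-class], of size
#'   `cfg@populationSize` (minus any members discarded for non-finite
#'   fitness).
#' @export
gaStep <- function(pop, fitness, cfg, backend, wildType) {
  sc <- .pop_scores(pop)
  if (anyNA(sc)) stop("all members must be scored before selection")
  wt_chars <- strsplit(residues(wildType), "", fixed = TRUE)[[1L]]
  st <- .fast_step(.pop_strings(pop), sc, fitness, cfg, backend, wt_chars)
  surv_members <- pop@members[st$ord[seq_len(st$n_surv)]]
  gen <- pop@generationIndex + 1L
  child_idx <- seq_along(st$strings)[-seq_len(st$n_surv)]
  new_members <- lapply(seq_along(child_idx), function(i) {
    j <- child_idx[i]
    .record_vs_wt(seqId(wildType), wt_chars,
                  strsplit(st$strings[j], "", fixed = TRUE)[[1L]],
                  paste0(seqId(wildType), "_g", gen, "_", i),
                  score = st$scores[j])
  })
  Population(c(surv_members, new_members), gen)
}

#' OptimizationResult: outcome of a GA run
#'
#' @slot best the best-scoring [MutantRecord-class] found.
#' @slot bestScorePerGeneration best fitness per generation
#'   (non-decreasing, by elitism).
#' @slot diversityPerGeneration unique-sequence count per generation.
#' @slot firstHitIteration 1-based index of the first generation attaining
#'   the overall best score.
#' @slot config the [GAConfig-class] used.
#' @slot seed the RNG seed of the run.
#' @export
setClass("OptimizationResult",
  representation(best = "MutantRecord", bestScorePerGeneration = "numeric",
                 diversityPerGeneration = "integer",
                 firstHitIteration = "integer", config = "GAConfig",
                 seed = "integer"))

setValidity("OptimizationResult", function(object) {
  tr <- object@bestScorePerGeneration
  if (length(tr) && any(diff(tr) < -1e-12))
    return("best-score trajectory must be non-decreasing (elitism)")
  TRUE
})

setMethod("show", "OptimizationResult", function(object) {
  tr <- object@bestScorePerGeneration
  cat("OptimizationResult: ", length(tr), " generations, best score ",
      format(max(tr), digits = 6), " first attained at generation ",
      object@firstHitIteration, "\n", sep = "")
  cat("  best mutant: [", formatMutationList(object@best@mutations),
      "]\n", sep = "")
})

#' @describeIn OptimizationResult-class best-score trajectory
#' @param x an `OptimizationResult`
#' @export
setGeneric("bestTrajectory", function(x) standardGeneric("bestTrajectory"))

#' @export
setMethod("bestTrajectory", "OptimizationResult",
          function(x) x@bestScorePerGeneration)

#' @describeIn OptimizationResult-class best mutant found
#' @export
setGeneric("bestMutant", function(x) standardGeneric("bestMutant"))

#' @export
setMethod("bestMutant", "OptimizationResult", function(x) x@best)

#' Run the full genetic algorithm
#'
#' Builds the initial population (the wild type plus `populationSize - 1`
#' proposed mutants), then iterates [gaStep()] for `generations`
#' generations — or until `stopOnScore` is attained. Fully reproducible:
#' all randomness flows from `cfg@seed`.
#'
#' @param wildType the starting [ProteinSeq-class].
#' @param fitness `function(residue_string) -> finite numeric`; larger is
#'   better.
#' @param cfg a [GAConfig-class].
#' @param backend mutation backend matching the configured strategy.
#' @return An [OptimizationResult-class].
#' @examples
#' wt <- ProteinSeq("wt", "MKTAYIAKQR")
#' land <- makeLandscape(landscapeSpec("target_match",
#'   target = ProteinSeq("t", "MKTAYIAKQA")))
#' cfg <- GAConfig(populationSize = 20, generations = 5,
#'   strategyConfig = StrategyConfig("basic", 1), seed = 7)
#' runGA(wt, land, cfg, basicMatrix())
#' @export
runGA <- function(wildType, fitness, cfg, backend) {
  stopifnot(is(wildType, "ProteinSeq"), is(cfg, "GAConfig"))
  set.seed(cfg@seed)
  scfg <- cfg@strategyConfig
  wt_str <- residues(wildType)
  wt_chars <- strsplit(wt_str, "", fixed = TRUE)[[1L]]
  region <- .resolve_region(scfg, length(wt_chars))
  # initial population: the wild type plus distinct proposed mutants
  init <- wt_str
  retries <- 0L
  while (length(init) < cfg@populationSize &&
         retries <= 10L * cfg@populationSize) {
    s <- paste(.mutate_chars(wt_chars, wt_str, scfg, backend,
                             region)$chars, collapse = "")
    if (s %in% init) retries <- retries + 1L else init <- c(init, s)
  }
  ev <- .fast_evaluate(init, rep(NA_real_, length(init)), fitness)
  strings <- ev$strings
  scores <- ev$scores
  best_per_gen <- max(scores)
  diversity <- length(unique(strings))
  gen <- 1L
  while (gen < cfg@generations &&
         !(is.finite(cfg@stopOnScore) &&
           best_per_gen[gen] >= cfg@stopOnScore)) {
    st <- .fast_step(strings, scores, fitness, cfg, backend, wt_chars)
    strings <- st$strings
    scores <- st$scores
    gen <- gen + 1L
    best_per_gen[gen] <- max(scores)
    diversity[gen] <- length(unique(strings))
  }
  ord <- order(-scores, strings, method = "radix")
  best <- .record_vs_wt(seqId(wildType), wt_chars,
                        strsplit(strings[ord[1L]], "",
                                 fixed = TRUE)[[1L]],
                        paste0(seqId(wildType), "_best"),
                        score = scores[ord[1L]])
  new("OptimizationResult", best = best,
      bestScorePerGeneration = best_per_gen,
      diversityPerGeneration = diversity,
      firstHitIteration = which.max(best_per_gen), config = cfg,
      seed = cfg@seed)
}
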