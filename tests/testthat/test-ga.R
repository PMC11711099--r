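make_scored_pop <- function(strings, scoresv) {
  Population(lapply(seq_along(strings), function(i) {
    MutantRecord("wt", list(), ProteinSeq(paste0("m", i), strings[i]),
                 c(fitness = scoresv[i]))
  }))
}

test_that("evaluation scores members, is idempotent and drops failures", {
  pop <- Population(lapply(1:4, function(i)
    MutantRecord("wt", list(), ProteinSeq(paste0("m", i), "MKTA"))))
  out <- evaluatePopulation(pop, function(s) 1)
  expect_identical(.pop_scores <- vapply(popMembers(out), function(m)
    scores(m)[["fitness"]], numeric(1)), rep(1, 4))
  # idempotent: a second pass does not re-evaluate (fitness would error)
  out2 <- evaluatePopulation(out, function(s) stop("must not be called"))
  expect_identical(popSize(out2), 4L)
  # target-fraction fitness
  target <- "MKTA"
  f <- function(s) mean(strsplit(s, "")[[1]] == strsplit(target, "")[[1]])
  expect_identical(vapply(popMembers(evaluatePopulation(pop, f)),
                          function(m) scores(m)[["fitness"]],
                          numeric(1))[1], 1)
  # one failing member is discarded with a warning, others survive
  boom <- function(s) if (s == "MKTA") stop("boom") else 1
  popmix <- Population(list(
    MutantRecord("wt", list(), ProteinSeq("a", "MKTA")),
    MutantRecord("wt", list(), ProteinSeq("b", "MKTG"))))
  expect_warning(res <- evaluatePopulation(popmix, boom), "failed")
  expect_identical(popSize(res), 1L)
  # non-finite scores are discarded too
  expect_warning(res2 <- evaluatePopulation(popmix,
    function(s) if (s == "MKTA") Inf else 1), "non-finite")
  expect_identical(popSize(res2), 1L)
})

test_that("survivor selection matches the sort-and-slice oracle", {
  # worked example: scores 1..10, keep 80% -> 8 kept, min score 3
  pop <- make_scored_pop(replicate(10, paste(sample(AA_ALPHABET, 4,
                                                    replace = TRUE),
                                             collapse = "")), 1:10)
  kept <- selectTopFraction(pop, 0.8)
  expect_identical(popSize(kept), 8L)
  expect_identical(min(vapply(popMembers(kept), function(m)
    scores(m)[["fitness"]], numeric(1))), 3)
  # fraction 1 is the identity up to ordering
  expect_identical(popSize(selectTopFraction(pop, 1)), 10L)
  # explicit ceiling rule
  pop5 <- make_scored_pop(replicate(5, paste(sample(AA_ALPHABET, 4,
                                                    replace = TRUE),
                                             collapse = "")), 1:5)
  expect_identical(popSize(selectTopFraction(pop5, 0.5)), 3L)
  # oracle equivalence across sizes, fractions, ties and orderings
  set.seed(31)
  for (n in 2:8) {
    for (rep in 1:10) {
      strings <- replicate(n, paste(sample(AA_ALPHABET, 3,
                                           replace = TRUE),
                                    collapse = ""))
      sc <- sample(c(1:3, 2L), n, replace = TRUE) + 0
      for (fr in c(0.25, 0.5, 0.8, 1)) {
        got <- vapply(popMembers(selectTopFraction(
          make_scored_pop(strings, sc), fr)),
          function(m) residues(m), character(1))
        want <- strings[oracle_select(strings, sc, fr)]
        expect_identical(got, want)
      }
    }
  }
  expect_error(selectTopFraction(Population(list(MutantRecord(
    "wt", list(), ProteinSeq("a", "MK")))), 0.5), "scored")
})

test_that("single-point crossover follows the cut-point definition", {
  expect_identical(crossoverSeqs("AAAA", "TTTT", cut = 2), "AATT")
  expect_identical(crossoverSeqs("MKTA", "MKTA", cut = 3), "MKTA")
  expect_error(crossoverSeqs("AAA", "AAAA"), "length")
  expect_error(crossoverSeqs("AAAA", "TTTT", cut = 4), "cut point")
  # children are position-wise members of {a, b} for both operators
  set.seed(5)
  for (rep in 1:25) {
    a <- paste(sample(AA_ALPHABET, 10, replace = TRUE), collapse = "")
    b <- paste(sample(AA_ALPHABET, 10, replace = TRUE), collapse = "")
    for (unif in c(FALSE, TRUE)) {
      child <- crossoverSeqs(a, b, uniform = unif)
      ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
      cc <- strsplit(child, "")[[1]]
      expect_true(all(cc == ca | cc == cb))
    }
  }
})

test_that("a full-retention, no-crossover step is a fixpoint", {
  set.seed(9)
  strings <- replicate(6, paste(sample(AA_ALPHABET, 8, replace = TRUE),
                                collapse = ""))
  pop <- make_scored_pop(strings, 1:6)
  cfg <- GAConfig(6, 5, retainFraction = 1, crossoverRate = 0,
                  strategyConfig = StrategyConfig("basic", 2), seed = 1)
  nxt <- gaStep(pop, function(s) 0, cfg, basicMatrix(),
                ProteinSeq("wt", strings[1]))
  expect_setequal(vapply(popMembers(nxt), residues, character(1)),
                  strings)
})

test_that("population size is conserved and elitism holds across steps", {
  set.seed(13)
  for (rep in 1:25) {
    L <- sample(6:10, 1)
    n <- sample(6:14, 1)
    wt <- randomProtein(L, id = "wt")
    target <- randomProtein(L, id = "t")
    f <- makeLandscape(landscapeSpec("target_match", target = target))
    cfg <- GAConfig(n, 3, retainFraction = runif(1, 0.2, 0.9),
                    crossoverRate = runif(1),
                    strategyConfig = StrategyConfig("basic",
                                                    sample(1:3, 1)),
                    seed = rep)
    pop <- evaluatePopulation(Population(lapply(1:n, function(i)
      MutantRecord("wt", list(),
                   ProteinSeq(paste0("m", i),
                              residues(randomProtein(L)))))), f)
    best0 <- max(vapply(popMembers(pop), function(m)
      scores(m)[["fitness"]], numeric(1)))
    nxt <- gaStep(pop, f, cfg, basicMatrix(), wt)
    expect_identical(popSize(nxt), n)
    best1 <- max(vapply(popMembers(nxt), function(m)
      scores(m)[["fitness"]], numeric(1)))
    expect_gte(best1, best0)
  }
})

test_that("full runs are reproducible, monotone and respect the budget", {
  wt <- randomProtein(15, seed = 3, id = "wt")
  target <- applyMutations(wt, mutationsBetween(
    wt, {
      set.seed(4)
      chars <- strsplit(residues(wt), "")[[1]]
      for (p in sample.int(15, 4))
        chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
      paste(chars, collapse = "")
    }))
  f <- makeLandscape(landscapeSpec("target_match", target = target))
  cfg <- GAConfig(30, 8, retainFraction = 0.5,
                  strategyConfig = StrategyConfig("basic", 4), seed = 42)
  r1 <- runGA(wt, f, cfg, basicMatrix())
  r2 <- runGA(wt, f, cfg, basicMatrix())
  expect_identical(bestTrajectory(r1), bestTrajectory(r2))
  expect_identical(residues(bestMutant(r1)), residues(bestMutant(r2)))
  expect_true(all(diff(bestTrajectory(r1)) >= 0))
  expect_lte(hammingDistance(wt, bestMutant(r1)@sequence), 4)
  expect_gte(max(bestTrajectory(r1)), bestTrajectory(r1)[1])
  # stop-on-score with an already optimal wild type converges at once
  fwt <- makeLandscape(landscapeSpec("target_match", target = wt))
  rstop <- runGA(wt, fwt, GAConfig(10, 5,
    strategyConfig = StrategyConfig("basic", 2), seed = 1,
    stopOnScore = 1), basicMatrix())
  expect_identical(rstop@firstHitIteration, 1L)
  expect_identical(length(bestTrajectory(rstop)), 1L)
})
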