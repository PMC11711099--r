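# enzopt

In-silico directed evolution of enzyme sequences with a genetic algorithm
(GA), pluggable mutation-proposal strategies, trainable fitness models, and
the downstream analytics needed to judge whether the optimized mutants are
structurally credible.

## The problem

Improving an enzyme — making it catalyze a target reaction at all, or
turning substrate over faster — means searching a sequence space of size
20^L. `enzopt` implements a population-based search over fixed-length
protein sequences:

1. **Mutation proposal.** Candidate point mutations come from one of three
   interchangeable strategies: a *masked-predictor* plug-in (`llm`) that
   ranks replacement residues at masked positions, the slot a protein
   language model occupies in production use; a *Smart* 20×20 transition
   matrix built from residue co-occurrence in a multiple sequence alignment
   of homologs; and a *Basic* uniform matrix, P(a→b) = 1/19 for every
   substitution, as the no-information control.
2. **Fitness.** Two trainable models score mutants: a random-forest
   classifier (100 trees, Gini splitting, 5-fold CV) whose vote fraction is
   the *feasibility score* F_s ∈ [0,1] that an enzyme catalyzes a given
   substrate→product transformation; and a gradient-boosted regressor for
   the turnover number on the log scale, log₁₀ kcat. Both consume
   concatenated substrate/product/enzyme embeddings behind a pluggable
   embedder contract.
3. **Evolution.** Each generation keeps the top fraction of scorers
   (truncation selection with elitism), refills to fixed population size by
   single-point crossover and mutation, and enforces the per-sequence
   mutation budget against the original wild type. Defaults follow the
   reference protocol: population 500, 30 generations, 80% retention.
4. **Diagnostics.** Convergence is summarized by the *first-hit iteration*
   (first generation attaining the run's best score) and compared across
   strategies by the exact 1-d Wasserstein distance between first-hit
   distributions and the ideal point mass at iteration 1; paired Wilcoxon
   tests compare strategies. Mutant-vs-wild-type score shifts
   ΔX = X_mutant − X_WT are tested with an in-package Mann-Whitney U
   (exact by enumeration for small samples).
5. **Structural validation analytics.** Post-MD, the package consumes
   tabular phi/psi dihedral time series and computes the deviation
   statistic

   f_sim(t′) = Σ_{t=t′}^{t_max} Σ_{i=1}^{i_max} (θ_i^wt(t′) − θ_i^mut(t))²
               / ((t_max − t′)·i_max)

   over the last 20 ns (100 ps snapshots), per-residue Pearson correlations
   between wild-type and mutant angle series, and two control-mutant
   generators: random re-mutations of the best mutant's positions, and a
   five-consecutive-proline substitution inside an alpha-helix as a
   deliberate structure breaker.

Every component has a synthetic-data generator with known ground truth
(separable reaction corpora with an analytic Bayes AUC, landscapes with a
closed-form optimum, dihedral trajectory pairs with controlled localized
perturbations), so the full pipeline is testable offline with no databases
or pretrained models.

## Worked example

```r
library(enzopt)

# a synthetic labeled reaction corpus with class separation delta = 3
ds <- makeReactionDataset(reactionSpec(nReported = 250, nRandom = 250,
                                       delta = 3, seed = 2026))
feas <- trainFeasibility(ds$records, ds$embedders, seed = 2026)
round(mean(feas$cv_auc), 3)
#> [1] 0.974

# parameter recovery: can the GA find a hidden 3-mutation optimum?
rec <- gaRecoveryExperiment(instanceSeed = 99, nSeeds = 30)
cat(rec$hits, "of", rec$nSeeds, "runs reached the hidden target;",
    "median first hit:", median(rec$firstHits), "\n")
#> 29 of 30 runs reached the hidden target; median first hit: 13

# exact rank test for mutant-vs-wild-type score shifts
str(mannWhitneyU(c(1, 2), c(3, 4)))
#> List of 3
#>  $ statistic: num 0
#>  $ p.value  : num 0.333
#>  $ method   : chr "exact"
```

The CV AUC of 0.974 says the feasibility model separates curated from
scrambled reactions nearly up to the generator's analytic Bayes ceiling
(Φ(δ/√2) ≈ 0.983 at δ = 3). The recovery experiment says the
evolutionary loop, under a uniform mutation proposal and a 3-mutation
budget on a 12-mer, finds the one sequence in its reachable space scoring
1.0 in 29 of 30 seeded runs. The shipped synthetic embedders carry signal
only for strings the generator produced; guided optimization of *novel*
mutants (the production use) requires plugging a real embedder or
predictor into the documented contracts.

A command-line front end over the same functions is installed as
`exec/enzopt` (subcommands `simulate-data`, `optimize`,
`train-feasibility`, `train-kcat`, `score`, `analyze-convergence`,
`md-analyze`); every run writes a `manifest.json` and re-running a
manifest's command reproduces its outputs byte-for-byte.

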