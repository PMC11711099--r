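---
title: "enzopt: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{enzopt: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzopt)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the assumptions they rest on, the parameters
that matter and why their defaults are what they are, what the synthetic
generators do and do not emulate, and the choices made where the design
was genuinely open.

## The optimization model

`enzopt` evolves fixed-length protein sequences over the 20-letter
amino-acid alphabet. An individual is a `MutantRecord`: a sequence plus
its mutation list relative to the wild type and attached scores. The
evolutionary loop (`runGA`) is truncation selection with elitism:

* every member is scored by a user-supplied fitness function (larger is
  better);
* the top `retainFraction` survive unchanged — since this always includes
  the best member, the best-score trajectory is non-decreasing by
  construction, which makes the reported "best mutant" well-defined and
  the first-hit diagnostic meaningful;
* each remaining slot is refilled by single-point crossover of two
  distinct survivors (probability `crossoverRate`; uniform crossover is
  available behind `crossoverType`) or a survivor copy, followed by the
  mutation operator of the configured strategy;
* survivor counts use `ceiling(fraction * n)` and score ties break by
  residue string, so runs are reproducible across platforms;
* all randomness flows from one seed recorded in the result.

**The mutation budget is enforced against the original wild type**, not
the immediate parent: a reported "best mutant with at most k mutations"
must mean k substitutions relative to the enzyme one would actually
engineer. Because crossover and mutation can push a child beyond the
budget, children are repaired by reverting excess differences. The repair
policy matters: reverting uniformly chosen differences frequently destroys
substitutions that selection has already vetted, and in our recovery
experiments that policy left the search hovering at the detection
threshold. The default therefore reverts the *freshly introduced*
mutations first (`clampPolicy = "newest_first"`), preserving vetted
material; the uniform policy remains available for comparison.

### Mutation-proposal strategies

Three interchangeable strategies generate candidate substitutions; all
first sample mutation positions uniformly inside the configured editable
region (whole sequence by default — which residues are mutable is
exposed as explicit configuration rather than guessed), with the number of
mutations per offspring uniform on `1..maxMutations`:

* **`llm`** — a masked-predictor plug-in: any object honouring the
  documented contract (ranked candidate residues per masked position,
  deterministic per input) can stand in; production use would wrap a
  protein language model. The pool of `candidatesPerPosition` (default 3)
  top candidates is either sampled uniformly or consumed greedily
  (`candidateMode = "sample"`/`"argmax"`); whether a language model's
  candidates should be sampled or argmax-selected is genuinely
  underdetermined, so both ship. The package includes a deterministic
  hash-based predictor (no signal, for plumbing) and a target-biased
  predictor (the synthetic analogue of a well-trained model on a landscape
  whose optimum is known).
* **`smart`** — a 20×20 row-stochastic transition matrix estimated from a
  user-supplied multiple sequence alignment: for every column, each
  ordered pair of residues from two distinct sequences counts as a
  substitution event (gaps and same-residue pairs discarded); rows
  normalize to probabilities, and residues never observed substituting
  fall back to the uniform row. This column-pair estimator captures
  conservation trends without requiring any homology-search tooling at
  run time.
* **`basic`** — the uniform matrix, every substitution 1/19. Diagonals
  are zero in both matrices: proposing a self-substitution would waste a
  fitness evaluation.

### Fitness models

The *feasibility* model is a 100-tree random forest (Gini splitting) on
concatenated substrate/product/enzyme embeddings, trained to separate
curated (`"reported"`) reactions from scrambled (`"random"`) triples
produced by independently permuting the three columns (with the
constraint that no scrambled triple reproduces a curated one). Its output
F_s is the raw vote fraction, uncalibrated, with 0.5 as the decision
boundary. Performance is estimated by stratified 5-fold cross-validation
(held-out AUC per fold) and the deployed model is refit on all rows.

The *turnover-number* model is a gradient-boosted tree regressor on
substrate and enzyme embeddings with the protocol hyperparameters
(learning rate 0.09, max delta step 1.19, min child weight 2.82, L1 1.94,
L2 4.95; 300 rounds). The target is log-transformed — base 10 by default;
the base is configurable and affects no rank-based conclusion — because
turnover numbers span orders of magnitude with multiplicative noise.
Metrics (MSE, R², Pearson r, always on the log scale) come from a random
80/20 held-out split with a recorded seed.

Embedders are pluggable: a function with a declared output dimension,
deterministic in its input. Adapters to pretrained chemistry/protein
models are the intended production route; the package ships a
hash-projection embedder (no signal) and a table embedder that returns
the synthetic generator's latent coordinates, which is what makes
model-recovery tests possible.

### Statistics

Score shifts are analyzed as ΔX = X_mutant − X_WT per reaction, compared
between groups with an in-package Mann-Whitney U test: exact by complete
enumeration of group assignments when the combined sample is ≤ 12 with no
ties (enumeration is cheap there and removes approximation error exactly
where small-sample inference is most fragile), otherwise a normal
approximation with tie and continuity corrections. Median splits assign
values `< m` to the low group and `>= m` to the high group. Pairwise
strategy comparisons use the paired Wilcoxon signed-rank test when the
(reaction, seed) grid is complete, falling back to the rank-sum test, and
the choice is recorded in the output.

## Convergence diagnostics

A run's *first-hit iteration* is the first generation attaining its
trajectory maximum. Strategy cells are compared by the exact first
Wasserstein distance between the empirical first-hit distribution and the
degenerate reference at iteration 1 — the ideal of converging in a single
step — which for that reference reduces to `mean(|x − 1|)`. Runs that
never reach a *known* optimum within the budget are censored at
`budget + 1`, so non-convergence weighs fully against a strategy rather
than vanishing from the comparison.

## Scaled-down experiments and why their parameters differ

Two stock experiments run the whole machinery at desk scale; both state
their problem sizes as package choices:

* **`gaRecoveryExperiment`** — population 50, sequence length 12, a
  hidden target exactly 3 mutations from the wild type, uniform-matrix
  proposals, 30 generations × 30 seeds. Retention is lowered to 10%:
  retaining a fraction r leaves `(1 − r)·N` novel candidates per
  generation, and the protocol default of 80% — set with population 500,
  i.e. 100 novel candidates per generation — would leave only 5 here,
  starving the search. 10% restores comparable absolute candidate
  throughput; crossover is disabled because at this scale survivors are
  near-identical and recombination only dilutes mutation throughput.
  Under these conditions the large majority of the 30 seeded runs recover
  the hidden target (the acceptance script reports the exact count for
  its instance).
* **`runConvergenceHarness`** — 3 strategies × maximum mutations
  {5, 10, 15} × 5 seeds × 3 synthetic reactions, population 100, 15
  cycles, on target-match landscapes with the target placed exactly
  `maxMutations` away. The same retention argument applies (10%). The
  informative strategy is the target-biased predictor in argmax mode —
  deliberately strong, since the point of the comparison is to verify the
  analytics *detect* an informative proposer: it converges within a few
  cycles while the uniform baseline censors at the budget, giving a
  strict, statistically significant ordering. The conservation-matrix
  strategy sits near the uniform baseline here, which is expected: a
  position-independent transition matrix biased toward the target's
  residue *composition* carries far less information than a per-position
  predictor.

## MD-derived structural analytics

The deviation statistic f_sim(t′) is implemented exactly as its formula
reads: the squared wrap-aware difference between the wild type *frozen at
t′* and the mutant at every running time t ≥ t′, summed over residues and
times, divided by `(t_max − t′)·i_max`. Two printed-formula quirks are
kept deliberately and documented rather than silently "fixed": the
denominator uses `t_max − t′` although the sum has one more term (t′ =
t_max is rejected to avoid division by zero), and the frozen-wild-type
reference is retained as the default even though the prose reading
"deviation from the wild-type angles" also admits a snapshot-by-snapshot
comparison — that variant ships as `variant = "time-matched"`. Note the
consequence: under the printed variant a trajectory compared with itself
is *not* zero unless it is constant in time; the time-matched variant is
the one that vanishes on identical trajectories.

Angle differences are minimal signed circular differences in
(−180°, 180°], so the ±180° seam never inflates a deviation; f_sim is
invariant under a common rotation of both trajectories. Profiles are
evaluated over the trailing 20 ns window (100 ps snapshots) by default,
the equilibrated portion of a production run. Per-residue Pearson
correlations between wild-type and mutant angle series use the raw
degrees; residues with zero variance are skipped with a warning. The
aggregation level (per-residue distributions per mutant, summarized by
median and IQR) is configurable because the right level is genuinely
ambiguous.

Two control generators calibrate these readouts. Random controls re-mutate
exactly the best mutant's positions, excluding the best mutant's residue
*and* the wild-type residue at each position — the latter is stricter than
the minimal reading ("exclude the best mutant's choice") but guarantees
every control is a genuine mutation; the looser rule is available via
`excludeWildType = FALSE`. The proline control substitutes (never inserts
— the fixed-length data model underpins every pairwise analysis) five
consecutive prolines wholly inside one uniformly chosen annotated
alpha-helix of length ≥ 5.

## Synthetic generators: what they emulate, and what they do not

* `makeReactionDataset` draws per-component latent coordinates from
  standard normals with a class shift of total Euclidean size δ split
  evenly across the three components' first coordinates, so the
  Bayes-optimal AUC is exactly `pnorm(δ/sqrt(2))` — an analytic ceiling
  for classifier-recovery checks (δ = 3 gives 0.983). Turnover numbers
  are a monotone function of two latent coordinates with Gaussian
  log-scale noise, i.e. log-normal on the natural scale — precisely the
  situation the log transform is for. Molecule strings are syntactically
  valid but chemically meaningless carbon-chain placeholders; enzyme
  strings are uniform random 30-mers. **Not emulated:** real embedding
  geometry, chemistry-driven feature correlations, class imbalance,
  EC-class structure. Passing recovery tests therefore demonstrates that
  the training/evaluation machinery is correct, not that any particular
  real-data accuracy is attainable.
* `makeLandscape` provides target-match (optimum 1 at a hidden target)
  and additive per-site-weight landscapes (optimum = sum of column
  maxima), with optional Gaussian evaluation noise. Real fitness
  landscapes are epistatic; these are not, by design — they make the
  optimum and its basin analytically known.
* `makeTrajectoryPair` generates per-residue base angles plus a shared
  slow sinusoidal drift (so unperturbed pairs are strongly correlated, as
  equilibrated replicate trajectories are) and independent thermal noise
  (default sd 10°); the mutant optionally adds a localized perturbation —
  a constant offset plus extra local noise of sd amplitude/3 inside a
  residue × snapshot window, emulating a helix break that both displaces
  and loosens the local backbone. Defaults (200 snapshots × 100 ps =
  20 ns) match the analysis window. **Not emulated:** Ramachandran
  statistics, correlated residue motions, autocorrelated noise.

## Numerical and degenerate-input choices

* Wasserstein distances are computed exactly from the merged breakpoints
  of the two empirical CDFs; no binning.
* The exact Mann-Whitney branch enumerates `choose(nA+nB, nA)`
  assignments; the two-sided p doubles the smaller tail, capped at 1.
* Offspring proposal retries duplicates up to a bounded budget (default
  50) and returns fewer offspring with a warning when a tiny
  neighbourhood is exhausted, rather than failing.
* Members whose fitness evaluation errors or returns a non-finite value
  are discarded with a warning; the generation simply runs smaller.
* Constant-kcat input yields MSE ≈ 0 and R² reported as 0 (the statistic
  is undefined); zero-variance dihedral series are skipped in
  correlations.
* Non-canonical residues (X, B, Z, U, O, `*`) are rejected at every parse
  boundary: all downstream models assume the 20-letter alphabet, and a
  silent mapping would corrupt them.
* Positions are 1-based everywhere a user sees them (mutation tokens such
  as `K2A`, helix ranges, dihedral residue ids).

## Known limitations

* The GA is heuristic: it offers no optimality guarantee, and on the
  synthetic landscapes a small fraction of seeds can miss the hidden
  target within the generation budget.
* The shipped predictors and embedders carry no biological signal; all
  real-data performance depends on user-supplied adapters.
* Sequences are fixed-length: no insertions or deletions anywhere,
  including the proline control (substitution by design).
* The smart matrix is position-independent; it cannot encode per-site
  conservation, only global substitution tendencies.
* Dihedral analytics require identical residue sets and snapshot grids
  for wild type and mutant; no interpolation or alignment is attempted.
* The foldability interface is a stub: per-residue structure-confidence
  scoring requires a pretrained folding model supplied by the user.
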