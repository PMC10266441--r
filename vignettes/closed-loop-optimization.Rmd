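---
title: "Closed-loop Bayesian optimization of reaction conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop Bayesian optimization of reaction conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnbo)
```

## The problem

Regioselective protection of unprotected glycosides — here, installing a
benzoyl group on the 6-OH (mono) or the 3- and 6-OH (di) of a
monosaccharide — is a classic needle-in-a-haystack optimization: most
combinations of base, benzoylating reagent, solvent, stoichiometry, and
concentration give no detectable product, a few give moderate yield, and the
optimum depends on the substrate.  rxnbo implements the closed-loop strategy
used by self-driving laboratories for this problem: a Gaussian-process (GP)
surrogate models the yield surface over a mixed continuous / ordinal /
categorical condition space, an expected-improvement (EI) acquisition with a
two-stage exploration schedule proposes the next experiment, and the proposed
conditions are scored by an oracle — a robot + UPLC in the laboratory, or the
synthetic consecutive-acylation simulator shipped here, which makes the full
loop runnable and benchmarkable on one desk CPU.

## The condition space

A `reaction_space` is an ordered set of typed parameters:

* continuous — benzoylating-reagent equivalents (`eq_bz`), base equivalents
  (`eq_base`), substrate concentration in mol/L (`conc`);
* ordinal — the benzoylating reagent (1 = BzCl, 2 = Bz2O), the base encoded
  as an integer 1–9 (below), and the delay `t1` in minutes between base and
  reagent addition (grid 0–20; campaigns report integer minutes and no wider
  domain, so a one-minute grid over the first twenty minutes is our
  assumption);
* categorical — the solvent: four pure solvents and all six pairwise 1:1
  mixtures, ten labels in total.

Reaction time (1 h) and ambient temperature are constants and live in the
space metadata, not in the search.  Continuous ranges in the shipped
configurations are documented assumptions: the first campaign's base
equivalents were capped at 16.7 eq (later raised to 30), and the remaining
ranges bracket the reported optima with headroom on both sides.

Candidates are plain tibbles, one column per parameter.  For the surrogate
every candidate is mapped to the unit cube: continuous values rescaled
affinely, ordinal levels mapped to ranks rescaled to [0, 1], categoricals
one-hot encoded.  `denormalize_candidates()` inverts the map exactly for
discrete parameters and to floating-point accuracy for continuous ones.  We
treat ordinal parameters as continuous ranks inside the GP and snap to the
nearest admissible level at suggestion time: the whole point of the PCA
encoding below is that distance along the base axis is meaningful, so
discarding that structure by one-hot encoding would waste information.
One-hot blocks were chosen for solvents precisely because no such ordering
exists there.

## Encoding reagents by descriptor PCA

When a discrete parameter has many levels, assigning integers arbitrarily
plants a false metric.  For the nine candidate bases, `descriptor_pca()`
standardizes a table of nine physicochemical descriptors (molecular weight,
density, refractive index, melting and boiling point, logP, dipole moment,
polar topological surface area, pKaH) and `assign_integers()` ranks the
items along the first principal component, orienting its sign — which is
mathematically arbitrary — so that a user-named reference item gets rank 1.
Integers are consecutive ranks rather than raw scores because the downstream
ordinal encoding only uses the ordering.  Correlation-matrix PCA (standardize
first) is mandatory here: the descriptors carry incommensurate units.

The shipped `base_descriptors_reconstructed.csv` is a clearly labelled
reconstruction from public reference sources, not any campaign's original
table; with triethylamine as the reference it reproduces the two anchor
facts that are checkable (Et3N -> 1, DIPEA -> 2).  Tests assert nothing else
about it; ordering properties are tested on synthetic tables with planted
structure.

```{r encode}
tbl <- read_descriptor_table(system.file(
  "extdata", "base_descriptors_reconstructed.csv", package = "rxnbo"))
encode_items(tbl, reference_first = "Et3N")
```

## The surrogate

`gp_fit()` is a Gaussian process with an anisotropic Matern-5/2 kernel over
the normalized space.  Continuous and ordinal coordinates get one lengthscale
each; a categorical one-hot block shares a single lengthscale, with the block
scaled so two candidates differing only in that categorical sit at distance
1/2 — a half-unit move, comparable to half the range of a continuous
parameter, before lengthscale adaptation.  Observed yields are standardized
to zero mean and unit variance (skipped when fewer than two distinct values
exist); a jitter of 1e-8 stabilizes the Cholesky factorization.

Hyperparameters (lengthscales in [1e-2, 1e2], signal variance in
[1e-3, 1e3], noise variance in [1e-6, 1] on the standardized scale) maximize
the log marginal likelihood by L-BFGS-B with analytic gradients.  One default
start and five seeded log-uniform restarts are screened with short runs and
the best is polished; this gives the same optima as full runs from every
start at a fraction of the likelihood evaluations, which matters because the
loop refits the surrogate after every experiment.  Fits are pure functions
of (data, seed): refitting reproduces hyperparameters bit-for-bit, which is
what makes interrupted campaigns resumable.  The O(n^2) likelihood and
gradient kernels are compiled (RcppArmadillo); everything else is R.

## Acquisition: expected improvement with a dual-xi schedule

EI demands an improvement margin xi over the incumbent f*:
EI = (mu - f* - xi) Phi(z) + sigma phi(z), z = (mu - f* - xi) / sigma, with
the limit max(mu - f* - xi, 0) at sigma = 0.  Instead of fixing one xi and
accepting the usual exploration/exploitation compromise, the loop runs a
dual schedule: a high xi (default 1.0 yield point) until a predefined number
of completed experiments — the changeover, default 48, counted strictly
(`n < changeover` keeps the high value) and including the opening design —
then a low xi (default 0.01) for careful descent into the located optimum.
The incumbent is the best *observed* yield, not the best posterior mean, and
under transfer (below) it is computed over current-substrate records only.

Campaigns open with `n_initial = 12` Latin-hypercube points: each continuous
dimension is stratified into n equal intervals occupied exactly once;
ordinal levels are drawn through the same stratified ranks; categorical
levels are stratified by shuffling.

`suggest_next()` maximizes EI by enumerating the free categorical level
combinations (up to 5000, then a seeded subsample), seeding each with random
points in the continuous/ordinal block, and refining the best starts by a
batched shrinking random search (Gaussian perturbations at radii 0.4, 0.15,
0.05, 0.02, evaluated in single posterior calls).  In the exploitative
regime additional starts are anchored at the best past experiments.  When
the incumbent is unreachably far above every posterior mean EI underflows to
zero everywhere; the optimizer then maximizes the posterior standard
deviation, which is EI's pure-exploration limit.  Ordinals are snapped at
the end, and any proposal within 1e-6 normalized distance of a past
experiment is replaced by the next-best distinct optimum — a robot should
never re-run an identical experiment.

## The synthetic oracle

`species_fractions()` models the reaction as consecutive pseudo-first-order
acylations A -> B -> C over the fixed 1 h:

* k1 (mono) = k1ref x base activation x reagent weight x solvent multiplier
  x concentration response x t1 modifier x eq_bz saturation;
* k2 (di) = k2ref x base activation x its own reagent/solvent weights x
  concentration response x a gradual stoichiometric onset in eq_bz.

Base activation is a logistic in the base integer times a logistic in base
equivalents, modulated by a per-level fingerprint vector: strong amine bases
(low integers) activate, weak pyridines give essentially zero rate, which is
what creates the large zero-yield regions.  The concentration response is
log-normal around a substrate-specific optimum; the closed form of the
intermediate makes the mono/di tradeoff honest — excess reagent converts
the mono product onward, so di-objective optima sit at 2-10x the reagent
equivalents of mono optima on every profile, and total conversion is
provably non-decreasing in eq_bz.

`measure_yield()` adds Gaussian noise (default sigma = 2 yield points, an
instrument-repeatability scale chosen in the absence of replicate
statistics) clipped to [0, 100], and reports exact zeros below a 0.5-point
detection limit, reproducing the hard zero readouts a chromatographic
integration threshold gives.

`make_profiles()` ships three calibrated profiles (glucoside-,
thiomannoside-, galactoside-like).  They were designed once, before the
benchmark suite was frozen, to satisfy four targets simultaneously: (i) a
12-point Latin-hypercube opening finds detectable (> 5%) yield about 1-2
times on average — the sparse-success landscape the campaigns show; (ii)
noise-free yields of any two profiles over 1000 random candidates have
Spearman correlation in 0.3-0.8 (computed on measured, detection-limited
yields; sub-detection ordering is chemically meaningless) — related enough
for transfer to help, different enough that optima differ; (iii) all three
share the qualitative optimum family (strong amine base, anhydride, excess
reagent, solvent-specific) while disagreeing on solvent, concentration
optimum, addition delay, and reagent tolerance; (iv) the mono landscape has
a smooth ridge leading to its optimum rather than a deceptive plateau — an
early draft with a fast second acylation produced a narrow mono peak hidden
behind a mid-yield plateau, which both contradicted the excess-reagent
optimum family and made the benchmark a lottery, and was redesigned before
freezing.  Each profile records its noise-free global maxima (mono and di),
located by a seeded dense random search with two shrinkage stages over the
shipped transfer space.

What the simulator does *not* emulate: acyl migration, HCl side reactions,
scale and equipment effects, or calibration differences between species
(scoring assumes equal UPLC response factors — a declared convention).
Passing benchmarks on it shows the optimizer works on landscapes with the
campaigns' qualitative structure, not that any particular chemistry result
is reproduced.

## Transfer learning

`augment_with_task()` adds one categorical "sugar" parameter over the task
labels.  It is fixed to the current substrate — every suggestion carries it
— but remains part of the surrogate input, so prior records ingested with
other labels shape the posterior through the kernel.  That is the entire
mechanism; no change to the optimizer.  `ingest_prior()` validates prior
records against the (possibly restricted) child space, derives mappable
columns (a categorical solvent maps onto the MeCN:THF ratio parameter as
MeCN -> 0, 1:1 -> 0.5, THF -> 1), and drops — never clips — anything out of
domain, reporting counts.  Prior records do not count toward the xi
changeover by default (a flag flips this): a warm-started campaign restarts
its own schedule.  With no scored current-substrate record yet, the EI
incumbent falls back to the best prior yield; it switches to the
current-task maximum from the first scored experiment on.

Schedules for warm-started campaigns are not pinned by any published value;
we open them without an LHS block (the priors replace it) and switch to the
low xi after 12 experiments with low xi 0.02, on the argument that an
informative prior has already paid for most of the exploration.

## Benchmarks and problem sizes

Two harness functions define the package's empirical claims, with all
randomness derived from per-campaign seeds:

* `benchmark_optimizer()` — the campaign shape of the first closed loop:
  budget 70 (12 LHS, changeover 48, xi 1.0 -> 0.01), glucoside-like profile,
  noise sigma = 2, compared at equal budget with uniform random search.  The
  test suite runs 20 seeds and requires the median final incumbent to reach
  95% of the recorded noise-free maximum and to beat random search.
* `benchmark_transfer()` — 71 prior records from a glucoside campaign
  ingested into a thiomannoside loop (budget 40), versus a cold start
  (budget 70), 20 seeds; the acceptance property is a >= 25% reduction in
  median experiments-to-90%-of-maximum, plus saturation: adding a third
  substrate's 40-record history moves the median by less than the cold
  start's interquartile range.

The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities at 10 seeds per arm to stay well inside a desktop run; the tests
carry the full 20-seed versions.

## Numerical choices and degenerate inputs

* Jitter 1e-8 on the covariance diagonal, escalated tenfold (to at most
  1e-4) only if factorization fails.
* Constant-output fits skip standardization and collapse to the prior mean.
* Zero-variance descriptor columns are dropped with a warning; exact PC1
  ties are broken lexicographically by item label and reported.
* Candidate validation never clips: out-of-domain values are errors (or
  dropped with per-record reasons during prior ingestion).
* Oracle failures are recorded with a missing score, excluded from the
  surrogate, and the loop continues; observed zero yields are data, not
  failures.
* Histories persist as delimiter-separated text with full floating-point
  precision (17 significant digits), so identical (configuration, seed)
  runs produce byte-identical tables; wall-clock provenance lives in the
  run manifest, not in the table.
* `detect_convergence()` (window 10, tolerance 1 yield point) is a
  post-hoc reporting diagnostic only — the stopping rule is always the
  budget.

## Known limitations

The surrogate is a single-output exact GP; histories beyond a few hundred
records would need sparse approximations that are out of scope.  The
transfer mechanism is the categorical-variable trick, not a learned
inter-task kernel, and inherits its limits: it helps when surfaces are
correlated in the kernel's geometry and saturates quickly.  The simulator is
a benchmark harness with plausible but invented functional forms; no claim
about real benzoylation chemistry should be read off it.
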