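# rxnbo

Closed-loop Bayesian optimization of chemical reaction conditions, with a
synthetic yield oracle that stands in for the robot and chromatograph so the
whole loop runs on a laptop.

## The problem

Regioselective benzoylation of unprotected glycosides — putting a benzoyl
group on exactly the 6-OH (mono) or the 3,6-OH pair (di) of a sugar — is a
hard optimization target: most of the condition space (base, benzoylating
reagent, solvent, stoichiometry, concentration, addition timing) gives zero
yield, and the optimum shifts from substrate to substrate.  Self-driving
laboratories attack this with a propose → run → measure → update loop.
rxnbo is that loop as an R package, for chemists and method developers who
want to study, benchmark, or extend the optimizer itself without hardware:

* **Mixed design spaces** (`build_space()`, `normalize_candidates()`):
  continuous, ordinal, and categorical reaction parameters with validation,
  unit-cube normalization, and space derivation (`restrict_space()`,
  `augment_with_task()`).
* **Descriptor-PCA encoding** (`descriptor_pca()`, `assign_integers()`):
  reagents with many levels (nine bases) are given *meaningful* integers by
  ranking them along the first principal component of standardized
  physicochemical descriptors.
* **GP surrogate + expected improvement** (`gp_fit()`, `suggest_next()`):
  a Matern-5/2 Gaussian process over the normalized space, and an EI
  acquisition with a dual exploration schedule — high xi (explore) for the
  first `changeover` experiments, low xi (exploit) after:

  EI(x) = (mu(x) − f* − xi) Φ(z) + sigma(x) φ(z),  z = (mu(x) − f* − xi)/sigma(x)

* **Closed-loop orchestration** (`run_closed_loop()`): Latin-hypercube
  opening, sequential suggestions, crash-resumable persistent histories,
  best-so-far traces and convergence diagnostics.
* **Transfer learning** (`augment_with_task()`, `ingest_prior()`): histories
  from related substrates enter the surrogate through one extra categorical
  "sugar" variable, pinned to the current substrate for suggestions.
* **Synthetic benzoylation oracle** (`make_profiles()`,
  `species_fractions()`): a consecutive-acylation model A → B → C with
  substrate-specific rate responses, large zero-yield regions, measurement
  noise and a detection limit — the test bed for every optimizer claim.

## Worked example

A full 70-experiment campaign on the glucoside-like substrate, in the shape
of a first closed loop — 12 Latin-hypercube openings, explorative EI
(xi = 1.0) until experiment 48, exploitative EI (xi = 0.01) after:

```r
library(rxnbo)

space    <- build_space(system.file("extdata", "space_transfer.yaml", package = "rxnbo"))
profiles <- make_profiles()

history <- run_closed_loop(loop_config(
  space, simulator_oracle(profiles$glucoside, "mono"),
  budget = 70, schedule = xi_schedule(1.0, 0.01, 48, 12),
  objective = "mono", seed = 42, task = "glucoside"))

table(history$phase)
#> bo_high  bo_low     lhs
#>      36      22      12

trace <- best_so_far(history)
max(trace$incumbent)
#> [1] 94.7
detect_convergence(history)      # window 10, tol 1 yield point
#> [1] 24
history[which.max(history$score),
        c("eq_bz", "eq_base", "conc", "bz_reagent", "base", "t1", "solvent", "score")]
#>   eq_bz eq_base  conc bz_reagent base t1  solvent score
#> 1  1.45    22.1 0.126          2    1  1 MeCN/THF  94.7
```

The loop finds 94.7% observed yield (the profile's recorded noise-free
maximum is 93.3%; observations carry sigma = 2 noise) at conditions that
read like the chemistry: benzoic anhydride (`bz_reagent = 2`) with a large
excess of the strongest amine base (`base = 1`, 22 eq) in the MeCN/THF
mixture.  `autoplot(history)` draws the yield-vs-experiment plot with the
incumbent trace.

Transfer learning reuses this history for a different sugar:

```r
asp <- augment_with_task(space, c("glucoside", "thiomannoside"), "thiomannoside")
history$sugar <- "glucoside"
warm <- run_closed_loop(loop_config(
  asp, simulator_oracle(profiles$thiomannoside, "mono"),
  budget = 40, schedule = xi_schedule(1.0, 0.02, 12, 0),
  priors = ingest_prior(history, asp), seed = 1, task = "thiomannoside"))
```

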