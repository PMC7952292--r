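---
title: "Methods: validating EQ-5D-5L against EQ-5D-3L in paired survey data"
author: "eqvalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating EQ-5D-5L against EQ-5D-3L in paired survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqvalid)
```

## The problem

The EQ-5D descriptive system asks a respondent to rate five dimensions of
health — mobility, self-care, usual activities, pain/discomfort,
anxiety/depression — on 3 ordinal levels (EQ-5D-3L) or 5 ordinal levels
(EQ-5D-5L), alongside a 0–100 visual analogue scale (EQ VAS). A value set
turns a profile into a single index value (utility), anchored at 1 for full
health. When a general-population survey administers *both* versions to the
same respondents, the finer 5L system can be validated against the
established 3L: does it keep responses consistent, reduce the ceiling
effect, increase informativity, and produce index values that behave as
health utilities should?

`eqvalid` implements that validation pipeline end to end, plus a calibrated
synthetic-population generator so every stage is testable without access to
survey microdata (which such surveys typically do not deposit).

## Redistribution and inconsistency

For each dimension, responses are cross-tabulated as a 3×5 table (3L level ×
5L level) over records where both items are non-missing. A pair is
*consistent* when the 5L level falls in the admissible set of its 3L level:

* 3L1 → {5L1, 5L2}, 3L2 → {5L2, 5L3, 5L4}, 3L3 → {5L4, 5L5},

so exactly 7 of the 15 possible pairs are consistent. The per-dimension
inconsistency is the percentage of pairs outside this scheme, and the
summary value is the *unweighted* mean over the five dimensions (this is the
convention that reproduces published summary values from per-dimension
ones; a pair-weighted mean is deliberately not used).

Conditional redistribution percentages are computed *among the consistent
pairs at each 3L level*, so each 3L-level block sums to 100% while
inconsistent pairs are reported separately. Published tables of this kind
sum each block to 100%, which is only possible under this convention (or if
inconsistent pairs were discarded before tabulation); we fix the convention
explicitly and report the per-dimension denominators (`n_pairs`) in every
report, because denominators are the recurring ambiguity in this
literature.

## Ceiling effect

The ceiling is the proportion of level-1 ("no problems") answers per
dimension, and the proportion of 11111 profiles for the whole instrument.
Per-dimension ceilings use all non-missing items of that dimension
(partially complete profiles still contribute to per-dimension statistics —
a deliberate choice, flagged in report metadata via the denominators);
profile ceilings use complete profiles only. The comparison test defaults
to a Pearson chi-square on the 2×2 instrument × at-ceiling table without
continuity correction, treating the two instruments as independent samples
— mirroring common field practice — while `test = "mcnemar"` provides the
statistically proper paired alternative. The a-priori hypothesis is
`ceiling_3L >= ceiling_5L`: a coarser scale catches more respondents at its
top level.

## Shannon informativity

For level counts $n_i$, $N = \sum n_i$, $p_i = n_i/N$ over $L$ levels:

$$H' = -\sum_{i=1}^{L} p_i \log_2 p_i, \qquad
  \mathrm{var}\,H' = \frac{\sum_i p_i(\log_2 p_i)^2 -
  \left(\sum_i p_i \log_2 p_i\right)^2}{N}, \qquad
  J' = \frac{H'}{\log_2 L}.$$

Numerical conventions: $0\log_2 0 \equiv 0$ by continuity; the 95% CI is
the normal approximation $H' \pm 1.96\sqrt{\mathrm{var}\,H'}$ (at survey
sample sizes the variance is tiny and the interval symmetric, so no
bootstrap is used); $H'_{max} = \log_2 L$ is kept at full precision
internally (2.3219 and 1.5850 bits; 2.32/1.58 are display values). The
3L→5L informativity change is $100\,(J'_{5L} - J'_{3L})/J'_{3L}$, undefined
when $J'_{3L} = 0$ (reported as missing with a warning). Because published
tables sometimes carry arithmetic done on rounded entries,
`informativity_report(mode = "as_printed")` recomputes the change from
3-decimal-rounded evenness; neither mode is asserted to be "the" published
arithmetic — for some dimensions both conventions reproduce the printed
change, for others neither does exactly.

## Value sets

A value set is additive: full-health value minus per-(dimension, level)
decrements, minus optional threshold constants ("any dimension ≥ L", as in
the N3 term of several 3L sets). Level-1 decrements are zero; decrements
are validated as nondecreasing in level with a *warning* rather than an
error, because some published sets violate monotonicity. Utilities below 0
are permitted (worse-than-dead states exist). National value sets are *not*
hardcoded — they are copyrighted tabulations external to this package — so
real analyses load a user-supplied coefficient file; the bundled toy sets
(5L decrement $0.05\,(l-1)$, 3L decrement $0.1\,(l-1)$ per dimension) exist
for tests and examples and score 11111 at 1.0 and the worst state at 0.0.

## Known-groups and convergent validity

One-way ANOVA of the index on age group, sex, diabetes and SF-1 (the single
self-rated-health item, 1 = excellent … 5 = poor), per instrument, with
listwise deletion per (factor, index) pair. The direction hypotheses —
older, female, diabetic, worse self-rated health ⇒ lower mean index — are
evaluated as flags on observed extreme-group means (oldest vs youngest,
etc.), not as one-sided tests; p-values stay two-sided. Per-sex OLS of the
index on age quantifies the age trend. Convergent validity is a Spearman
matrix (average-rank ties, pairwise-complete cells) of the 5L dimensions
and index against EQ VAS, the 3L dimensions and SF-1. Signs are reported as
observed, with the orientation note that dimension levels code *problems*
while index and VAS code *health*; published tables sometimes mix these
orientations, so no cell-by-cell sign matching is attempted.

## Model-based construct validity

The "theoretical model" procedure asks whether observed 5L index values are
consistent with what a model of *expected* health, given only demographics,
predicts:

1. score the survey with the value set and keep complete cases on the five
   predictors (age group, sex, education, economic status, diabetes);
2. split 60/40 into training and test sets, uniformly at random, seeded;
3. fit a random forest of 300 regression trees on the training set
   (bootstrap resampling per tree, `mtry = max(floor(5/3), 1)`, minimum
   node size 5 — the standard regression-forest defaults of the
   `randomForest` package, recorded in the fitted spec);
4. compute per-observation **absolute** prediction errors on the training
   set (internal/resubstitution errors) and on the held-out set;
5. report RMSE_int, RMSE_val, the empirical 95th percentile of the internal
   errors (linear-interpolation quantile, `stats::quantile` type 7), and
   the *coverage*: the percentage of held-out errors at or below that
   percentile.

Design choices where the procedure is underdetermined: errors entering the
distributions are absolute (a one-sided 95th-percentile criterion is only
meaningful for a nonnegative error measure; RMSE keeps its usual
squared-error definition); internal errors are resubstitution errors — the
declared "internal error of the model itself" — with `internal = "oob"`
offering out-of-bag errors as the methodologically stricter option; the
coverage comparison is non-strict so that the noiseless limit (every error
exactly zero) reports full coverage — for continuous error distributions
the strict and non-strict conventions agree almost surely. A well-specified
model yields near-overlapping error distributions and coverage near 95%;
structure present only in the held-out data (simulated in tests by shifting
held-out outcomes by +0.3 utility) collapses coverage. The procedure is
deliberately *not* presented as a calibrated statistical test: no p-value
is attached, and the anti-symmetry check (shuffled outcomes give coverage ≈
95 with RMSE ≈ sd of the outcome) shows that high coverage alone cannot
distinguish "valid construct" from "no signal at all" — the RMSE magnitudes
must be read together with the coverage.

## The synthetic-population generator

The generator is a first-class, tested module that emulates the *marginal*
structure a Polish adult general-population survey reports:

* demographics: age-group weights (19.2/16.1/15.4/17.6/19.1/12.6%), 53.2%
  female, 6.8% diabetes, six education and seven household-income
  categories with published weights; integer ages uniform within group,
  the open 70+ group capped at 87 (the oldest sampled age);
* a latent utility $u = a_{sex} + b_{sex}\,\mathrm{age} + \delta\,
  \mathrm{diabetes} + N(0, \sigma_L)$ with the published per-sex regression
  lines as trends (male $1.0674 - 0.0029\,\mathrm{age}$, female
  $1.0903 - 0.0036\,\mathrm{age}$) and $\delta = -0.07$ (a plausible
  population-level diabetes decrement, large enough to be detectable at
  n ≈ 4000);
* 5L items by thresholding a per-dimension noisy copy of the disability
  $1-u$ at four calibrated cutpoints;
* 3L items by a consistent collapse (5L1→3L1, 5L3→3L2, 5L5→3L3; 5L2→3L1
  with probability 0.60 else 3L2; 5L4→3L2 with probability 0.35 else 3L3),
  replaced with probability $\epsilon = 0.044$ by a uniform draw from the
  *inconsistent* levels for that 5L level (the published total
  inconsistency rate fixes $\epsilon$; its direction is unreported, hence
  uniform);
* EQ VAS as $\mathrm{clip}(\mathrm{round}(20 + 60u + N(0,10)), 0, 100)$ and
  SF-1 by thresholding $1-u$ at quantile-calibrated cutpoints matching the
  published SF-1 distribution;
* instrument-level MCAR missingness at 0.4%/0.9%/0.1% (5L/3L/VAS).

**Calibration (done once, frozen).** The mechanism is a latent-threshold
model because only marginal targets are published (ceilings, age trends,
an inconsistency rate) — any joint response model matching those marginals
is admissible, and thresholds make the calibration transparent. The
per-dimension cutpoints are the empirical quantiles of the simulated noisy
disability at cumulative target level proportions whose level-1 entries are
the published 5L ceilings (73.7/90.3/82.1/47.2/57.9%) and whose levels 2–5
fill the remainder in the proportions implied by the published
redistribution counts. The noise scales ($\sigma_L = 0.106$, per-item sd
0.083) were set so that the *discretisation gain* is one: OLS of the
toy-set index on age recovers the generating latent slope (the gain is
$0.05\sum_{j} f(c_j)$ over the 20 cutpoints, where $f$ is the disability
density; matching it to 1 pins the total noise scale at ≈ 0.153 sd). Both
calibrations were computed from one deterministic 2-million-draw simulation
and frozen as package constants; they are not revisited.

The collapse probability for 5L2 (0.60 to 3L1) deserves a note: the
marginal redistribution counts alone would suggest a smaller value, but
under a shared latent the respondents near the ceiling have conditionally
little 5L2→3L2 mass, and a small value inverts the profile-level ceiling
ordering that the instruments are hypothesised (and observed) to satisfy.
The chosen default preserves `ceiling_3L ≥ ceiling_5L` for the full profile
in every tested replicate, at the cost that the generated *3L* ceilings for
pain/discomfort and anxiety/depression run above their published values;
the 5L ceilings — the calibration targets — are unaffected.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: the joint dependence among dimensions beyond the
single shared latent (real data can have dimension-specific correlation);
informativity levels of the real survey (level-2–5 splits are only loosely
constrained); geographic stratification and survey weights (the analyses
are unweighted by design); any non-MCAR missingness; and real value-set
nonlinearities (the toy sets are exactly additive and monotone).

## Problem sizes and reproducibility

Simulation-based tests use n = 4000 (the study's scale) with 20 replicates
for distributional claims and 50 replicates for the slope-recovery
experiment; the Shannon CI coverage check uses 500 multinomial draws at
N = 4000. Every stochastic step — generation, train/test split, forest —
is a pure function of its seed, and the full pipeline
(`run_full_validation`) is byte-deterministic given (inputs, seed). All
rounding (1 decimal for percentages, 3 for utilities and bits) happens in
print methods only; JSON output carries full precision.

## Known limitations

* The chi-square default ignores the pairing of the two instruments; use
  the McNemar option when the proper paired test is wanted.
* The Shannon CI is a normal approximation; it degenerates at $H' = 0$
  (zero-width interval) and is not corrected for multiplicity.
* The construct-validity coverage has no reference distribution; judge it
  together with the RMSE ratio, as discussed above.
* Index-based analyses inherit whatever value set the user supplies;
  nothing validates that a supplied file matches its published source.
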