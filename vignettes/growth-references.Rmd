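---
title: "Constructing anthropometric growth references with the LMS method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing anthropometric growth references with the LMS method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmsgrowth)
```

## The model

Anthropometric measurements of children — height, weight, and especially BMI
— are positive and right-skewed, and their distribution shifts with age and
differs by sex. The LMS method summarises the distribution in each age–sex
cell by three parameters: a Box–Cox power $L$ (lambda) that removes
skewness, the median $M$ (mu), and a coefficient of variation $S$ (sigma).
Under the Box–Cox Cole–Green (BCCG) model, the transformed measurement

$$z = \frac{(y/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
  z = \frac{\log(y/M)}{S} \quad (L = 0)$$

is standard normal, so every centile and z-score follows in closed form:
$C_p = M (1 + L S z_p)^{1/L}$, with $z_p = \Phi^{-1}(p)$, and
$C_p = M \exp(S z_p)$ in the lognormal limit $L = 0$. `lms_centile()` and
`lms_zscore()` implement the pair; they are exact inverses of each other,
and $C_{0.5} = M$ always.

The power transform is only defined while $1 + L S z > 0$. Requesting a
centile outside that range is an error that names the offending percentile
— a reference built from such a triple would be meaningless, so the package
refuses rather than clamps. `|L| < 10^{-7}` switches to the log-form
expressions; the two branches agree to better than $10^{-6} M$ across
$p \in [0.01, 0.99]$ at the switch point, which the test suite asserts.

Normal quantiles are always computed by `qnorm()` at full floating
precision. This matters: published reference cells reproduce only with
full-precision quantiles, not with 2-digit approximations like 1.28 or
1.64. Internal computation is never rounded; only the rendering layer
(`round_half_up()`, ties away from zero, as published tables are rounded)
produces 2-decimal output.

## Fitting

`lms_fit()` estimates one triple per age–sex–measure cell by directly
maximising the BCCG log-likelihood

$$\ell = \sum_i \left[(L-1)\log y_i - L\log M - \log S
  - \tfrac{1}{2}\log 2\pi - z_i^2/2\right],$$

omitting the density's positivity truncation term, the standard Cole–Green
simplification, which is negligible while $S \ll 1/|Lz|$ — comfortably true
for adolescent anthropometry, where $S$ is 0.04–0.25.

The optimiser is deliberately boring: start at $(1, \mathrm{median},
\mathrm{sd}/\mathrm{mean})$, box-constrained quasi-Newton over
$L \in [-5, 7]$, $S \in (0, 1]$, followed by a Nelder–Mead polish, keeping
the better of the two. There is no randomness anywhere in the fit, so the
same sample always yields the same triple — a property the validation
module depends on (refitting the full cohort must give exactly zero
error). The suite verifies the optimiser beats a $50^3$ brute-force grid
over $(L, M, S)$ on small samples and recovers known generating parameters
at $n = 5{,}000$ within $|\Delta L| \le 0.3$, 1% on $M$ and 5% on $S$.

The minimum group size defaults to 20: three-parameter maximum likelihood
on smaller cells is unstable, with $L$ drifting to its bounds. Cells below
the minimum are a hard error unless the caller opts into skipping them.

## From cohort to reference table

`build_reference()` stratifies records by sex and completed year of age
(`floor(age_years)`, the convention of school surveys), fits each cell, and
evaluates a configurable percentile set per row. Height and weight default
to {P3, P10, P35, P50, P65, P90} and BMI to {P5, P15, P50, P85, P90, P95},
the sets used by the published reference this package ships. BMI is always
recomputed as $\mathrm{weight}_{kg}/\mathrm{height}_m^2$; an input BMI
column is never trusted.

Fitting is per integer age, matching the row structure of published
reference tables, rather than a continuous-age penalised likelihood.
Cross-age smoothing of the three parameter series is available
(`smooth_lms_series()`, least-squares polynomials with a per-parameter
equivalent-degrees-of-freedom knob) but defaults to off, because the
artifact being reproduced is a table of per-age values; with edf equal to
the number of ages the smoother is an interpolator and returns the series
unchanged. Whether a published curve smoothed its parameters across age is
usually unstated, so both behaviours are supported and the choice is
recorded in the table's provenance attribute.

## Validation by back-substitution

The back-substitution test asks: if the reference had been built from a
random subsample of the cohort, how far would its medians move?
`back_substitution()` draws a seeded simple random subsample without
replacement within each sex–age stratum (preserving the stratified design),
refits, and reports per-age signed relative errors
$(\mathrm{actual} - \mathrm{fitted})/\mathrm{actual}$ between the full-data
and subsample medians.

Two summaries are reported per sex and measure, because they answer
different questions: the mean of the signed unrounded errors (bias — the
quantity per-row entries of published validation tables correspond to) and
the true MAPE, the mean of absolute percentage errors (spread), which
drives the Lewis accuracy classification. The bands are left-closed:
below 10% "Highly accurate", 10–20% "Good", 20–50% "Reasonable", 50% and
above "Inaccurate" — a MAPE of exactly 10 is "Good", since only errors
*below* 10% count as highly accurate.

The subsample fraction defaults to 0.5; the fraction used by any given
published study is typically unreported, so this is a package default, not
a reproduction. An explicit seed is required — an irreproducible validation
report is not evidence.

## Comparison with external references

`compare_medians()` joins a local reference's P50 series against external
median tables (the package ships WHO 2006, US-CDC 2012, India 2011, Turkey
2015 and China 2013 medians for ages 12–16) and reports per-age differences
(local − external) with per-source extremes. Comparison is medians-only:
cross-study percentile comparison beyond P50 is not meaningful without the
external references' full LMS parameters. Cells a source does not publish
(WHO weight-for-age in this range) are absent, not zero, and are skipped
with a log message. A heuristic guard flags a greater than 3-fold
local/external ratio as a probable unit mismatch.

## The synthetic cohort generator

No raw cohort accompanies the published reference, so the package includes
a generator that emulates the survey the analysis assumes:
`generate_cohort()` draws, for each sex–age cell, standard-normal deviates
mapped through the forward LMS transform of a supplied parameter table
(default: the shipped published triples), with ages uniform within the
completed year. Defaults mirror the study design: ages 12–16, two sexes,
297 children per cell (2,970 records), and `emulate_sampling_design()`
reproduces the 3 strata × 20 schools × 50 students cluster-label shape.

Choices a survey does not specify, fixed once here:

* **Height–weight dependence.** Within-child correlation is physiologic
  but unreported; the generator couples the height and weight deviates
  through a Gaussian copula with $\rho = 0.5$ by default, exposed as a
  parameter rather than hidden. BMI is then derived arithmetically from
  each child's height and weight (`derive_from_hw`), keeping the three
  measures consistent; the alternative `independent_lms` mode samples BMI
  from its own triple when matching a published BMI reference matters more
  than within-child coherence.
* **Positivity.** The rare deviate violating $1 + L S z > 0$ is rejected
  and redrawn. A cell whose *theoretical* rejection rate
  $\Phi(-1/|LS|)$ exceeds 1% errors out: silent truncation would bias
  parameter-recovery tests. The theoretical rate is used rather than the
  realised count so that small cells cannot trip the cap by chance.

What the generator does **not** emulate: school-level clustering of
measurements (design labels are metadata only), measurement error and
digit preference, missingness, secular trends, or within-year age
structure beyond uniformity. Passing tests therefore demonstrate that the
pipeline recovers the distributions it assumes — not that those
assumptions hold in any real population.

The survey sample-size equation $n = \lceil Z^2 P Q / e^2 \cdot D \rceil$
is included (`sample_size()`) because reference studies justify their
cohort size with it.

## Numerical and serialisation choices

* Files are comma-separated UTF-8 with headers; sex is "male"/"female",
  case-insensitive on read.
* Doubles are serialised with 17 significant digits and parsed back with
  `strtod`, so cohort, reference-table and validation-report round trips
  are bit-exact; human-readable `*_2dp` display columns are written
  alongside and ignored on read.
* All randomness (generation, subsampling) flows from explicit integer
  seeds; two runs with the same configuration are byte-identical.
* `run_pipeline()` drives simulate → fit → validate → compare → chart from
  one flat YAML file; unknown keys are rejected rather than ignored.

## Known limitations

* The shipped published reference table contains a handful of internally
  inconsistent cells: the girls' weight rows at ages 15–16 have their P65
  and P90 entries interchanged between the two rows, several girls' BMI
  off-median cells and four boys' BMI P15/P85 cells differ by 0.02 from
  what their own row's $L/M/S$ implies. The loaders return these cells
  exactly as printed; the test suite checks reproduction of every
  *consistent* cell to ±0.01 and excludes the inconsistent ones rather
  than contorting the transform to match them.
* Fitting is cross-sectional; no longitudinal (growth-velocity) modelling.
* The BCCG model captures skewness only; populations with heavy-tailed
  measures would need a four-parameter (BCT/BCPE) extension, which is out
  of scope.
* Test and example problem sizes (250–600 children per cell for recovery
  checks, 10,000 for distributional checks) are chosen to keep the default
  suite fast while leaving comfortable statistical margins; the stated
  tolerances are calibrated to those sizes.
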