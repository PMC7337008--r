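---
title: "Median-effect synergy analysis: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-effect synergy analysis: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyci)
```

## The model

Every dose–response curve in this package is the median-effect equation,
the mass-action law

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m, \qquad f_u = 1 - f_a,$$

with three interpretable parameters:

* **`Dm`** — the median-effect dose, in the declared concentration unit
  (µM or µg/mL): the dose at which half the maximal effect is reached.
  It plays the role IC50 plays in other parameterisations.
* **`m`** — a dimensionless shape exponent: `m = 1` gives a hyperbolic
  (Michaelis–Menten-like) curve, `m > 1` sigmoidal, `m < 1` flat-sigmoidal.
* **`r`** — the Pearson correlation of the log-linearised plot, reported
  as goodness of fit (see below). It is descriptive, not enforced.

Its closed forms are `fa_from_dose()`, $f_a = 1/(1 + (D_m/D)^m)$, and the
inverse `dose_for_fa()`, $D_x = D_m\,(f_a/(1-f_a))^{1/m}$. The forward
form is evaluated on the log scale so extreme dose/`Dm` ratios do not
overflow; note that in double precision $f_a$ still rounds to exactly 0 or
1 beyond roughly 17 decades from `Dm`, which is why boundary values are
treated as out of domain everywhere rather than "impossible".

### Fitting

`fit_median_effect()` is the classical median-effect plot: ordinary least
squares of $y = \log_{10}(f_a/f_u)$ on $x = \log_{10} D$; the slope is `m`,
the intercept $-m \log_{10} D_m$, and `r` the correlation of $(x, y)$.
Deliberate choices, made where the method's descriptions are silent:

* **Boundary exclusion, not clamping.** Points with $f_a \le 0$ or
  $f_a \ge 1$ (possible after viability truncation) are *dropped* — the
  log-transform is undefined there and any clamp value would be an
  arbitrary, high-leverage pseudo-observation. `n_used` reports how many
  points actually entered the fit.
* **Base-10 logs.** The slope is base-invariant; only the intercept-to-`Dm`
  conversion must match the base, and it does.
* **Unweighted OLS.** No weighting scheme is part of the method's standard
  description; none is invented.
* **Quality is reported, not enforced.** A warning (class
  `synergyci_low_r`) is raised when $|r| < 0.9$, but the fit is returned;
  there is no published cutoff to enforce.
* **Average-then-fit.** Replicate wells are pooled to a mean $f_a$ per
  dose (`pool_replicates()`) before fitting, and the pipeline does this
  automatically when a `replicate` column is present. Whether reference
  software averages before or after the transform is not documented; we
  adopt averaging-first because the logit-like transform amplifies noise
  asymmetrically near the boundaries, so averaging in effect space is the
  stabler convention. This is a convention, and fitting per-replicate
  points remains possible by simply not pooling.

## Viability processing

MTT absorbances are converted as
$\mathrm{viability}\,\% = 100\,(A_\mathrm{sample} - A_\mathrm{blank}) /
(A_\mathrm{control} - A_\mathrm{blank})$. Control and blank wells are
pooled by their mean OD across the whole table before the formula — plate
layouts pairing specific control wells to specific samples are not
assumed. A plate whose control does not exceed its blank has no signal
window and is rejected. Raw viability may leave $[0, 100]$ on noisy
plates; it is truncated only at the aggregation step (the raw mean is kept
in `viability_raw` for audit), and the fraction affected is
$f_a = 1 - \mathrm{viability}/100$ — an *inhibition* endpoint, so "affected"
means growth-inhibited. Replicate spread is the sample SD
($n-1$ denominator, 0 when $n = 1$).

## Combination index

For drugs given together at doses $d_j$ producing observed effect $f_a$,

$$\mathrm{CI}(f_a) = \sum_j \frac{d_j}{D_{x,j}(f_a)}$$

with $D_{x,j}$ from each single drug's fitted curve. CI is linear in the
dose vector, independent of all `m` values at $f_a = 0.5$ (where every
$D_{x,j} = D_{m,j}$), and invariant under a common rescaling of doses and
`Dm` values — three properties the test suite asserts directly. Mixed
units are rejected; the package never converts concentration units
implicitly (a µg/mL-vs-µM mismatch cannot be resolved without molecular
weights, which the inputs do not carry).

Two CI views are exposed, both conventional:

* `ci_table()` scores each *observed* dose level at its observed $f_a$
  (the report-table style). Rows whose observed $f_a$ is exactly 0 or 1
  after truncation are excluded — CI is undefined there — with the count
  attached as attribute `n_excluded`.
* `fa_ci_curve()` scores a grid of effect levels on the *fitted*
  combination curve: total dose from `dose_for_fa()` on the mixture fit,
  split into components by the design weights. The default grid
  0.05–0.95 in steps of 0.05 avoids the undefined boundaries while
  spanning the plot range used in practice.

### Fixed-ratio design

`design_fixed_ratio()` mixes components in proportion to their potencies,
$w_j = D_{m,j} / \sum_k D_{m,k}$, so at total dose $\sum_k D_{m,k}$ each
drug sits exactly at its own `Dm`. Dose levels are a serial-dilution
ladder (default 1:1.5); when no top dose is given the ladder is centred so
$\sum_k D_{m,k}$ is an interior level — mirroring the wet-lab convention
of placing the Dm-combination mid-range. The mixture's own `Dm` from
`fit_combination_as_single()` is interpreted as a *total* dose, allocated
to components by the design weights.

### Classification bands

`classify_ci()` uses half-open, lower-inclusive bands. The conventional
published bands — $[0.1, 0.3)$ strong synergism, $[0.3, 0.7)$ synergism,
$[0.7, 0.85)$ moderate, $[0.85, 0.90)$ slight, $[0.90, 1.10)$ nearly
additive (containing the additive point CI = 1) — do not tile $(0,
\infty)$, so they are extended with $(0, 0.1)$ very strong synergism,
$[1.10, 1.20)$ slight antagonism, $[1.20, 3.3)$ antagonism and
$[3.3, \infty)$ strong antagonism, following the standard extended scale.
Lower-inclusive edges are a pure tie-break convention; the tests verify
every boundary switches bands and no gap exists anywhere on $(0, \infty)$.

## The synthetic-data generator

The generator is first-class, tested code: it is what makes every stage
verifiable without proprietary plate data.

* `simulate_single_drug()` draws points exactly on a median-effect curve,
  optionally adding per-replicate Gaussian noise to $f_a$ (truncated to
  $[0,1]$). Noise is placed on $f_a$, not OD, because that keeps the
  ground truth in the model's natural effect space; an OD-level plate mode
  (`as_plate = TRUE`, with control/blank constants) exists so the
  viability module can be exercised from raw absorbances. Default noise
  settings used in the tests — $\sigma = 0.01$–$0.02$ on $f_a$, triplicate
  wells, 8 dose levels on a 1:1.5 ladder bracketing `Dm` — emulate the
  stated experimental scale of the motivating assay (triplicate MTT
  plates, serial-dilution designs).
* `simulate_combination()` plants a *known* CI profile $\kappa$ (a
  constant or a function of $f_a$): the Loewe-additive total dose at
  effect $f_a$ is $D_\mathrm{add}(f_a) = (\sum_j w_j / D_{x,j}(f_a))^{-1}$,
  and the simulated mixture reaches $f_a$ at $\kappa \cdot
  D_\mathrm{add}(f_a)$. For a requested total dose the achieved $f_a$ is
  recovered by bisection on this strictly monotone relation (bracket
  $[10^{-6}, 1-10^{-6}]$, tolerance $10^{-10}$, derivative-free by
  design). By construction, $\kappa = 1$ is exact Loewe additivity and a
  drug "combined" with itself reproduces its own curve — the sham test.
* **Default combination dose ladder.** The default is an 8-level 1:1.5
  ladder centred on the mixture's *own* median-effect total dose
  $\kappa \cdot D_\mathrm{add}(0.5)$, not on $\sum_k D_{m,k}$. The reason
  is identifiability: with $\kappa$ far from 1, a $\sum D_m$-centred
  ladder samples only one saturated tail of the mixture curve (at
  $\kappa = 0.27$, all observed $f_a \ge 0.83$), and no fitting procedure
  can recover the curve from one tail. A generator whose purpose is
  known-truth validation must produce an informative experiment for any
  planted $\kappa$; explicit `total_doses` override the default when the
  badly-centred design itself is the object of study.
* `simulate_protein_table()` plants exact counts of up-/down-regulated
  proteins with fold changes guaranteed beyond the 1.5/0.67 thresholds
  (margin ≥ 0.1 log2 units), and null proteins whose log2 fold change is
  truncated at ±0.5 — strictly inside the thresholds — so the screen's
  exact-recovery test is a guarantee, not a probabilistic hope.

What a green test does **not** establish: the generator makes no attempt
to emulate plate edge effects, systematic row/column drifts, OD
saturation, pipetting-correlated errors, or deviations from the
median-effect law itself (biphasic or partial-efficacy drugs). Recovery
under its noise model shows the pipeline is correct and stable, not that
real plates meet the model's assumptions.

## Proteomics screen

`filter_differential()` applies *strict* fold-change thresholds
(`> 1.5`, `< 0.67`); values exactly at a threshold are unchanged.
`enrich_terms()` is a local stand-in for web enrichment services: the
one-sided hypergeometric tail $P(X \ge k)$ on a user-supplied term→protein
map and background, with Benjamini–Hochberg adjustment across terms (the
motivating analyses apply a p < 0.05 cutoff without naming a multiplicity
method; BH is the defensible default). An optional EASE mode substitutes
$k - 1$ for $k$, reproducing the conservative variant some services use;
it is off by default because no statistic beyond the tool name is
documented. `network_degree()` collapses duplicate edges, drops
self-loops, counts distinct neighbours (via igraph), and ranks degree
descending with ties broken by id — a deterministic ordering.

## Pipeline and reproducibility

`run_synergy_pipeline()` chains the stages and emits CSV tables (a
single-drug fit table, the combination fit, the CI table in 2-decimal
display form plus a lossless full-precision companion, the Fa–CI curve)
and a JSON manifest recording configuration, seed, design weights and
package version. The pipeline itself draws no random numbers, so a fixed
manifest and inputs reproduce byte-identical full-precision outputs; any
stage failure aborts the run and removes partial outputs. The
`synergy_cli()` entry point exposes each stage (`fit`, `design`, `ci`,
`curve`, `simulate`, `screen`, `run`) for shell use, logging to stderr and
writing results only to files unless `--stdout` is given.

## Known limitations

* Only the median-effect parameterisation is supported — no
  four-parameter logistic baseline/asymptote, no Bayesian fitting, no
  bootstrap intervals on `Dm`.
* CI assumes both axes share the single-drug curves' unit; cross-unit
  experiments must be converted by the user beforehand.
* The Fa–CI curve inherits all uncertainty of the fitted curves;
  no confidence band is propagated onto CI.
* Alternative synergy nulls (Bliss independence, HSA, ZIP) and the
  dose-reduction index are out of scope.
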