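---
title: "Fixed-ratio Loewe synergy screening: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-ratio Loewe synergy screening: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loewescreen)
```

## The model

A viability dose-response series (percent of DMSO vehicle control,
measured after fixed-time drug exposure) is modelled with the
four-parameter logistic (4PL):

$$ v(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
          {1 + (d/\mathrm{IC}_{50})^{h}} $$

with `top` the zero-dose asymptote (near 100% because data are
control-normalised), `bottom` the infinite-dose asymptote, `IC50` the
midpoint dose and `h > 0` the Hill slope. The maximum achievable growth
inhibition is `100 − bottom`.

For a fixed-ratio combination of drugs PD and AZ at PD:AZ ratio $r$,
the Loewe-additivity combination index at growth-inhibition level $y$ is

$$ CI(E_y) = \frac{d_{PD}}{D_{PD}} + \frac{d_{AZ}}{D_{AZ}}
           = \frac{r\,d_{AZ}}{D_{PD}} + \frac{d_{AZ}}{D_{AZ}} $$

where $d_{AZ}$ is the AZ-component dose at which the *combination*
curve reaches $y$% inhibition, $d_{PD} = r\,d_{AZ}$, and $D_{PD}$,
$D_{AZ}$ are the single-agent doses for the same effect. Under Loewe
additivity — a combination behaving as a dilution of either drug alone —
$CI \equiv 1$; in particular any *sham* combination of a drug with
itself must return 1, which is the central self-consistency check of
the whole pipeline. CI is evaluated on the effect grid $y = 50, 51,
\dots, 80$ (31 levels; the convention is to tabulate "between 50% and
80% inhibition", and a fine fixed grid makes summaries reproducible).

## Fitting: parameters, bounds, determinism

* Fitting happens on log10 dose with all replicate wells as individual
  observations (pre-averaging would discard the error structure that
  triplicate independent experiments provide).
* Default bounds: `top` ∈ [70, 120], `bottom` ∈ [0, 100], `h` ∈
  [0.1, 10], `IC50` ∈ [min dose / 100, max dose × extrapolation limit].
  Control-normalised data pin `top` near 100; the loose box mainly
  prevents identifiability collapse on shallow curves.
* Multi-start: 5 deterministic initialisations with the IC50 start
  placed at quantiles of the log-dose grid and `h = 1`; lowest residual
  sum of squares wins. Several starts typically reach the same minimum
  with different optimizer stopping codes, so among runs whose RSS is
  within numerical rounding of the best we prefer the first cleanly
  converged one — this keeps the winner deterministic while avoiding
  spurious non-convergence flags.
* A fit is flagged non-converged when the optimiser fails or when IC50
  or the Hill slope pins to its bound. The asymptotes are deliberately
  excluded from the pinning rule: `bottom = 0` (complete kill) and
  near-100 `top` values sit *on* their bounds for perfectly good fits.

## Effect-level inversion, censoring, and classification

`dose_at_inhibition()` inverts the 4PL in closed form. Two guard rails:

* **Attainability margin**: a level within 2 percentage points of the
  curve's maximum inhibition is reported unattainable rather than
  inverted, because the inverse dose diverges at the asymptote.
* **Extrapolation limit**: doses beyond 10× the highest tested dose are
  censored at that bound. Published screens report values like
  "IC50 > 100 µM" for resistant lines, which implies some such rule;
  the exact published convention is unstated, so the 10× limit is this
  package's own choice, recorded here.

Censoring propagates into CI points explicitly: an unattainable dose
makes the point `unattainable` (CI undefined), while a single-agent
dose censored at the limit yields an `upper_bound` CI (true CI can only
be smaller, since the true $D$ is larger). A *censored combination*
dose is treated as unattainable — the combination never reached the
effect within its admissible range, so no finite bound on CI is
implied. Profile summaries (median, mean, quartiles) use exact and
upper-bound points; a profile with fewer than 3 usable points is
flagged undefined.

Classification conventions, matching the published band definitions:
IC50 < 2 µM sensitive, > 10 µM resistant, boundary values intermediate
(strict-inequality reading); median CI < 0.5 strong synergism, < 0.8
synergism, 0.8–1.2 additive (band edges assigned to additive), > 1.2
antagonism. The median over the effect grid was chosen as the
classification statistic — the source convention (median vs mean vs the
full tabulated set) is not stated, and the median is robust to the grid
edges; the mean is reported alongside. The combination IC50 used for
sensitivity classification is expressed as *total* drug concentration
$(1+r)\,d_{AZ}$; whether published combination IC50 axes are total or
component concentration is likewise unstated, and total dose is the
convention here. Panel percentages are round-half-up integers
(8/28 → 29%).

## The synthetic-data generator

`simulate_panel()` emulates a 28-line screen with three independent
replicates per condition:

* Single-agent IC50s drawn log-uniformly over published-spread-like
  ranges — PD 0.03–150 µM (below 50 nM to above 100 µM), AZ 0.15–33 µM;
  Hill slopes uniform in [0.8, 1.5]; `top = 100`; `bottom` uniform in
  [0, 10]% so the E50–E80 grid stays attainable on true curves.
* Dose grids: 9-point half-log series, 0.01–100 µM for single agents
  and 0.004–40 µM on the AZ-component axis for combinations — chosen to
  bracket the IC50 ranges above.
* Noise: per-well multiplicative lognormal with mean 1 and a chosen
  coefficient of variation (default 5%). Viability is a positive ratio
  measure, which motivates multiplicative over additive noise; only
  mean ± SD of triplicates is typically published, so the 5% default is
  a field-realistic choice, not a published value.
* Combinations are constructed to have a **constant true Loewe index
  κ**: the AZ-component dose reaching inhibition $y$ is
  $d_{AZ}(y) = \kappa / (r/D_{PD}(y) + 1/D_{AZ}(y))$, the unique root
  of the Loewe equation at index κ. The monotone dose→effect map is
  then inverted numerically and sampled on the dose grid. Real
  combinations may well have effect-level-dependent interaction; the
  constant-κ construction is a deliberate simplification that makes κ
  the single recoverable ground truth.
* One master seed; per-line and per-condition substreams are derived by
  a fixed string hash, so adding a line never perturbs the others and
  identical specs give byte-identical CSVs.

What a green simulation-based test establishes: that the pipeline is
*internally consistent* — sham combinations score additive, constant-κ
constructions are recovered unbiasedly across κ ∈ [0.3, 1.5] under 5%
noise, and classification bands behave exactly. What it does not
establish: anything about the biology of real panels (no raw viability
data are published for the motivating screen), plate artefacts,
effect-dependent interaction, or non-logistic response shapes.

## Numerical choices and degenerate inputs

* Fewer than 4 distinct doses or constant viability are rejected as
  errors (no fit is attempted).
* The sham/constant-κ identity holds to ±0.01 noise-free; fit tolerance
  dominates, not the closed-form inversion (exact to machine
  precision, verified against brute-force root finding).
* κ values that place the whole combination curve outside the dose grid
  raise an unusable-design error instead of producing a vacuous series.
* `screen_panel()` sorts input rows internally, so results are
  invariant to row order; lines with failed or missing fits go to an
  exclusions table and shrink that condition's denominator rather than
  being silently dropped.
* Optimal-ratio selection operationalises "more synergistic CI values"
  as: most lines synergistic or stronger, ties broken by lower median
  of per-line median CIs, then by smaller ratio.

## Known limitations

* No 5PL or biphasic models; strongly non-logistic data will fit badly
  and should be caught via `rss` and convergence flags.
* No Bliss/HSA/ZIP scores and no checkerboard designs — fixed-ratio
  Loewe only.
* The 10× extrapolation limit and the 2-point attainability margin are
  package conventions; both are explicit parameters.
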