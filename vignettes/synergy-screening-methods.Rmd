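---
title: "Methods: synergy screening, median-effect analysis and TGI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy screening, median-effect analysis and TGI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscreen)
```

This vignette documents the statistical models behind `synergyscreen`, the
choices made where the methodology is genuinely open, and what the
synthetic-data generators do and do not emulate.

## Viability normalization

A well's viability is its background-subtracted signal relative to the
plate's vehicle controls,
$\mathrm{viability} = (s - \bar b)/(\bar v - \bar b)$, and the fraction
affected is $F_a = 1 - \mathrm{viability}$. Three choices are deliberate:

* **Mean controls.** Vehicle and blank statistics use the mean, the
  ubiquitous plate-practice convention; a handful of control wells gives
  the median no robustness advantage worth the efficiency loss.
* **Per-replicate clamping.** Each replicate's $F_a$ is clamped to
  $[0, 1]$ *before* averaging. This keeps the reported replicate standard
  deviation a property of values on the meaningful scale and bounds every
  quantity that later divides by an $F_a$. A consequence worth knowing:
  replicates scattered symmetrically around the vehicle mean average to a
  small positive $F_a$, because negative excursions are clamped and
  positive ones are not.
* **Plate-local controls.** Each plate is normalized against its own
  controls; no cross-plate or spatial (edge-effect) correction is applied.
  Conditions whose replicates span plates are normalized per replicate,
  then aggregated.

Whether a medium-only blank is subtracted at all varies between
laboratories, so blank handling is configurable: `normalize_plate()`
demands blank wells by default and rejects plates without them, while
`require_blank = FALSE` (and `compute_fa()`'s `blank_signals = 0` default)
normalizes against a zero blank.

Normalization is exactly invariant to rescaling all of a plate's signals
by a positive constant and to shifting them all by a constant — both
transformations cancel in the viability ratio.

## The Synergy Index screen

For every library compound the screen measures $F_a$ alone, and in
combination with each of two ferroptosis inducers. The Synergy Index
against an inducer is

$$SI = \frac{F_{a,\mathrm{comb}} - F_{a,\mathrm{cpd}}}{F_{a,\mathrm{inducer}}},$$

with $SI > 1$ synergism and $SI < 1$ antagonism. A compound is a **hit**
when both combinations reach at least 50% kill (inclusive) *and* both SI
values strictly exceed 1. Details that matter:

* **Denominator floor.** The ratio is numerically meaningless when the
  inducer kills almost nothing, so $SI$ is *undefined* (reported missing,
  never coerced to 0) when $F_{a,\mathrm{inducer}} < \varepsilon$ with
  $\varepsilon = 0.01$ by default. An inducer dosed to a measurable effect
  — the intended design — never trips this floor.
* **Mean-first.** SI is computed on replicate-mean $F_a$ values; replicate
  sds are propagated in quadrature into a descriptive `si_sd` (no test is
  attached to SI — the screen is a ranking device, not an inference).
* **Ranking.** Compounds are ordered by $\min(SI_E, SI_R)$ descending —
  a hit must synergize with *both* inducers, so the weaker pairing is the
  binding score — with ties broken by mean combination kill, then by
  compound id for determinism. Compounds with a missing arm sink to the
  bottom and are excluded from hit calling.
* **Two cell lines.** A multi-line screen is scored per line;
  `combine_screen_hits()` defaults to intersecting the per-line hit sets
  (a hit must replicate in every line), with union available.
* No multiple-testing correction is applied, deliberately: the screen
  statistic has no null model attached.

Under Bliss-independent data
($F_{a,\mathrm{comb}} = F_{a,c} + F_{a,i} - F_{a,c}F_{a,i}$) the SI has
the closed form $1 - F_{a,c} \le 1$, so a Bliss-generated screen can never
produce a hit — the screen's synergy calls are calls of *excess over
Bliss*.

## Median-effect fitting and the Combination Index

The mass-action median-effect model $f_a/f_u = (D/D_m)^m$ linearizes to

$$\log_{10}\frac{f_a}{1-f_a} = m\,\log_{10} D - m\,\log_{10} D_m,$$

and `fit_median_effect()` is unweighted OLS on these coordinates — the
method's canonical linearization. Nonlinear refinement is deliberately
omitted: the linear fit is exactly reproducible, and its bias under
moderate noise is small compared with inter-experiment variability.
Numerical choices:

* Points with $f_a$ outside the open interval $(0.005, 0.995)$ are
  excluded (log-odds of 0 or 1 are unrepresentable) and counted in
  `n_excluded`; at least 3 usable points are required.
* A non-positive fitted slope signals non-monotone data and raises a
  `model_violation` error rather than returning a meaningless $D_m$.
* The fit quality is reported as the Pearson correlation $r$ of the
  median-effect plot.

`ic50()` is $D_m$ by definition of the model. The Combination Index for a
constant-ratio combination fitted as one agent on total dose is the
two-term (mutually exclusive) form

$$CI = \frac{d_1}{D_{x1}} + \frac{d_2}{D_{x2}},$$

evaluated by default at $f_a \in \{0.5, 0.75, 0.9\}$ (configurable; the
three-level report is the field's convention). The non-exclusive third
term is omitted — the dominant modern convention. Classification uses a
$10^{-9}$ additivity band around $CI = 1$, so "additivity" is reported
only at numerical equality. Non-constant-ratio designs are rejected: the
combination must be refit per ratio.

Two identities anchor the implementation and its tests: a sham
self-combination gives $CI = 1$ at every effect level and ratio (since
$d_1/D_x + d_2/D_x = p + (1-p)$), and scaling a combination's $D_m$ by $s$
scales every $CI$ by $s$.

## Synthetic data: what it emulates, what it does not

The generators' defaults *are* the reference study conditions; they are
fixed once and the tests inherit them.

**Screen generator.** 303 compounds against two inducers dosed to
$F_a = 0.3$, triplicate wells, 10 planted hits, viability noise sd 0.02.
Single-compound effects are uniform on $[0, 0.5]$ — screening doses are
chosen sub-lethal as single agents, which also keeps the planted
combination $F_a$ below 1 so no truth is distorted by clamping. Non-hit
combinations follow Bliss independence; planted hits get an additive
Bliss excess $\delta = 0.35$, giving the analytically available truth
$SI = 1 - F_{a,c} + \delta/F_{a,i}$. Configurations in which a planted
hit could not reach $SI > 1$ are rejected as unusable ground truth. Wells
are laid out 80 to a 96-well plate with 8 vehicle and 8 blank wells in the
outer columns — the standard control-column layout. Noise is additive
Gaussian on the viability scale (converted to signal units by the
vehicle-blank span), truncated by flooring signals at half the blank; with
zero noise every emitted value equals its model value exactly. The
generator does **not** emulate spatial plate effects (edge evaporation,
gradients), optical-density nonlinearity, compound carry-over, or
inter-plate drift — passing recovery tests therefore demonstrates
correctness of the statistical machinery, not robustness to those
artifacts.

**Combination generator.** The mixture at dose fractions $(p, q)$ is
treated as one agent whose median-effect dose is
$s \cdot D_{m,\mathrm{ref}}$, where
$D_{m,\mathrm{ref}} = 1/(p/D_{m,a} + q/D_{m,b})$ is the Loewe-additive
reference total dose and $s$ the planted potency shift ($s < 1$ synergy,
downstream $CI = s$). With equal component slopes the Loewe-additive
mixture is exactly median-effect at every level, so the construction is
exact; with unequal slopes the reference is exact at $f_a = 0.5$ and the
combination slope is taken as the ratio-weighted mean — an approximation
flagged here because real unequal-slope mixtures are not exactly
median-effect either.

**Xenograft generator.** Exponential growth $V(t) = v_0 e^{gt}$ from
enrolment at $v_0 = 100$ mm³, measured every 4 days to day 28, 6 animals
per group, vehicle $g = 0.10$/day vs treated $0.04$/day. Volumes are
emitted as caliper pairs under a fixed aspect ratio $L/S = 1.25$ (a
documented constant; real tumors vary in shape) with 0.3 mm Gaussian
caliper noise per diameter, the short diameter floored at 0.1 mm and the
pair reordered so $L \ge S$. Biological growth-rate heterogeneity between
animals is *not* simulated — all variation is measurement noise — so the
recovery tests validate the TGI computation, not its power under animal
heterogeneity.

All generators drive every random draw from a single seed through R's
default generator in one fixed order; equal seeds give bit-identical
tables.

## Tumor growth inhibition

Volumes are $V = L S^2/2$; swapped caliper pairs ($S > L$) raise an error
unless `fix_swapped = TRUE` auto-corrects them. The TGI statistic is

$$\mathrm{TGI}(\%) = \frac{V_c - V_t}{V_c - V_0} \times 100$$

on group **medians**, with $V_c, V_t$ the control/treated medians at the
endpoint and $V_0$ the *control* baseline median (a per-group-baseline
variant sits behind `baseline = "per_group"`). Values above 100
(regression below baseline) and below 0 (treated outgrew control) are
reported as-is. The endpoint is the last measurement day common to all
groups at or before the requested day; animals missing the endpoint
contribute their last earlier observation (carried forward, with a logged
count) — the convention for animals withdrawn at a humane volume cap. A
control that did not grow ($V_c \le V_0$) makes TGI undefined and raises
an error rather than returning an unstable ratio.

## Problem sizes and determinism

The packaged checks use sizes a laptop handles in seconds: 100 simulated
reference screens for hit sensitivity/precision, a
$3 \times 4$ noiseless $(D_m, m)$ recovery grid plus brute-force
grid-search oracle comparisons on noisy series, bisection-oracle checks of
the Loewe-additive CI, and 100 simulated xenograft studies against the
closed-form TGI. The end-to-end pipeline writes an MD5-checksummed
manifest and is byte-reproducible under a fixed seed.

## Known limitations

* The SI screen carries no error model; calls near the thresholds are as
  noisy as the underlying $F_a$ values, and the package reports `si_sd`
  only descriptively.
* The OLS median-effect fit weights all usable points equally; extreme
  $f_a$ values carry disproportionate log-odds leverage under
  heteroscedastic noise.
* The CI implementation covers the mutually exclusive form only; dose
  reduction indices and isobolograms are out of scope.
* TGI compares medians at one endpoint; it uses no longitudinal model and
  attaches no inferential test.
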