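---
title: "Methods: assay quantification, scoring and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assay quantification, scoring and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoflux)
```

`mitoflux` quantifies the standard colon-mitochondria assay battery of a
rodent colitis study. This vignette documents the models and conventions
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
choices made where the methodology left room.

## Slope extraction

Every assay reduces to the slope of a signal over time. Slopes are
ordinary least squares on the raw samples — no smoothing, since typical
respirometer and spectrophotometer exports are already low-noise at
1–5 s sampling and any filter would bias fast initial rates. Input
times are in seconds but **all rates are per minute**; the ×60
conversion happens once, inside `estimate_slope()`, which eliminates an
entire class of 60× unit errors downstream.

Two windowing modes exist because the assays differ in where their
informative rate lives:

* `fixed_window` — for assays whose rate is stable over a known segment
  (complex II/III, citrate synthase, respirometry states);
* `steepest_window` — scans every contiguous window of a given length
  and keeps the maximum |slope|, for assays where the fastest initial
  rate after substrate addition is the measurand (complex I after NADH).
  The default scan length is 30 s — wide enough for ≥ 10 samples at
  2 s sampling, short enough to stay inside the initial linear phase —
  and ties break to the earliest window start so results are
  deterministic.

## Respirometry

State 2 begins at the `homogenate` injection (substrate present, no
added ADP; the "state 2" label is kept as used in colon-homogenate
respirometry rather than re-mapped to state-4 nomenclature) and state 3
at the `ADP` injection. Windows avoid the injection transients: each
slope is taken at least `settle_time` (default 60 s) after its
injection, with the state-2 window being the `window_length`
(default 120 s) immediately preceding ADP and the state-3 window the
120 s starting 60 s after ADP. Concentration slopes become
whole-chamber fluxes via `J_O2 = −slope × V` (the colon protocol's
chamber holds 2.1 mL); consumption is positive, and a rising-oxygen
segment is returned with a QC flag rather than clipped. RCR is
state 3 / state 2 and is only defined for a positive state-2 flux —
a flat or rising state-2 segment raises an error rather than returning
an unbounded ratio.

Fatty-acid-oxidation runs have no ADP transition and are quantified by
`single_state_flux()` from a single post-injection window.

## ROS and percent electron leak

The Amplex Red calibration line is fitted **with** an intercept (the
blank fluoresces), but only its slope enters the conversion
`(AU/min) / (AU/µM) × V = nmol/min`. Superoxide is exactly twice the
H₂O₂ rate, by the dismutation stoichiometry.

For percent electron leak, two denominator conventions are
implemented. The default expresses leaked electrons relative to the
electrons delivered to O₂ — `100 · 2J_H2O2 / (4J_O2)` — reading the
leak as a shunt "as opposed to" complex IV flux. The alternative
(`denominator = "total"`) divides by all electrons,
`4J_O2 + 2J_H2O2`. At the ~1–2 % leaks these assays produce, the
conventions differ by under 0.05 percentage points, so the choice does
not affect any qualitative conclusion; it is exposed as a config
switch for transparency. Fluorescence slopes are taken over the same
windows as the paired respiration state, since ROS is recorded
simultaneously in the same chamber.

## Enzyme kinetics

Beer–Lambert conversion is
`rate = |dA/dt| / (ε·ℓ) × V_assay × 1000` nmol/min, with the
per-enzyme constants pre-populated in `default_assay_configs()`:
ε = 6.22 mM⁻¹cm⁻¹ at 340 nm (complex I, NADH), 19.1 at 600 nm
(complex II, DCPIP), 18.7 at 550 nm (complex III, cytochrome *c*),
13.6 at 412 nm (citrate synthase, DTNB thiolate). A slope opposing the
configured direction of change is returned negative with a QC flag —
it usually means an inverted or mislabelled trace. Inhibited
non-enzymatic backgrounds are subtracted; a negative net rate is again
flagged, never clipped, because silently zeroing over-subtraction
hides assay problems. When no background trace exists the background
defaults to 0 with a QC note.

The citrate synthase plate assay's optical pathlength depends on the
fill volume of the well and is not derivable from the reaction recipe,
so pathlength and final volume are required configuration; the
defaults (1 cm, 0.25 mL) trigger a warning urging real plate geometry.

Electron-flux units use the fixed equivalence {NADH 2, DCPIP 2,
cytochrome *c* 1, O₂ 4} — standard redox bookkeeping (two-electron
carriers, the one-electron heme of cytochrome *c*, four-electron O₂
reduction). Complex II accounting is the same 2 e⁻ whether followed
through succinate or DCPIP. Normalization to mitochondrial content
divides an electron flux per gram by the citrate synthase rate per
gram; the per-minute terms cancel, leaving nmol e⁻/nmol citrate.

## Disease activity

The DAI sums three 0–3 subscores. The weight-loss rubric's bins are
integer-labelled and non-contiguous (≤ 2, 3–6, 7–12, > 12 %), so the
percent loss is rounded to the nearest integer before lookup — every
input then maps to exactly one bin. Baseline is each animal's day-0
weight (dosing starts at day 0), scores use the same-day loss, and
`score_dai()` also reports each animal's peak score and peak loss as a
convenience, since disease severity is usually reported at its peak.

## Statistics

Two-group contrasts use the pooled-variance Student's t-test
(two-sided) — deliberately not Welch, matching the stated analysis
convention of the assays this package serves. Multi-group contrasts
use one-way ANOVA; the post-hoc is Tukey HSD (the standard companion,
attached when the omnibus test is significant at 0.05), switchable to
unadjusted pairwise t-tests. No multiple-testing correction is applied
across endpoints. When both groups are exactly constant (which happens
with saturated ordinal scores in small groups) the t-test degenerates:
equal means return t = 0, p = 1, unequal means p = 0.

## The synthetic-data generator

The generator is a forward model of the assays, not of the biology.
Traces are piecewise-linear latent signals — slopes implied by the
target rates and the chamber/assay volume, changing at injection
events — plus i.i.d. Gaussian noise; with zero noise, the analysis
stages recover the generating parameters to floating-point accuracy,
which is what the roundtrip tests assert. Respirometry traces start at
450 nmol/mL oxygen (a chamber oxygenated before tissue addition) so
that a 600 s two-state trace at control-like fluxes stays feasible; a
spec whose fluxes would exhaust the chamber raises an infeasibility
error instead of producing negative concentrations.

Cohorts draw per-animal endpoint values as group mean × lognormal
noise (mean-preserving, so sample means converge to the specified
means; physiological endpoints are positive, which rules out additive
Gaussian noise). The default between-animal CV is 15 % — chosen so the
encoded effects are detectable at n = 8/group while leaving the tests
non-trivial. The default effect multipliers encode the qualitative
sex × disease pattern the pipeline is designed to resolve: control
males below control females on complex I/II-driven respiration, MCFA
oxidation and complex II–IV activities; diseased males losing citrate
synthase, cardiolipin and catalase with a ~2-fold leak increase
(1.4-fold on MCFA); diseased females halving intact respiration and
RCR (4 → 2), losing complex I and IV activity, doubling leak on every
substrate, and showing colon shortening with hypertrophy; and
mitochondria-targeted therapy arms partially restoring female — but
not male — endpoints. Weight trajectories dip to a sex-specific nadir
(8 % male, 11 % female) at days 2–3 and rejoin the control growth
curve by day 7; stool categories follow a severity profile peaked at
days 2–3.

What the generator does **not** emulate: mechanistic ETC kinetics or
ROS chemistry (effects are phenomenological multipliers), oxygen
back-diffusion or instrument drift, injection artifacts (available but
off by default: real traces spike at injections), correlations between
endpoints within an animal, and day-7/day-30 recovery cohorts. Passing
tests therefore demonstrate that the *computations* are correct and
that the statistical machinery detects effects of the encoded size and
structure — not that real colon homogenate data will show those
effects.

## Numerical choices and degenerate inputs

* OLS r² is reported as `NA` for a zero-variance signal (slope 0 is
  still returned).
* Windows are inclusive of their endpoints; the sample at an event
  time belongs to both adjacent segments of a continuous piecewise
  trace, which is harmless for slope fitting.
* `steepest_window` requires ≥ 3 samples per window and errors
  otherwise, as does any fixed window with < 3 samples.
* Generators save and restore the session RNG state, so seeded
  generation never perturbs user code.
* Problem sizes in the test suite: roundtrips use 301-sample traces;
  the noise-recovery check uses 200 replicates against the analytic
  OLS standard error; the null-calibration check uses 2000 simulated
  t-tests at n = 6/group; the cohort regression test uses the default
  n = 8/group at CV 15 % under a fixed seed.

## Known limitations

Trace file ingestion expects delimited text in a declared dialect;
proprietary instrument formats must be exported to CSV first. Per-gram
normalization relies on caller-supplied tissue masses (the package
does not model homogenate dilution chains). The DAI weight subscore
uses same-day loss; studies reporting peak-loss-based scores should
read the peak table. The pipeline's trace quantification currently
covers respirometry and fluorescence channels end-to-end; absorbance
assays are quantified through the `quantify_enzyme()` /
`citrate_synthase_activity()` functions directly.
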