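# mitoflux

Quantification of mitochondrial bioenergetics assays — from raw
instrument traces to disease scores and group statistics — for rodent
colitis studies.

Physiology labs measuring colon mitochondrial function face the same
chain of computations in every study: oxygen-concentration traces from
a high-resolution respirometer must be turned into state-2 and state-3
fluxes and a respiratory control ratio; Amplex Red fluorescence must be
calibrated into H₂O₂ production and expressed as a percent electron
leak; absorbance kinetics for the electron transport chain (ETC)
complexes and citrate synthase must pass through Beer–Lambert
conversion, background subtraction and normalization to mitochondrial
content; daily animal observations must become a disease activity
index; and everything ends in sex-stratified group comparisons.
`mitoflux` implements that chain as composable, tested R functions,
plus a synthetic-data generator that emulates the traces and the
sex × treatment cohort structure so the entire pipeline can be
exercised and validated without animal data.

## The quantities computed

**Respiratory control ratio (RCR).** From an oxygen-concentration trace
with `homogenate` and `ADP` injection events, ordinary-least-squares
slopes (per minute) are taken over windows flanking the ADP event and
converted to whole-chamber fluxes, `J_O2 = −slope × V_chamber`. Then

```
RCR = J_O2(state 3) / J_O2(state 2)
```

with state 2 the substrate-only segment before ADP and state 3 the
ADP-stimulated segment after it. Well-coupled colon mitochondria sit
around RCR ≈ 4; uncoupling drives the ratio toward 1.

**Percent electron leak.** The Amplex Red assay reports H₂O₂; with
superoxide dismutase present, superoxide production is stoichiometrically
`J_SO = 2 · J_H2O2`. Each superoxide carries one leaked electron and each
O₂ reduced at complex IV accepts four, so

```
percent leak = 100 · (2 · J_H2O2) / (4 · J_O2)
```

measured simultaneously with respiration in the same chamber.

**Enzyme activities.** An absorbance slope `dA/dt` becomes a rate via
Beer–Lambert, `rate = |dA/dt| / (ε · ℓ) × V_assay`, using the assay's
extinction coefficient (NADH 6.22 mM⁻¹cm⁻¹ at 340 nm for complex I,
DCPIP 19.1 at 600 nm for complex II, cytochrome *c* 18.7 at 550 nm for
complex III, DTNB thiolate 13.6 at 412 nm for citrate synthase).
Inhibited non-enzymatic background rates are subtracted; complex IV is
measured polarographically as oxygen consumption. Rates convert to
electron flux (2 e⁻ per NADH or DCPIP, 1 per cytochrome *c*, 4 per O₂)
and normalize to citrate synthase activity — the mitochondrial-content
marker — giving nmol e⁻/nmol citrate.

**Disease activity index (DAI).** Sum of three 0–3 subscores: percent
weight loss from the day-0 baseline (0: ≤ 2 %, 1: 3–6 %, 2: 7–12 %,
3: > 12 %), stool consistency (normal → diarrhea) and stool color
(brown → bloody). Colon weight/body weight and colon weight/colon
length ratios index hypertrophy.

**Statistics.** Groups are summarized as mean ± SEM and compared with
the unpaired pooled-variance Student's t-test (two groups) or one-way
ANOVA with Tukey HSD post-hoc (more), with the usual star thresholds
(\* ≤ 0.05 through \*\*\*\* ≤ 0.0001).

## Worked example

```r
library(mitoflux)

# a noiseless synthetic respirometry trace: state-2 flux 25, state-3
# flux 100 nmol O2/min in a 2.0 mL chamber, homogenate at 60 s,
# ADP at 360 s
tr <- make_trace(trace_spec("respirometry", state2_flux = 25,
                            state3_flux = 100, chamber_volume = 2.0))
segment_states(tr, chamber_volume = 2.0)
#> <respiration_states>
#>   state 2: 25 nmol O2/min  (window [240, 360] s)
#>   state 3: 100 nmol O2/min  (window [420, 540] s)
#>   RCR:     4

# calibrated ROS: fluorescence slope 10 AU/min against a 10 AU/uM
# calibration in 2 mL, paired with J_O2 = 100 nmol O2/min
cal <- fit_calibration(c(0, 1, 2), c(5, 15, 25))
ros_result(10, cal, 2.0, 100)
#> <ros_result> J_H2O2 = 2 nmol/min, J_SO = 4 nmol/min
#>   percent electron leak = 1% (against J_O2 = 100 nmol O2/min)

# a full synthetic cohort and the sex-stratified comparisons
co <- make_cohort(cohort_spec(n_per_group = 8, seed = 1))
cmp <- compare_endpoints(co$endpoints, c("rcr", "leak_ci", "cs_activity"))
cmp[, c("endpoint", "stratum", "p_value", "stars", "fold_change")]
#>      endpoint stratum      p_value stars fold_change
#> 1         rcr  female 1.458563e-04   ***   0.4633709
#> 2     leak_ci  female 3.097237e-08  ****   1.9454862
#> 3 cs_activity  female 4.970189e-01    ns   0.9403355
#> 4         rcr    male 4.674189e-01    ns   1.0513980
#> 5     leak_ci    male 6.855387e-07  ****   1.9087461
#> 6 cs_activity    male 1.428558e-05  ****   0.6162265
```

The cohort comparison reads exactly as the assays are designed to:
females lose respiratory coupling (RCR falls to about half, p ≤ 0.001)
while males do not; electron leak roughly doubles in both sexes; and
the citrate synthase (mitochondrial content) loss is male-specific.

The whole chain also runs from one config:

```r
run_pipeline(default_config(seed = 1, output_dir = "results_run"))
# writes endpoints.csv, dai_scores.csv, dai_daily.csv,
# comparisons.csv, config_used.yaml, run_log.txt
```

or from the shell via `exec/mitoflux <simulate|quantify|score|stats|run>`.

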