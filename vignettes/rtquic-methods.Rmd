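---
title: "RT-QuIC positivity calling, titration and simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-QuIC positivity calling, titration and simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtquic)
```

## The analysis procedure

RT-QuIC (real-time quaking-induced conversion) amplifies misfolded protein
seeds by cyclic shaking of a recombinant substrate and reports conversion as
thioflavin T (ThT) fluorescence, in relative fluorescence units (RFU), read
once per hour per well. This package implements the standard calling
procedure for such runs.

**Threshold.** Each plate gets its own positivity threshold

$$T_p = \bar{B}_p + m \cdot s_p,$$

where $\bar{B}_p$ and $s_p$ are the mean and sample standard deviation
(n−1 denominator) of the *pooled* set of the first $k$ readings of every
non-excluded well on the plate, with defaults $k = 5$ and $m = 10$. Three
readings of "mean of the first five measurements of all wells plus 10 SD"
are arithmetically possible — pooling all well × read values, a per-timepoint
SD, or a per-well SD later averaged. We use the single pooled estimate: the
procedure describes one average and one SD, and the pooled reading is the
simplest faithful one. The choice matters little in practice (baseline read
noise is small against between-well baseline spread) but is fixed and
documented so thresholds reproduce bit-exactly. Controls are pooled too
(`include_controls_in_threshold = TRUE`): non-carrier control wells are
seeded reactions like any other. Per-plate thresholds are never shared
across plates.

**Well metrics.** `RFU_initial` is the single reading at the starting point
(not an early-read average); `RFU_max` is the maximum over the analysis
window $[0, 40]$ h inclusive, even when the run is longer; the ratio
`RFU_max / RFU_initial` summarises response strength. A well *crosses* when
any in-window reading is **at or above** $T_p$ (inclusive, so ties resolve
deterministically), and its lag phase is the earliest measured timepoint at
or above $T_p$. We deliberately do not interpolate between hourly reads:
lags in this assay are conventionally reported as whole-hour ranges matching
the read schedule, and interpolation would invent precision the instrument
does not provide. A zero `RFU_initial` makes the ratio undefined; this is
flagged, not an error.

**Replicate calling.** A sample × dilution group is positive iff at least
`min_positive_replicates` (default 2) of its replicate wells (default 4)
crossed. A group with exactly one crossing well is negative but carries
`spontaneous_flag`: single-well responses occur occasionally even without
seed, and the flag preserves the audit trail without changing the call.
Replicate counts other than 4 are supported but must be configured
deliberately.

**Titration.** Dilutions are stored as integer exponents relative to tissue
(10⁻² ≡ 1% homogenate), never floats. The endpoint is the most dilute
(most negative exponent) positive call; ND means no positive call at any
tested exponent. Series are *not* truncated at the first negative: reaction
inhibitors in crude homogenates can weaken the least dilute (10⁻³) wells, so
a negative below a more dilute positive is legitimate and flagged
(`inhibited_low_dilution_flag`, `monotone = FALSE`). Endpoints compare on
the total order ND < 10⁻³ < 10⁻⁴ < … with ND placed exactly one step below
the least dilute tested level; comparisons never coerce ND to a number.
Fold differences between two defined endpoints are $10^{|e_a - e_b|}$ —
the only quantitation endpoint dilution supports; no continuous titre (e.g.
SD50) is inferred.

## The synthetic plate generator

Real raw fluorescence data for assays of this kind are rarely deposited, so
the package ships a generator with known ground truth against which every
pipeline stage is validated. It is a deliberately minimal mechanistic
stand-in, not a fitted model:

- **Conversion** is single-hit Poisson: a well at effective dose $d$
  converts with probability $1 - e^{-d}$, where
  $d = 10^{\log_{10}\text{titre} + e}$ at dilution exponent $e$. This one
  assumption reproduces the partial-well positivity (2–3 of 4) seen near
  endpoints.
- **Kinetics** of a converted well follow a logistic curve
  $F(t) = B + (P - B)/(1 + e^{-(t - T_{lag})/\tau}) + \varepsilon(t)$,
  clipped to $[0, 260{,}000]$ RFU, with
  $T_{lag} = \alpha + \beta \max(0, -\log_{10} d) + \text{jitter}$:
  lag grows with dilution only below unit dose, where finding a seed is
  already improbable. Unconverted wells are baseline plus noise.
- **Spontaneous positives** occur per well with probability
  `p_spontaneous` (default 0.01) and use the same curve with a lag drawn
  uniformly in the final third of the run — late, isolated, and correctly
  dismissed by the 2-of-4 rule.
- **Inhibition** at low dilutions (default at 10⁻³) attenuates both the
  effective dose and the plateau, because inhibited reactions show *both*
  longer lags and lower `RFU_max/RFU_initial` ratios.

### Calibration of defaults

Only two instrument anchors and some narrative lag ranges constrain the
kinetics, so the defaults are calibration choices, documented as such, not
measurements: baseline 4,000 ± 1,500 RFU between wells with 800 RFU read
noise — giving pooled thresholds of
$\approx 4000 + 10\sqrt{1500^2 + 800^2} \approx 21{,}000$ RFU, inside the
typical 15,000–25,000 band; plateau 180,000 ± 20,000 RFU under the 260,000
saturation ceiling; $\tau = 1.5$ h; $\alpha = 20$ h; $\beta = 5.5$ h per
decade below unit dose; lag jitter SD 0.9 h. A logistic curve crosses the
threshold $\tau \ln((P-B)/(T_p-B) - 1) \approx 2{-}4$ h before its
midpoint, so $\alpha = 20$ h centres strong-dose crossings near 17 h and
keeps them in the 14–20 h band; near-endpoint wells (dose within a decade
of 1) cross by ~26 h and wells a further decade out by ~31 h, inside the
up-to-34 h envelope. Gaussian draws for baseline and plateau are clamped at
±2.5 SD and lag jitter at ±2 SD: the emulated phenomenology has tightly
banded lags, and unclamped tails would occasionally produce curves no real
plate shows. Preset titres use the convention that an uninhibited sample
with $\log_{10}\text{titre} = k$ has unit dose at $10^{-k}$, where
$P(\geq 2\text{ of }4) \approx 0.86$, and ~0.05 one dilution further — so
its analytic endpoint is $-k$; inhibited colon samples with endpoint 10⁻³
use titre 3.4 so the 10⁻³ wells convert with probability ≈ 0.59,
reproducing partial-well calls at the least dilute step.

### Determinism

Every well owns a private RNG substream seeded by a hash of (master seed,
plate, sample, dilution exponent, replicate). Identical configurations are
byte-identical, and adding or removing a well never perturbs any other
well's draws. The draw order within a well is fixed regardless of which
branch (converted / spontaneous / flat) is taken.

### The analytic endpoint

The truth table records each sample's *analytic* endpoint: the most dilute
tested exponent where $P(\geq 2$ of $4$ wells convert$) \geq 0.5$ under the
model (binomial over the per-well conversion probability, spontaneous rate
included). Recovery tests compare pipeline endpoints against this quantity
on the ND-aware step scale, counting ND ↔ 10⁻³ as a one-step discrepancy.

## What the generator does and does not emulate

It emulates: dose-dependent lag and partial-well positivity along serial
ten-fold dilutions; flat negatives; occasional late single-well spontaneous
positives; 10⁻³ inhibition; instrument saturation; per-plate threshold
variation. It does **not** emulate: nucleation–polymerisation chemistry
(no rate constants are fitted), substrate depletion, shaking/bead
mechanics, temperature effects, plate-edge effects, cross-well
contamination, or drifting baselines. Passing tests therefore demonstrate
that the *calling and titration rules* behave correctly on data with the
study's phenomenology — not that the generator's curves are statistically
indistinguishable from any particular instrument's output.

## Degenerate inputs and numerical conventions

An all-constant plate has SD 0 and threshold equal to the constant, so
every well "crosses" at t0 — correct under the rule, and a reminder that
the threshold formula assumes real baseline noise. Saturated readings are
retained and flagged, never dropped: saturation still evidences
positivity. Readings above the ceiling are an error unless clipping is
requested explicitly. CSV round-trips are bit-exact: doubles are written
with 17 significant digits and re-parsed with `strtod` rather than the
fast (1-ulp-lossy) CSV parser. The threshold identity
$T_p - \bar{B}_p = m \cdot s_p$ holds to 1e−9 relative tolerance.

## Problem sizes used in validation

The shipped validation suites use 20 simulated plates for threshold/lag
calibration checks, 100 simulated three-plate cohorts (≈ 1,800
sample-runs, 600 control samples) for endpoint recovery, 1,000 wells for
the unit-dose conversion self-test, and exhaustive enumeration of all 2⁴
replicate crossing patterns for the calling rule. These sizes give
3-binomial-SD margins on every stochastic check while keeping the full
suite inside a few minutes on one CPU.

## Known limitations

Cross-run concordance ("detected at least twice") is not auto-merged:
repeat assays of the same sample are exposed as separate per-run calls, and
the concordance convention is left to the analyst since no single rule is
universal. No well-exclusion heuristics (e.g. edge-well rules) are
provided; `excluded` is a manual flag. Endpoint comparison is
semi-quantitative by design; if continuous titres are needed, an SD50-style
estimator should be layered on top rather than read off endpoints.
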