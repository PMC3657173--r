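---
title: "Screening fibroblasts for collagen VI deficiency by flow cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening fibroblasts for collagen VI deficiency by flow cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(col6screen)
```

## The assay and what the package computes

Cultured skin fibroblasts secrete collagen VI into their extracellular
matrix. In Ullrich congenital muscular dystrophy (UCMD) mutant collagen VI
is largely retained intracellularly, so surface immunolabelling collapses;
in Bethlem myopathy (BM) the reduction is milder and more variable. The
flow-cytometry screen immunolabels a fibroblast suspension with an
anti-collagen VI antibody plus a PE-conjugated secondary, acquires 15,000
events per sample, and reads out the percentage of antigen-positive cells.
Each subject is measured twice: without permeabilisation (surface antigen
only) and with detergent permeabilisation (surface + intracellular antigen).

Three derived quantities carry the clinical signal:

* **percent positive** per sample — events above the positivity gate;
* **retention** per subject — permeabilised minus non-permeabilised percent
  positive, an estimate of intracellular accumulation in percentage points;
* **severity band** per subject — surface percent positive below 37%
  (`UCMD_range`), above 44% (`BM_or_control_range`), or in between
  (`indeterminate`).

## Gate calibration

No instrument threshold separates "positive" from "negative" by itself; the
screen calibrates it per staining batch from a **negative control** in which
the primary antibody is omitted. `derive_positive_gate()` takes the
empirical quantile $q$ of the control's PE channel and uses it as the
threshold for every sample of the batch; an event is positive iff its
fluorescence is strictly greater.

Choices that matter:

* **Quantile, default $q = 0.99$.** The assay description fixes the
  mechanism (gate set from the negative control) but not the quantile; 1%
  is the conventional false-positive allowance for a no-primary control and
  is exposed as a parameter.
* **Type-1 (inverted-CDF) empirical quantile.** The threshold is always an
  observed control event, which makes the derivation exactly reproducible
  by a full sort (`sort(x)[ceiling(n * q)]`) and keeps quantiles commuting
  with monotone transforms — deriving on log10 fluorescence and
  exponentiating gives bit-identical gates.
* **Strict inequality; ties go negative.** For a deficiency screen the
  conservative direction is to under-call positives.
* **Side scatter.** The acquisition is displayed as SSC vs PE, but no
  debris-exclusion bounds are part of the method; an optional
  `ssc_window` is provided and off by default.

A direct consequence of quantile gating: for a sample with true positive
fraction $p$, the expected estimate is not $p$ but

$$\mathbb{E}[\hat p] \approx p + (1 - q)(1 - p),$$

because a fraction $(1-q)$ of the genuinely negative events sits above the
background threshold. At $q = 0.99$ this is at most one percentage point
(+0.8 points for a UCMD-like sample, +0.35 for a control-like one). The
package reports raw gated percentages — as the assay does — and does not
background-correct; the recovery experiments below must be read with this
offset in mind.

## Group statistics

`group_comparison()` fits ordinary least squares of the measure on group
indicator variables with the control group as reference. With dummy coding
the coefficients are *exactly* the group-mean differences from controls (a
property the test suite asserts against a hand-solved normal-equations fit),
and each coefficient's two-sided $t$ test gives the per-group p value. No
multiple-testing correction is applied: the screen makes two contrasts
(BM vs control, UCMD vs control). Groups of size one are allowed but
flagged; a zero-residual fit is reported with a degeneracy flag instead of
fabricated standard errors. Group summaries use the sample SD
($n-1$ denominator), matching the mean ± SD convention for small groups.

`deficiency_ratio()` is the case/control ratio of group mean surface
expression; in the published cohort it quantifies UCMD expression at less
than one third of control levels (19.6/65.3 ≈ 0.30).

The 37/44 classification cuts are the observed separation between the
diagnostic categories in the published cohort (all UCMD below 37, all BM
above 44). They are defaults, not re-optimised cutoffs: the package keeps
the gap explicit as `indeterminate` rather than forcing a single cutoff,
and deliberately does not attempt to separate BM from controls, whose
ranges overlap (44.8–66.2 vs 50.0–76.9).

## The synthetic cohort generator

No event-level data accompany the published screen, so the package ships a
generator whose defaults *are* the published study conditions, making every
downstream stage testable and the whole pipeline's calibration checkable.

**Event level.** Each event is independently antigen-positive with the
sample's true fraction. Fluorescence is log-normal per population —
negative centred at $10^{1.0}$, positive at $10^{3.0}$, both with SD 0.35
decades — i.e. two clean decades of separation, more than 4 SD, matching
the clean bimodality that gate-based counting presumes. The display-axis
convention (log-scale PE) is the only distributional hint the assay
description gives; log-normal populations are the standard cytometry
idealisation. Side scatter is normal (mean 450, SD 90, floored at 0) and
carries no signal. Values are stored linear.

**Subject level.** Biological variability is placed on the true positive
fraction, not on fluorescence intensities: the assay reports only percent
positive, so a per-subject fraction drawn from the group distribution is
the minimal faithful noise model. Fractions follow truncated normals with
the published mean, SD and range per group:

| group | staining | mean ± SD (%) | range (%) | n |
|---|---|---|---|---|
| control | surface | 65.4 ± 10.7 | 50.0–76.9 | 5 |
| BM | surface | 54.1 ± 8.0 | 44.8–66.2 | 5 |
| UCMD | surface | 19.6 ± 10.0 | 9.7–36.8 | 8 |
| control | permeabilised | 95.3 ± 2.2 | 90–100 | 5 |
| BM | permeabilised | 96.1 ± 2.2 | 90–100 | 5 |
| UCMD | permeabilised | 90.5 ± 2.2 | 90–100 | 8 |

Two derived choices deserve flagging:

* **Mean calibration.** A normal with mean 19.6 and SD 10 truncated to
  [9.7, 36.8] has expectation ≈ 21.5, not 19.6: published summary
  statistics describe the *observed, bounded* data, so treating the printed
  mean as the latent normal's location would build a biased generator. The
  package instead solves (closed-form truncated-normal mean + `uniroot`)
  for the latent location whose truncated mean equals the printed mean, for
  every group. `draw_group_fractions()` therefore reproduces each printed
  group mean in expectation, which is what makes end-to-end parameter
  recovery a meaningful test.
* **Permeabilised BM/UCMD means are back-derived.** The source states only
  that permeabilised staining exceeded 90% in every group (controls
  95.3 ± 2.2). The BM and UCMD permeabilised means are reconstructed as
  group surface mean + printed group retention mean (54.1 + 42.0 = 96.1;
  19.6 + 70.9 = 90.5) with the control SD, clipped to [90, 100], so the
  printed retention means are recoverable. They are a reconstruction, not
  published values.

Pairing enforces permeabilised ≥ surface fraction per subject
(intracellular staining can only add positives). One negative control is
generated per batch, mirroring the shared-gate design. Seeds are
hierarchical — a base seed deterministically yields per-sample seeds — so
any single sample regenerates in isolation, and identical configurations
give bit-identical cohorts.

**What the simulator does not emulate**: spectral spillover and
compensation, doublets and debris (hence no default SSC gate), acquisition
drift, antibody-binding kinetics, or qualitative abnormalities of the
collagen VI network that leave percent positive unchanged — the known blind
spot of the real assay for mild BM. Passing tests on synthetic cohorts
demonstrate that the *analysis* is calibrated and self-consistent, not that
the assay separates patient groups on any particular instrument.

## Numerical and degenerate-input choices

* Empirical quantiles: type 1 everywhere, for exact oracle agreement.
* Truncated-normal draws use the inverse-CDF transform (one uniform per
  draw) — reproducible and order-stable; `sd = 0` collapses to the mean;
  calibration rejects targets on or outside the truncation bounds; the
  root bracket (±6 SD beyond the range) spans every attainable interior
  mean while keeping both normal tails representable in double precision.
* Negative retention (permeabilised < surface) is physically implausible;
  it is returned but warned about, and the cohort generator cannot produce
  it by construction.
* A negative control with fewer than 100 events warns (noisy threshold);
  an empty SSC window, an absent channel, an inverted pair of
  classification cuts, and a missing batch negative control are errors.
* Sample files that fail to read are recorded as failed results; the batch
  continues and reports the failure count.
* FCS: only float32 list-mode is written (offsets kept consistent between
  HEADER and TEXT; `$BEGINDATA`/`$ENDDATA` authoritative if the file
  outgrows the 8-character header fields). Integer list-mode (uniform
  16-bit unsigned or 32-bit) is read-only. Multi-dataset files, ANALYSIS
  segments, spillover keywords and escaped delimiters inside keyword
  values are unsupported and rejected explicitly.

## Problem sizes used in the shipped experiments

The bundled tests and the acceptance script simulate 15,000 events per
sample wherever the check concerns the assay's standard acquisition
(gate calibration, recovery of group means through the full pipeline:
200 subjects per group), and 300–2,000 events where the check is
structural (round trips, determinism, report plumbing). Replicate
significance uses 100 subject-level cohorts at the original 5-control /
8-UCMD sizes; with a ≈ 45-point effect against a ≈ 10-point SD the
UCMD-vs-control contrast is expected below p = 0.001 in essentially every
replicate. A full run of suite plus acceptance script completes in well
under a minute on one CPU.

## Known limitations

* The severity bands are descriptive of one 18-subject cohort; they are
  not ROC-optimised and carry no uncertainty statement. Values in the
  44–50% corridor classify as `BM_or_control_range` yet sit below every
  observed control; clinical context must stay in the loop.
* Raw gated percentages carry the $(1-q)(1-p)$ background term discussed
  above; comparisons between groups are unaffected (the term is nearly
  constant across groups), but absolute percentages are biased upward by
  up to one point at the default quantile.
* The generator's two-population model cannot express partially shifted
  (smeared) fluorescence distributions, where gate-based counting and
  median-shift readouts would diverge.
* BM vs control separation is genuinely limited in the real assay — one
  published BM value exceeded the control average — and nothing in the
  analysis layer can recover signal the measurement does not contain.
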