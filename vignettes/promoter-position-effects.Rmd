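---
title: "Measuring chromosomal position effects on promoter activity from microplate reporter kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromosomal position effects on promoter activity from microplate reporter kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoflux)
library(dplyr)
```

## The measurement problem

A transcriptional reporter module — a promoter fused to a stable yellow
fluorescent protein, insulated by strong terminators — is inserted at
defined chromosomal positions of *Escherichia coli* (origin-, middle- and
terminus-proximal sites on both replichores: OL, OR, ML, MR, TL, TR, plus
special sites such as MLup directly upstream of the ribosomal operon
*rrnG* and a site downstream of the *araBAD* operon). Cultures grow in a
microplate reader that records optical density (595 nm) and fluorescence
(485/535 nm) every 10 minutes for up to 23 hours. The question is how the
chromosomal context — replication-associated gene dosage, nucleoid
structure, supercoiling domains, upstream transcription — changes the
promoter's output, and how that changes when a nucleoid-associated
protein such as HU is deleted (the *hupA/B* mutant).

nucleoflux implements the complete quantitative path from raw plate
readings to position-resolved promoter statistics, plus a synthetic plate
generator that provides ground truth for every stage.

## From raw signals to expression

Raw signals are corrected per time point:

* **OD**: subtract the time-matched mean of the blank wells (medium
  only).
* **Fluorescence**: subtract the time-matched mean of the background
  wells — a non-fluorescent strain that grows and autofluoresces but
  carries no reporter.
* **Expression**: `F/OD`, the ratio of the corrected signals, a
  per-biomass reporter level.

Whether reference wells should be matched by time or by optical density
is genuinely open; we match by time because the protocol corrects each
recorded time point, and because OD-matching would require an
interpolation model for the reference wells. The reference aggregate is
the mean, not the median: plates carry few reference wells and the noise
is approximately Gaussian.

Division by near-zero OD is meaningless, so F/OD is only defined where
corrected OD exceeds `od_epsilon` (default 0.01 absorbance units,
roughly three standard deviations of typical plate noise above zero);
other points are masked, never interpolated. Negative corrected
fluorescence is clamped to zero before division by default (`clamp_f`),
since negative reporter signal is unphysical; the unclamped path is kept
for diagnostics.

## Two promoter-activity estimates

**Discrete activity.** The first difference of expression,
\[
[d(F/OD)]_n = (F/OD)_n - (F/OD)_{n-1},
\]
is the simplest proxy for instantaneous promoter output. Signed values
are always retained (`d_fod_raw`); the clipped profile
(`d_fod_clipped = max(d, 0)`) exists for display, because transient
negative differences are measurement noise, not repression. Differences
telescope exactly to the net expression change, and the statistic is
invariant to constant offsets in F/OD.

**Spline synthesis rate.** For a stable, non-maturing reporter the
accumulation model is \(dF/dt = q(t)\,OD(t)\), so the per-biomass
synthesis rate is \(q(t) = F'(t)/OD(t)\). Corrected fluorescence and OD
are each fit with a least-squares cubic B-spline; the fluorescence
spline is differentiated analytically and divided by the OD spline
(floored at `od_epsilon`).

Knot selection does not use generalized cross-validation; interior knots
are placed at quantiles of the observation times and adjusted so the
Schoenberg–Whitney conditions hold — every cubic basis function's
support contains data, with a strictly interleaving assignment of points
to basis functions — which guarantees a unique least-squares solution.
This trades some smoothness optimality for speed and transparency; on
plate-reader noise levels the quantile-placed least-squares cubic spline
preserves the signal while suppressing noise. The default interior knot
count is `max(4, floor(N/12))` for `N` points — about one knot per two
hours of 10-minute data. Derivatives of cubic splines are unreliable
near the boundary, so evaluation excludes a 30-minute margin at each end
by default.

One numerical nuance: the least-squares residual is guaranteed
non-increasing only under *nested* knot refinement (adding knots to an
existing vector). Quantile-selected knot sets of different sizes are not
nested, so the residual can rise slightly between adjacent counts even
on noiseless data; coarse-to-fine improvement still holds.

Reporter maturation and degradation are deliberately neglected — YFP is
stable on the experiment's timescale and the F/OD interpretation itself
assumes accumulation. A maturation-corrected estimator would need rate
constants the data do not constrain.

## Induction responses and cross-position normalization

The oxidative-stress response of a module is quantified as the total
increase in F/OD over a fixed window after treatment:
`delta_fod = F/OD(t_treat + window) - F/OD(t_treat)`, with endpoints
taken at the nearest measurement grid point (the 10-minute cadence makes
the default 40-minute window exactly four steps; interpolation would add
nothing). The defaults `t_treat = 170` min and a 40-minute window follow
the reference protocol, where the response to 50 µg/ml hydrogen peroxide
is essentially complete after 40 minutes. Negative responses are floored
at zero and flagged.

Absolute responses are not comparable between experiments (detector
gain, inoculum, plate effects), so each position's response is
normalized to the total response of all positions within the same
genetic background and experiment:
\(p_i = 100\, r_i / \sum_j r_j\). If all k positions contribute equally
each fraction is \(100/k\) — for the six-position design 100/6, about
17% — so deviations from that reference line are position effects.
Zero-total groups are flagged rather than divided. Between-replicate
dispersion (per-position min/max/sd of the fractions across experiments)
summarizes how reproducible the position pattern is; strong fluctuation
is the signature of the HU-deficient background.

## What the simulator emulates

`plate_scenarios()` builds a set of scenario configurations mirroring
the study conditions; `render_plate()` turns one into measured wells,
layout and a ground-truth record.

**Growth** is piecewise logistic: inoculation at 1:200 of the carrying
capacity, an initial lag, logistic growth at maximal specific rate
`mu_max`, and an optional intermediate lag in which growth pauses —
emulating the pause seen when cells from a rich starter culture must
re-activate amino-acid biosynthesis in minimal medium. Defaults:
`mu_max` 0.028 min⁻¹ and capacity 0.55 in casamino-supplemented medium,
0.020 min⁻¹ and 0.45 in plain minimal medium, lags of 40/60 min; the
HU-deficient background grows at 0.8× the wild-type rate. These are
plausible plate-reader magnitudes for *E. coli* in M9-based media, not
fitted values.

**Promoter programs** express archetypes as gains on growth state, with
per-biomass activity `a(t) = base_rate × gain(t)`:
growth-rate-coupled (fis-like, on in exponential phase), constitutive
with a mild stationary rise (hns-like), and stationary-phase-induced
with weak exponential activity, transient intermediate-lag activation
and an inducible oxidative-stress pulse that switches off 40 minutes
after treatment (dps-like). The pulse's hard stop stands in for
regulator shutdown, for which no kinetic mechanism is modelled.

**Position effects** combine (i) gene dosage,
\(2^{c\,(1-x)\,\mu(t)/\mu_{max}}\) for relative origin distance
\(x \in [0,1]\) — origin-proximal modules gain up to \(2^c\)-fold during
fast growth and the effect vanishes in stationary phase, matching the
observation that the stationary-induced module shows no copy-number
effect while the induction-phase measurements do; (ii) a constant
genotype-specific multiplier (1 in wild type; in the mutant e.g. 2.5 for
the supercoiling-sensitive module at MLup versus ML, the midpoint of the
observed 2–3-fold excess, and weaker/stronger factors at TR/MR where
only the sign is known); (iii) a lognormal between-replicate fluctuation
(CV 0.4 in the mutant, 0 in wild type), drawn once per insertion locus
and experiment and shared by paired conditions of the same experiment —
so paired contrasts such as arabinose on/off remain reproducible while
the position pattern fluctuates between experiments; and (iv) an
upstream-transcription coupling factor (0.5 in the mutant's ara
scenario: active upstream transcription halves the module's output;
1 in wild type).

**Measurement** adds a blank offset (0.04), Gaussian noise (OD sd 0.003,
fluorescence sd 5), and autofluorescence proportional to live biomass
(150 units per OD), then truncates at zero as a real detector does.
Background wells share their scenario's growth parameters so the
autofluorescence correction is exact in truth-recovery tests — an
idealization of the real protocol, where one wild-type strain serves as
background for all genotypes.

**Replicates**: five per condition in the induction, fis-pair and ara
scenarios (matching the five independent induction experiments of the
reference design), three in the growth-phase and media scenarios.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: reporter maturation and degradation,
evaporation and edge effects, diauxic or nutrient-explicit growth,
mechanistic supercoiling dynamics, and cell-to-cell heterogeneity; it
also assumes a shared, exactly synchronous time grid across wells.

## Operational statistics

Cross-condition comparisons need scalar summaries, which the study
figures imply but do not define; the package fixes them as:

* **End-point expression**: mean F/OD over the final 60 minutes of
  unmasked data (`endpoint_fod()`), the "final reporter amount".
* **Exponential-phase expression**: mean F/OD over points where
  corrected OD lies between 10% and 60% of the well's maximum
  (`exponential_mean_fod()`) — mid-exponential growth, excluding the
  low-density region where the F/OD ratio is noise-dominated.

## Problem sizes and verification

The test suite validates every stage against independent oracles at
small, fast sizes: closed-form correction and difference examples;
Schoenberg–Whitney admissibility on 200 random sampling patterns;
cubic-polynomial reproduction of the least-squares spline to 1e-8
relative; plateau recovery of a piecewise-constant synthesis rate within
5% and agreement with a central finite-difference oracle within 1% on
noiseless 1-minute-grid wells; and end-to-end parameter recovery from
rendered plates — the 2.5-fold fis-pair position effect, the 2.5-fold
media effect (recovered in the 2–3 band), the 0.5× arabinose coupling
(within 20% over three seeds), and strictly larger between-replicate
dispersion in the HU-deficient induction scenario over five seeds.
Standard plates are 139 ten-minute time points (23 h); induction plates
are 35 points (340 min); oracle wells use 1-minute grids without noise.

## Limitations

The F/OD statistic inherits every assumption above: stable reporter,
well-mixed cultures, reference wells that track the samples. The
synthesis-rate estimator is a derivative of a smoother and so trades
bias for variance through the knot count; it should not be read within
30 minutes of the series boundaries. The simulator's mutant parameters
(fluctuation CV, position multipliers beyond the fis pair, reduced
dosage) encode the *direction* of the reported effects with free
magnitudes; recovery tests validate the pipeline, not the biology.
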