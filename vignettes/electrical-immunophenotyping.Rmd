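---
title: "Electrical immunophenotyping from cyclic voltammetry: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrical immunophenotyping from cyclic voltammetry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltphen)
```

## The measurement model

A two-electrode cell holding 500 µL of culture media behaves, to first
order, as a capacitor: the electrode double layer and the media between the
electrodes store charge. Suspended cells add membrane capacitance. Because
the specific capacitance of a biological membrane is nearly universal
(~1 µF/cm² = 0.01 F/m²), the added capacitance is proportional to the total
membrane area in the gap — which is why capacitance ranks cell types by
size. `voltphen` models the suspension as

$$C_\mathrm{tot} = C_\mathrm{media} + c_\mathrm{spec} \sum_{j=1}^{n} A_j,$$

with per-cell membrane areas $A_j$ drawn log-normally around a type-specific
mean (log-normal because areas are positive and right-skewed).

Under a cyclic-voltammetry sweep the capacitive (non-Faradaic) current obeys

$$i(t) = C\,\frac{dv}{dt},$$

so a triangular sweep at scan rate $S_\mathrm{rate}$ draws a constant
$|i| = C \cdot S_\mathrm{rate}$ on each branch. Inverting this relation,
sample by sample, is the core computation:
$C(t) = i(t) \big/ (dv/dt)(t)$.

Two non-idealities are modelled explicitly:

* a **series resistance** $R_s$ (media/electrode access resistance). The
  capacitor voltage then follows $C\,dv_c/dt = (v - v_c)/R_s$. For a
  staircase input this equation has an exact per-step solution
  ($v_c \leftarrow v + (v_c - v)\,e^{-\Delta t/R_sC}$), which the simulator
  uses directly; the reported current is the mean charging current over each
  step, $C\,\Delta v_c/\Delta t$. This update is exact and stable for any
  ratio of step duration to time constant — important because the default
  conditions sit deep in the relaxed regime ($R_sC \approx 10^{-4}$ s versus
  a 0.05 s step), where a naive explicit Euler step on the acquisition grid
  would diverge. In that regime the current reduces exactly to
  $C \cdot S_\mathrm{rate}$ mid-branch, so extraction remains unbiased.
* a **Faradaic reduction peak**: a Gaussian-in-potential cathodic current
  centred at −0.2 V, applied on the negative-going branch only. Only the
  peak's location is empirically established for this system; the Gaussian
  shape is the package's modelling choice, chosen as the simplest localized
  peak. The peak biases the extracted capacitance on the cathodic branch by
  exactly $i_f(v)/S_\mathrm{rate}$ — which is what makes the capacitance
  curve *peak in time* and provides the stable readout instant used by the
  concentration analysis.

## The excitation program

The canonical program sweeps 0.9 → −0.9 V with a potential step
$E_\mathrm{step}$ = 2 mV at $S_\mathrm{rate}$ = 0.04 V/s: 900 steps of
0.05 s per half-sweep, 90 s per cycle. The scan rate is specified in V/s and
the step duration derived as $E_\mathrm{step}/S_\mathrm{rate}$; this is the
dimensionally coherent convention (an instrument-style "seconds per step"
reading of the same number would be redundant with the two other
parameters). One sample is taken per potential step, at the step end,
matching how a staircase potentiostat acquires. The sweep starts at the
positive vertex and descends first, so the reduction peak is encountered on
the first half-sweep; both the start vertex and the cycle count are
configurable.

## Capacitance extraction: numerical choices

* **Differentiation**: central differences at interior samples, one-sided at
  the ends. For the ideal triangular staircase this is exact
  ($\pm S_\mathrm{rate}$) everywhere except at the vertex sample itself;
  second-order accurate for general waveforms.
* **Validity masking**: the quotient $i/(dv/dt)$ blows up where the slope
  approaches zero. Samples are invalid when $|dv/dt|$ falls below
  `min_slope_frac` (default 0.5) of its maximum, or within
  `vertex_exclusion` (default 3) samples of a slope sign change. The
  defaults discard only a handful of samples around each vertex of a
  1801-sample sweep.
* **Smoothing**: a centred moving average, default window 5 samples, applied
  within contiguous valid runs only, with the window truncated at run edges.
  Valid samples are never sacrificed to smoothing, and values never leak
  across the masked vertex gaps.
* **Sign**: $i$ and $dv/dt$ change sign together on a passive load, so the
  quotient is positive on both branches without any case analysis.
* **Degenerate inputs**: traces shorter than 3 samples, non-uniform time
  grids, or masks that remove every sample raise errors naming the offending
  parameter; a constant-voltage trace has no valid samples by construction.

## De-embedding

The cells-free media trace is the background reference: each sample trace is
divided by it pointwise (the media linearly interpolated between its valid
samples when grids differ). This cancels the electrode/media baseline and,
in a real cell, localized electrode-polarization contributions. Two outputs
are reported side by side, because a published de-embedded quantity can be
read either way: the dimensionless `ratio`, and `rescaled_F` — the ratio
multiplied by the media capacitance at the reference time, which restores a
farad scale. Readouts default to the rescaled series. The media value is
floored at 1 fF; divisions below that are refused rather than silently
amplified. De-embedding a trace against itself returns exactly 1, which the
test suite asserts as a property over randomized models.

## Peak-time readout and phenotype analysis

Readings are taken at a common reference time. The default policy is the
median of the per-trace peak times — in this model every trace peaks where
the sweep crosses the reduction peak (−0.2 V, i.e. ≈27.5 s into the default
sweep), so the median is a stable, dataset-derived reference; a fixed
user-supplied time (e.g. an empirically established 29.2 s) is equally
supported. Readings use the nearest valid sample within a tolerance
(default 0.5 s); ties in the peak search resolve to the earliest time.

Per type, the readings over the `k_lowest = 3` smallest concentrations are
averaged (mean ± SEM = sd/√k). The three lowest are used because the highest
concentration of a dilution series is the most vulnerable to pipetting and
preparation error; the subset actually used is always recorded in the result
and the run log. Types are ranked by descending mean and three blinded
samples are classified largest → MAC, middle → DC, smallest → THP1. Means
within a relative tolerance of 1e−9 are treated as ties and the
classification is refused as inconclusive rather than guessed.

Between-type comparisons use the hand-coded pooled-variance two-tailed
Student's t-test (df = nₐ + n_b − 2); a Welch variant is available behind
`var_equal = FALSE`. With k = 3 readings per group these tests are
deliberately underpowered — they are reported as descriptive statistics, and
no multiple-testing correction is applied (the three pairwise p-values are
reported raw, and flagged as such). Zero pooled variance with equal means
returns t = 0, p = 1; with unequal means, p = 0 with a degeneracy flag.

## What the synthetic generators emulate — and what they do not

The **suspension simulator** reproduces the features that drive the
analysis: the staircase voltammogram shape with equal-magnitude anodic and
cathodic plateaus, a cathodic reduction peak at −0.2 V, a media-dominated
total capacitance near 0.8 µF, concentration series from 10 to 10⁵ cells per
500 µL, cell-count- and area-proportional capacitance increments ordered
MAC > DC > THP1, RC relaxation after vertices, and additive Gaussian current
noise (default s.d. 50 pA ≈ 0.16% of the 32 nA media-level capacitive
current — a realistic noise floor for a benchtop potentiostat at µA full
scale, consistent with visually smooth published capacitance curves). It
does **not** model electrode polarization physics, Butler–Volmer kinetics,
Debye-layer restructuring, electrode fouling, or non-additive interactions
between cells and the double layer; whether real cells add membrane
capacitance in parallel or restructure the double layer is an open question
that the additive model sidesteps. Passing tests therefore demonstrate that
the *analysis* recovers what the *model* encodes — they cannot certify the
equivalent-circuit model itself against a physical instrument.

A consequence worth stating plainly: with membrane-sized per-cell
contributions (~6–36 pF/cell), 10–1000 cells shift the capacitance by only
parts in 10⁴–10², far less than the ~0.1 µF separations reported for
physical measurements of this design. Real suspensions evidently couple to
the electrode more strongly than the naive additive sum. The package keeps
the physically grounded additive model and correspondingly small noise
rather than inflating per-cell capacitance to match published magnitudes;
the *ordering*, not the magnitude, is the recovery target.

The **micrograph synthesizer** emulates the morphology that matters for
area measurement: round THP-1 cells (disks, mean 150 µm²), branched DCs
(star polygons with 4–6 radial arms, mean 450 µm²) and large spread MACs
(low-eccentricity blobs, mean 900 µm²), placed without overlap with a 2 px
clearance, with exact per-object ground-truth pixel areas. The default means
encode the documented MAC > DC > THP1 ordering at plausible magnitudes; the
electrical arm derives per-cell membrane area from the projected area by a
fixed factor of 4 (the surface-to-cross-section ratio of a sphere), linking
the two arms through a single profile set. The synthesizer does not emulate
touching or overlapping cells, uneven illumination, debris, or fluorescence
artifacts — which is why the segmentation stage needs no watershed split and
why its results on real micrographs would require exactly those additions.

## Imaging arm

Segmentation is the simplest standard pipeline, fully logged: a global Otsu
threshold (or a fixed value), 8-connected component labelling, and removal
of objects below `min_object_size` (default 30 px, about a fifth of the
smallest default cell at 0.5 µm/px). Areas convert to µm² as
pixel count × pixel_size². On clean synthetic images this recovers the
ground-truth masks exactly; the acceptance checks assert per-object
agreement within 2% and the analytic πr² area of a lone disk within 5%.

## Determinism and problem sizes

Every stochastic stage draws from a model-level seed; series and scenarios
derive per-trace sub-seeds deterministically from the master seed and the
trace index (a fixed affine map modulo 2³¹ − 1), so identical configurations
reproduce bit-identical outputs and no seed is ever reused across traces.

The shipped tests and the acceptance script use the full 1801-sample
canonical program throughout. Distributional properties are checked at 100
seeded repetitions (ordering recovery, cross-arm agreement), 50 seeds per
capacitance level (parameter recovery), and 20 randomized models
(de-embedding identity); micrograph checks use up to 200 cells per type
pooled over four synthetic fields of view, mirroring how areas would be
pooled over several real images. These sizes were chosen to make the
property estimates stable at the percent level while keeping a full run in
the minutes range on a single core.

## Known limitations

* The equivalent-circuit model is additive and linear; it cannot reproduce
  the magnitude of cell-induced capacitance changes seen in physical
  two-electrode measurements (see above), only their structure.
* The Faradaic peak model is a fixed-amplitude Gaussian, identical for media
  and samples; real redox chemistry varies with composition.
* De-embedding assumes the media reference was measured under identical
  electrode geometry and program; there is no drift or fouling correction.
* Segmentation assumes non-touching cells and a bimodal intensity
  histogram; real micrographs need watershed splitting and illumination
  correction before these tools apply.
* The classifier is a fixed three-way size ordering; it does not generalize
  to other panels without redefining the label map.
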