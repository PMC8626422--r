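---
title: "Models and methods behind the three crosslinking pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the three crosslinking pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinktools)
```

This package implements three analyses that together characterise a
kinase–substrate interaction captured by genetically encoded
photocrosslinkers: an enrichment screen over quantitative proteomics
tables, a fluorescence foci quantification, and an iCLIP crosslink-profile
analysis on ribosomal RNA. Each is driven either by user data or by a
bundled generator that simulates the corresponding input with known ground
truth. This vignette explains the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic data can and
cannot demonstrate.

## 1. The dual-crosslinker screen

### Model

The screen design crosses two crosslinker conditions (AbK, non-cleavable;
DiZASeC, cleavable by H2O2) with two fractions (proteins *released* from
the capture resin by cleavage; proteins *retained* on the resin) and
replicates. A genuine substrate trapped by the bait shows a dual
signature: enriched in the DiZASeC released fraction and in the AbK resin
fraction. Per protein and fraction we test AbK vs DiZASeC log2 intensities
with Welch's unequal-variance t test; the *Welch difference* is
mean(AbK) − mean(DiZASeC), so DiZASeC enrichment is negative. Both tests
are drawn as volcanoes (the resin plot with an inverted y axis,
`resin_y = +log10 p`), and proteins are classed:

- **blue** — released p < α and difference < −d_min, and resin p < α and
  difference > +d_min (the dual substrate signature);
- **green** — not blue, resin p < α and difference < −d_min
  (DiZASeC-enriched on the resin only);
- **grey** — tested, neither;
- **untested** — fewer than `min_reps` observed values in any of the four
  groups.

Hits are ranked by `welch_score = −(released difference)`, the magnitude
of DiZASeC enrichment on release. The score is a single-axis quantity by
choice: ranking should order validated substrates by how strongly cleavage
released them, and combining the two volcanoes into one scalar would mix
evidence with effect size; the definition is configurable in the result
table (all per-fraction statistics are reported per protein).

### Parameters

- `alpha` (default 0.05) and `d_min` (default 1.0 log2): the significance
  and effect cut-offs behind "significantly enriched" are not published;
  both are mandatory, echoed into `screen_params.tsv` of every report.
- Raw p-values drive classification, matching a volcano whose y axis is
  the Welch p. Benjamini–Hochberg q-values are reported alongside but
  never used for classing.
- Degenerate variance: identical constant groups give p = 1 (no evidence);
  constant groups with unequal means give p = 0 with a warning.
- No imputation. Missing values simply reduce the per-group replicate
  count; proteins falling under `min_reps` anywhere become untested.

### The generator

`simulate_screen()` draws a per-protein baseline from
N(`base_log_mean`, `base_log_sd`), adds `release_effect` log2 units for
spiked proteins in the (DiZASeC, released) and (AbK, resin) cells, adds
replicate noise, and blanks values completely at random at `missing_rate`
(default 0 — no missingness model is published, so missingness is off
unless requested, and MCAR when on). The background proteome size and
intensity scale are placeholders (1000 proteins, log2 scale centred at
25): nothing about the original background distribution is published, so
these defaults are explicitly *not* recovered parameters.

A deliberately honest note on power: with 3 replicates, a 2.0 log2 effect
and replicate noise 0.5, the per-fraction two-sided Welch test has power
≈ 0.88 (the random Welch degrees of freedom at n = 3 cost real power
against the pooled-df ideal), so the joint blue probability per spiked
protein is ≈ 0.78 and a 5-substrate screen recovers ≥ 4 of them in only
about two-thirds of runs. The recovery tests measure exactly this; the
specificity side (false blue calls under the null) is controlled far below
the α²/4 bound implied by two independent sign-constrained tests.

## 2. Foci ("M-body") quantification

### Procedure

For each experiment: gamma-correct
(`out = max × (in/max)^gamma`, default gamma 1), compute for every
*control* image the `percentile`-th percentile (default 99.5, linear
interpolation between order statistics — `stats::quantile` type 7) of
in-mask pixel intensities, and threshold **all** images of the experiment
(controls included) at the mean of those per-image values. Pixels strictly
above threshold are labelled under 8-connectivity; each component is
assigned to the cell containing its centroid (nearest pixel; background
centroids are discarded) and kept when its equivalent diameter
`2·sqrt(area·px²/π)` lies inside the inclusive gate (default 0.1–0.5 µm,
the reported size range of the mitotic bodies). Per-cell counts are
compared with an unpaired two-sided t test (unequal-variance form) for two
conditions, or one-way ANOVA with Tukey HSD for more, with the usual
ns/*/**/***/**** tiers.

### Why pixel size, percentile and gate interact

A percentile threshold leaves (100 − P)% of control pixels above it *by
construction*, whatever the noise level. Those survivors are mostly
isolated pixels, so the minimum size gate is what rejects them — which
works only if a single pixel is smaller than the gate. At 0.1 µm/px a
lone pixel already has equivalent diameter 0.113 µm (inside a 0.1–0.5 µm
gate); at the default 0.05 µm/px, speckles up to 3 pixels fall below
0.1 µm and detection is robust. This is why the generator and detector
default to 0.05 µm pixels, and why calibration should use control images
without foci: if foci occupy more than (100 − P)% of a control's cell
area, the percentile lands inside the focus intensity population and the
threshold is ruined. Both effects are real properties of the published
procedure, not artefacts of the simulation.

Counts are monotone non-increasing in the threshold between the
background-noise ceiling and the focus intensity plateau (components only
shrink or vanish there). Above the plateau a focus fragments
stochastically and counts can rise; the monotonicity tests therefore run
over thresholds 3000–18000 at the generator's default grey levels
(background 2000, foci 20000).

### The generator

Foci are ideal filled disks — no point-spread function, because the
analysis under test is thresholding plus size gating, not deconvolution —
placed without overlap (bounded retries, then a packing error) inside
rectangular "cells" on a labelled grid mask, over a Gaussian-noise
background, with optional gamma distortion last. Real images differ in
ways that matter: spatially correlated background, diffraction-limited
edges, out-of-focus light, irregular cell shapes. Passing tests show the
*procedure* is implemented correctly and behaves sensibly under iid noise;
they do not certify performance on real micrographs.

The in-silico treated experiment (`mbody_treatment_experiment()`) uses 15
counted cells per condition — the per-condition cell count of the original
foci comparisons — with 6 expected foci per untreated cell against a
3-fold reduction, plus two foci-free calibration images, and detects the
reduction at p < 0.05 in essentially every run.

## 3. iCLIP rRNA crosslink profiles

### Procedure

Read-level tables are collapsed to crosslink events by exact UMI match per
(sample, reference, position); 10-nt UMIs upstream, but any uniform length
works. Per-sample profiles on a reference are normalized by that sample's
**total rRNA crosslinks** (the "number of rRNA reads" phrasing of the
display material is treated as synonymous after UMI collapse; the
normalizer reference set is an argument). Metaprofiles for display are
smoothed with a discrete Gaussian kernel of width 9 (offsets −4..+4) and
sd 2 positions; window quantification always uses the **raw** normalized
counts, so kernel leakage can never move signal between adjacent windows.
Windows (1-based inclusive; BED I/O converts to 0-based half-open) default
to ES3SB 200–250, Site A 510–550 and ES10S 1500–1600. Per window we report
per-sample sums (sums, not means — proportional for a fixed-width window),
condition mean ± SD, the mitotic/asynchronous ratio of condition means,
and a Welch test; n = 2 groups are allowed and flagged `low_n`.

Smoothing edge rule: each position's mass is distributed over the kernel
taps that stay inside the vector, with the kernel renormalized per source
position. Interior positions (beyond the kernel radius from the ends)
equal ordinary convolution; the profile total is conserved exactly, which
is the property that matters for normalized count profiles. The price is
that the few edge positions of a flat profile dip slightly — a deliberate
trade against losing mass off the ends.

### The generator

`simulate_crosslinks()` draws per-position counts Poisson(depth × rate)
on a 1869-nt reference (the approximate human 18S length; only positions
up to 1600 are analysed, so the exact value is a free choice). Rates are
`background_rate` (default 20) times per-window multipliers; Site A is
shaped to a triangular apex at position 527 so the strongest simulated
crosslink position matches the known major site, and per-sample depth
factors are drawn from U(0.5, 2) to force the normalization to do real
work. Defaults inject the published effect as truth: the mitotic ES3SB
multiplier is 3.5× the asynchronous one.

With `conserve_total = TRUE` (default) the non-peak background of the
mitotic condition is rescaled so both conditions share the same expected
total rate: condition effects redistribute a fixed crosslinking capacity
rather than create material. This matters because the published 3.5-fold
number is a fold change of *depth-normalized* counts; if the extra ES3SB
signal simply added to the mitotic total, the normalized fold change would
shrink below the injected multiplier (to ≈ 3.2 at these peak sizes) and no
pipeline could recover 3.5 from data in which 3.5 was never the normalized
truth. The recovery harness (`es3sb_recovery()`, 100 datasets of 3 + 3
samples) returns a mean fold change within a percent of 3.5 and a median
Welch p around 10⁻⁶.

## Problem sizes and determinism

Every generator runs one private RNG stream from an explicit seed and
restores the caller's RNG state, so all outputs are bit-reproducible; the
demo orchestrator `run_demo()` expands one top-level seed into per-stage
seeds and writes a config echo plus an md5 manifest. The test suite uses
deliberately modest Monte-Carlo sizes chosen as the package's own working
sizes — 100-seed recovery runs for the screen, the foci experiment and the
iCLIP fold change, 300 simulations for null p-value calibration, 200
random images against the flood-fill oracle — with fixed seeds throughout.

## Known limitations

- The screen models log-intensities as Gaussian with protein-independent
  noise; real label-free data show intensity-dependent variance and
  non-MCAR missingness, neither of which is published for this design.
- Foci are ideal disks on iid noise; no optics model, no 3-D (inputs are
  taken as already-projected), no cell segmentation (masks are inputs).
- The iCLIP module ingests crosslink tables; alignment, multimapping
  policy and crosslink-position definition are upstream and taken as
  given. Peak calling beyond the three fixed windows is out of scope.
- The choice `welch_score = −(released difference)` and the α/d_min
  defaults are declared conventions, not recovered parameters; reports
  echo them so downstream consumers can tell which thresholds produced a
  hit list.
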