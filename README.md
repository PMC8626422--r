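# xlinktools

Reusable R implementations of three desk analyses that arise when a kinase
bait carrying a genetically encoded photocrosslinker is used to trap, purify
and characterise its substrates:

1. **Dual-crosslinker interactome screen** (`screen_stats()`): label-free
   intensity tables from a pulldown run with two crosslinkers — one
   cleavable (DiZASeC, releasing trapped partners from the resin on H2O2
   treatment) and one not (AbK, leaving them resin-bound) — are tested
   protein-by-protein with Welch's unequal-variance t test in each fraction,
   plotted as two stacked volcanoes, and classified into quadrant hit
   classes.
2. **Mitotic foci ("M-body") quantification** (`run_mbody()`):
   single-channel fluorescence images with labelled cell masks are
   gamma-corrected, thresholded at a percentile-calibrated intensity learned
   from control images, and foci of 0.1–0.5 µm equivalent diameter are
   counted per cell and compared across conditions.
3. **iCLIP rRNA crosslink profiles** (`run_clip()`): per-position crosslink
   counts on 18S rRNA are UMI-collapsed, normalized by each sample's total
   rRNA crosslinks, smoothed for display with a width-9 Gaussian kernel
   (sd 2), and quantified in the ES3SB (200–250 nt), Site A (510–550 nt,
   peak at 527) and ES10S (1500–1600 nt) windows with per-window fold
   changes and Welch tests.

Every stage has a synthetic-data generator with known ground truth
(`simulate_screen()`, `simulate_images()`, `simulate_crosslinks()`), so the
full pipelines can be exercised and calibrated without any external
download, and parameter-recovery harnesses (`es3sb_recovery()`,
`screen_recovery()`, `mbody_treatment_experiment()`) that measure how
faithfully each analysis returns what the generator injected.

## The statistics in brief

For two replicate groups with means $\bar{x}_1,\bar{x}_2$, variances
$s_1^2, s_2^2$ and sizes $n_1, n_2$, the screen reports the Welch
difference $d = \bar{x}_1 - \bar{x}_2$ (log2 units, group 1 = AbK) and

$$t = \frac{d}{\sqrt{s_1^2/n_1 + s_2^2/n_2}},\qquad
\nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
           {\frac{(s_1^2/n_1)^2}{n_1-1} + \frac{(s_2^2/n_2)^2}{n_2-1}}$$

with a two-sided p from the t distribution on $\nu$ degrees of freedom. A
**blue** hit is DiZASeC-enriched when released ($p<\alpha$,
$d<-d_\mathrm{min}$) *and* AbK-enriched on the resin ($p<\alpha$,
$d>+d_\mathrm{min}$); **green** marks DiZASeC enrichment on the resin;
everything else tested is **grey**. Foci detection thresholds pixels
strictly above the mean of per-control-image percentiles, labels 8-connected
components, and gates them on equivalent diameter
$2\sqrt{A\,\mathrm{px}^2/\pi}$. iCLIP window quantification sums raw
normalized counts per window and reports the mitotic/asynchronous ratio of
condition means.

## Worked example

Simulate the default iCLIP experiment (3 asynchronous + 3 mitotic samples,
Poisson counts on a 1869-nt 18S reference, per-sample depth jitter, and a
3.5-fold mitotic gain injected in ES3SB) and run the pipeline:

```r
library(xlinktools)
params <- clip_sim_params(seed = 20260927L)
sim <- simulate_crosslinks(params)
res <- run_clip(sim$crosslinks, sim$design, "18S", params$ref_length,
                conditions = c("asynchronous", "mitotic"))
res$windows[, c("window", "fold_change", "p")]
```

```
  window start  end fold_change           t       df            p low_n
1  ES3SB   200  250   3.5258075 190.1438477 2.297302 7.152826e-06 FALSE
2  SiteA   510  550   0.9929988  -0.6563571 3.990773 5.475124e-01 FALSE
3  ES10S  1500 1600   0.9981902  -0.5259205 3.880619 6.275601e-01 FALSE
```

The ES3SB fold change recovers the injected 3.5-fold effect (the other two
windows sit at 1, as injected), the Welch test on 3 vs 3 window sums is
strongly significant, and the smoothed asynchronous metaprofile peaks at
position 527, the known major crosslink site in the mRNA entry channel.

The same pattern holds for the other stages; `analysis/01…04` are runnable
narrative drivers that write every table under `results/`:

```sh
Rscript analysis/01_screen_enrichment.R   # volcano + quadrant classes + hits
Rscript analysis/02_mbody_foci.R          # thresholds, per-cell counts, Tukey
Rscript analysis/03_iclip_rrna.R          # metaprofiles + window table
Rscript analysis/04_parameter_recovery.R  # recovery summary across stages
```

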