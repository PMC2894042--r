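---
title: "Factorial analysis of two-color loop-design microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial analysis of two-color loop-design microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(byssofact)
```

## The experiment this package models

Zebra mussels (*Dreissena polymorpha*) attach to submerged surfaces
with byssal threads secreted by exocrine glands in the foot.
Byssogenesis — thread production — responds to the environment, and a
natural way to dissect that response at the transcriptome level is a
factorial experiment: expose mussels to every combination of two
levels of water temperature (factor A: 4°C vs 22°C), water agitation
(B: stirred vs static), dissolved oxygen (C: 5 vs 10 mg/L) and
attachment status (D: attached vs detached), and profile foot gene
expression on a spotted cDNA array. Four two-level factors give
`2^4 = 16` treatment combinations; with pools of 6 animals and 4
biological replicate pools per treatment, each treatment consumes
`6 × 4 = 24` mussels and the experiment has 64 RNA samples.

On a two-color platform each slide co-hybridizes two samples, one
labeled in the red channel (Cy5-class dye, scanned at 635 nm) and one
in the green (Cy3-class, 532 nm). Instead of comparing every sample to
a common reference, a *loop design* chains samples head-to-tail in
cycles: each arrow is one slide, the arrow's start is the red sample
and its end the green one, so around a cycle every sample is measured
exactly twice, once per dye. Loops spend every slide on an informative
contrast and balance dyes by construction.

## The per-gene model

Let $y_{ge}$ be the normalized log-ratio $M = \log_2(R/G)$ of gene $g$
on slide $e$. Each sample's expected log2 expression is

$$x_g(t) = \mu_g + A\,a(t) + B\,b(t) + \dots + ABCD\,a(t)b(t)c(t)d(t),$$

where $a(t), \dots, d(t) \in \{-1, +1\}$ are the sum-to-zero codes of
treatment $t$'s levels and the 15 coefficients are the main effects
($A,B,C,D$), the six two-way, four three-way and one four-way
interaction. A slide measures the *difference* between its red and
green samples, so the grand mean $\mu_g$ cancels and the design-matrix
row of slide $e$ is the difference of the two treatments' effect
encodings, with entries in $\{-2, 0, +2\}$; `byssofact` reports
$\mu_g$ only as the gene's mean average-intensity. Because the two
levels of an effect sit at $+\beta$ and $-\beta$, the log2 fold change
between levels is exactly **twice the fitted coefficient** — the
`log_fc` columns everywhere in the package.

The coding orientation is chosen so that positive log-FC means
up-regulation at low temperature, under flow, at low dissolved oxygen,
and in the attached state.

Per gene, `fit_factorial()` solves ordinary least squares over the
slides where the gene's spot is unflagged, with an optional all-ones
dye-intercept column (default on). Standard errors use the per-gene
residual variance with `residual_df = informative slides − fitted
columns` (48 for the default 64-slide design with 16 columns), and
two-sided p-values come from the corresponding t distribution. An
empirical-Bayes variance-moderated variant is deliberately *not* the
default: the analysis this package reproduces used plain least-squares
t statistics, and the defaults follow that. No multiple-testing
adjustment is applied at selection time — the raw-p cutoffs (0.05,
0.01) are instead calibrated empirically with self-self slides (below).

With only 16 slides per replicate set, estimability depends on the
loop topology: the treatment graph must be connected.
`build_design_matrix()` checks the numerical rank of the effect
columns (15 for a valid design) and names the non-estimable effects
otherwise. The default layout partitions the 16 treatments into three
cycles of sizes 6/5/5 and *rotates the cycle boundaries between
replicates*, so each replicate contributes 16 slides (64 total) and
the union of loops is connected. The original three-loop layout is
published only as a figure, so the exact arrow topology is
user-configurable (`loop_spec`, or a graph file via `read_graph()`);
the inference depends only on connectivity and balance, which are
asserted.

## Preprocessing

The platform's processing steps are background correction,
within-array normalization and between-array normalization; the exact
algorithms behind those names were not recorded, so `byssofact` uses
era-typical defaults, all selectable:

* **Background**: `subtract` (foreground − local background), floored
  at half the smallest positive corrected value per channel per slide
  so all log-ratios stay finite; or `none`.
* **Within-array**: loess of $M$ on
  $A = \tfrac12\log_2(R\,G)$ — local quadratic, tricube weights, span
  0.3, robust (`family = "symmetric"`, 2 robustness iterations);
  the fitted trend is subtracted. Flagged (weight-0) spots never bend
  the curve but are still transformed. `surface = "direct"` computes
  exact local fits (and reproduces an exactly quadratic dye-bias curve
  to machine precision); `"interpolate"` is the usual kd-tree
  approximation, appropriate for slides with many thousands of spots.
* **Between-array**: `scale` — each slide's $M$ divided by the ratio
  of its median absolute $M$ to the geometric mean of all slides'
  median absolute $M$; or `none`. With strong, frequent true effects
  scale normalization slightly compresses fold changes (the signal
  inflates the slide's median absolute M); at the default effect
  frequencies the compression is ~1–2%.

## What the simulator states, and what it does not

`simulate_arrays()` is the package's ground-truthed stand-in for real
scanner output, and its defaults *are* the stated world of the
experiment it emulates: a 750-probe slide composed of 3% foot-protein,
37% exocrine-gland-peptide, 1% host-defense, 6% housekeeping and 53%
unannotated probes (largest-remainder apportionment, ties by declared
order); planted absolute log-FCs uniform on 0.12–0.63 (the scale of
the reported hits) on 10%/4%/4%/1% of probes for D/A/C/B; log-normal
spot intensities around a baseline of mean 10, SD 1.2 (log2);
gene-wise replicate SD 0.1; multiplicative spot noise SD 0.05 per
channel; additive normal background (mean 80, SD 15) reported in the
background columns; a smooth quadratic intensity-dependent dye bias
(amplitude 0.3 by default) applied +/− half to the two channels; and
1% flagged bad spots.

One modeling decision deserves emphasis. Each biological sample sits
on two slides of a loop. If the replicate noise were drawn once per
*sample*, the two slides sharing it would have correlated errors, and
ordinary least squares — which this pipeline deliberately uses — would
be anticonservative (empirically ~5× the nominal type-I error at
α = 0.01). The fitted model's error term is independent per
observation, so the simulator draws the gene-wise replicate noise
independently per hybridization channel: it represents the
labeling/hybridization realization of the sample, which in practice
dominates repeat-hybridization scatter. A green calibration test
therefore establishes that the *fit matches its own model*, not that
OLS is robust to sample-induced correlation — analyzing real loop
data, where the same labeled cDNA is split across slides, would need
a duplicate-correlation or mixed-model treatment that is out of scope
here.

The simulator also does not model print-tip or spatial artifacts,
scanner saturation, or probe sequence content.

Self-self slides (`simulate_self_self()`) hybridize one sample against
itself: every probe is null by construction. `calibrate_fdr()`
preprocesses them like experimental slides and tests each probe's M
against zero with a one-sample t across slides — with the two
replicate slides of the original assay that is the only estimable
contrast (df = 1) — then tabulates observed false positives against
the binomial expectation `alpha × n_genes` at each cutoff.

## Downstream accounting

`factor_overlap()` classifies each significant gene by the exact
subset of factors that selected it; per-factor totals are sums over
subsets containing the factor (e.g. 19 A-only + 1 AB + 1 AC + 6 AD
gives an A total of 27). `percent_of_array()` reports counts as
round-half-up integer percentages of the slide, reproducing the
"73 genes (10% of the total genes on the slide)" reporting style.
Note one printed figure in the source material — 26 genes called
"4%" — is itself an approximation (26/750 = 3.47% rounds to 3); the
reporter does the honest arithmetic.

`build_profile_matrix()` gives each selected gene a 4-vector of signed
log-FCs, zero where the gene was not significant for a factor
(profiles encode "no significant change" as 0; a `raw` flag keeps all
fitted log-FCs instead). `cluster_profiles()` runs average-linkage
hierarchical clustering on Euclidean distances, cut at `k = 10` by
default — the cluster count used in the original heatmap; no cut
criterion was stated, so `k` is a parameter. Rows are sorted by probe
id first, making merges deterministic. The optional
`profile_heatmap()` keeps the source's color legend — green = up,
red = down — even though it inverts the common convention.

## qPCR validation logic

`delta_delta_ct()` implements 2^−ΔΔCt quantification under perfect
doubling: ΔCt = target − reference within a sample (replicate means),
ΔΔCt against a calibrator, fold = 2^−ΔΔCt. The calibrator defaults to
the lowest-expressing *detected* sample (largest ΔCt; the "lowest (+)"
convention), detection being mean Ct below 36 cycles — the source
reports only +/− calls, so the cutoff is a documented default.
Replicate SDs combine in quadrature in ΔCt space and are propagated to
the fold scale by the delta method; dispersions are labeled SD
explicitly. Per-sample Ct offsets (loading) cancel exactly in ΔCt.
`timecourse_ratios()` applies the same machinery per timepoint with
the detached group as calibrator (fold 1).

## Numerical choices and degenerate inputs

* Treatments, samples, slides and output tables are emitted in
  deterministic lexicographic order; p-value ties in tables break by
  probe id.
* Genes whose residual variance is numerically zero (noise-free data)
  report p = 1 for zero coefficients and p = 0 otherwise; genes with
  fewer informative slides than design columns are marked unfit and
  excluded from tables; residual df < 3 is flagged low-confidence.
* All `simulate_*` functions are pure functions of (configuration,
  seed) and restore the caller's RNG state.
* GPR files are written with 17 significant digits so write→read is
  lossless.

## Worked example

```{r pipeline, eval = FALSE}
res <- run_pipeline(seed = 1, surface = "interpolate")
res$summary
cal <- calibrate_fdr(simulate_self_self(res$template, 2, seed = 1001))
cal
```

At the default settings this selects on the order of a hundred genes
at P < 0.01 for the attachment factor (the simulator plants 10% of
750 probes with attachment effects, and power for |log-FC| ≥ 0.3 is
high at 48 residual df), and the two-slide self-self calibration
observes false-positive counts scattered around the binomial
expectations 37.5 and 7.5 at α = 0.05 and 0.01. Every number shown in
the README is the printed output of these calls.

## Known limitations

* OLS with independent errors is both the method and the simulator's
  world; correlated-error designs need tooling out of scope here.
* The loess span (0.3) and the scale between-array method are
  conventions, not estimates; strong asymmetric differential
  expression can bias both.
* With two self-self slides the null t has 1 df: individual p-values
  are extremely coarse, which is precisely why the calibration reports
  counts at fixed cutoffs rather than an FDR curve.
* Real GPR files parse only through the documented column subset;
  GEO series files are not read.
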