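---
title: "Methods: signed co-expression networks and cell-type-aware age associations in brain transcriptomes"
author: "brainAgeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed co-expression networks and cell-type-aware age associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

brainAgeNet implements a complete desk-scale pipeline for studying how gene
expression in post-mortem human brain changes with donor age:

1. **Detection filtering** of transcript-level expression against a
   per-sample intronic background noise floor.
2. **Signed weighted co-expression network** construction (soft-thresholded
   adjacency, topological overlap, static tree cut, module eigengenes,
   connectivity and hubs).
3. **Association** of module eigengenes with biological and technical
   covariates, and of individual transcripts with age.
4. **Cell-type deconvolution** in the PSEA (population-specific expression
   analysis) style: marker-derived per-sample reference signals, multiple
   regression, and neuron-corrected age associations.
5. **Cross-dataset validation** of per-gene age-association profiles.
6. **Hypergeometric gene-set over-representation** for modules.

Because the cohorts this kind of analysis is usually run on are
access-controlled, the package ships a synthetic cohort generator with full
ground truth; every stage is validated against planted structure rather
than against irreproducible external data.

# The expression model and its assumptions

All operations consume a transcripts-by-samples matrix of **already
normalized, log-scale expression**. The pipeline performs no normalization
of its own: the upstream pipeline (alignment, quantification,
conditional-quantile or similar normalization) is out of scope, and the
generator emits normalized values directly. Downstream methods assume
values are finite, roughly Gaussian per transcript, and comparable across
samples.

## Detection filter

A transcript is *detected* in sample $s$ when its expression exceeds the
sample's intronic background mean by strictly more than one intronic SD:
$x_{ts} > \mu_s + \sigma_s$. A transcript is retained when it is detected
in strictly more than a fraction $f$ (default 0.95) of samples. Both
inequalities are strict — "more than one SD", "more than 95%" — and
$f = 1$ is special-cased to mean "detected in every sample", since a
strict count inequality against $n$ itself is unsatisfiable.

Thresholds are per sample by default because RNA-Seq background scales
with library depth; a pooled global threshold (mean of the per-sample
means plus mean of the per-sample SDs) is available via `perSample =
FALSE` for data where only pooled intronic summaries exist.

## Signed network

With Pearson correlation $c_{ij}$ across samples, adjacency is

$$a_{ij} = \left(\frac{1 + c_{ij}}{2}\right)^\beta,$$

so anti-correlated transcripts get adjacency near 0 rather than near 1 —
the *signed* convention, needed because module-age correlations are
reported with sign. The topological overlap matrix is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu},$$

with unit diagonal; $1 - \mathrm{TOM}$ is the clustering dissimilarity.
The implementation uses one matrix product; a deliberately naive
triple-loop oracle in the tests confirms it to $10^{-12}$.

**Soft power.** `pickSoftThreshold()` evaluates the scale-free topology
fit of the connectivity distribution for candidate powers: connectivities
are grouped into ten equal-width bins, and $\log_{10} p(k)$ is regressed
on $\log_{10} \bar k$; the fit statistic is $-\mathrm{sign}(\text{slope})
\cdot R^2$. Equal-width binning is the only meaningful choice here:
equal-count bins would make every bin frequency identical by construction
and the regression degenerate. The chosen power is the smallest candidate
reaching the target fit (default 0.8), otherwise the best-fitting power
with a warning. For cohort-scale brain data the conventional choice is
$\beta = 6$, which is the package default in `buildNetwork()`; the
synthetic cohort is analyzed at $\beta = 6$ as well so that results are
comparable with that convention.

**Module detection.** Average-linkage hierarchical clustering of
$1-\mathrm{TOM}$ with a *static* cut at `cutHeight`, then merging of
clusters below `minModuleSize` into `"grey"`. The static cut was chosen
over dynamic hybrid tree cutting for determinism and transparency; the
dynamic variant is a natural extension point. Surviving modules are named
by decreasing size along the conventional color sequence (turquoise,
blue, brown, ...).

A note on the cut height: average-linkage merge heights on $1-\mathrm{TOM}$
are strictly below 1, so a literal cut at the conventional cohort-scale
value 1 returns a single cluster. That value is retained as the
function default for fidelity to common practice, but all synthetic-cohort
analyses in this package cut at **0.90** with **minModuleSize 10**. On the
default cohort the planted-module merge heights sit well below 0.90 while
between-module and noise merges sit above it, so this cut separates the
planted structure; the choice was fixed once from the dendrogram geometry
of the generator and is used unchanged everywhere (tests, examples, the
acceptance script).

**Eigengenes.** Module members are standardized across samples; the
eigengene is the first right singular vector of the standardized
members-by-samples matrix, unit norm, sign-oriented to correlate
non-negatively with the module's mean standardized profile (so a module of
transcripts that fall with age has an eigengene that falls with age).
`varianceExplained` is $d_1^2 / \sum d_k^2$. A singleton module's
eigengene is its own standardized profile, normalized, with variance
explained 1. Hubs maximize within-module connectivity; ties break to the
lexicographically smallest transcript ID for reproducibility.

## Associations

Correlations are Pearson throughout (the field's default for these
pipelines); two-sided p values come from
$t = R\sqrt{(n-2)/(1-R^2)}$ on $n-2$ df. Multiplicity correction is
Benjamini–Hochberg, with the family chosen per analysis: the full
module-by-trait grid for eigengene associations, and all transcripts for
transcript-age associations. The method behind "adjusted p" in published
cohort analyses is often unstated; BH was chosen as the transparent,
rank-preserving standard. Binary traits are encoded 0/1; a multi-level
batch is expanded into per-level indicators and the level with the largest
$|R|$ is reported, which keeps one number per trait as heatmap-style
summaries require. Constant traits report $R = 0$, $p = 1$ with a
`degenerate` flag rather than NaN.

Per-transcript output includes the least-squares slope and intercept plus
the residual SD, from which `confidenceBand()` reconstructs the pointwise
95% CI of the mean response,
$t_{0.975, n-2}\, \hat\sigma \sqrt{1/n + (x - \bar x)^2 / S_{xx}}$,
matching `predict.lm(interval = "confidence")` to $10^{-9}$ in the tests.

## PSEA-style deconvolution

For each cell type, each present marker gene is scaled by its own
cross-sample mean and the scaled markers are averaged: one **reference
signal** per sample with mean exactly 1. This mean-scaling formulation
follows the established PSEA convention; it makes the reference invariant
to rescaling any marker by a positive constant, and requires expression on
a positive scale. Reference signals are *relative* abundance estimates,
never absolute fractions, and all outputs are labeled accordingly.

`estimateCellContributions()` regresses every gene on the four reference
signals **plus an intercept** (whether published analyses included one is
typically unstated; with an intercept the coefficients are invariant to
per-gene baseline shifts, so it is included). Collinear reference sets
(design condition number above $10^8$) are refused with advice to revise
the markers.

`correctForNeurons()` residualizes each transcript on the neuronal
reference (OLS with intercept) and **adds the grand mean back**, so the
corrected matrix stays on the original scale and remains a valid input to
every downstream operation, including the detection-filtered association
step. Residuals are exactly uncorrelated with the reference. Correction
defaults to transcript level (each isoform corrected separately); the same
function applies unchanged to a gene-collapsed matrix when gene-level
correction is wanted. When corrected features are themselves neuronal
markers used to build the reference, summaries exclude them (the
`exclude` argument of `compareCorrectedAssociations()`) to avoid
circularity.

## Cross-dataset validation

Gene-level comparison requires one value per gene: each gene is
represented by its highest-mean-expression transcript (ties to the
smallest ID), after excluding *divergent* genes — genes with at least two
nominally significant transcripts of opposite sign. Published analyses
exclude genes whose transcripts "diverge widely" without giving a formula;
sign-discordant nominal significance is the operationalization here, with
the threshold exposed. Cross-dataset agreement is the Pearson correlation
of the two per-gene $R$ vectors over the **gene intersection** (never
union-with-imputation), pairwise per dataset pair in panels since
detection differs by dataset.

## Enrichment

Over-representation uses the exact upper-tail hypergeometric probability
$P(X \ge k)$ with BH correction **within each module**, against a
universe defaulting to all detection-surviving genes (the effective
background of the analysis; overridable where a genome-wide background is
preferred). This replaces proprietary multiple-testing schemes of web
tools with a transparent equivalent: ranks are comparable, absolute p
values are not.

# The synthetic cohort generator

`simulateCohort()` emulates the structure of a frontal-cortex aging
cohort: by default **60 donors aged 15–79** (uniform), **10 planted
modules of 40 genes**, 1–3 transcripts per gene, **200 noise genes**, and
**25 marker genes per cell type** for neurons, astrocytes,
oligodendrocytes and microglia. Cell-type proportions drift linearly with
age — neurons decline, oligodendrocytes rise (the pattern reported for
aging cortex) — with biological noise, clipped at 0.01 and renormalized to
the simplex.

Design choices worth knowing:

* **Planted effects are realized exactly in-sample.** Module factors are
  built as $f = \alpha\, z(\text{age}) + \sqrt{1-\alpha^2}\, z(\epsilon
  \perp \text{age})$, so the factor-age correlation equals its target
  $\alpha$ exactly rather than approximately; likewise the cellularity
  modules hit their proportion coupling (0.95) exactly, and proportion
  noise is drawn orthogonal to age so the proportion-age coupling is
  governed by the configured slopes. This removes one layer of sampling
  noise from what the tests must tolerate, while eigengene estimation,
  marker noise and transcript noise remain genuinely stochastic.
* **Default planted age effects** are $\pm 0.7$, $\pm 0.5$, $\pm 0.3$
  (direct modules), two cellularity modules (neuron-linked and
  oligodendrocyte-linked, no direct age term), and two null modules —
  covering strong/moderate/weak signal, both mechanisms, and the null.
* **Proportion slopes** of $\mp 0.0015$/year with noise SD 0.09 put the
  neuron-proportion-age correlation near $-0.4$. This moderate coupling
  is deliberate: if proportions tracked age too tightly, regressing out
  the neuronal signal would also remove most *direct* age effects and the
  two mechanisms would be unidentifiable at $n = 60$.
* **Within-module correlation** 0.6 between transcripts of different
  genes; transcripts of one gene share their gene signal with
  transcript-specific noise (SD 0.3), giving isoform correlations near
  0.9.
* **Detection floor**: per-sample intronic means near 1.0 (SD 0.3 across
  the floor, log units) sit far below baseline expression (uniform 5–9),
  and 5% of non-marker transcripts are replaced by background-level noise
  so the filter genuinely removes something. Markers are exempt so marker
  lists remain valid inputs.
* `simulateSecondPlatform()` redraws an independent cohort from the same
  configuration (module layout and loadings are deterministic given the
  configuration, so ground truth is shared across seeds), collapses to
  genes, subsets and adds platform noise — the testbed for cross-dataset
  validation. With the original seed, full subset and zero noise it
  reproduces the collapsed original bit-for-bit.

**What the generator does not emulate:** count-level sampling noise and
normalization artifacts, batch confounding beyond a label column,
correlated technical covariates (RIN/PMI are independent of expression by
construction), heavy-tailed or bimodal expression, isoform switching, and
spatial/regional heterogeneity. Passing tests therefore demonstrate that
the *methods* behave as specified under a Gaussian factor model with known
truth — not that any particular biological dataset will show the same
effect sizes.

# Numerical choices and degenerate inputs

* Detection comparisons are strict; equality with the threshold never
  counts as detected, so an SD of zero with expression at the background
  mean retains nothing.
* Ties in gene collapse and hub calling break lexicographically.
* Adjacency and TOM are explicitly symmetrized ($10^{-12}$-level) and
  clamped to $[0,1]$; the TOM denominator is validated positive.
* All-equal connectivities (perfectly regular networks) yield scale-free
  fit 0 with a warning, never NaN.
* `minModuleSize` above the transcript count yields all-grey labels with
  a warning; a module of one transcript gets variance explained 1.
* Zero-variance transcripts are hard errors in network construction
  (named), and excluded with a warning from association tables.
* Degenerate (constant) traits and references: traits report $R = 0$,
  $p = 1$, flagged; a constant neuronal reference is a hard error.

# Problem sizes

All shipped analyses run on one CPU in well under a minute: the default
cohort is ~1300 transcripts by 60 samples (network construction on the
~1240 detection-surviving transcripts takes a few seconds), the null
calibration uses ~1000 noise transcripts, and the oracle comparisons use
8-node networks. These sizes were chosen so the full test suite and the
acceptance script stay interactive while every statistical property being
checked (recovery bands, type-I level, cross-platform agreement) is
already stable at $n = 60$ samples.

# Known limitations

* The static tree cut requires a cut height suited to the data's TOM
  scale; unlike dynamic tree cutting it will not adapt to dendrograms
  whose module merges sit at unusual heights.
* Deconvolution is unconstrained OLS: coefficients may be negative, and
  no attempt is made to calibrate absolute cell fractions.
* The divergence filter's sign-discordance rule is one reasonable
  operationalization; genes with many weakly discordant isoforms pass it.
* BH-adjusted enrichment p values are not comparable to web-tool
  corrected values; ranks are.
* With only ~14 samples of the minority sex in a 56-60 sample cohort,
  sex associations are underpowered by design in both the emulated
  cohort and the generator.
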