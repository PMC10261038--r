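---
title: "Quantifying biomass heterosis and its metabolite signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biomass heterosis and its metabolite signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigormet)
```

## The problem

Hybrid vigor (heterosis) is the tendency of an F1 hybrid to outperform its
parents for a quantitative trait. For vegetative biomass in Arabidopsis
intraspecific crosses, the practical questions are: which parental
combinations produce it, how strongly, whether the effect is symmetric
across the reciprocal crosses (A×B versus B×A), and which primary
metabolites travel with it. `vigormet` implements that analysis as a
pipeline of small, testable stages, together with synthetic-data
generators that carry known ground truth so every stage can be validated
without access to raw measurements.

## Phenotyping model

### Reference values

For a cross of parents $P_1$ and $P_2$ with trait means $\bar{p}_1$ and
$\bar{p}_2$:

* mid-parent value $\mathrm{MPV} = (\bar{p}_1 + \bar{p}_2)/2$,
* better-parent value $\mathrm{BPV} = \max(\bar{p}_1, \bar{p}_2)$,

and heterosis of a hybrid with mean $\bar{f}$ is expressed as a
percentage over either reference,
$100\,(\bar{f} - \mathrm{ref})/\mathrm{ref}$ (MPH over the MPV, BPH over
the BPV). $\mathrm{MPV} \le \mathrm{BPV}$ always, so BPH never exceeds
MPH. On an exact parental tie, parent1 is designated the better parent and
a tie flag is recorded.

### Significance and the four-class rule

Each reciprocal hybrid is compared with the better parent's replicate
values by a two-sample pooled-variance Student's t-test, two-sided with a
post-hoc direction check. Two-sided plus direction was chosen over a
one-sided test because published significance marks for this kind of
comparison are generic t-test asterisks without a stated sidedness; a
pooled-variance test is the default, since group sizes are similar and
small (a Welch test would lose degrees of freedom where they are
scarcest). The comparison group is the better parent's replicates — a
t-test needs a group, and replicate-level data is what exists.

A combination (both reciprocals, evaluated against the same BPV) is then
labeled by a decision tree, evaluated in order:

1. **unclassifiable** if the reciprocals show opposite significant trends
   (one significantly above, one significantly below the BPV);
2. **high** if both reciprocals are significantly above the BPV (default
   $\alpha = 0.05$) and at least one has BPH ≥ 10%;
3. **weak** if at least one reciprocal is significantly above, with both
   BPH values in $[0, 10)$%;
4. **none** if neither reciprocal is significantly above;
5. **unclassifiable** for any remaining mixed pattern (e.g. one
   reciprocal significantly above by ≥ 10% while the other sits
   nonsignificantly below zero).

Rule 5 exists because the verbal taxonomy behind rules 1–4 does not
partition the outcome space; assigning leftovers to the unclassifiable
class keeps the four labels a true partition, which is tested as an
invariant. The 10% threshold and both alphas are parameters
(`bph_threshold`, `alpha`) with the defaults above.

Degenerate inputs follow explicit rules: two zero-variance groups with
equal means give $p = 1$ and no flags; zero variance with unequal means is
significance at the machine limit with a `degenerate` flag.

### Germination synchronization and the seed screen

Biomass comparisons assume developmental synchrony, so lines are sown at
offsets that equalize expected germination. Germination time (t50) is the
time at which half the seeds show fully opened cotyledons, estimated as
the linearly interpolated first crossing of 0.5 on the cumulative course
(if the first observation already exceeds 0.5, its time is returned, and
the method used is recorded). Linear interpolation between the two
straddling observations was chosen because scoring is at 12-hour (densely,
4-hour) granularity; the alternative — the first observation time at or
above 0.5 — differs by at most one observation interval. First crossing
wins if the curve touches 0.5 repeatedly. Sowing offsets are
$\max_\ell t50(\ell) - t50(\ell)$, so the slowest line is sown first and
offsets are nonnegative with at least one zero; lines that never reach 0.5
are excluded rather than given a sentinel value.

The seed-area screen compares each accession's seed areas to a control
accession (pooled t-test, default $\alpha = 0.01$) and marks accessions
with significantly *larger* seeds for exclusion — a guard against maternal
seed-size effects masquerading as vigor. Smaller-seeded accessions are not
excluded; the direction check is part of the contract.

## Metabolite profiling

### Internal-standard normalization

Stable-isotope internal standards (IS) are spiked at fixed concentration,
so cross-sample variation in IS rows is technical. The per-sample scale
factor is

$$ s_j = \frac{g_j}{\big(\prod_j g_j\big)^{1/n}}, \qquad
   g_j = \Big(\prod_{i \in IS} x_{ij}\Big)^{1/|IS|}, $$

the geometric mean of the sample's IS areas anchored to the grand
geometric mean, and every non-IS area is divided by $s_j$. The exact
normalization formula of any given instrument protocol varies (per-peak
matched-IS schemes exist); geometric-mean scaling was chosen as the
default because it captures the testable contract — removal of a
sample-level multiplicative technical factor — without inventing
per-peak detail. Two consequences are documented and tested:

* *Idempotence.* IS rows are retained but flagged consumed; a normalized
  matrix passes through unchanged rather than being re-divided.
* *Equivariance.* Because factors are anchored to the grand mean,
  rescaling one sample's column by $c$ shifts **all** normalized values by
  the single constant $c^{1/n}$; relative abundances are exactly
  invariant, and the test asserts equality up to one global factor.

An already normalized matrix (e.g. a published data matrix) can be read
with `normalized = TRUE` to skip this stage.

### Imputation and transform

Zeros and missing areas are replaced by half the minimum positive area of
that peak across samples, then the matrix is log2-transformed. Half-minimum
was preferred over `log2(x + 1)` because it keeps fold changes of
low-abundance peaks bounded; the offset variant remains available
(`method = "offset"`). Peaks missing in every sample are dropped with a
warning and a count. Imputation preserves the rank order of positive
values within each peak.

### Differential calls and fold changes

Per peak, the hybrid is tested against each parent (pooled t on log2
values); each hybrid-versus-parent family of peaks is adjusted with
Benjamini–Hochberg (`stats::p.adjust`), keeping the FDR family at the
level the comparisons are reported: one family per hybrid-parent pair.
Pooling across combinations would mix experiments run and interpreted
separately. A metabolite is called changed only when it differs from
*both* parents in the same direction at FDR < 0.05 — the conjunction is
what makes the call a hybrid effect rather than a parental difference.

Fold change versus the MPV is computed on linear-scale means
(back-transformed from the log2 matrix): the quantity of interest is a
ratio of abundances, not of log-means. The difference-of-log2-means
variant is reported alongside (`log2fc_vs_mpv_logmeans`) since the two
differ under skew. A peak absent from a combination propagates as `"ND"`
in the wide heatmap table.

### Fumarate/malate ratios

Ratios are computed per sample and then averaged per line — box plots of
this statistic display per-sample ratio distributions, and the per-sample
ratio cancels the sample's technical factor exactly. The hybrid's fold
versus the MPV is its mean ratio over the mean of the two parental mean
ratios. "Versus the MPV" is ambiguous between (i) the MPV of per-line mean
ratios and (ii) the ratio of MPV-fumarate to MPV-malate; (i) is the
default and (ii) is always reported alongside (`fold_vs_mpv_of_areas`).
Group differences across the four lines are assessed by one-way ANOVA with
Tukey HSD (`stats::aov`, `stats::TukeyHSD`) and summarized as a compact
letter display built by the insert-and-absorb algorithm, with letters
assigned in descending order of group means so output is deterministic.
Shared letter ⇔ Tukey-adjusted $p \ge \alpha$ is verified exhaustively in
the tests for up to six groups, and cross-checked against
`multcomp::cld`.

### PCA

Samples are observations and peaks variables (for the default experiment,
a 24 × 178 matrix after removing the 10 IS rows). Peaks are mean-centered;
unit-variance scaling is optional (`scaling = "autoscale"`). Centering
only is the default: the log2 transform already tames the dynamic range,
and autoscaling inflates near-constant peaks. Published percent-variance
figures depend on this unstated choice, so reproduction checks try both
conventions and record which matches. Decomposition is by SVD
(`stats::prcomp`); explained variance is $100\,\lambda_k/\sum\lambda$.
Loading signs follow a fixed convention (largest-magnitude element
positive) for cross-platform determinism. Constant peaks under autoscaling
are dropped with a warning; an entirely constant matrix is an error.

## What the generators emulate — and what they do not

`simulate_trait_table()` draws replicate trait values as
$\mathcal{N}(\mu, (cv \cdot \mu)^2)$ truncated at zero, with F1 population
means placed at $\mathrm{BPV}\,(1 + \mathrm{BPH}/100)$. Defaults — 6
replicates, cv = 0.05, both-reciprocal BPH = 30% — represent a strongly
heterotic cross under controlled growth; replicate variance magnitudes for
fresh weight are not published, so the cv was fixed once at a value that
makes published effect sizes (BPH from roughly −20% to +44%) plausibly
detectable at the replicate numbers typical of such experiments, and is
not revisited.

`simulate_germination()` produces logistic cumulative curves observed on
the 9-point schedule (every 12 h from 0–72 HAS, plus every 4 h from 48–60
HAS).

`simulate_metabolome()` draws 188 peaks × 24 samples (103 known
metabolites, 75 unknowns, 10 IS; 4 lines × 6 replicates): lognormal base
abundances, line-specific multiplicative effects keyed by annotation,
lognormal biological noise (sd 0.1 on the log2 scale), and a per-sample
technical factor (lognormal, sd 0.1 on the natural-log scale) applied to
every peak including the IS rows. The default effect pattern encodes a
high-heterosis signature: TCA intermediates (citrate, cis-aconitate,
isocitrate, 2-oxoglutarate) at 0.7× in both hybrids and fumarate at 2.2×
(F1) and 1.9× (reciprocal), malate unchanged — so the ground-truth
fumarate/malate fold versus MPV is exactly 2.2 and 1.9. Technical factors
are drawn with unit geometric mean, which makes IS normalization recover
the noise-free matrix to floating-point accuracy — a deliberate
identifiability choice, tested at 1e-9. Ground truth (effects, folds,
technical factors, the noise-free matrix) is emitted as a sidecar, never
embedded in the data.

The generators start at tabulated measurements: no chromatography,
peak-picking, spectral annotation, image analysis, or growth-chamber
variation is modeled. Passing recovery tests therefore demonstrates that
the *analysis* is correct and calibrated under the stated noise model —
not that real instruments behave this way. In particular, real GC-TOF-MS
data have correlated peak noise, batch structure, and missingness
mechanisms the generator does not emulate.

## Problem sizes and calibration checks

The packaged checks use: 100 seeded simulations for classification
recovery (high-heterosis configuration called "high" in ≥ 95 of 100);
1000 null simulations for calibration (zero injected heterosis yields
"high" in ≤ 1% — the both-reciprocal significance requirement compounds
the per-test α, so the realized rate is far below it); 100 seeded
metabolome simulations for fold recovery (mean within 5% of the injected
2.2×); and 1000 random vectors against a brute-force Benjamini–Hochberg
oracle. These sizes make the Monte-Carlo standard errors small relative
to each tolerance while keeping a full test run under a minute per
module.

## Known limitations

* The IS-normalization formula is a sample-level geometric-mean scheme; a
  per-peak matched-IS mapping hook is a natural extension but is not
  implemented.
* The classification consumes one trait (fresh weight in the motivating
  design); leaf area is carried descriptively, not classified.
* Published percent-variance and fold values from any specific experiment
  can only be reproduced from that experiment's data matrix; the package
  validates its computations on synthetic ground truth and accepts
  published matrices as drop-in CSV input.
* No pathway enrichment, flux modeling, or transcriptome integration:
  the pipeline ends at differential tables, ratio statistics and
  ordination.
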