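---
title: "Reconstructing spatial and temporal expression axes in the cranial neural plate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing spatial and temporal expression axes in the cranial neural plate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateaxes)
```

# The problem

Dissociating a tissue for droplet single-cell RNA-seq destroys the spatial
arrangement of its cells. In the embryonic mouse cranial neural plate, cell
identity varies smoothly and reproducibly along two spatial axes —
anterior-posterior (AP: forebrain, midbrain/rhombomere 1, hindbrain) and
mediolateral (ML: ventral midline to lateral border) — and in developmental
time (somite stage). Because these axes dominate transcriptional variation,
they can be *reconstructed* from expression alone: a diffusion map of the
cell-cell similarity graph yields smooth components, and the components
that track each axis can be identified from a handful of literature
markers. Once cells are ordered, the genes patterned along each axis can be
catalogued by a graph autocorrelation test, grouped into modules, and used
to read out how a perturbation (here emulated as a Smoothened-agonist-like
expansion of the medial program) reshapes regional transcription.

This vignette documents the model assumptions, parameter choices, numerical
conventions and known limitations of each stage, and what the synthetic
validation does and does not demonstrate.

# Quality control

Three per-cell filters remove clearly damaged material: library size
> 1,000 UMIs; mitochondrial fraction < 20%; and a complexity filter that
regresses log10(genes detected) on log10(UMIs) by ordinary least squares
across cells and removes cells whose residual is below −0.1. The
complexity filter is one-sided by intent: cells dominated by one gene
program (stressed, RNA-leaking cells) detect too few distinct genes for
their library size. The line is fit once on the input cells; refitting
after removal would move it slightly, so the filter is only approximately
idempotent — a second application may trim a few borderline cells, a
property the tests bound at 2%.

After basic filtering, a residual low-quality population can persist as a
distinct low-library-size mode. We detect it with a Gaussian KDE (Scott's
rule bandwidth, 512-point grid) on log10 library size: modes are local
density maxima, basin boundaries are the density minima between them, and
a unimodal outcome is valid (nothing more to remove). With two modes, cells
are finely clustered (unit-weight kNN graph at k = 8, Leiden at resolution
4 — fine clustering is the point, as mode mixtures hide inside coarse
clusters) and each cluster's mean log10 library size is compared to the
high mode by a two-sample Z-test; clusters with p < 1e-10 on the low side
are removed wholesale. Filtering at the cluster level avoids a single hard
threshold through the middle of the distribution. The Z-test uses library
size only; per-cluster gene-count statistics are reported as a diagnostic
alongside.

# Normalization, feature selection and geometry

Counts are scaled per cell to the median library size and transformed with
ln(x+1). Normalization depends on the cell set through the median, so it is
recomputed after any subsetting (per-region analyses re-normalize their
subset).

Highly variable genes are ranked by variance-stabilized standardized
variance: a loess trend (span 0.3, degree 2) of log10 variance on log10
mean across genes predicts each gene's expected standard deviation; counts
are standardized by it, clipped at √n, and the variance of the clipped
values is the ranking statistic. Mitochondrial genes (symbol prefix
`mt-`), ribosomal genes (`Rps`/`Rpl`) and genes detected in fewer than 10
cells are excluded from ranking; curated marker genes are force-retained
and flagged. The default of 3,000 genes follows the study design this
pipeline reproduces.

Cell-cycle influence is removed by regressing each gene's normalized
expression on per-cell cell-cycle signature scores (ordinary least
squares, means restored afterwards). Two choices matter here. First, this
is a deliberate simplification of factor-model detrending: a linear score
regression is transparent, deterministic and fully testable, and removes
exactly the component of expression linearly explained by the scores.
Second, the covariate is the *raw* signed score, not the z-normalized one:
the per-cell z-scaling (division by the cell's expression standard
deviation) is useful for comparing signatures across cells but injects a
nonlinear function of the factor into the covariate, leaving residual
correlation behind after regression.

PCA is computed by exact singular value decomposition of the gene-centered
(not unit-scaled) log-normalized HVG matrix; genes are centered only,
because unit scaling would let near-constant genes dominate. The number of
components is the smallest explaining 75% of variance. Exact SVD keeps the
result deterministic at the problem sizes this package targets (10³–10⁴
cells); randomized methods would trade that determinism for speed we do
not need.

kNN graphs are exact (full distance matrix; ties broken by lower cell
index, making graphs deterministic) with two weight modes: unit weights
for community detection, and adaptive Gaussian weights
exp(−d²/σᵢ²) with σᵢ the distance to the ⌈k/3⌉-th neighbor for diffusion
maps, imputation and autocorrelation. The ⌈k/3⌉ rule adapts the kernel to
local density; it is recorded in the graph object and tunable. Graphs are
symmetrized by taking max(w_ij, w_ji), so an edge exists if either
endpoint claims it.

# Diffusion components and multiscale space

The Markov matrix M = D⁻¹W is diagonalized through its symmetric conjugate
D^{−1/2} W D^{−1/2}; eigenvectors are mapped back by D^{−1/2}, the
stationary eigenvector (λ = 1) is dropped, and components are labeled DC0,
DC1, … in descending-eigenvalue order. Two conventions make results
reproducible: each eigenvector's largest-magnitude entry is made positive
(eigenvectors are defined up to sign), and a disconnected graph is handled
by computing on the giant component with missing coordinates elsewhere
(plus a warning), rather than mixing incomparable spectra.

The number of informative components is chosen by the largest eigengap
among the first 40 eigenvalues; ties take the smaller count. The multiscale
embedding rescales component i by λᵢ/(1−λᵢ), which sums the contributions
of all powers of the Markov matrix and yields a space in which Euclidean
distance reflects multi-step diffusion proximity.

Crucially, the mapping between components and tissue axes is *established,
not assumed*: each candidate component is correlated with a
marker-signature score (e.g. anterior markers for AP), and the
best-matching component carries the axis. On the reference synthetic
tissue the AP axis lands on DC0 and the ML axis on DC2 with time on DC3 —
but the code searches a window of the top components (10 by default)
rather than hard-coding indices, and the multiscale space is taken wide
enough to span the eigengap selection and both identified axis components.
Per region, the same machinery computed on the region's cells yields DC0
as a temporal axis, validated by (and oriented to increase with) Spearman
correlation against somite stage.

# Spatially informative genes

For a latent space (a single axis component, or the multiscale space), an
adaptive-Gaussian kNN graph (k = 30) is symmetrized, row-normalized and
re-symmetrized into weights w. For each gene, expression x (log-normalized
layer — never the imputed layer, which would inflate autocorrelation by
construction) is standardized across cells, and

H = Σ_{i≠j} w_ij x_i x_j

measures how coherent expression is among graph neighbors — a
graph-weighted relative of Moran's I. Under the null of independent
expression across cells, E[H] = −S₀/(n−1) with S₀ the total edge weight
(the Moran's I permutation expectation — slightly negative because
standardized values must anti-correlate somewhere), and
Var[H] = 2 Σ_{i≠j} w_ij² for symmetric weights under the iid-standardized
approximation. The resulting Z = (H − E[H])/√Var[H] is compared one-sided
to a standard normal, and BH-adjusted across genes. Two checks bound the
approximation: on unstructured negative-binomial data the Z distribution
is indistinguishable from N(0,1) by Kolmogorov-Smirnov, and on 300-cell
instances the analytic Z agrees with a 10,000-permutation z-score within a
few percent. Constant genes are assigned Z = 0, p = 1.

Selection applies, in order: natural-log expression range > 1 (removing
lowly expressed genes whose apparent pattern is shot noise), FDR < 1e-5,
and Z ≥ 10. The Z cutoff can also be chosen by knee point on the sorted Z
curve — the index of maximum perpendicular distance to the chord between
the curve's endpoints, ties to the smallest index, with a straight line
returning the first index under a warning. Both modes are provided because
a fixed cutoff is portable across runs while the knee adapts to the
dataset; the defaults use the fixed value.

# Trends and modules

Expression is denoised for display and trend-fitting only, by MAGIC-style
diffusion: a row-stochastic Markov matrix from a small adaptive-Gaussian
graph (k = 5), applied t = 3 times to the normalized layer; t = 0 is the
identity and constant genes are fixed points. Trends along an axis are
penalized cubic-spline GAMs (8 basis functions at axis quantiles,
smoothness by GCV), predicted at 500 equally spaced axis values. Trends
are clustered by z-normalizing each trend across bins, building an
adaptive-Gaussian kNN graph (k = 20) between genes and running Leiden;
weighted edges matter here because with k comparable to family sizes the
graph necessarily contains cross-family edges, and distance-decayed
weights keep them from merging distinct shapes. Cluster labels are ordered
by mean trend-peak position, so anterior-peaked clusters come first.

Gene modules at multiple scales come from Ward linkage (on Euclidean
distances between rows of the gene-gene Pearson correlation matrix,
computed on the log-normalized layer). Labels are read at fixed linkage
distances (10, 6, 4 by default — heights grow with gene count, so these
are configurable), which nest by construction. The default cut is the knee
point of the curve "number of clusters → median intra-cluster pairwise
correlation", where the curve value is the median over clusters of each
cluster's median pairwise correlation: a pooled median would let a cut
that has merged two modules look as coherent as the true cut, because the
merged cluster's cross-pairs can be outvoted by the intact clusters'
pairs. Module activity per cell is scored with the positive-only signature
score.

# Cell typing by absorbing Markov chain

Signature scores are signed means: mean normalized expression over
positive markers minus mean over negatives, z-normalized against the
analytic null of a same-size random signature drawn from the cell's own
expression distribution (mean μ_c, variance v_c over genes):
z = s/√(v_c(1/m⁺ + 1/m⁻)) with negatives, z = (s − μ_c)/√(v_c/m⁺)
without. The analytic null is deterministic; a Monte-Carlo random-signature
null is kept as a test oracle. Scoring the all-genes set gives exactly
z = 0 — a useful identity check.

Typing proceeds: fine Leiden clustering on PCA; preliminary label per
cluster by maximum mean signature (ties to the first set, logged);
training-set construction with the 20th-percentile rule (a cell trains for
its own type only if it beats its type's threshold and no other type's);
then semi-supervised classification by absorbing Markov chain — training
cells become absorbing states of the row-normalized transition matrix, and
for unlabeled cells the linear system (I − Q)B = R (aggregated by label)
gives the probability a random walk is first absorbed in each class. Rows
sum to one up to solver precision; unreachable cells get a uniform row and
a warning; classification is invariant to rescaling the graph weights. On
graphs of a few hundred nodes the sparse solve agrees with a dense oracle
to 1e-6.

# Two-part hurdle differential expression

Expression for testing is log2(median-normalized + 1) with the median
library size computed jointly over both conditions, so the two groups are
on one scale. Per gene and region, the test has two parts: a detection
part — a likelihood-ratio (G) test of equal detection probability,
replaced by Fisher's exact test when any expected 2×2 count is below 5 —
and a continuous part — Welch's t-test on the detected cells' values,
skipped when either group has fewer than 3 positives. The parts are
combined by Fisher's method; the combined statistic is χ² with 2 degrees
of freedom per available part (4 when both are present). Calibration is
checked empirically: over 20,000 null gene-region tests the rejection rate
at p < 0.001 sits inside the binomial 95% interval.

The effect size is the difference of zero-inflated means,
π_b·μ_b − π_a·μ_a on the log2 scale (π the detection fraction, μ the mean
over detected cells) — a closed-form analogue of a hurdle-model
fold-change that responds to both detection and magnitude shifts. The
calling rule is two-tier: significant at FDR < 0.001 (BH within region)
and |effect| > 0.24; genes significant somewhere are additionally
propagated to regions with p < 0.001 and |effect| > 0.10. The midline is
excluded by default (too few cells), as a configurable default rather than
hard-coded. Label swap negates effects and preserves p-values.

# The synthetic tissue generator

The generator is the test bed for every stage, and its defaults are the
study conditions: 2,000 cells × 500 genes per dataset, 60 AP-, 40 ML-,
20 both-axes- and 30 time-patterned genes, the rest null plus 10
mitochondrial and 10 ribosomal housekeeping genes. Cells carry latent
uniform AP/ML coordinates and one of six somite-stage bins; regions derive
from fixed breakpoints (AP < 0.33 forebrain, < 0.66 midbrain/r1, else
hindbrain; ML < 0.08 midline). Patterned genes follow smooth templates:
logistic AP fronts at the region breakpoints (sharpness 0.03 — boundaries
between brain regions are sharp) plus free-position fronts; ML gradients
in both directions and near-binary midline markers (logistic at the
ML = 0.08 boundary, amplitude doubled — floor-plate markers are
effectively on/off); products of fronts and gradients for both-axes genes;
monotone temporal ramps. Template amplitude 3 means a patterned gene
varies 4-fold across its axis. Baseline abundances are log-normal with
sdlog 0.8 — abundances must span orders of magnitude, as they do in real
transcriptomes; if all genes sat at one abundance, the patterned genes
would dominate their own mean-variance stratum and self-mask during HVG
selection. Counts are negative binomial (dispersion 0.3, typical droplet
overdispersion) with log-normal library sizes (median 5,000 UMIs over 500
genes, matching deeply sequenced embryonic data scaled to the reduced gene
panel).

The low-quality mode multiplies library size by 0.25, boosts mitochondrial
rates 3-fold, and reassigns 80% of each cell's rate mass to the 50
globally highest-rate genes — one predominant program, depressed
complexity. The treatment multiplies medial-program gene rates by the
effect size and divides lateral-program rates by it, in configurable
regions; the gene model (templates, baselines) is drawn once and shared
between control and treated arms, so under effect = 1 the two arms are
draws from the same distribution and the DE null calibration is meaningful.
Ground truth travels as a sidecar table that no pipeline stage reads.

What the generator does *not* emulate: ambient RNA, doublets, batch or
replicate effects, discrete cell-type mixtures beyond an optional
contaminating population, bursty (zero-inflated beyond NB) expression, and
gene-gene correlation beyond what the shared latent axes induce. Passing
tests therefore demonstrate that each algorithm recovers the structure it
targets under realistic noise — not that real cranial neural plate data
are this clean, nor that the printed catalogues of the original study
would be reproduced gene for gene (that would require the full-scale
public dataset and its external databases).

# Numerical conventions and degenerate inputs

- Eigenvector signs: largest-|entry| positive. kNN ties: lower index.
  Eigengap/knee ties: smallest index, logged.
- Constant genes: autocorrelation Z = 0, p = 1; correlation tables record
  them as missing; module clustering drops them with a warning.
- All-zero or saturated detection in the hurdle test: that part carries no
  information and is skipped; if both parts are skipped the result is
  missing, not zero.
- Disconnected graphs: diffusion on the giant component (warning);
  absorption gives unreachable cells a uniform row (warning).
- Containers: a single-file serialized container with a magic header;
  corrupt or truncated files error loudly rather than loading partially.
  Subsetting invalidates embeddings and graphs — geometry is always
  recomputed on the cells at hand.

# Problem sizes

The validation suite runs at 2,000 cells × 500 genes for the reference
tissue (axis recovery, selection, typing), 1,500 × 400 for QC, 700 cells
per arm × 6,700 genes for the 20,000-test null calibration, and
250–400-cell constructions for trend, module and oracle checks. These
sizes were chosen so that planted effects are comfortably identifiable
at the study's own thresholds while every algorithm runs in its exact
(dense-solver) regime.

# Known limitations

- The complexity filter is approximately, not exactly, idempotent (the
  regression line is refit on filtered cells).
- Modularity community detection has a resolution limit: very large
  homogeneous cell populations are subdivided at the default resolution.
  Cluster counts are therefore not biologically meaningful on their own;
  downstream stages (Z-test removal, signature-based labeling,
  absorption refinement) are designed to be robust to over-clustering,
  and the resolution is exposed wherever clustering is called.
- The autocorrelation null treats standardized expression as iid across
  cells; heavy library-size structure correlated with the latent space
  would violate it. The permutation oracle in the tests bounds the
  approximation at the tested scales.
- The hurdle test carries no covariates (no replicate or batch terms);
  datasets with strong replicate structure need that structure removed or
  balanced upstream.
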