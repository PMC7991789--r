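---
title: "Methods: graph-theoretic analysis of resting-state connectomes with psychometric subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretic analysis of resting-state connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fconnectome)
```

# Overview

`fconnectome` implements an end-to-end region-of-interest (ROI) analysis of
resting-state functional connectivity for a three-group case-control design:
healthy controls (HC) and two patient subtypes distinguished by
anxiety/depressive status (FCAD and FCNAD, discovered from psychometric
scales). The stages are

1. **Psychometric subtyping** of patients by Ward hierarchical clustering of
   four normalized anxiety/depression scales, with cluster-number selection
   by three validity indices and a k-medoids / fuzzy C-means concordance
   retest.
2. **Temporal cleaning** of ROI time series: demeaning/detrending and
   24-parameter motion + white-matter + CSF nuisance regression, motion
   scrubbing, and 0.01–0.08 Hz band-pass filtering.
3. **Network construction**: Pearson correlation between all node pairs,
   Fisher z transform, proportional-sparsity binarization over a 10–30%
   grid, and group-occurrence averaging.
4. **Topology**: global metrics (Cp, Lp, Eglob, Eloc), random-network
   normalization (gamma, lambda, small-world-ness sigma), nodal degree and
   efficiency, and AUC integration over the threshold grid.
5. **Modular analysis**: greedy modularity on control-group occurrence
   graphs, module-level connectivity and participation metrics for all
   subjects under the control partition.
6. **Network-based statistic (NBS)**: edgewise omnibus F tests,
   suprathreshold component extraction, and a max-component permutation
   null.
7. **Group inference**: covariate residualization, one-way ANOVA with fixed
   Bonferroni families or FDR, pooled post hoc t-tests, the gender
   chi-square, and partial correlations with clinical measures.

Because subject-level imaging data of this kind are generally private, the
package ships a first-class synthetic cohort generator that emulates the
statistical structure such a study assumes; every stage is exercised and
tested against it.

# The synthetic cohort generator

`cohort_spec()` fixes the study design: 43/42/41 subjects (HC/FCNAD/FCAD),
246 nodes partitioned into seven functional modules of sizes
50/50/48/21/22/27/28 (frontoparietal, salience, default-mode, limbic,
visual, sensorimotor, basal-ganglia), 195 usable frames at TR = 2 s, and
group psychometric means/SEs taken from the emulated demographic table
(e.g. FCAD depression 69.02 ± 1.47 vs HC 37.40 ± 1.18). Standard deviations
are recovered as SE·sqrt(n); scale draws are truncated to their valid range
(20–80 for the Zung and state/trait anxiety scales) and symptom ratings
clipped to 0–100. Gender is assigned to match the configured per-group
counts exactly rather than binomially, so the gender chi-square worked
example is reproducible by construction.

**Signals.** Each subject's frames-by-nodes matrix is white Gaussian noise
multiplied by the Cholesky factor of the group's target correlation matrix —
a block matrix with `within_r = 0.3` inside modules and `between_r = 0.05`
between them. No temporal autocorrelation is modelled: the downstream
Pearson estimator is invariant to it in expectation, and none of the tested
quantities require it. A baseline signal level (1000 units) and a small
per-node linear drift are added so that DVARS (expressed as % of mean
signal) and detrending operate on realistic inputs. Motion traces are
six-parameter random walks; at a few spike frames (3 per subject, about
1.5–3% of frames once spike-adjacent displacements are counted, below the
5% scrubbing tolerance) a 2 mm displacement and a coincident global signal
offset are injected so the conjunction scrubbing rule has something to find.

**Planted effects.** Patient groups differ from controls in three ways that
mirror the qualitative findings the pipeline is designed to detect:

* a *flattened modular contrast* (within-module correlations scaled by
  0.75, between-module correlations raised by 0.035), which lowers the
  normalized clustering coefficient and small-world-ness;
* *weakened key regions* (all correlations involving the designated rostral
  anterior cingulate and thalamus nodes scaled by 0.7), lowering their
  nodal degree/efficiency;
* a *salience–sensorimotor increment* (+0.10 correlation on the SN–SMN
  block), raising inter-module connectivity.

The magnitudes were chosen once as clearly detectable planted truths —
deliberately strong enough that recovery tests are decisive at desk-scale
cohort sizes rather than hovering at the edge of power — while preserving
the small-world regime in all groups. The `node_scale` effect is a diagonal
congruence with the diagonal reset to one, so it cannot break positive
definiteness; other perturbations are checked and, if needed, repaired by
eigenvalue clipping at 1e-6 followed by renormalization to unit diagonal,
with a warning (the repair is deterministic and logged, never silent).

What the generator does **not** emulate: spatial (voxel-level) structure,
scanner artefacts, physiological noise spectra, temporal autocorrelation,
and site/heterogeneity effects. Tests passing on this cohort therefore
validate the *pipeline machinery and its statistical behaviour*, not claims
about real patient populations.

# Temporal cleaning

The cleaning order is fixed: nuisance regression (whose design includes an
intercept and linear trend, i.e. demeaning/detrending) → scrub flagging →
linear interpolation of flagged frames + band-pass filtering →
re-censoring. Correlations downstream use valid frames only. Framewise
displacement is the sum of absolute frame differences of the three
translations plus the three rotations projected on a 50 mm sphere. DVARS is
defined here as the root-mean-square across nodes of the frame-difference
signal as a percentage of the grand mean signal (the usual scrubbing
companion; the choice is a package convention). Scrubbing removes frames
exceeding *both* FD > 0.5 mm and DVARS > 0.5% — the conjunction as the
design prescribes — with an `"or"` switch exposed because the two readings
are both defensible; no neighbour augmentation is applied. Subjects losing
more than 5% of frames are flagged loudly rather than dropped.

Filtering uses a hard discrete-Fourier mask over [0.01, 0.08] Hz rather
than an IIR filter: it is deterministic, has exact band edges, and is
trivially idempotent. Flagged frames are interpolated before the transform
so censored spikes do not ring into the passband, then re-censored.

# Networks and topology

Connectivity is Pearson correlation over valid frames, Fisher-transformed
(`z = atanh(r)`), with |r| clipped at 1 − 1e-7 so degenerate duplicated
signals stay finite. Binarization keeps the E = round(s·N(N−1)/2) largest
signed z values (round half away from zero; negative correlations are not
selected, the proportional-thresholding default of the standard toolboxes).
Ties at the cut break by ascending lexicographic (i, j), which makes edge
sets nested across the grid — a property the tests assert. Group graphs
keep edges present in at least ceiling(tau·n_subjects) subject graphs; the
subject graphs enter at a reference sparsity of 0.20, the grid midpoint, a
parameter the design leaves open and the configuration exposes.

Global metrics follow the GRETNA-style conventions: Cp averages
2·triangles/k(k−1) with zero for degree < 2; Lp is the mean shortest path
over pairs of the largest connected component (keeping it finite on
disconnected graphs); efficiencies use 1/∞ = 0 natively. Gamma and lambda
normalize Cp and Lp by their means over degree-preserving rewired null
graphs, and sigma = gamma/lambda. The null family and replicate count are
not dictated by the design being emulated; the package default is 100
double-edge-swap rewired graphs (50 in the heavier sweeps), recorded in
output metadata. Null graphs are sampled along a single swap Markov chain —
10 attempted swaps per edge of burn-in, one sample per additional swap per
edge — which is statistically equivalent to independent restarts for the
ensemble means used here at a fraction of the cost. AUC is the trapezoid
rule on the literal grid, not rescaled by grid width; a single grid point
is an error rather than a silent zero.

# Modular analysis

Community detection is agglomerative greedy modularity maximization
(Clauset–Newman–Moore merging): starting from singletons, repeatedly merge
the community pair with the largest gain dQ = e_st − 2·a_s·a_t until no
gain is positive, with deterministic ties toward the smallest community
pair. The merge-tracked Q is checked against the definition
Q = sum_s(e_ss − a_s²) to 1e-12 in the tests, and against an independent
degree-product oracle. Reference partitions come from the control group's
occurrence graphs over tau = 0.50–0.70 (step 0.01); the reporting partition
is the tau with maximal Q — the design names a fixed threshold without
stating which, so max-Q selection is the recorded default. Detected modules
are named by majority overlap with the atlas module table.

"Normalized" within-module degree/efficiency is the ratio to the node's own
module mean (the named toolbox's convention), with a Guimerà-style z-score
variant behind a switch since the defining formula is not stated in the
emulated design. Participation is 1 − sum_s(k_is/k_i)², zero for isolated
nodes. Intra/inter-module connectivity is binary edge density by default
with a mean-Fisher-z weighted option. Because partitions at different tau
have different module identities, per-node modular metrics are
AUC-integrated over the tau grid while module-pair connectivity is
evaluated under the single reporting partition.

# Network-based statistic

Edgewise one-way ANOVA F statistics across the three groups (on z values
residualized for age/gender by default — the metric pipeline residualizes,
so the edge pipeline does too, behind a switch) are thresholded at the
primary value F = 12; suprathreshold edges form components, and family-wise
error is controlled by the permutation distribution of the maximal
component size in edges. Labels are shuffled once globally per permutation
(10,000 by default) and corrected p-values use the (b+1)/(m+1) convention,
so p ≥ 1/(m+1) and the test is exact-valid. The permutation loop computes
all edgewise F statistics per shuffle through one blocked matrix product,
which is what makes the 200-replicate calibration study run in about a
minute. Post hoc pairwise tests are pooled-variance two-sample t by
default (Welch optional); edges with zero pooled variance report ±Inf/0
rather than erroring.

# Group statistics

Metrics are residualized on age and gender (0/1) pooled across subjects
before the one-way ANOVA; post hoc comparisons are pooled t-tests. The
global-metric family uses the a-priori Bonferroni denominator 7 (threshold
0.05/7 ≈ 0.0071); the three correlation families use the printed
denominators 40, 8 and 64 as given, without reconstructing their
composition; nodal/modular maps use Benjamini–Hochberg FDR at q = 0.05.
The gender test is a Pearson chi-square without continuity correction.
Partial correlation is the Pearson correlation of OLS residuals on the
covariates with a t reference on n − 2 − q degrees of freedom.

# Subtyping

The four scales are z-scored (a min–max option exists; "normalized" admits
both readings and z-scoring is the default) and clustered with Ward's
minimum-variance criterion on Euclidean distances (`ward.D2`). Candidate k
in 2–6 are scored by mean silhouette (max), Calinski–Harabasz (max) and
Davies–Bouldin (min); k is the majority vote with ties toward smaller k.
Dendrogram inspection — inherently qualitative — is replaced by a
machine-readable linkage-height report. The cluster with the higher mean
normalized score is deterministically named FCAD. A weak-structure flag is
raised when the selected solution's mean silhouette is below 0.4 (at most
"weak" on the usual silhouette bands), so a forced split of homogeneous
data cannot pass silently. The retest runs PAM k-medoids and fuzzy C-means
(fuzzifier m = 2, maximal-membership defuzzification) at the selected k and
reports adjusted Rand indices against the Ward labels.

# Numerical choices and degenerate inputs

* Edge counts round half away from zero; binarization refuses an empty
  edge set.
* Correlations of ±1 are clipped before `atanh`; zero-variance nodes are a
  named error, not an NA.
* Rank-deficient nuisance or covariate designs drop collinear columns with
  a warning.
* Occurrence counting applies a 1e-9 guard inside the ceiling so exact
  fractions are not tipped by floating-point representation.
* Modules with a single node report within-metrics of 0, logged.
* An all-zero within-group variance yields F = Inf, p = 0 (documented
  rather than masked).

# Problem sizes used by the test-suite studies

The acceptance studies run at sizes chosen to make their statistical
claims decisive while staying desk-scale: the small-world sweep uses the
full 246-node cohort over 20 simulation seeds with 50 rewired nulls per
graph; NBS calibration uses 200 null replicates of 60-node networks with
90 subjects and 1,000 permutations, with power probed by a planted
9-node/8-edge component over 20 seeds; parameter recovery evaluates the
gamma/sigma pipeline on 60-node cohorts (full 43/42/41 group sizes when
effects are planted; 100 null replicates at 15/15/15 for specificity, where
group size affects only power, not validity). Subtype selection is
replicated over 100 seeds. These sizes are package choices and are all
configurable.

# Known limitations

* The generator's Gaussian, temporally white signals cannot probe
  autocorrelation-induced bias in correlation standard errors; the
  pipeline's inferences are permutation- or ANOVA-based on derived
  quantities, which do not rely on per-correlation standard errors.
* Greedy modularity has the usual resolution limit; very small planted
  modules inside very large networks may merge. The planted 7-module
  structure is comfortably above that limit.
* The NBS primary threshold is taken as a fixed F; threshold-free variants
  are out of scope.
* Lp on a disconnected graph is a convention (largest component), and
  gamma/lambda inherit whatever convention the null shares; both sides use
  the same rule so the ratios stay comparable.
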