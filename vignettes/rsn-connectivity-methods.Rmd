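---
title: "Methods: three-level resting-state network connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-level resting-state network connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnconn)
```

## The analysis model

`rsnconn` compares resting-state functional connectivity between a patient
group and a control group. The unit of data is one subject's T x N matrix of
preprocessed ROI time series (N = 36 spherical ROIs of 6 mm radius in the
packaged atlas, partitioned into six resting-state networks: DMN, DAN, FPCN,
AN, SMN, VN). Inputs are assumed to be fully preprocessed (realignment,
nuisance regression including the global mean signal, band-pass filtering);
the package starts where preprocessing ends.

For each subject, Pearson correlations between all ROI pairs give a square
N x N matrix with entries $r_{ij}$. Correlations are then mapped to a
positive similarity through an exponential function of the hyperbolic
correlation distance,

$$\eta_{ij} = e^{-\xi d_{ij}}, \qquad d_{ij} = \frac{1 - r_{ij}}{1 + r_{ij}},$$

with decay constant $\xi = 2$ by default. The transform is strictly
increasing in $r$, maps $r = 1$ to $\eta = 1$ and $r = 0$ to $e^{-2}$, and
vanishes as $r \to -1$. Its purpose is to make all connectivity values
positive so that sums and means over edges are not degraded by cancellation
between positive and negative correlations.

The transformed matrix is analyzed at three levels:

1. **Nodal integration.** $\Gamma_i = \sum_{j \ne i} \eta_{ij}$, a
   total-connectivity-degree measure per ROI (36 values). The self term
   $\eta_{ii} = 1$ is excluded by default — it is a constant that would
   shift every $\Gamma_i$ by exactly 1 and carry no information; a flag
   (`include_diagonal`) restores the literal all-$j$ sum.
2. **Network composites.** The intra-network composite of a network $X$ is
   the mean of $\eta$ over the $\binom{|X|}{2}$ unordered within-network
   pairs; the inter-network composite of $X, Y$ is the mean over all
   $|X||Y|$ cross pairs. With six networks this gives 6 + 15 = 21
   composites, hence 57 summary measures per subject in total. Each
   unordered pair is counted once (means are unchanged by double counting,
   but pair counts in outputs are not).
3. **Edge-wise NBS.** Each of the $N(N-1)/2 = 630$ edges is tested with the
   linear model $\eta \sim \text{intercept} + \text{group} + \text{age} +
   \text{sex}$; the group t statistic (patients minus controls) and
   $F = t^2$ are retained. Edges with $F$ strictly above the
   component-forming threshold (default 5.3) are split by the sign of $t$
   into two one-directional graphs, and the connected components of each
   graph are the candidate effects, sized by their number of links.

## Inference

Group differences of the 57 summary measures use the same covariate-adjusted
t statistic, with significance from permutation. With covariates present the
Freedman-Lane scheme is used: residuals of the reduced model (intercept +
covariates) are row-permuted, the reduced fit is added back, and the
full-model group t is recomputed; one permutation is applied identically to
all measures so that the multiplicity structure is preserved. When the
number of distinct group-label assignments is at most B, exhaustive
enumeration over assignments replaces sampling and the p-value is
deterministic. Sampled p-values use the add-one convention
$p = (1 + b)/(1 + B)$ so that p is never zero (a plain-proportion
convention is available as `p_convention = "strict"`).

Two reporting tiers are emitted: FDR-corrected significance
(Benjamini-Hochberg at $\alpha = 0.05$) and a lenient uncorrected
$p < 0.05$ tier. FDR is applied within two separate families — the 36 nodal
measures, and the 21 network composites — since these address different
questions; both result tables are returned so either family definition can
be inspected.

For the NBS, the null distribution of the *maximal* component size is built
from B label permutations (Freedman-Lane with covariates); the corrected p
of an observed component of size M is $(1 + \#\{b: \max_b \ge M\})/(1+B)$.
Permutation maxima are recorded per direction, each observed direction
compared with its own null; a combined-direction analysis
(`use_direction = FALSE`) thresholds on F alone. Component sizes use edge
counts, ties exactly at the threshold are excluded (strict >), and p is
monotone non-increasing in M within a run by construction.

Brain-behavior association is exploratory: within patients only, each
altered measure (lenient-tier summary measures and edges of significant NBS
components) is Spearman-correlated with MMSE and MoCA. Points outside the
Tukey fences $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ of either
variable are removed first (single pass, closed interval, type-7
interpolated quartiles); removed indices are always reported. No
multiplicity correction is applied at this tier, matching its exploratory
role. The Spearman p-value is exact (full enumeration) for n <= 7 without
ties and otherwise uses the t approximation on mid-ranks.

Quality control drops any subject whose mean frame-wise displacement (Power
formulation: sum of absolute parameter deltas, rotations converted to arc
length on a 50 mm sphere) exceeds the sample mean by more than 2 sample
standard deviations. The threshold is computed in one pass over the pooled
sample by default; whether the original rule pooled groups or not is
ambiguous, so a per-group variant is available (`qc_by_group = TRUE`) but
not asserted as the canonical choice. Subjects with missing cognitive
scores are retained for connectivity analyses and dropped pairwise from the
behavior association.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `xi` | 2 | decay constant of the eta transform (dimensionless) |
| `f_threshold` | 5.3 | component-forming threshold on the edge F statistic |
| `B` | 5000 | permutations for both summary tests and NBS |
| `alpha` | 0.05 | level for the FDR, lenient, and NBS tiers |
| `outlier_k` | 1.5 | Tukey fence multiplier for behavior association |
| `clamp_eps` | 1e-12 | clamp offset at r = -1 in the eta transform |

The eta transform diverges at $r = -1$; the default clamps such values to
$-1 + 10^{-12}$ with a warning (the transformed value then underflows to 0,
which is the correct limit), preserving monotonicity without introducing
NaN. A hard-error mode is available.

## The synthetic-study generator

`simulate_study()` draws complete studies so every stage is testable without
clinical data. Each subject's series is multivariate normal with a
block-structured target correlation matrix — `base_r_within = 0.4` inside
each network and `base_r_between = 0` across networks — passed through a
stationary AR(1) filter (`ar1 = 0.3`) to mimic the temporal smoothness of
band-passed fMRI. The between-network base of 0 reflects that the emulated
preprocessing regresses out the global mean signal, which centers
off-diagonal correlations near zero; within-network correlations around 0.4
are typical of small spherical ROIs inside a coherent network after
band-passing. Group sizes (15 + 15), series length (220), demographics
(ages around 61-62, 7/15 and 8/15 male, education 8-9 years), head-motion
summaries (means 0.086 / 0.073 mm) and cognitive-score ranges (patients
around MMSE 24 / MoCA 19 with SD near 3.5-4, controls 28 / 27 with SD 1)
emulate a small elderly case-control sample.

Planted effects shift target correlations of chosen edges or network pairs
by `delta` in one group; the default configuration reduces a connected
6-edge auditory-sensorimotor component by 0.25 in patients and couples both
cognitive scores to the first planted edge's eta. Target matrices are
checked for positive definiteness; a non-PD target is repaired by eigenvalue
clipping and the configuration rejected if the repair moves any entry by
more than 0.05. All randomness flows from a single study seed through
per-subject sub-seeds, so studies are bit-reproducible. Correlation targets
are exact in expectation at `ar1 = 0` and approximate otherwise.

What the generator does **not** emulate: hemodynamics, physiological noise,
motion artifacts in the series themselves (motion enters only as the
manifest summary), lesion anatomy, and spatial structure below the ROI
level. Passing tests on synthetic studies therefore validate the
statistical machinery — calibration, error control, recovery of planted
dependence structure — not robustness to fMRI artifacts.

## Numerical choices and degenerate inputs

- Correlations are symmetrized and clipped to $[-1, 1]$ before the
  transform; matrix diagonals are exactly 1 at both stages.
- Zero-variance ROI columns are a hard error in `correlation_matrix()`
  (named by abbreviation) and a warning at load time.
- Constant measures receive permutation p = 1 with a warning rather than an
  error, so one degenerate column cannot abort a family.
- Tail counting in permutation tests uses a relative tolerance of 1e-8 so
  statistics equal up to floating-point noise land in the tail; the Fisher
  exact test uses a relative tolerance of 1e-7 when comparing table
  probabilities, so equal-probability tables are not misclassified.
- ROI sphere membership uses voxel-center Euclidean distance <= radius in
  mm, the convention of common sphere-ROI toolboxes.
- The exhaustive permutation path enumerates group-label assignments and
  refits the group regressor (covariates stay attached to subjects); the
  sampled path permutes reduced-model residual rows (Freedman-Lane). The
  two agree under the null and the exhaustive path includes the identity,
  so neither can return p = 0.

## Statistical power at the published operating point

Two properties of the NBS at its default operating point (36 ROIs,
15 + 15 subjects, F = 5.3) are worth understanding before interpreting
results; both are measured by the package's acceptance checks.

First, error control holds: over 200 simulated null studies the fraction
reporting any significant component is about 0.065 — the per-direction test
is valid (each at most 0.05), and testing two directions raises the overall
rate slightly above 0.05 despite their negative dependence.

Second, power against *small* components is essentially nil. At F = 5.3 the
per-edge, per-direction null exceedance is about 0.015, so roughly 9 of the
630 edges are suprathreshold by chance in each direction. Nine random edges
on 36 nodes merge: even for independently placed edges the null maximal
component size has a 95th percentile around 7 links, and with realistic
within-network correlation between edge estimates it is 12-18. An effect
spanning only ~6 edges therefore almost never exceeds the null 95th
percentile regardless of its amplitude — in 50 simulated studies with the
default planted 6-edge component (a large per-edge effect, t around 8-9)
the recovery rate is below 15%, while the same edges are trivially
recovered edge-wise. Detectable NBS effects at this threshold must span on
the order of 20+ links; that is the regime in which the method is intended
to operate. Users wanting sensitivity to compact components should raise
`f_threshold` (a stricter primary threshold shrinks the null maxima much
faster than a strong localized effect).

## Problem sizes used by the test suite

The unit tests run at small sizes (tens of subjects, small graphs). The
heavier calibration checks use: 200 null studies at B = 1000 for the NBS
family-wise error; 50 replicates at B = 1000 for planted-component
recovery; 500 studies for the behavior-association null rate and 200 for
the strong-coupling ranking check. These sizes put Monte-Carlo standard
errors at or below about 0.015 for the rates being verified.

## Known limitations

- Static connectivity only: no sliding-window or dynamic measures, no
  Fisher z alternative, no partial correlations.
- The NBS has the component-size power profile described above.
- The outlier rule for behavior association is a documented convention
  (Tukey fences per variable), not a claim about any particular published
  procedure; alternative rules can be supplied via `outlier_k` or by
  pre-filtering.
- The generator's AR(1) temporal model means sample-correlation targets are
  approximate for `ar1 != 0`; the bias is small (the targets are matched in
  expectation at `ar1 = 0` and the AR filter is common to all columns).
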