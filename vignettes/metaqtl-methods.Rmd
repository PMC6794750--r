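---
title: "Meta-QTL analysis on a consensus genetic map: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL analysis on a consensus genetic map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlmeta)
```

## The problem

Veraison — the onset of grape berry ripening — is the phenological stage
that determines the climatic window a berry ripens in, and its timing is
under polygenic control. Dozens of independent QTL studies have mapped
veraison and related phenology traits, each on its own linkage map, each
reporting wide confidence intervals. `qtlmeta` implements the integration
chain that turns this scattered evidence into a short, prioritized
candidate-gene list:

1. merge the component linkage maps into one **consensus map** per linkage
   group (LG);
2. **project** every QTL onto the consensus through shared flanking markers;
3. collapse co-located QTLs into **meta-QTLs** with a Gaussian-mixture model
   selected by five information criteria;
4. **anchor** meta-QTL intervals onto the genome assembly and collect the
   genes they span;
5. intersect those positional candidates with **transcriptomic candidates**
   selected by expression-filtering rules around the veraison transition.

Every stage is also exercised against a synthetic-data generator
(`simulate_bundle()`) that emits all inputs with known ground truth, so the
full pipeline is testable without any external download.

## Consensus map construction

Component maps are first reconciled: marker spellings are normalized
through a synonym table; each LG is oriented against a reference map
(flip iff the Spearman correlation of shared-marker orders is negative;
ties keep the original orientation); LGs sharing fewer than two markers
with the rest are dropped; and residual order conflicts are resolved by
iteratively removing, among conflicting markers, the one carried by the
fewest maps (ties break alphabetically for determinism).

The merge itself works chromosome by chromosome. The component with the
most markers on the LG is the initial *calibration frame* (ties go to the
lexicographically smallest map id); the remaining maps join in decreasing
order of markers shared with the current frame. Each joining map is
calibrated by monotone piecewise-linear interpolation through its shared
markers (markers outside the shared span extrapolate the terminal
segment's slope), and every marker's consensus position is refreshed as
the arithmetic mean of its calibrated positions. After merging, the LG is
shifted so its first marker sits at 0 cM; positional ties order by
descending map support, then name. The frame rule makes the procedure
deterministic and testable; it is a documented stand-in for the
unpublished internals of the interactive software historically used for
this step, and agreement is therefore claimed at the *order* level (rank
correlation), not at the coordinate level.

## QTL projection

Projection is homothetic. With shared flanking markers at source positions
`a_L <= peak <= a_R` and consensus positions `b_L, b_R`, the scale is
`s = (b_R - b_L) / (a_R - a_L)` and every coordinate maps through
`f(x) = b_L + s (x - a_L)`; CI lengths scale exactly by `s`. A projection
is rejected when fewer than two shared markers exist on the LG ("no
anchoring markers"), when the flank distance degenerates to zero, or when
`s < 0.25` — the published scaling rule is ambiguous about which ratio is
"reduced", and this package reads it as: the consensus flank distance may
not shrink below a quarter of the source distance. No upper bound is
applied by default (`max_scale` is exposed for users who want one). Peaks
outside the shared span extrapolate through the two nearest shared markers
and are flagged. QTLs published without a CI get the standard meta-QTL
fallback `CI95 = 530 / (N * R^2)` cM before projection; records lacking
both CI and R² keep a projected peak but are excluded from meta-analysis.

## The meta-QTL model

Each projected QTL contributes an observation `x_i` (peak, cM) with a
known standard deviation `sigma_i = CI_i / 3.92` (a 95% normal CI). A
K-component mixture

`logL = sum_i log sum_k pi_k * N(x_i; mu_k, sigma_i^2)`

is fitted by EM; because the variances are known, the M-step mean is the
responsibility- and precision-weighted average and the free parameter
count is `p = 2K - 1` (K means, K − 1 weights). Initialization is k-means
seeding plus random restarts (10 by default) under a fixed seed, so fits
are deterministic given the configuration; the log-likelihood is asserted
non-decreasing across iterations. K is scanned from 1 to
`min(n, K_max = 10)` and selected by majority vote of AIC, AICc, AIC3,
BIC and AWE, each voting for its minimizing K; vote ties resolve to the
smallest K. AICc is dropped from the vote whenever it is undefined
somewhere in the scan (`n - p - 1 <= 0`), rather than letting it vote on a
truncated range. AWE is computed on the classification likelihood under
hard assignments — the criterion is named without a formula in the
meta-QTL literature, and this is the convention adopted here.

A selected cluster is summarized by its members (hard assignment), peak
`mu_k`, `CI95 = mu_k ± 1.96 * sigma_meta` with
`sigma_meta^2 = 1 / sum_i sigma_i^{-2}` (member precisions accumulate, so
`sigma_meta` never exceeds the best member), and the unweighted member
mean of R². When responsibilities overlap heavily a soft mean can drift
marginally outside its hard members' span; the reported peak is clamped
onto that span so the summary always respects its contract. Before any
fit, same-study QTLs with overlapping CIs are pruned to the highest-R²
representative, so no study is double-counted; the focal set is further
restricted to QTLs belonging to a CI-overlap cluster of at least two. The
cross-trait mode pools the focal trait with other phenology QTLs whose
CIs overlap a focal CI — pooling disjoint traits provably changes nothing.

## Co-localization testing

Within- and cross-trait co-location uses single-linkage clustering of
closed CIs (touching endpoints count as overlap); clusters supported by
two or more populations are flagged confirmed. Significance uses a binned
test: the genome is cut into 5-cM bins, each bin scored covered/uncovered
by each trait, and the 2×2 table tested by chi-square with Yates
correction. The binning itself is a reconstruction — the cited procedure
is not restated in the meta-QTL literature in enough detail to copy — so a
circular-shift permutation test is provided as a robustness alternative.
The chi-square approximation is calibrated when bin coverage events are
close to independent, i.e. when CI lengths do not exceed the bin width;
the package's calibration experiment therefore simulates 80 QTLs per
trait with CI lengths of 1–4 cM on a 19 × 100 cM genome. Longer CIs
produce runs of covered bins, inflate the type-I error of the chi-square
variant, and are exactly the regime where the permutation method should
be preferred.

## Genome anchoring and candidate retrieval

Markers with a unique BLAST placement on the expected chromosome form the
anchor set; multimappers, wrong-chromosome hits and anchors breaking the
cM/bp monotonicity of their LG are excluded (monotonicity repair greedily
drops the anchor involved in the most inversions, maximizing the number
retained). Meta-QTL CI endpoints convert to bp by piecewise-linear
interpolation between flanking anchors, extrapolating terminal slopes and
clamping to the chromosome; the conversion is monotone, so wider genetic
intervals always give superset physical intervals. Gene retrieval uses
closed-interval any-overlap on GFF3 coordinates (1-based inclusive; BED
output converts to 0-based half-open at write time).

## Expression integration

Four rules turn expression data into a transcriptomic candidate set, all
thresholds exposed in `pipeline_config()`:

* **organ atlas**: keep genes with an expressed-call in berry, rachis or
  seed;
* **ever expressed**: keep genes with ≥ 2 replicates at ≥ 1 FPKM in at
  least one (year, time point);
* **onset interval**: per year, the adjacent pre-veraison time-point pair
  across which the most biomarker genes are differentially expressed
  (ties to the earliest pair);
* **modulation**: `|log2 FC| >= 1` on replicate means with pseudocount 1
  across the onset interval, in at least 2 of the 3 years — the published
  phrasing ("highest modulation, by inspecting FPKM values") is not
  quantified, and this threshold is the package's explicit
  operationalization.

The year-rule genes are unioned with an externally provided
all-genotypes DE list (an input file; its derivation belongs to the
original expression studies and is not recomputed). Final candidates are
the intersection of positional and transcriptomic sets, and an 18-term
GO-slim (nucleotide binding, DNA/RNA binding, transcription-factor
activity, signalling, development, growth, …) flags the
regulation/signalling/development subset.

## What the generator emulates — and what it does not

`sim_config()` encodes the study conditions: 10 component maps of 60
markers per LG drawn from a shared pool (40% sharing), per-map affine
scale in [0.8, 1.25] plus 0.5-cM order-preserving jitter; veraison QTL
observations in a 1-cluster (LG 1) + 3-cluster (LG 2) layout with 2–7
QTLs per cluster, `sigma` in [0.8, 1.5] cM, R² in [0.05, 0.35], six
studies; a 200-kb/cM genome with anchors on half the shared markers plus
planted multimappers and incongruent anchors; and a 3-year, 6-time-point,
triplicated FPKM course with a planted log2-FC = 2 transition and 30
biomarkers. Distortions are affine + jitter, *not* recombination-based —
the generator exercises calibration, projection and clustering, and is
honest about not simulating meioses, segregation distortion, or
real marker ascertainment. Planted modulated candidates step upward
(induced at veraison) so that the pseudocount cannot mask their fold
change at low baselines.

Two presets matter for validation. The distorted default measures *order*
recovery (consensus rank correlation ≥ 0.95 per LG) and K-recovery (the
μ = 20/50/80, 12-QTL, σ ∈ [1.5, 4] experiment selects K = 3 in
≥ 80% of 100 seeds, median peak error ≤ 1.5 cM). `funnel_config()`
(scale 1, jitter 0) is used for the gene-for-gene funnel comparison: with
undistorted maps, projection and anchoring are exact and the only noise
left is the QTL observation scatter itself. Because a gene planted at μ
lies inside the realized meta-QTL CI95 with probability ≈ 0.95 per
cluster *by construction of the CI*, exact recovery across all four
clusters is a fixed-seed experiment (the generator default, seed 17), not
a property of every seed; across random seeds the package reports the
Jaccard overlap instead.

## Numerical choices and degenerate inputs

* EM convergence: absolute log-likelihood improvement < 1e-8, 500
  iteration cap; empty hard clusters trigger refits, and a K whose every
  restart degenerates is dropped from the scan.
* Positions are stored as doubles and written at 2 decimals (consensus
  map) — matching the precision of published meta-QTL tables.
* Calibration through duplicate source positions collapses them to their
  mean target; a map sharing < 2 markers with the growing frame is a
  hard error naming the disconnected maps.
* Projection onto flanks with zero source distance is rejected as
  degenerate rather than producing infinities.
* `sd_from_ci()` refuses non-positive CI lengths; QTL records violating
  `ci_start <= peak <= ci_end` or R² ∉ [0, 1] fail validation by name.

## Problem sizes

The shipped experiments run at deliberately desk-scale sizes: 1000 random
instances for the closed-form check, 100 generator seeds for K-recovery,
1000 replicates for the chi-square calibration, and one full synthetic
pipeline run (two LGs, ~300 consensus markers, 160 genes, 54 expression
samples). These sizes were chosen so the whole validation suite completes
in a few minutes on a single core while keeping every Monte-Carlo rate
stable to within a couple of percentage points.

## Known limitations

* The consensus merge is order-accurate, not distance-accurate, across
  strongly nonlinearly distorted maps; only rank-level agreement is
  promised.
* The 0.25 projection rule follows this package's reading of an ambiguous
  published phrase; an upper scale bound is off by default.
* The chi-square co-localization variant inherits the binning
  reconstruction described above; use the permutation method when CIs are
  long relative to the bin.
* Manual curation steps of the original analyses (which of several
  redundant QTLs a curator kept) are approximated by the deterministic
  pruning rule and are not exactly reproducible.
* The published 3130-marker consensus map and the 272-gene candidate list
  derive from 39 literature maps and public expression datasets that are
  not bundled; the package reproduces the *procedure* and validates it on
  synthetic ground truth plus the in-table arithmetic of the published
  meta-QTL summary (`published_ver_metaqtls()`).
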