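---
title: "Quantifying TIL infiltration and spatial proximity from mIHC fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TIL infiltration and spatial proximity from mIHC fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilspatial)
```

## The analysis problem

Multiplex immunohistochemistry yields, per imaged field, the nuclear
coordinates of every segmented cell together with binary positivity calls
for a marker panel (here DAPI plus CD4, CD8, CD20, CD127, KLRG1, FoxP3).
Two questions drive the analyses this package implements for two-arm
neoadjuvant studies (chemotherapy vs chemo-immunotherapy, paired pre/post
specimens):

1. *How much* of each lymphocyte phenotype infiltrates the tumor, and how
   does that change with treatment and relate to pathological response and
   survival?
2. *Where* are those cells relative to each other — specifically, are CD8⁺
   T cells and their CD127⁺ (memory-like) and KLRG1⁺ (effector-like)
   subsets spatially associated with CD4⁺ T cells and CD20⁺ B cells?

## Phenotype gating

Cells are gated exclusively on lineage markers: CD20⁺ → B cell, else CD4⁺
→ CD4 T cell, else CD8⁺ → CD8 T cell, else "other" (DAPI-only). A cell
positive for two lineage markers cannot be resolved from binary calls, so
it is assigned "other" and flagged `ambiguous` with a warning; fabricating
a lineage or silently dropping the cell would bias both the densities and
the DAPI denominator. Subset markers (CD127, KLRG1, FoxP3) do not
participate in the gate; a subset phenotype such as `"CD8_T+CD127"` selects
cells whose lineage is CD8 T *and* whose CD127 call is positive. Subset
densities therefore nest inside their lineage density by construction.

Infiltration is reported as the ratio of phenotype-positive cells to DAPI⁺
cells per field. A specimen's ~10 fields are combined by the unweighted
mean of per-field ratios (the default): fields are equal-effort samples of
the slide, and per-patient summaries in this literature are field means.
Pooling counts across fields before dividing is available
(`aggregate = "pooled"`) and differs only when fields vary strongly in
cellularity; whether the original analyses pooled or averaged is not
knowable from binary exports, so both are provided and the choice is
recorded in the output.

## The bivariate K function

For reference set $a$ and target set $b$ on a $W \times H$ field of area
$\alpha$:

$$\hat K(r) = \frac{\alpha}{D} \sum_{i \in a}\sum_{j \in b,\, j \neq i}
  I(d_{ij} \le r)\, e_{ij}.$$

Three choices deserve justification:

- **Normalization.** The printed univariate form divides by $n(n-1)$,
  which is only meaningful when $a = b$. For two distinct phenotypes the
  package defaults to the standard cross normalization
  $D = n_a n_b$ (`normalization = "cross"`); `"as_printed"` is retained
  for same-set analyses and raises a contract error if requested for
  distinct phenotypes rather than silently producing a mis-scaled value.
- **Edge correction.** $e_{ij}$ is the translation correction
  $WH/((W-|\Delta x|)(H-|\Delta y|))$ for rectangular windows. It makes
  the estimator *exactly* unbiased under complete spatial randomness:
  conditional on the counts, $\mathbb{E}[\hat K(r)] = \pi r^2$, which is
  what the calibration tests assert to 3 Monte-Carlo standard errors over
  500 fields at every sweep radius. `correction = "none"` reproduces the
  literal uncorrected sum (useful for reading the raw formula; its CSR
  expectation falls short of $\pi r^2$, the edge deficit, which is also
  tested).
- **Threshold and ties.** The indicator is inclusive ($d \le r$), matching
  $I(d_{ij} \le r)$; duplicate coordinates are legal (distance 0 counts);
  the same physical cell appearing in both sets (a CD8⁺CD127⁺ cell is both
  a `"CD8_T"` and a `"CD8_T+CD127"` cell) is excluded from its own pairs.

The radius sweep {10, 20, 30, 40, 60, 80} μm is evaluated in one pass over
pairwise distances. Neighbour counting is grid-accelerated in C++ (cell
lists with bin edge ≥ r) and is required by the test suite to agree
*exactly* with exhaustive enumeration.

## Proximity density

The proximity readout is the mean number of target cells within r = 30 μm
of each reference cell's nuclear centre. It is deliberately uncorrected —
it is a raw neighbourhood count, not an estimator of a theoretical K — so
its edge bias is characterised rather than removed: tests compare it to
λπr² on toroidal geometry, where the bias vanishes. At cohort level the
specimen value is the mean over fields with at least one reference cell;
fields without reference cells are excluded and logged, and specimens with
no eligible field are dropped with a message.

## Pathological response and TLS density

Per-patient response is the arithmetic mean of per-slide viable-tumor
percentages (1–5 slides). pCR is 0% viable; MPR is ≤ 10% (the boundary is
MPR); pCR patients count as MPR in rate computations — this is forced by
arithmetic: 23/35 MPR with 16 pCR in the same arm is only consistent if
pCR ⊂ MPR. Display rounding is one decimal, half away from zero. TLS
density is count per mm² of evaluated area; TLS identification itself is
morphological and upstream.

## Statistical layer

Group comparisons are two-sided at α = 0.05 throughout: Mann-Whitney
(unpaired), Wilcoxon signed-rank (paired; exact two-sided p by full
enumeration of the $2^n$ sign assignments on midranks for n ≤ 15, so tied
absolute differences are still exact), Kruskal-Wallis (tie-corrected H),
Pearson chi-square without continuity correction, Spearman correlation,
and two-way ANOVA for response × timepoint designs. The ANOVA uses Type II
sums of squares via model comparison (main effects adjusted for each
other; interaction from the full model) with Holm-adjusted pairwise
cell-mean contrasts — the multiple-comparison procedure is not identified
in the source analyses, and Holm is the conservative default that assumes
nothing about dependence. Degenerate zero-variance fits resolve to F = 0
(p = 1) for zero sums of squares and F = ∞ (p = 0) otherwise, rather than
NaN.

Survival uses the Kaplan-Meier product-limit estimator and the log-rank
test, with the hazard ratio reported as $(O_1/E_1)/(O_2/E_2)$ and a
log-scale CI from $\sqrt{1/E_1 + 1/E_2}$ — appropriate because all the
curve comparisons here are univariate, with no covariate adjustment.
Dichotomization is by median (ties to the high group: high iff value ≥
median) or by the maximally selected log-rank statistic: every observed
value is a candidate cutpoint, groups must each keep at least
`minprop · n` patients (default 0.1 — the search needs a floor and 10% is
the conventional one; the source does not state its constraint), and ties
break toward the lower cutpoint. The p-value at the selected cutpoint is
*not* corrected for the maximal selection; it accompanies the KM display
only and is documented as optimistic. No correction is implemented because
the cutpoint is used descriptively, to draw high/low curves, not to claim
significance of the split itself.

## The synthetic-data generator

No per-cell coordinates are published for the motivating study, so the
generator stands in for the raw data with known ground truth. What it
emulates, and how the defaults were chosen:

- **Fields**: 669 × 500 μm rectangles (a plausible 20× multispectral field;
  the true Mantra field size is instrument-dependent and configurable), ten
  per specimen. Baseline intensities put ≈ 660 cells in a field (≈ 2000
  nuclei/mm², of which ~25% lymphocytes), with B ≈ CD4 ≈ CD8 ≈ 0.0001–
  0.00012 μm⁻² and smaller CD127⁺/KLRG1⁺/FoxP3⁺ subsets — magnitudes a
  pathologist would call ordinary for treated NSCLC.
- **Treatment effects** are multiplicative post/pre fold-changes per arm:
  chemotherapy alone raises only B cells (×2); chemo-immunotherapy raises
  B (×2), CD4 and CD4⁺CD127⁺ (×1.8), CD8 (×2) and its CD127⁺/KLRG1⁺
  subsets (×2.5); Tregs unchanged — the qualitative pattern of the study
  arms. Patient-level lognormal factors (sdlog 0.4) are shared by both
  timepoints (so they cancel in changes); timepoint factors (sdlog 0.25)
  are not.
- **Attraction** is a Neyman-Scott (Thomas-type) process: the study reports
  proximity enrichment without a generative model, and a parent-offspring
  cluster process is the standard minimal mechanism. CD8 classes are
  offspring of CD4/B parents in post-NAPC only, with σ = 15 μm so the
  effect concentrates inside the 30 μm analysis radius, and background
  fraction 0.4. Marginal class intensities are preserved exactly, so
  attraction changes geometry, not abundance. Boundary handling defaults to
  clipped-with-redraw (intensities stay exact); toroidal wrapping is
  reserved for edge-free calibration.
- **Response**: MPR ~ Bernoulli(plogis(a + 1.5·Z)) with Z the latent log2
  post/pre change of the CD8 density; the intercept a is calibrated by
  numerical integration over the known distribution of Z so the marginal
  arm rates are exactly the configured 20% (NAC) and 65.7% (NAPC). pCR is
  drawn within MPR (16/23 for NAPC, 0 for NAC). Per-slide viable
  percentages are witnesses of the label (pCR: 0; MPR: Uniform(0,10];
  non-MPR: Uniform(10,90]), not a biological model.
- **Survival**: exponential DFS/OS with the hazard multiplied by 0.32 for
  patients above the cohort-median latent post-treatment CD8 density. The
  covariate enters as a threshold rather than linearly so that the
  configured high/low hazard ratio is exact ground truth for the recovery
  tests; censoring is exponential with per-patient rate chosen so the
  censoring probability equals the configured 0.3. The slide count per
  patient is uniform on 1–5.

What the generator does **not** emulate: tissue architecture (tumor nests,
stroma, necrosis), inhomogeneous cell intensity across a field, segmentation
and unmixing error in the marker calls, unpaired specimens, and any
transcriptomic layer. Passing tests therefore demonstrate that the
estimators and tests behave correctly under the stated point-process and
clinical models — not that the biological effect sizes are realistic beyond
the configured magnitudes.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to make Monte-Carlo bands tight
while keeping the suite quick: 500 fields for CSR calibration (3 SE bands),
100 random fields for exact oracle equivalence, 100 replicate cohorts at
the study's arm sizes (30/35) for the directional proximity finding and its
null calibration, 200 replicates at n = 200/arm for hazard-ratio recovery
(at 30/35 patients the sampling spread of a log hazard ratio is ±0.35 on
the log scale, so no estimator could pin 0.3 inside [0.2, 0.45] reliably),
and 2000 null replicates for the 5% ± 2% type-I checks. Distances compare
squared magnitudes (no square roots in the inner loop); all randomness
descends from a single integer seed, which output files record in their
header.

## Known limitations

- Binary marker calls are trusted as given; intensity thresholding and
  segmentation quality are upstream concerns.
- The proximity density is edge-biased by design (documented above);
  comparisons between groups imaged with the same field geometry are
  unaffected, absolute values near πr²λ are slightly deflated.
- The maximally selected cutpoint's p-value is optimistic (no selection
  correction).
- The O/E hazard ratio is a univariate summary; for covariate adjustment
  use a proportional-hazards model, which is out of scope here.
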