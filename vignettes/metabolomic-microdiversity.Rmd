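---
title: "Methods: metabolomic microdiversity from ultra-high-resolution peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomic microdiversity from ultra-high-resolution peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodiv)
library(dplyr)
```

`metabodiv` implements a complete analysis chain for comparing the
metabolomes of many co-occurring bacterial strains profiled by
direct-infusion ICR-FT/MS: peak lists in, diversity statistics and
discriminative-metabolite tables out. This vignette explains the models and
conventions behind each stage, the parameters that matter, and what the
synthetic-data generator does and does not emulate.

## The data model

Each sample is a peak list: (m/z, intensity, S/N) triples from a broadband
positive-mode acquisition over 150–2000 m/z, exported at a signal-to-noise
threshold of 1. Samples are strains × cellular fractions (extracellular
"SN1", intracellular soluble "SN2", cell-insoluble "pellet"). External
calibration keeps relative mass errors well below 1 ppm, which is the
property everything else rests on: at that accuracy an exact neutral mass
determines a small (usually singleton) set of elemental formulas for
metabolite-sized molecules.

## Alignment

`align_peaklists()` pools all peaks, sorts by mass, and cuts the sorted
sequence wherever the gap between consecutive masses exceeds
`tol_ppm × mean(mz)/1e6` — single-linkage binning. It is deterministic and
order-independent, and on instances up to a few hundred peaks it is tested
to be exactly equivalent to a brute-force transitive-closure grouping. The
default tolerance of 1 ppm is a safe envelope over sub-0.1-ppm calibration:
within-ion spread stays an order of magnitude below the envelope while
distinct formulas almost never fall inside it. When one sample contributes
two peaks to a bin, the more intense survives (tie → lower mass) and the
discard is logged. Consensus masses are intensity-weighted means, which
suppresses the mass error of weak peaks.

## Formula assignment

`enumerate_formulas()` searches CHNOS composition space under the standard
constraints: C ≤ 100, 0 ≤ O ≤ 80, N ≤ 5, S ≤ 1, the nitrogen rule, an
O/C ≤ 1 cap, RDBE in [0, 40], hydrogen at most 2C + N + 2, and a 0.5 ppm
window. Hydrogen is solved directly (neighbouring H counts are ~1.008 Da
apart, far beyond any sub-ppm window), which makes the search exhaustive
over (C, N, O, S) only; the test suite checks exact agreement with an
independent oracle that enumerates hydrogen explicitly. Two published
constraints needed interpretation:

* the O/C bound appears in garbled form in the source material; we use the
  conventional O/C ≤ 1 CHNOS filter, configurable via
  `constraint_set(max_oc_ratio = )`;
* no hydrogen bound or RDBE cap is published; the valence cap H ≤ 2C + N + 2
  and RDBE ∈ [0, 40] are our additions, both configurable.

The nitrogen rule is implemented as parity of H versus parity of N, which
for CHNOS is equivalent to the textbook formulation (odd nitrogen count ⇒
odd nominal mass) and to RDBE integrality.

`remove_isotopologues()` removes ¹³C satellites before assignment: a feature
one ¹³C–¹²C spacing (1.0033548 Da, ±0.001) above a lighter feature is
removed when its median intensity ratio to the parent is below
1.2 × C × 0.0107 (natural ¹³C abundance per carbon; C from the parent's
assignment when available, else the constraint maximum) and, where three or
more samples share both features, their intensity patterns correlate.

`assign_formulas()` keeps the lowest-|error| candidate per feature and flags
features with several in-window candidates as ambiguous. Mass degeneracy is
real above roughly 1 kDa even at 0.5 ppm; for metabolite-sized molecules
(< 1000 Da) assignment is essentially unique, which is why recovery on
synthetic data exceeds 99% at 0.2 ppm noise.

## Networks

`build_mass_difference_network()` connects formula-assigned features (only
those with |error| < 0.5 ppm become nodes) whenever their mass difference
matches a biochemical transformation within 0.1 ppm. The shipped
transformation list (`mass_diff_list()`, ~50 entries: hydrogenation,
(de)methylation, condensations, amino-acid and sugar residues, sulfur
chemistry) is a stated surrogate for unpublished lists used with this
network style; deltas are computed from element masses, never typed in. The
ppm denominator is the larger of the two node masses — the convention is
not published, so it is documented and configurable in one place. Edge sets
are tested against an all-pairs oracle.

`build_correlation_network()` connects samples whose intensity profiles have
Pearson r above 0.90 (positive correlations only); connected components then
recover fraction- or site-specific sample groups. `class_specificity()`
implements the 10-fold presence-frequency rule used to colour
class-specific features.

## Supervised models and discriminative selection

`opls_da()` follows the orthogonal-signal-correction scheme: Y-orthogonal
components (default 1) are identified and deflated from the preprocessed
matrix, then a single predictive PLS component is fitted. With zero
orthogonal components the model reproduces one-component PLS-DA to machine
precision — a degeneracy the tests assert at 1e-8. Class encoding is −1/+1
on the alphabetically sorted labels.

Three selection rules are combined for discriminative metabolites:

* **VIP ≥ 1** — `vip()` computes
  VIP_j = sqrt(p · Σ_a w_ja² SSY_a / Σ_a SSY_a); mean VIP² is 1 by
  construction, so Σ VIP² = p is asserted on every fitted model.
* **Joint covariance/correlation** (`select_candidates()`) — |cov(t₁, x_j)|
  and |corr(t₁, x_j)| are each rescaled so their maxima equal 100%; a
  feature qualifies when both exceed 50% (strict inequality).
* **Wilcoxon rank-sum p < 0.05** (`wilcoxon_select()`) — raw p-values drive
  selection to match common chemometric practice with these data;
  Benjamini–Hochberg q-values are reported alongside for reference.

Preprocessing defaults to mean centring with Pareto scaling, the usual
FT-MS compromise. One caveat discovered during validation and worth
stating plainly: under Pareto scaling the covariance axis of the S-plot
scales with absolute intensity, so the joint 50% rule keeps only the most
intense candidates (recall against a planted truth collapses to a few
percent). Under unit-variance scaling the same rule behaves as a
per-feature standardized criterion and recovers planted discriminative
features with precision and recall above 0.9. The original software's
scaling is unpublished; the discriminative-selection analyses in this
package therefore fit with `scale = "uv"`, while Pareto remains the default
elsewhere.

`cluster_support()` quantifies whether a strain partition supports a
classification model: 7-fold cross-validated Q² of a one-component PLS-DA
(threshold 0.4) plus a 200-permutation p-value (threshold 0.05). The
criterion is our choice — no specific rule is published — and both
thresholds are arguments.

## Metabotype OTUs and diversity

`ward_dendrogram()` clusters strains so each merge minimises the increase
in within-cluster error sum of squares; merge heights equal that ESS
increase (two points at Euclidean distance d merge at d²/2). Conventions
for "Ward distance" differ between implementations, so this one is pinned
by an exhaustive greedy-ESS oracle on small instances. The input metric is
Euclidean distance on the centred, Pareto-scaled intensity matrix — the
original metric is unstated, and this matches the preprocessing used for
the latent-variable models.

`cut_percent()` cuts at pct/100 × the dataset's maximal merge distance, so
thresholds are comparable across fractions whose absolute Ward scales
differ by large factors. Partitions are nested across thresholds, hence
along any grid the m-OTU count and Shannon index are non-increasing and
Good's coverage non-decreasing — `diversity_profile()` asserts this on
every run. Diversity statistics use the textbook closed forms: Shannon in
natural log units, Good's C = 1 − n₁/n_t, and hypergeometric rarefaction
E[S_n] = Σ_i (1 − C(N−N_i, n)/C(N, n)) (cross-checked against
`vegan::rarefy`). Individuals are strains; species are m-OTUs. The default
report grid is 5–100% in 5% steps with the 10%/40% working range
highlighted.

## Fingerprint dendrograms

`similarity_dendrogram()` covers the two binary-fingerprint analyses:
UPGMA on Dice similarity for genomic restriction band patterns, and single
linkage on the matched-peak percentage for whole-cell MALDI spectra.
Positions match under a 1% relative tolerance (a typical gel band-matching
setting; the original tolerance is unpublished). Heights are
100 − similarity. UPGMA is pinned by a brute-force average-linkage oracle.

## The synthetic-data generator

`generate_truth()` + `simulate_peaklists()` create a fully known study:
chemically valid CHNOS formulas (every one passes the default constraint
set, masses in the acquisition window after protonation), split into a
shared core metabolome and disjoint group-specific accessory sets, plus a
synthetic annotation reference table over a configurable fraction
(default 15%) of formulas with a planted class-frequency skew.

Default sizes mirror one intracellular fraction of the kind of study this
package targets: 5332 core + 274 + 136 accessory formulas
(≈ 5700 features, ≈ 7% discriminative between an "old" reference group and
"new" isolates). The formula sampler draws C between 5 and 40 so masses
concentrate below ~1000 Da — metabolite-sized molecules, where exact-mass
assignment is informative; planting kilodalton-scale CHNOS species would
manufacture mass degeneracy no real metabolome exhibits.

The noise model (`noise_model()`) has five active parts:

| parameter | default | emulates |
|---|---|---|
| `mass_noise_ppm` | 0.1 | externally calibrated mass accuracy (<100 ppb) |
| `intensity_cv` | 0.05 | technical intensity reproducibility (RSD < 5%) |
| `strain_cv` | 0.4 | biological between-strain intensity variation |
| `dropout_prob` | 0.05 | per-strain absence of a core feature |
| `n_noise_peaks` | 100 | spurious peaks, ≥3 ppm from any true mass |

`strain_cv` deserves a sentence: strains are not technical replicates, and
with only the 5% instrument CV, presence/absence dropout would dominate all
between-strain distances and no intensity effect of realistic size could
ever be recovered by unsupervised clustering. Group effect sizes
(`truth_config(effect_size = 2)`, in units of the total per-feature SD)
therefore sit on top of a biological CV of 40%. ¹³C satellites are added at
+1.0033548 Da with intensity ratio 0.0107 × C.

What the generator does **not** emulate: correlated metabolite modules
(features are independent given the group), adducts beyond protonation,
multiply charged ions, detector saturation, batch drift between
experimental sets, and retention behaviour (direct infusion has none).
Passing recovery tests therefore demonstrate the statistical machinery and
the mass-domain logic, not robustness to every artefact of real spectra.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run: 1000-mass enumeration
oracle comparisons below 500 Da; a 500-formula assignment-recovery
simulation at 0.2 ppm noise; a study-sized (5742-feature, 20 + 20 strain)
discriminative-recovery run; a 24-strain, 4-cluster m-OTU recovery; and
~100-node network oracle comparisons. Together they complete in well under
two minutes on one CPU.

Tie-breaks and degenerate inputs are fixed as follows: intra-sample
alignment collisions keep the higher intensity, then the lower mass;
all-zero covariance profiles select nothing; zero-variance samples are
isolated nodes with a warning; empty peak lists warn rather than error
(a cultured strain can legitimately express nothing above threshold in a
fraction); percentage cuts at 0 or above 100 are errors. Printed-style
percentages round half away from zero (whole percents for the old-vs-new
table style, one decimal for the cluster table style); one published cell
(986/3698 → "26%") is not consistent with that rule (26.66% rounds to 27%)
and is deliberately not reproduced.

## Known limitations

Only CHNOS formulas and ±H adducts are considered; multi-class contrasts
must be run pairwise; the transformation list and annotation vocabulary are
surrogates for unpublished resources; m-OTU thresholds are descriptive
choices, not estimates — the package deliberately offers no automatic
"correct" threshold.
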