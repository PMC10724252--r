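---
title: "Methods: CF-MS interactome inference with cfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CF-MS interactome inference with cfnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfnet)
```

# The model

Co-fractionation mass spectrometry (CF-MS) quantifies proteins across the
fractions of a native chromatographic separation. The statistical premise
is that subunits of a stable complex share an elution peak, so the
similarity of two protein chromatograms is evidence for a physical
interaction. `cfnet` operationalizes this as a supervised learning
problem over protein pairs:

1. **Features.** For each experiment, per-pair chromatogram similarity is
   computed with measures whose missing-value handling is fixed:
   distance correlation and weighted cross-correlation impute missing
   intensities as zeros (a missing CF-MS value usually means below the
   detection limit, i.e. effectively zero signal); cosine similarity
   imputes seeded near-zero noise, which avoids the artifactual
   similarity that shared exact zeros would create between sparsely
   detected profiles; mutual information uses pairwise-complete
   positions only. How many measures are computed per experiment follows
   a tier rule on the number of experiments available for the species
   (1 / 2 / 4 for >10 / 6–10 / ≤5 experiments, in descending order of
   single-measure performance: distance correlation, weighted
   cross-correlation, cosine, mutual information), trading per-dataset
   feature richness against total dimensionality.
2. **Labels.** Intra-complex pairs from a complex catalog are positives;
   pairs of catalog proteins never co-complexed are negatives. This
   "inter-complex negatives" convention makes reported precision
   deliberately conservative: many inter-complex pairs do interact but
   are missing from the catalog.
3. **Classifier.** A random forest with 100 trees scores each pair. Folds
   are split at the level of *complexes*, not pairs: a positive pair
   inherits the fold of its (smallest-id) source complex, so the model
   scoring a pair has never seen any pair from that complex — the
   standard guard against within-complex information leakage. Unlabeled
   pairs are scored by the mean over fold models (variance-reducing and
   symmetric in the folds).
4. **Thresholding.** Cumulative precision over labeled pairs is computed
   down the ranked list; the network keeps the deepest rank whose
   precision meets the target (default 50%), or alternatively a fixed
   top-k.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `L` (WCC lag window) | 1 | fractions | tolerates single-fraction peak shifts; `L = 0` reduces WCC to Pearson |
| `B` (MI bins) | 10 | — | plug-in histogram estimator; ≥ `B` pairwise-complete points required |
| `sigma` (noise imputation) | 1e-4 | × chromatogram max | "near-zero": three orders below signal |
| `min_fractions` | 4 | fractions | proteins quantified in fewer fractions carry too little profile shape |
| `k` (CV folds) | 5 | — | complex-level splitting; requires ≥ k complexes |
| `n_trees` | 100 | trees | forest size used throughout |
| `target_precision` | 0.5 | — | conservative given the inter-complex negative convention |
| `proportion` (augmentation) | 0.33 | × native labeled pairs | low injection proportions work best; injected pairs are training-only |
| `min_size`, `max_size` (coherence) | 10, 100 | proteins/term | terms below are statistically unstable, above are uninformative |
| phosphosite priority threshold | 5 | fractions | detection depth as a proxy for functional relevance |

The weighted cross-correlation functional form (triangular lag weights
$w_k = 1 - |k|/(L+1)$ over raw cross-covariances of mean-centered
vectors) and the MI discretization (equal-width bins over the
pairwise-complete range) are this package's own choices; the measures are
named in the CF-MS literature without a canonical definition, so both are
exposed as configuration and documented here rather than hard-coded
silently.

# The synthetic study generator

`simulate_study()` emulates the statistical structure the inference
relies on, with all parameters in `sim_config()`:

* each complex draws one co-elution peak center per experiment (uniform
  over fractions); members jitter around it (`jitter_sd`, default 2
  fractions) with Gaussian peak shapes (`width_mean` 2.5 fractions) and
  log-normal amplitudes; monomers elute independently;
* multiplicative log-normal noise (`noise_sd` 1) plus a small additive
  background; missingness combines a detection-limit quantile (30%,
  mimicking the abundance bias of CF-MS towards highly abundant
  proteins) with 25% random dropout.

The noise defaults were chosen so that the labeled classes overlap the
way they do in real CF-MS data (cross-validated AUROC in the low-to-mid
0.9s on the default study rather than ≈ 1.0). This matters beyond realism:
with perfectly separable classes, the score of the weakest accepted
labeled negative tends to zero and the 50%-precision threshold
degenerates, sweeping in every mildly co-eluting unlabeled pair. The
member-jitter of 2 fractions (comparable to peak width), intensity noise
of log-normal sd 1, and combined ~45% missingness are typical of
published size-exclusion datasets.

What the generator does *not* emulate: overlapping complex membership,
condition-specific (partial) assembly, correlated noise between
co-measured proteins, peptide-level identification artifacts, and
isotope-labeling channel structure. Tests passing on this generator
therefore validate the statistical machinery, not performance on any
real dataset.

Two structural consequences of the design are worth stating explicitly,
because they set expectations for the bundled end-to-end checks:

* **Ground-truth precision at the 50% threshold.** In the default study
  every true intra-complex pair is labeled. At the deepest rank $k$ with
  cumulative labeled precision ≥ 0.5, the precision is necessarily just
  above 0.5 (it moves by less than $1/n$ per labeled pair), and since
  truth ⊆ labels, the ground-truth precision of the thresholded network,
  $TP_k / k \le TP_k / n_{labeled}(k) \approx 0.5$, is bounded by the
  target itself. A recovery precision far above the threshold target is
  therefore impossible by construction in this design — the relevant
  quality signals are the AUROC and the coherence of the thresholded
  network, not its raw ground-truth precision.
* **Augmentation is neutral here.** The simulated external pool is drawn
  from the same generative distribution as the target study, so native
  labeled pairs are fully representative and the forest saturates with
  tens of examples; injecting external labeled pairs neither helps nor
  hurts (median AUROC differences within ±0.005 over 10 seeds). The
  benefit of augmentation in practice arises when native training data
  is scarce *and* unrepresentative relative to model capacity, a regime
  this generator deliberately does not manufacture.

# Numerical choices and degenerate inputs

* Distance correlation returns 0 when either distance variance is zero
  (constant chromatogram); WCC returns 0 with a warning on a zero
  denominator; cosine errors on a zero-norm vector (an all-missing
  profile cannot be noise-imputed); MI returns the missing-feature
  marker (`NA`) when fewer than `B` pairwise-complete positions exist.
* Missing-feature markers are zero-filled immediately before model
  fitting (consistent with the zero-imputation semantics of the dominant
  measures); a median fill is available via `fill = "median"`. An
  internal assertion guarantees no marker reaches the learner.
* Gene collapsing keeps the chromatogram with the fewest missing values;
  ties break by larger summed intensity, then lexicographically smaller
  group id, so results are invariant to input row order. Collapsing
  happens before the minimum-fractions filter.
* Ranking ties break by alphabetized pair order, making every ranked
  list and threshold deterministic under row permutation.
* All randomness (simulation, noise imputation, fold split, forest,
  augmentation and transfer sampling) is drawn through seeded local RNG
  streams derived from the user seed; the caller's RNG state is never
  disturbed.
* Neighbor-voting: proteins with degree zero or only hidden-annotated
  neighbors score 0 rather than missing, keeping the ROC well defined;
  the negative class is network proteins never annotated with the term;
  the AUC estimator is the exact rank-based Mann–Whitney statistic.
* Parent-peak detection for phosphosite stoichiometry uses 3-point
  moving-average smoothing and a 10% relative prominence floor — both
  exposed as arguments, as peak calling is not standardized.

# Design decisions

* The one-fitting-function idiom: `train_score_cv()` returns a
  `ranked_network` with `print`, `summary`, `plot` and `predict`
  methods, so the whole inference is one call on a feature table and a
  label set.
* Fold splitting at complex level (k = 5 default) rather than pair level:
  pair-level splitting leaks complex structure between folds.
* A pair positive in one complex and a member of another is a positive
  (the positive label dominates); negatives are never sampled from
  co-complexed pairs.
* Training uses all labeled pairs by default; `negative_ratio` offers
  class-balance subsampling where negatives overwhelm.
* External pools carry distance correlation only by default (the
  strongest single measure and the cheapest to compute at scale);
  `augment_training` validates that the pool covers whatever measures
  the target manifest uses.
* Transfer pseudo-replicates: each external labeled pair is assigned a
  seeded random tuple of external experiments matching the target's
  replicate count, with replacement (and a warning) only when the pool
  has fewer experiments than needed.
* Ortholog projection admits only one-to-one maps; ambiguous rows are
  dropped on both sides, which loses coverage but never mislabels.

# Problem sizes used in the bundled checks

The test suite exercises oracle equivalence on ~100 randomized small
instances per statistic (≤ 30 proteins, ≤ 20 ranks), null calibrations
over 50–100 seeds, and the end-to-end study at its default size (200
proteins, 20 complexes, 3 experiments of 50 fractions, 10 seeds); the
acceptance script uses the same sizes. These sizes were chosen so that a
full run finishes in minutes on a single core while keeping the labeled
pair counts (≈ 120 positives, ≈ 2300 negatives) large enough for stable
precision curves.

# Known limitations

* The feature tier rule and measure defaults are fixed to the four-measure
  family; the wider space of co-elution measures is out of scope.
* Complexes in the generator are disjoint; real catalogs overlap heavily,
  which mainly affects fold inheritance (handled by the smallest-id rule)
  and the positive/negative boundary.
* `pair_property_correlation` assumes profile matrices share the
  network's identifier namespace; no identifier mapping is attempted.
* The phosphosite module treats aggregate-only (e.g. TMT) intensities as
  one experiment with zero fraction detections, which under-counts
  detection depth for such datasets.
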