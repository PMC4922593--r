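---
title: "Inferring and predicting cognitive map structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and predicting cognitive map structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(submapr)
```

## The model

`submapr` treats the structure of allocentric spatial memory as the outcome
of clustering in a subject-specific *psychological space*. Each building is
described by features — spatial position, visual appearance, function,
and name-similarity surrogates — and a subject's memory assigns a
dissimilarity to every pair. The package's central hypothesis-driven
machinery has two parts:

1. a **metric** over pairwise feature differences Δx, either the
   weighted-Euclidean form $d_M(\Delta x) = \sqrt{\sum_f w_f \Delta f^2}$
   (a Mahalanobis distance with diagonal inverse covariance) or the
   Gaussian-discriminant form $d_{GDA}(\Delta x) = 1 - p(c=1\mid\Delta x)$,
   where the class-conditional densities of same- and different-sub-map
   pair differences are multivariate Gaussians and the posterior follows
   from Bayes' rule;
2. a **grouping mechanism**: a Dirichlet-process Gaussian mixture (DP-GMM)
   with truncated stick-breaking weights $\pi_k = v_k \prod_{j<k}(1-v_j)$,
   $v_k \sim \mathrm{Beta}(1, \alpha_1)$, component means from
   $N(0, I)$ and precisions from $\mathrm{Wishart}(D, I)$. Its key property
   is that the number of sub-maps is inferred from the data. Hard
   memberships are read off as $c_i(p) = \arg\max_c \pi_c N(p; \mu_c,
   \Sigma_c)$.

Ground truth on the measurement side comes from the recall-order paradigm:
objects on one sub-map are recalled together, so a sub-map is a subset of
buildings that forms a contiguous block, in any internal order, in every
recall sequence. The ordered tree of such consistent subsets is summarized
by its height and by the log-cardinality $c(T) = \log_2 \prod_i n_i!$ (the
number of orderings the tree licenses), and leave-one-sequence-out
jackknifing removes sequences whose omission significantly changes either
statistic (two-sided $z$, $\alpha = 0.05$, population variance over the
$N$ omissions; a zero-variance statistic contributes $z = 0$; removal is
single-pass).

## Parameters that matter

| parameter | default | meaning |
| --- | --- | --- |
| `alpha` (jackknife) | 0.05 | two-sided significance for outlier removal |
| `exclude_cue_position` | `TRUE` | analyse only the uncued part of cued sequences |
| `n_random` | 10{,}000 | random maps behind the sketch-map null (doubling it changes nothing) |
| `w` (windows) | 5, 15, 31 | odd moving-average windows for co-representation probabilities |
| `budget` | 2000 | DIRECT objective evaluations; weight bounds $[0,1]^d$ |
| `ridge` | $10^{-4}$ | L2 penalty keeping the logistic fit finite under separation |
| `lambda` (GDA) | 0.1 | covariance shrinkage toward the diagonal, plus $10^{-6} I$ |
| `alpha1` | 1.0 | DP concentration; smaller values resist spurious components |
| `truncation` | 10 | stick-breaking truncation level |
| `prior_scale` | 3 | data scale, in prior standard deviations (see below) |

## Numerical choices

**Standardization.** Feature differences are divided by their training-set
standard deviation before any metric is fitted, so weights are importances
on comparable scales (spatial distances otherwise dwarf similarity
ratings). Learned weights can be mapped back to the raw feature scale as
$w_f / s_f^2$.

**Embedding.** For a linear metric with per-building feature values, each
standardized column is multiplied by $\sqrt{w_f}$, so Euclidean distances
between embedded points equal $d_M$ exactly (weighting by $w_f$ itself
would square the metric's intent; we resolve in favor of the metric).
Pairwise-only features and the GDA metric are embedded by classical
scaling of the full distance matrix in $\min(n-1, \#\text{features})$
dimensions; the relative residual (stress) is reported.

**DP-GMM inference.** Mean-field variational inference on the truncated
stick-breaking representation, implemented in C++. Three choices deserve
explanation:

- *Principal-subspace projection.* The data are centered and rotated onto
  their principal subspace (null directions dropped, deterministic sign
  convention) before fitting. The priors are rotation-invariant, so this
  changes nothing statistically, but it makes the fit depend only on the
  shape of the configuration — the direct linear embedding and the MDS
  embedding of the same metric then yield identical clusterings.
- *Prior scale.* The configuration is scaled isotropically so that the
  variance per retained dimension is `prior_scale`² . The Wishart prior
  floors each component's covariance near $W_0^{-1}/\nu$, so this scale
  sets the model's resolution: at scale 3 a grouping must be roughly three
  prior standard deviations tighter than the overall spread before
  splitting raises the bound. Unit scale makes five-point samples
  unsplittable; very large scales fragment everything.
- *Mean-prior coupling.* The conjugate prior couples the mean to the
  component precision, $N(0, (\beta_0\Lambda)^{-1})$. With $\beta_0 = 1$ a
  tight cluster's mean is shrunk so hard toward the origin that small
  samples never split; `beta0 = 0.01` emulates the model's independent
  $N(0, I)$ mean prior while keeping conjugacy.

Initialization is deterministic: Ward agglomerative cuts at $1..k$ groups,
each refined by VB, best variational bound wins; ties in hard assignment
break toward the lowest component index; components with weight below
$1/(10\,K)$ are pruned. Identical inputs and seed give identical output.

**DIRECT.** The classic rectangle-trisection scheme over $[0,1]^d$ with the
potentially-optimal selection rule ($\varepsilon = 10^{-4}$). The first
evaluation is the domain center — equal weights — so the returned optimum
is never worse than uniform weighting. The objective is
$1 - \text{mean Rand}$ of clustering under the candidate metric against the
subject's training structures; it is piecewise constant, which is exactly
the situation a Lipschitzian space-dividing optimizer handles and gradient
methods do not.

**Cue exclusion and laminarity.** Only the uncued part of cued sequences is
analysed. Dropping cue positions weakens the contiguity constraint, so two
genuinely consistent subsets can partially overlap (a sub-map against a
near-complement artifact whose missing member was a dropped cue). The tree
pipeline resolves conflicts by keeping a laminar family, preferring
smaller subsets — the elementary sub-maps the analysis is after. With
well-varied full sequences the family is laminar and the step is a no-op;
`build_ordered_tree()` still rejects non-laminar input outright, as a
guard against corrupted data.

**Scoring.** Excluded singletons in the subject's structure are dropped
from scoring (they were excluded from subject data); predicted singleton
clusters stay in as their own groups, so predicting a grouped building as
a singleton counts as a mistake. Exact accuracy is strict: one wrong
membership fails the whole structure. The chance baseline treats
prediction as assigning one of $K+1$ values per building,
$(1/(K+1))^B$.

## The synthetic cohort: what it emulates, and what it does not

The simulator defines the study conditions for every quantitative claim in
the test suite.

- **Subjects** draw feature weights from a symmetric Dirichlet whose
  concentration is `1/sparsity`; sparsity 2 gives the strongly
  heterogeneous profiles that motivate subject-specific models. A
  `quadratic` variant perceives colour through a fold (colours equidistant
  from the scale midpoint look alike), giving a grouping rule no monotone
  weighted metric can represent.
- **Environments.** The `two-groups-middle` layout reproduces the
  controlled training trials: two tight groups of two buildings, equal
  colour and function within a group (one group shops, one houses), and a
  variable middle building. `random` layouts are unconstrained. The
  `contrastive` layout gives each of `n_active` features its own latent
  two-group split: with `n_active = 2` each environment adjudicates one
  feature pair (used for the weight-recovery study, where identifiability
  is the point), with `n_active = 5` every feature competes (used for the
  prediction benchmark). This mirrors the logic of generating controlled
  environments to probe feature importances.
- **Recall** lists the structure's groups contiguously — random group
  order, random within-group order, the cued building's group first with
  the cue first inside it; one cued sequence per building plus two uncued.
  Distractions are injected as a single adjacent transposition across a
  group boundary (the minimal corruption that breaks contiguity), never
  displacing a cue. Randomly drawn orders can by chance leave a spurious
  subset contiguous everywhere, so clean trials are resampled (up to 50
  draws) until tree analysis inverts them — this enforces the order
  variety that cueing is meant to produce. Structures with fewer than two
  groups are unidentifiable from recall order and are returned unverified.
- **Sketch maps** use a hierarchical noise model: each sub-map is a local
  reference frame whose centroid receives the full positional jitter while
  buildings inside receive half of it, plus within-frame contraction and a
  random similarity transform for the empty canvas. This reproduces the
  signature that within-sub-map relations are remembered more precisely
  than across.

What passing tests on this cohort do **not** show: human recall contains
strategy effects (articulatory rehearsal, episodic-memory intrusions,
circular read-off from notes) that the generator only represents as
abstract swap noise or not at all; real feature values are correlated in
ways the independent latent splits are not; and the human headline
accuracies depend on the original participants and cannot be reproduced
here. The benchmark numbers are the synthetic analogue of those results —
their value is the *ordering* (subject-specific above subject-general,
both far above chance), not the absolute percentages.

## Study sizes

The test suite runs the generator/extractor duality on 1000 random
structures (5 and 8 buildings), the weight-recovery study on 50 subjects ×
20 pairwise-contrast environments (DIRECT budget 150), the end-to-end
benchmark on 20 subjects × 5 fully contrastive environments (4 train / 1
test, GDA shrinkage 0.1), and the bootstrap calibration on 1000 null
sketches against 200 random maps each. The analysis drivers use a smaller
12-subject cohort; `scripts/acceptance.R` re-runs the benchmark at the
full 20-subject size.

## Known limitations

- A sub-map covering *all* buildings is indistinguishable from an
  unstructured map in the recall paradigm (no proper subset witnesses it).
- Jackknifing on clean data occasionally removes a legitimate sequence,
  and removing a corrupted sequence can leave six sequences that admit a
  spurious subset; exactness claims therefore attach to tree analysis
  proper, with jackknifing evaluated statistically.
- The within/across sketch-error contrast depends on the noise model;
  contraction alone (without local-frame noise) biases the contrast the
  other way.
- GDA's single Gaussian per class cannot represent multimodal same-sub-map
  difference distributions; with few training environments per subject the
  pooled subject-general model can then look locally competitive even
  though it misses individual weightings.
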