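---
title: "Methods: an MRI-derived severity index for Alzheimer's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an MRI-derived severity index for Alzheimer's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adindex)
```

## The problem and the model

Alzheimer's disease produces a characteristic spatial pattern of brain
atrophy — strongest in medial-temporal structures (hippocampus, entorhinal
cortex, amygdala) with ex-vacuo enlargement of the adjacent ventricles —
that is measurable from T1-weighted MRI via automated segmentation.
`adindex` condenses 57 regional measures into a single continuous severity
index by training a supervised latent-variable discriminant (OPLS) on
baseline AD-vs-control data, and then applying that frozen model to any
subject at any timepoint: MCI patients (for conversion prediction),
follow-up scans (for atrophy-rate tracking), and cognitively normal elders
(for heterogeneity/pre-clinical analysis).

### Preprocessing

Volumes are divided by the subject's estimated intracranial volume to
remove head-size variation; thickness measures are not normalised, as
thickness does not scale with head size. Each feature is mean-centred and
scaled to unit variance. Two conventions are fixed here because the
upstream description leaves them open:

* **SD convention** — sample SD (n−1 denominator), applied consistently in
  the scaler, the generator checks and the z-scoring utilities.
* **Frozen parameters** — all scaling statistics are estimated on the
  training set only and re-applied verbatim to every new table. Inside
  cross-validation the scaler is re-fit per fold; the final model's scaler
  never sees non-training data. Missing values are rejected rather than
  imputed, mirroring the practice of excluding failed segmentations.

### OPLS core

For autoscaled $X$ ($n \times p$) and class codes $y \in \{0,1\}$
(CTL = 0, AD = 1), the single-response O-PLS recursion is:

1. $w \propto X^\top y$, normalised to $\lVert w\rVert = 1$. For a single
   response this direction is invariant under orthogonal deflation.
2. For each of $n_o$ orthogonal components: $t = Xw$,
   $p = X^\top t / t^\top t$, $w_o \propto p - (w^\top p)\,w$,
   $t_o = X w_o$, $p_o = X^\top t_o / t_o^\top t_o$, deflate
   $X \leftarrow X - t_o p_o^\top$.
3. On the filtered matrix: $t = Xw$, inner regression
   $b = t^\top (y - \bar y)/t^\top t$, prediction
   $\hat y = \bar y + b\,t$.

By construction every orthogonal score satisfies
$\operatorname{corr}(t_o, y) = 0$, and the training predictions with $k$
orthogonal components coincide with a $(k{+}1)$-component PLS1 fit. The
test suite verifies both properties against an independently written
NIPALS PLS1 oracle at $10^{-6}$, so the orthogonal filtering is
interpretation-only by checked construction, not by assumption.

**Number of orthogonal components.** Not identifiable from the published
description, so the default is a forward rule evaluated on the training set
only: starting at 0, add the next orthogonal component while it strictly
increases cross-validated Q²(Y), capped at 5. Any fixed count can be set
per block via `n_ortho`/`n_ortho_top`.

### Cross-validated significance

Q²(Y) = 1 − PRESS/SSY with PRESS pooled over out-of-fold predictions and
SSY = Σ(y − ȳ)², the total variation of the centred class codes. Under
this convention the mean predictor scores exactly 0 and perfect prediction
exactly 1; Q² is invariant to swapping the class labels. Q² > 0.05
(strict) is treated as significant. Folds are stratified by class and
assigned deterministically from a seed. The default is k = 7; the source
work reports both 7- and 10-fold for the same model, so the count is
configurable and neither value is asserted as ground truth.

### The hierarchical index

Thickness (34 features) and ICV-normalised volumes (23 features) are
modelled in separate OPLS blocks; the block scores are autoscaled and fed
to a top-level OPLS whose predicted class value is the index. Open design
points resolved here:

* **Which block outputs feed the top model** — the predictive score plus
  all orthogonal scores of each block (richest faithful reading of
  hierarchical modelling), configurable to predictive-only
  (`block_scores = "predictive"`).
* **No clipping** — the index is the raw top-model prediction. Published
  per-group summaries include values below 0 and above 1, so clipping
  would be unfaithful.
* **Ties at 0.5** — labelled CTL-like; only values strictly above 0.5 are
  AD-like.
* **CV of the hierarchy** — the entire hierarchy (scaler, blocks, top) is
  re-fit inside every outer fold. Whether the original software nested its
  CV this way is unknown; this choice is the leak-free one.
* **Feature importance** — within a single OPLS model, features are ranked
  by |predictive loading|. For the hierarchy, importance propagates the
  class-separating direction only: within-block |p| times the top model's
  |p| on that block's predictive score. The alternative — the exact
  composed linear coefficient of the index on each feature, available as
  `coef()` — mixes orthogonal-filtering directions into the ranking and
  is demonstrably worse at recovering planted effects; it is kept for
  exact linear-map queries, not ranking.

### Evaluation conventions

Sensitivity = 100·AD-like/(positive group), specificity =
100·CTL-like/(negative group), both rounded half-up to integer percent
(verified against all ten published worked-example cells). The ROC is the
empirical threshold sweep; AUC is the trapezoidal area, equal to the
tie-corrected U/(n₁n₂) (checked against a brute-force pair count), with a
Hanley–McNeil SE. The original work computed AUC with a binormal-model web
tool, so published AUC±SE values are context, never test assertions.
Baseline AD/CTL report rows use out-of-fold CV indices; MCI and follow-up
rows use direct application of the final model — MCI subjects are never in
training.

### Longitudinal quantities

Annual rate = index(12 m) − index(baseline), the literal published
formula; it is not divided by the exact inter-scan interval because
per-subject intervals are not modelled. Average index = mean of the two
timepoints; pattern-of-atrophy stratification uses the average index.
Rank-based tests follow fixed conventions: Mann–Whitney exact by
enumeration for total n ≤ 20 without ties, otherwise normal approximation
with tie correction and no continuity correction (making U/(n₁n₂) equal
the empirical AUC exactly); Spearman exact for n ≤ 10 without ties, t
approximation otherwise; paired comparisons report both the paired t and
the Wilcoxon signed-rank. The "repeated one-way ANOVA" of the source is
implemented as one-way ANOVA on annual rates across diagnostic groups; the
original factor structure is ambiguous and no alternative is asserted.
P-values are reported raw, without multiplicity correction, matching the
source analysis.

## The synthetic cohort: a stated world

No real data are redistributable, so the generator emulates the
*statistical structure the analysis assumes*; its defaults are fixed
before testing and are not tuned toward any outcome.

Per subject a latent severity $s$ is drawn from a group-specific Gaussian:
CTL mean 0, AD mean 1 (the effect profile is defined as the AD-vs-CTL
shift), MCI non-converters at 0.45 and converters at 0.8 of the way from
CTL to AD (converters are, by the stated ordering, the more AD-like
group), common SD 0.3. Each standardised feature is
$s \cdot e_j + \varepsilon_j$, where $e$ is the effect profile and the
residual $\varepsilon$ (total SD 0.9) splits into a shared global-atrophy
factor (30 % of residual variance), a within-lobe block factor (20 %) and
independent noise — so inter-regional correlation is present and the
hierarchical blocks are non-trivially coupled. With the default
hippocampal shift of −1.5 SD this yields an observable Cohen's d ≈ −1.5,
the separability regime of the published training set.

The default effect profile gives the ten medial-temporal regions the
largest magnitudes (1.0–1.5 SD; ventricular enlargement positive) and all
other regions small shifts (≤ 0.45 SD). Features map to natural scales via
fixed population means/SDs (thickness ~1.6–3.6 mm, volumes at plausible
FreeSurfer magnitudes, shipped as a versioned fixture); volumes are
multiplied by the subject's ICV (Gaussian, mean 1.5 × 10⁶ mm³, SD
1.5 × 10⁵) relative to the reference ICV, so ICV normalisation genuinely
removes head-size variance. Twelve-month features add a per-group severity
increment (AD +0.16, CTL +0.10, MCI-c +0.10, MCI-nc +0.06 — anchored to
published 12-month index shifts) times the effect profile, plus fresh
measurement noise (SD 0.15), on top of the *retained* baseline residual,
giving realistic within-subject correlation across timepoints. Within MCI,
APOE e4 carriers (group-specific carrier rates 27–59 %) receive a +0.3
severity shift. Follow-up retention is a random within-group subset with
fractions matching the published attrition (348 → 214). Cognitive scores
(MMSE, CDR sum-of-boxes, ADAS word-recall) are noisy affine functions of
current severity anchored to published group means.

**What a green test does and does not establish.** The generator's world is
linear-Gaussian with a single severity axis; green acceptance tests
establish that the pipeline recovers planted structure correctly under the
assumed model — they do not establish performance on real cohorts, which
add scanner/site effects (deliberately not modelled; an optional hook
would be the extension point), non-Gaussian pathology heterogeneity,
segmentation failures and diagnosis noise.

## Numerical choices and degenerate inputs

* Orthogonal extraction stops with an error if no orthogonal variation
  remains (weight norm < 1e−10); `n_ortho` must be below the rank of X.
* Constant features are rejected at scaler fit time by name; ICV must be
  positive and finite; duplicate subject × timepoint rows are errors.
* Scores/orthogonality are asserted at 1e−8, oracle equivalence at 1e−6,
  scaling round-trips at 1e−10 — comfortably above double-precision noise
  for these problem sizes and below any scientifically meaningful
  difference.
* Model JSON serialisation writes doubles at full precision; a restored
  model reproduces predictions to 1e−12.
* Single-value groups report SD 0 with an explicit degeneracy flag rather
  than NA, so downstream tabulation never silently drops a group.

## Known limitations

* The index model is linear; no kernelisation or covariate adjustment
  (age/education are deliberately not regressed out, matching the source
  design).
* Pattern labels at exactly 0.5 default to CTL-like by convention; with
  continuous indices this is a measure-zero event but matters for
  constructed examples.
* The variable-importance ranking is not the proprietary VIP statistic of
  commercial PLS software; rankings agree on strongly planted effects but
  need not match historical outputs cell-for-cell.
* Published real-data AUCs, medians and correlations are not reproduction
  targets: the underlying clinical dataset is not redistributable, and the
  binormal AUC engine used there differs from the empirical ROC used here.
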