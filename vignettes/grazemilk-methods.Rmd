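---
title: "Detecting grass-based feeding from milk composition: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting grass-based feeding from milk composition: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`grazemilk` classifies herd bulk-milk records as produced under a
grass-based diet (GRASS) or not (NOGRASS) when no grazing calendars
exist, using the calendar month of the milk test as an indirect label,
and then derives farm feeding typologies from the predicted class
probabilities. This vignette explains the models, the choices behind
the tunable parameters, what the synthetic-data generator does and does
not emulate, and the package's numerical conventions.

## Indirect labeling from the test month

The core assumption is regional: in a temperate maritime dairy region
nearly all herds graze from April to September, with full grazing from
May to August, so the test month predicts the feeding regime with
month-dependent reliability. Three nested schemes trade sample size
against label purity: scheme 1 labels May–August GRASS and
November–February NOGRASS; scheme 2 removes the more ambiguous May and
November; scheme 3 further removes June and December. Each scheme is
balanced (equal numbers of GRASS and NOGRASS months), all remaining
months are OTHERS and never enter training, and the month sets nest
(scheme 3 ⊂ scheme 2 ⊂ scheme 1). Labels are assigned from the calendar
month alone — no day-level logic and no inference from the traits
themselves.

GRASS is the positive class everywhere in the package, so sensitivity
always reads as GRASS recall. Whether "sensitivity" should instead
attach to NOGRASS is genuinely ambiguous in this field's reporting; we
fixed the GRASS convention and state it in every function's
documentation.

## The classifier

Discrimination uses partial least squares on the 0/1 class response —
the standard PLS-DA construction. Two design points deserve
explanation:

* **PLS1 on a single 0/1 column.** Two-class PLS-DA with two-column
  dummy coding is identical, up to an affine transform of the
  prediction, to PLS1 on one 0/1 column; we implement the latter. All
  rankings (components, VIP, ROC) are unaffected.
* **Autoscaling.** Predictors are mean-centered and scaled to unit
  variance before extraction. The 48 traits span units from mg/kg
  (minerals) to kg/day (milk yield); without scaling both the PLS
  subspace and the VIP scores would be dominated by the traits with the
  largest raw variance rather than the most informative ones.

Components are extracted by the NIPALS recursion; for a single response
the inner iteration collapses to a closed form (the weight vector is
the normalized predictor–response covariance), so no convergence
tolerance is ever active in practice. Extraction stops early if the
weight vector or the score norm falls below 1e-12 (for example after
rank exhaustion), and the effective component count is recorded.
Zero-variance predictors cannot be autoscaled and are dropped with a
warning before fitting. Collinear (even duplicated) predictors are
handled without error.

The number of latent variables is selected by maximizing mean held-out
AUC over a 10-fold cross-validation stratified on the two modalities,
with ties broken toward the smaller count and a hard cap at 30
components to limit overfitting. Each fold is fitted once at the
maximal count and all truncated models are read off that fit, so
selection costs k fits rather than k × 30.

### Class probabilities

PLS produces a continuous prediction, not a probability; the mapping to
[0, 1] is a free design choice because every strictly monotone map
leaves ROC/AUC — the selection criterion — unchanged. We use logistic
(Platt) calibration, `P(GRASS | s) = plogis(a0 + a1 s)`, with the two
coefficients fitted by logistic regression of the training labels on
*out-of-fold* scores from an internal 5-fold cross-validation. Fitting
the calibration on the training scores themselves is the naive
alternative and is markedly overconfident whenever the classes separate
well: the slope diverges and every probability collapses to 0 or 1,
which destroys exactly the graded, transition-tracking behaviour that
makes the probabilities useful for typology. Out-of-fold calibration is
the standard Platt procedure and keeps the probability scale honest.
Under complete separation even of the out-of-fold scores, the logistic
slope is capped at a finite value so probabilities stay strictly
monotone in the score. The NOGRASS probability is defined as the
complement, so the two modalities sum to one per record, and the 0.5
threshold reproduces the calibrated class decision.

### Variable importance

The raw VIP score of predictor j aggregates its squared normalized
weights over components, weighted by the response sum of squares each
component explains; by construction the mean squared raw VIP over the
retained predictors is exactly 1. Reduction thresholds in this field
are customarily quoted on a 0–100 scale, which is only consistent with
a max-normalized score, so the package also reports
`vip_scaled = 100 * raw / max(raw)` and `reduce_by_vip()` thresholds on
that scale (50 is the conventional cutoff). VIP uses all extracted
latent variables of the fitted model.

## Evaluation protocol

Model quality is reported the way this literature reports it: per-fold
AUC, sensitivity and specificity as mean ± SD over the 10 stratified
folds. AUC is computed by rank concordance (the Mann–Whitney
probability, ties counting one half), which equals the trapezoidal area
under the empirical ROC curve exactly and deterministically; the test
suite verifies it against brute-force pair enumeration and an
independent ROC implementation. Accuracy is the overall fraction
correct (not balanced accuracy).

External validation is deliberately month-restricted: only December and
January records (taken as NOGRASS truth) and July and August records
(GRASS truth) enter, identically for every scheme, so validation
accuracies are comparable across schemes even though their training
month sets differ. Splitting is by farm — 30% of farms calibrate, all
records of the remaining farms validate — so validation farms are
never seen in training.

Monthly probability curves average the per-record GRASS probability per
(year, month), including the transition months the models never saw;
the rise from spring to summer and fall toward winter on these months
is the key qualitative check that the classifier captures feeding, not
merely the month. Correlations with meteorology pool all year-month
cells (years are not averaged separately) and join on exact
(year, month) keys, dropping missing cells pairwise. The
temperature–humidity index is THI = 0.8·T + (H/100)·(T − 14.4) + 46.4
(T in °C, H in %).

## Farm typology

Farm × year vectors of 12 monthly mean probabilities (only farm-years
with all 12 months present; exclusions are counted and reported) are
clustered by Ward.D2 hierarchical agglomeration — Euclidean input
distances with the squared-distance Ward update through the
Lance–Williams recursion, i.e. the `"ward.D2"` convention where the
caller does not pre-square distances. The implementation delegates to
`stats::hclust`; the test suite verifies the resulting trees
merge-by-merge against a brute-force agglomeration that recomputes the
Ward criterion from cluster members at every step. Farm-years, not
farms, are the clustering unit: a farm can move between clusters across
years, which is informative in itself (year weather moves the
spring/autumn shoulders of the profile).

The cluster count K is a configuration parameter (the pipeline default
is 12, matching common practice of reading K off the dendrogram
heights; small simulated cohorts use smaller K). No automatic height-gap
selection is attempted. Cluster summaries average milk yield, fat,
protein, and SFA/MUFA/LCFA — the last three divided by the record's fat
content to give g/100 g of fat — unweighted over all records of the
farm-years in the cluster.

Clusters whose mean fat is below 1 g/100 g correspond to farms
submitting skimmed (processed) samples; their spectra describe a
modified milk matrix, so their predictions are uninterpretable for
feeding and the cluster is flagged and excluded from the intensity
mapping. The per-farm intensity index scores each year −1 if the
farm-year sits in an intensive-mapped cluster and +1 otherwise — the
intermediate group deliberately scores +1 together with extensive,
which is the convention this analysis tradition uses; because it is
surprising, the cluster-to-group map is fully configurable. A farm is
"always-intensive" only if every observed year is intensive, and
"always-extensive" only if every year is in the extensive group.
`assign_cluster_groups()` automates the mapping for simulated cohorts
by ranking clusters on their overall mean probability; with real data
the mapping should be read off the cluster curves.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
proprietary milk-recording data. It emulates:

* **Meteorology**: one monthly station series (temperature sinusoid
  peaking in July, mean 10 °C, amplitude 7.5 °C, noise SD 0.8 °C;
  humidity and cloud anti-phased; rain nearly aseasonal), with THI
  derived from the printed formula.
* **Grass fractions**: a latent per-farm-month fraction g ∈ [0, 1] of
  grass in the ration — zero December–February, logistic spring and
  autumn ramps (default width 1.5 months, midpoints at month 4.2 and
  9.8), a summer plateau at the farm's `grass_amplitude`, and a mild
  upward THI modulation of the plateau (+10% per 20 THI units)
  emulating grass growth responding to heat.
* **Traits**: each of the 48 traits is
  `baseline_mean · (1 + (multiplier − 1) g)` plus Gaussian noise. The
  multipliers encode the relative effects reported for pasture milk
  (C18:3 ×4, conjugated linoleic acid ×2, fat and protein ×1.05, milk
  yield ×0.62, long-chain FAs up ~25%, short/medium-chain FAs down
  15–20%, Ca up, P down). The noise SD of the 44 equation-predicted
  traits is the published root-mean-squared error of the corresponding
  FT-MIR prediction equation, so predictive difficulty is realistic;
  the four direct spectrometer traits have no published RMSE and use
  plausible herd-level residual SDs (fat 0.25, protein 0.12 g/100 g,
  urea 4 mg/dL, lactose 0.08 g/100 g). Baseline means are plausible
  values for Holstein-dominated Western-European bulk milk — the source
  data's herd means are not public, so these are documented defaults,
  not reference values. Fatty-acid traits share a common noise factor
  per record (correlation 0.3) because they derive from one spectrum.
  FA traits are generated in g/dL of milk; the g/100 g-of-fat scale is
  derived by dividing by the simulated fat content
  (`fa_per_100g_fat()`).
* **Farm archetypes**: intensive (plateau 0.30–0.45), intermediate
  (0.65–0.80), extensive (0.92–1.00, plus a winter ration richer in
  long-chain FAs), and skimmed farms whose submitted sample is
  processed milk — fat stripped to ≈0.25 g/100 g, fat-borne FA traits
  scaled down proportionally, and the sample composition decoupled from
  the herd's feeding season, so these records carry no grazing signal
  and produce the characteristic flat probability profile.
* **Reproducibility**: one root seed; every farm draws from a substream
  derived by stable hashing of its farm id, so enlarging a cohort never
  perturbs existing farms, and identical configurations give
  byte-identical tables.

What it does **not** emulate: raw FT-MIR spectra or the prediction
equations behind the 44 traits (traits are simulated directly);
within-herd cow-level variation; multiple test days per month (one
record per farm-month, a monthly bulk aggregate); herd size, breed,
lactation-stage or diet-composition effects beyond the single latent
grass fraction; spatial meteorology variation (one station serves all
farms). Consequently, passing tests show that the pipeline recovers the
structure this generator encodes — they do not certify performance on
real milk-recording data, where label noise (farms deviating from the
regional calendar), drift, and correlated non-feed effects will lower
every metric.

## Numerical conventions and degenerate inputs

* Early-stop tolerance 1e-12 on residual variance and weight norms;
  score orthogonality and the equivalence of the coefficient and
  score-route predictions hold to 1e-8 in the test suite.
* AUC ties count one half via midranks; single-class inputs are an
  error for AUC but allowed for confusion metrics (a constant
  classifier is a legitimate degenerate prediction).
* Stratified folds deal shuffled class members round-robin, so per-fold
  class counts differ by at most one; each class must have at least k
  members.
* Component-selection ties break toward the smaller count (first
  maximum).
* Ward merge ties (exactly equal heights) follow `stats::hclust`'s
  deterministic ordering; the brute-force oracle in the tests uses
  continuous random profiles, where ties have probability zero.
* Labeling a set with an empty GRASS or NOGRASS class, splitting fewer
  than two farms, cutting more clusters than profiles, and mapping
  clusters incompletely are all explicit errors with named messages.

## Problem sizes in the test suite

The end-to-end checks run on deliberately compact cohorts chosen to
keep the full suite fast while leaving the tested effects far above
their noise floors: the main study-condition run uses 200 farms × 3
years (7,200 records); the null-control runs use 56 farms × 3 years
(≥2,000 records) at three seeds; archetype-recovery uses 40 farms × 2
years with a 40/40/20 intensive/extensive/skimmed mix and K = 3; the
intensity-index cohort uses 400 farms × 3 years with 10% intensive
farms against an extensive majority and K = 2 — 400 farms keeps the
binomial noise of the drawn archetype mix well inside the ±3-point
recovery band. With intermediate farms present, per-year cluster
membership of borderline farms moves with the year's spring and autumn
weather (probabilities on shoulder months sit near the decision
boundary), so pure-group fractions are recovered cleanly only when the
contrasted archetypes are well separated; this mirrors the between-year
cluster movement expected of real farms and is why the two-archetype
design is used for that check.

## Known limitations

* The month-derived labels are wrong for any farm that deviates from
  the regional grazing calendar; the models can only be as good as this
  indirect truth, and external accuracy is measured only on the four
  least ambiguous months.
* Probabilities saturate when the simulated effects are strong;
  amplitude differences between heavy-grazing archetypes then survive
  mainly in the spring/autumn shoulder months, which are also the most
  weather-sensitive. Real data, with weaker separation, occupies the
  informative mid-range more.
* The VIP-threshold comparison (full vs reduced predictor set) is
  resolvable only when the AUC is not saturated; at near-perfect
  separation the difference sits below fold-level measurement
  resolution.
* `intensity_index()` categories depend on the cluster-to-group map;
  with real data that map is an interpretive step, not an algorithmic
  one.
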