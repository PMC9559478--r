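# grazemilk

Tools for detecting grass-based dairy feeding from routine bulk-milk
composition records, and for deriving farm feeding typologies from the
resulting class probabilities.

## The problem

Many dairy labels (pasture-milk schemes, protected designations of
origin) require a minimum number of grazing days, but grazing calendars
are rarely recorded, so there is no factual verification. In temperate
maritime regions nearly all herds graze from roughly April to September,
with full grazing from May to August. The calendar month of a routine
milk test therefore carries *indirect* information about the feeding
regime, and grazing leaves a strong compositional fingerprint in milk:
C18:3 (alpha-linolenic acid) rises about fourfold, conjugated linoleic
acid about twofold, fat and protein by about 5%, long-chain fatty acids
rise while short- and medium-chain fatty acids fall, milk yield drops,
and mineral contents shift.

`grazemilk` is aimed at milk-recording organisations and chemometrics
researchers who have herd bulk-milk tables of mid-infrared-predicted
composition traits (48 traits: fat, protein, urea, lactose, milk yield,
31 fatty acids, lactoferrin, 6 protein fractions, 5 minerals) and want
to (1) classify records as GRASS vs NOGRASS, (2) interpret which traits
drive the discrimination, and (3) type farms by feeding intensity. A
seeded synthetic-data generator emulates such tables, so the entire
pipeline is developed and tested without any proprietary data.

## The method

**Indirect labels.** Three nested month-derived schemes define the
training modalities (all other months are OTHERS and are excluded from
training):

| scheme | GRASS months | NOGRASS months |
|--------|--------------|----------------|
| 1      | May–Aug      | Nov–Feb        |
| 2      | Jun–Aug      | Dec–Feb        |
| 3      | Jul–Aug      | Jan–Feb        |

**Classifier.** Two-class PLS discriminant analysis: NIPALS partial
least squares of the 0/1 class response *y* on the autoscaled predictor
matrix *X* (n × p). Components are extracted sequentially,

> w_a ∝ X'_{a-1} y_{a-1},  t_a = X_{a-1} w_a,  followed by deflation,

the number of latent variables A is chosen by 10-fold stratified
cross-validated AUC and capped at 30, and regression coefficients are
b = W (P'W)⁻¹ q. Class probabilities come from a logistic (Platt)
calibration of the continuous PLS prediction, fitted on out-of-fold
scores. Variable importance uses the VIP score,

> VIP_j = sqrt( p · Σ_a SS_a (w_ja / ‖w_a‖)² / Σ_a SS_a ),

rescaled to 0–100 (100 = most important predictor) for thresholding.

**Validation.** Farm-level splitting (30% of farms calibrate, the rest
validate), fold-wise AUC / sensitivity / specificity, and an external
accuracy computed only on December/January (NOGRASS truth) and
July/August (GRASS truth) records, identically for every scheme.

**Meteorology.** Monthly mean GRASS probabilities are correlated with
temperature, humidity, cloud, rain and the temperature–humidity index
THI = 0.8·T + (H/100)·(T − 14.4) + 46.4.

**Typology.** Farm × year profiles of 12 monthly mean GRASS
probabilities (full-coverage farm-years only) are clustered with
Ward.D2 hierarchical clustering; clusters are summarized (milk yield,
fat, protein, SFA/MUFA/LCFA in g/100 g fat), skimmed-milk clusters
(mean fat < 1 g/100 g) are flagged as uninterpretable, and a per-farm
intensity index (−1 per intensive year, +1 otherwise) classifies farms
as always-intensive, always-extensive, or intermediate.

## Worked example

```r
library(grazemilk)
cfg <- pipeline_config(n_farms = 60, n_years = 2, seed = 2024, K = 4)
report <- run_pipeline(cfg)
#> simulate: 60 farms x 2 years -> 1440 records
#> split: 18 calibration farms (432 records), 42 validation farms (1008 records)
#> label scheme 1: 288 of 432 calibration records retained
#> scheme 1: A = 1, CV AUC = 0.997, external accuracy = 0.976 (n = 336)
#> ...
#> meteo: r(THI) = 0.97, r(cloud) = -0.90
#> typology: 120 farm-year profiles (0 excluded for coverage)

report$models$GRASS1$cv
#> Stratified 10-fold cross-validation, 1 latent variable(s)
#>   auc          99.67 +/- 1.05 %
#>   sensitivity  99.33 +/- 2.11 %
#>   specificity  99.33 +/- 2.11 %

round(report$meteo_correlation, 2)
#> temperature    humidity       cloud        rain         thi
#>        0.96       -0.95       -0.90       -0.41        0.97

head(report$models$GRASS1$vip[order(-report$models$GRASS1$vip$vip_scaled), ], 3)
#>                 predictor      vip vip_scaled
#> 24 c18_3_cis9_cis12_cis15 1.806617  100.00000
#> 33                 omega3 1.673460   92.62946
#> 28                    ufa 1.584634   87.71276
```

Reading the output: the month-labeled classifier separates GRASS from
NOGRASS almost perfectly on this synthetic cohort (cross-validated AUC
99.7%), external accuracy on the unambiguous four-month window is
97.6%, the monthly probability curve tracks the heat index (r = 0.97)
and opposes cloud cover, and the most informative predictors are the
pasture-sensitive fatty acids (C18:3, omega-3, unsaturated FAs), as
expected from the grazing fingerprint.

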