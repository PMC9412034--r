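# ecgsoo

Predicting the ventricular chamber of origin of outflow-tract ventricular
arrhythmias (OTVAs) from single 12-lead QRS complexes.

## The problem

Idiopathic ventricular arrhythmias most often arise in the outflow tracts,
and the first question before a catheter ablation is whether the ectopic
focus sits in the left (LVOT) or right (RVOT) outflow tract — the approach,
risk and procedure time differ substantially between the two. The QRS
morphology of the ectopic beat carries that information (most prominently
the precordial transition: the first chest lead V1–V6 where the dominant
QRS polarity flips), but manual rule-based ECG algorithms are laborious and
generalize poorly. Large labelled clinical OTVA databases do not exist, so
supervised classifiers are best trained on *simulated* beat populations and
validated against smaller clinical cohorts.

`ecgsoo` packages that whole workflow for R users who want a controllable,
fully offline test bed:

* a **synthetic beat generator** producing a factorial database of
  noise-free 12-lead QRS complexes — anatomies × sites of origin (SOO) ×
  electrode placements, with the default design 16 × 12 × 13 = 2,496
  beats (7 LVOT + 5 RVOT sites per anatomy) — plus noisy, imbalanced
  "clinical-like" test sets;
* **preprocessing**: wavelet-threshold QRS delineation, max-abs
  normalization, R-peak alignment, and bin-mean downsampling to the
  10-sample-per-lead "raw10" representation;
* a **feature battery** (381 named features) over the raw signal, its
  undecimated quadratic-spline wavelet transform (with Q/R/S fiducials
  from multiscale zero crossings), and Welch power spectra;
* **mixup augmentation** with an anatomical neighbor constraint,
  `x̂ = λ·xᵢ + (1 − λ)·xⱼ`, `λ ~ Beta(5, 1.5)`, label from the dominant
  parent (`yᵢ` iff `λ > 0.5`), `λ` kept as the sample weight;
* **classification**: RBF support vector machines (with exact per-sample
  weighting), stratified 5-fold cross-validation, balanced accuracy
  (mean of per-class recalls) for imbalanced test sets, exhaustive
  lead-subset search over all 2¹² − 1 = 4,095 lead combinations,
  extra-trees feature ranking, and PCA variance analysis;
* three evaluation **scenarios**: train on simulated data only (sc1,
  optionally with augmentation), on clinical-like data only (sc2), or on
  the hybrid concatenation (sc3).

## Worked example

Train on a reduced simulated database and evaluate on a noisy,
RVOT-dominant clinical-like cohort:

```r
library(ecgsoo)

cfg <- generatorConfig(nAnatomies = 4, nElectrodeConfigs = 3, seed = 1)
db  <- generateDatabase(cfg)             # 4 x 12 x 3 = 144 beats

clin <- generateClinicalLike(100, lvotFraction = 77/334,
  config = generatorConfig(nAnatomies = 4, nElectrodeConfigs = 3,
                           seed = 2, noiseSd = 0.3))

res <- runScenario("sc1", "raw10", simulated = db,
                   tests = list(clinical = clin), seed = 1)
res
#> ScenarioResult SC1 [raw10]: CV accuracy 1.000 (n = 144)
#>   test 'clinical': balanced accuracy 0.940
res@testResults$clinical$confusion
#>       pred
#> true   LVOT RVOT
#>   LVOT   26    1
#>   RVOT    6   67
```

The CV accuracy of 1.000 is the in-domain (simulated) 5-fold accuracy; the
balanced accuracy of 0.940 is the mean of the LVOT recall (26/27) and the
RVOT recall (67/73) on the held-out noisy cohort — the imbalance-robust
metric, since 73 of the 100 test beats are RVOT. Feature ranking on the
same data puts transition-zone leads on top, as an electrophysiologist
would expect:

```r
fm <- extractFeatureMatrix(db)
head(rankFeaturesExtraTrees(fm$x, fm$chamber, seed = 1), 3)
#>               feature importance        sd
#> 1 wavelet.xcorr.V3_V5 0.04571429 0.2039398
#> 2  signal.polarity.V2 0.04000000 0.1969464
#> 3  signal.xcorr.V2_V5 0.03363636 0.1746307
```

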