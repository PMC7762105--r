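# qdelta

Voxel-based quantification of imaging subtypes of pancreatic ductal
adenocarcinoma (PDAC) on multiphase CT, and the statistics that relate the
subtype to outcome.

PDAC tumors differ in how conspicuous their border is against the normal
pancreas on contrast CT: tumors with a conspicuous border ("high delta")
behave more aggressively than near-iso-enhancing, inconspicuous ("low
delta") tumors. Radiologist scoring of this subtype is subjective in
borderline cases. `qdelta` implements a quantitative replacement: a
voxel-counting enhancement statistic, a logistic classifier built on it,
and the agreement and outcome analyses needed to validate such a
classifier. Everything runs on seeded synthetic phantoms and cohorts, so
the full pipeline is testable without patient data. The intended audience
is quantitative-imaging researchers and biostatisticians working with
multiphase CT biomarkers.

## The quantities

**Normalized enhancement (NE).** For a co-registered pancreatic-protocol
study (pre-contrast NC, arterial AR, portovenous PV) the enhancement map of
a phase is the voxelwise subtraction `phase − NC`. Given a reference region
of interest (~1 cm³ of normal pancreatic parenchyma, NPP, or anterior
abdominal fat, AAF) with mean enhancement μ and sample SD σ,

    NE = 100 × #{ tumor voxels with enhancement > μ + 1·σ } / #tumor voxels

i.e. the percentage of tumor voxels enhancing more than one SD above the
reference mean (the qEASL construction). Four features per study: AR-NPP,
PV-NPP, AR-AAF, PV-AAF.

**nAUC.** The tumor-to-parenchyma ratio of time-weighted mean enhancement,

    nAUC = [5·ΔmAR + 35·(ΔmAR + ΔmPV)] / [5·ΔpAR + 35·(ΔpAR + ΔpPV)]

with Δm and Δp the NC-subtracted mean HU of tumor and parenchyma per phase;
a transport summary that equals 1 when the tumor enhances like parenchyma.

**q-delta classifier.** Univariate logistic screens of the four NE
features, backward elimination at α = 0.05, a multivariate logistic fit on
the retained features, and ROC evaluation (rank-based AUC, DeLong 95% CI,
Youden or fixed operating point).

**Agreement and outcomes.** Dice similarity for repeated contours;
single-measure absolute-agreement ICC(A,1) with McGraw–Wong F intervals for
repeated NE measurements; Kaplan–Meier/log-rank, Cox proportional hazards
(Efron ties), Fisher exact + likelihood-ratio tests with relative risk on
one-year survival, Spearman correlation, and Welch t-tests.

## Worked example

```r
library(qdelta)

# a conspicuous (high-delta) phantom: hypo-enhancing tumor in parenchyma
ph <- simulate_phantom(phantom_params(class_label = "high", seed = 1))
compute_ne_features(ph$study, ph$masks)
#> Normalized enhancement (% tumor voxels above reference mean + 1 SD)
#>   AR-NPP:   0.1   PV-NPP:   0.5
#>   AR-AAF:  80.0   PV-AAF:  72.1
compute_nauc(sample_hu(ph$study, ph$masks))
#> [1] 0.409

# an inconspicuous (low-delta) phantom enhances nearly like parenchyma
ph_low <- simulate_phantom(phantom_params(class_label = "low", seed = 1))
compute_ne_features(ph_low$study, ph_low$masks)
#> Normalized enhancement (% tumor voxels above reference mean + 1 SD)
#>   AR-NPP:  14.5   PV-NPP:  15.2
#>   AR-AAF:  99.6   PV-AAF:  99.0
compute_nauc(sample_hu(ph_low$study, ph_low$masks))
#> [1] 0.921

# a second rater's contour and its overlap
rater_b <- perturb_contour(ph$masks$tumor, magnitude_mm = 1.5, seed = 2)
dice(ph$masks$tumor, rater_b)
#> [1] 0.93
```

The high-delta tumor barely exceeds the parenchyma reference band
(NE(AR-NPP) ≈ 0%) and transports far less contrast than normal pancreas
(nAUC 0.41), while the low-delta tumor sits near the parenchyma band
(higher NE, nAUC 0.92) — the separation the classifier exploits. Both
phantoms stand well above the non-enhancing fat reference.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/05_outcomes.R` run the study end to
end on synthetic data, writing tables under `results/`: cohort and phantom
generation; image-domain NE/nAUC quantification (via NIfTI round-trip);
classifier training with backward elimination and holdout ROC; the
30-case Dice/ICC agreement study; and the survival/stroma association
battery. Each script states what it found on stderr and is a thin driver
over the package functions.

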