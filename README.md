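# ecglvh

Left ventricular hypertrophy (LVH) — pathological thickening of the
left-ventricular myocardium — is a strong, modifiable risk factor for
cardiovascular events, yet the most accessible screening tool, the
resting ECG, detects it poorly with classical voltage criteria
(sensitivities around 0.1). Cardiac magnetic resonance (CMR) measures
left-ventricular mass accurately but cannot screen populations.

`ecglvh` is an R package for researchers in cardiovascular machine
learning and biomedical signal analysis. It implements, end to end, a
deep-learning pipeline that predicts CMR-derived **indexed LV mass**
(iLVM, g/m²) from eight-lead median-beat ECGs plus routine clinical
covariates, and converts the predictions into LVH decisions:

* **Median-beat extraction** — zero-phase 1–45 Hz Butterworth
  filtering, R-peak detection on the leads' first principal component,
  ±50 ms cross-correlation beat alignment with rejection of beats
  correlating < 0.8 with the running template, and pointwise averaging;
  the mean R-R interval supplies the ventricular rate.
* **Clinical-variable derivation** — Mosteller body surface area
  (`sqrt(height_cm x weight_kg / 3600)`), sex-specific LVH labels
  (iLVM > 70 g/m² male / > 55 g/m² female), medication adjustments
  (+15/+10 mmHg BP; cholesterol ÷ 0.73 and ÷ 0.66), condition flags
  (BP > 130/85, HbA1c ≥ 48 mmol/mol, cholesterol ≥ 5 mmol/L).
* **A fully convolutional network** — three conv blocks
  (128×8, 256×5, 128×3) with batch norm and max pooling, dropout
  0.4/0.6, global average pooling, metadata concatenation and two fully
  connected layers (~290k parameters), trained with Adam (5e-4, batch
  64) under a log-cosh loss with learning-rate reduction (×0.1 after 10
  stalled epochs) and early stopping (20 epochs); plus staged
  fine-tuning (heads at 5e-5/1e-4 weight decay, then conv blocks
  deepest-first) with morphology-preserving augmentation for transfer to
  a shifted cohort.
* **Logistic recalibration** — LVH regressed on (predicted iLVM, sex)
  with class-balanced weights, yielding adaptive sex-specific iLVM
  cut-offs `-(b0 + b_sex*sex)/b_ilvm` that correct the systematic
  underestimation a skewed target induces.
* **Benchmarks and statistics** — Sokolow–Lyon (S_V1 + max(R_V5, R_V6)
  ≥ 3.5 mV) and Cornell voltage (R_aVL + S_V3 > 2.8/2.0 mV) criteria;
  empirical AUROC with Hanley–McNeil analytic intervals, fast midrank
  DeLong tests, Youden-J operating points, Wilson intervals,
  bootstrapped MAE/ME, Bland–Altman agreement; integrated-gradients
  attribution with baseline averaging.
* **A synthetic-cohort generator** — seeded, sex-specific log-normal
  iLVM calibrated to a target LVH prevalence, Gaussian-wave ECG
  morphology whose QRS amplitude/width encode iLVM, stratum-shifted
  covariates, noise/wander/corrupted beats, and an "external" preset
  with shifted demographics — so the whole pipeline runs and is tested
  without access-restricted cohort data.

## Worked example

```r
library(ecglvh)

cfg <- synthetic_cohort_config(n_participants = 160,
                               lvh_prevalence_target = 0.15, seed = 77)
res <- run_lvh_pipeline(cfg, seed = 5, max_epochs = 8, n_boot = 100)
res
```

```
LVH pipeline result (ukb, n = 160, seed 5, hash 7c44fd4a)
  training: 8 epochs (stop: max_epochs)
  recalibrated cut-offs: male 42.8, female 42.6 g/m^2
Evaluation on n = 24 (2 LVH):
  AUROC 1.000 (1.000, 1.000)
  Youden point: sens 1.000 (0.342, 1.000), spec 1.000 (0.851, 1.000), F1 1.000
  MAE 12.75 (7.13, 20.58) g/m^2, ME -5.36 (-16.21, 1.69), r 0.969, adj R^2 0.937
  DeLong vs predicted_ilvm_direct: z 0.00, p 1
```

Reading the output: the pipeline simulated 160 participants, extracted
their median beats, trained the network for eight epochs on the 70%
split, and recalibrated the iLVM predictions. After so few epochs the
predictions *rank* the 24 held-out participants almost perfectly
(r = 0.97, and the recalibrated probabilities separate the two true LVH
cases, AUROC 1.0 — n is tiny, so the analytic interval collapses at the
degenerate value) while their *scale* is still compressed: MAE is
12.8 g/m² with systematic underestimation (ME −5.4). That compression is
exactly what the recalibration step absorbs — the implied decision
cut-offs (42.8/42.6 g/m²) sit well below the published 70/55 g/m²
thresholds. With the default cohort (n = 2000, 1.5% prevalence, 30
epochs) held-out correlation reaches ~0.99 and MAE ~1.6 g/m²; see
`vignettes/ecglvh-methods.Rmd` for what the synthetic cohort does and
does not demonstrate.

Individual stages are plain functions:

```r
ecg  <- make_raw_ecg(make_median_template(60, "male", 60, cfg), 60, cfg, seed = 1)
beat <- extract_median_beat(ecg)
beat
#> Median beat synthetic: 600 x 8 @ 500 Hz, rate 59.9 bpm (13/13 beats retained)
sokolow_lyon(measure_wave_amplitudes(beat))
#> $index_mv
#> [1] 2.365921
#> $positive
#> [1] FALSE
```

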