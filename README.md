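# asindex — activation synchrony index for neonatal EEG

`asindex` quantifies **interhemispheric synchrony (IHS)** in discontinuous
neonatal EEG. During quiet sleep near term age, healthy newborn EEG
alternates high-amplitude bursts with low-amplitude inter-burst intervals
(tracé alternant), and bursts normally start nearly simultaneously over
both hemispheres. Loss of that temporal co-incidence is a classical visual
marker of abnormal brain function. This package replaces the visual
impression with the **activation synchrony index (ASI)** and everything
needed to evaluate it: windowed epoch schemes with a test–retest stability
criterion, a thresholded classifier of EEG normality with ROC analysis, a
synthetic discontinuous-EEG generator with a plantable synchrony defect,
and EDF/EDF+ input/output. It is aimed at clinical neurophysiology
researchers working on quantitative EEG biomarkers for the neonatal brain.

## The index

For a homotopic pair of bipolar derivations (default C3→O1 vs C4→O2),
each analysis window passes through four stages: zero-phase band-pass
(0.5–20 Hz) with pre-emphasis; amplitude envelope (rectify, 1-s moving
average, decimate to 16 Hz); equal-occupancy quantization into Q = 8
levels; and the lagged mutual-information ratio

    ASI = mean{ I(τ) : |τ| ≤ 0.5 s } / mean{ I(τ) : 5 s ≤ |τ| ≤ 30 s },

where I(τ) is the plug-in mutual information (bits) of the joint Q×Q
histogram of the two quantized envelopes at relative lag τ. Co-incident
bursting concentrates dependency at zero lag (ASI ≫ 1); asynchronous
bursting leaves both lag sets at chance level (ASI ≈ 1). Rank-based
quantization makes the index exactly invariant to channel gain and any
monotone envelope rescaling.

Stability of a windowing scheme over a cohort is scored by the mean
squared difference between each subject's two epoch-level estimates,
`MSD = (1/n) Σᵢ (ASI₁ᵢ − ASI₂ᵢ)²`; classification uses the per-subject
minimum of the two epoch means, `ASI_class = min(ASI₁, ASI₂)`, predicting
*abnormal* at or below a threshold (default 3.6), with staircase ROC/AUC
(equal to the normalized Mann–Whitney U) and Youden operating point.

## Worked example

```r
library(asindex)

# simulate 3 normal (0.2-s burst-onset jitter) + 3 abnormal (8-s jitter)
spec <- cohort_spec(n_normal = 3, n_abnormal = 3, seed = 1)
cfg  <- pipeline_config(pairs   = default_pairs()[c("C3O1-C4O2", "Fp1C3-Fp2C4")],
                        schemes = default_schemes()[c("2.5min_x4", "10min_x1")])
res <- run_pipeline(cfg, spec, out_dir = "asi_out")
res$grid$grid
#>             2.5min_x4  10min_x1
#> C3O1-C4O2   0.3814950 13.909664
#> Fp1C3-Fp2C4 0.1319264  9.918664
res$scores
#>   subject_id asi_class    group      pma
#> 1        S01 8.9681930   normal 40.12214
#> 2        S02 8.2430662   normal 38.30462
#> 3        S03 8.8806136   normal 40.61905
#> 4        S04 1.0385530 abnormal 38.98620
#> 5        S05 0.9117784 abnormal 40.30571
#> 6        S06 1.1206662 abnormal 41.95144
```

Reading the output: averaging four 2.5-min windows is far more repeatable
than one 10-min window (MSD 0.13–0.38 versus ~10–14 — longer single
windows score larger, more variable indices), and the planted groups
separate cleanly: tightly synchronized records score ASI ≈ 8–9, jittered
ones ≈ 1, so the 3.6 threshold classifies all six correctly. The written
`report.txt` summarizes the same run:

```
asindex pipeline report (config 6ad1fe25c679341d75ab442e4428f4f3)
subjects: 6
most stable cell: pair Fp1C3-Fp2C4, scheme 2.5min_x4 (MSD = 0.132)
classification at ASI <= 3.60: accuracy 100.00% (6/6), sens 1.00, spec 1.00
ROC AUC: 1.000
group difference (Welch t): t = 32.45, p = 0.000433
```

`run_pipeline()` also accepts a vector of EDF paths (with optional
ground-truth JSON sidecars) instead of a `cohort_spec`, and
`write_cohort_edf()` exports simulated cohorts to EDF+C for use by other
tools. See the vignette (`vignettes/activation-synchrony-index.Rmd`) for
the model, parameter defaults and design rationale.

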