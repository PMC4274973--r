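---
title: "Quantifying interhemispheric synchrony in neonatal EEG with the activation synchrony index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interhemispheric synchrony in neonatal EEG with the activation synchrony index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asindex)
```

## The problem

Near term age, a healthy neonate's quiet-sleep EEG is *discontinuous*:
high-amplitude bursts of activity lasting a few seconds alternate with
low-amplitude inter-burst intervals (tracé alternant / tracé discontinu).
A hallmark of normal brain function in this state is **interhemispheric
synchrony (IHS)** — bursts tend to start at nearly the same time over both
hemispheres. Clinicians grade IHS by eye, which requires expertise and has
no quantitative definition. The **activation synchrony index (ASI)**
replaces the visual impression with a statistic: it measures how much of
the statistical dependency between the two hemispheres' amplitude
envelopes is concentrated at (near-)zero lag, relative to the dependency
that chance coincidence of pseudoperiodic bursting produces at long lags.

## The index

For one homotopic pair of bipolar derivations (by default the
centro-occipital pair C3→O1 versus C4→O2), one analysis window is
processed in four stages:

1. **Preprocessing** (`preprocess_eeg()`): zero-phase Butterworth
   band-pass (default 0.5–20 Hz, order 4, applied forward–backward with
   mean removal and odd-reflection padding so no edge transients leak into
   the envelope), followed by a first-difference pre-emphasis
   $y_t = x_t - \alpha x_{t-1}$ with $\alpha = 0.95$ that up-weights the
   higher frequencies carrying burst texture.
2. **Amplitude envelope** (`amplitude_envelope()`): rectification, a 1.0-s
   centered moving average, and decimation to a 16-Hz frame rate. The
   moving average is simultaneously the anti-alias filter; burst dynamics
   live at ≲1 Hz, far below the frame rate.
3. **Equal-occupancy quantization** (`quantize_envelope()`): rank-based
   quantile binning of each window's envelope into $Q = 8$ levels. Because
   only ranks enter, the index is *exactly* invariant to channel gain and
   to any strictly monotone rescaling of the envelope, and every level is
   occupied equally (to one sample), maximizing marginal entropy.
4. **Lagged dependency ratio** (`lag_dependency_profile()`,
   `compute_asi()`): with quantized envelopes $a_t$, $b_t$, the plug-in
   mutual information (in bits) of the joint $Q \times Q$ histogram of
   $(a_t, b_{t+\tau})$ is evaluated over a lag grid, and

   $$\mathrm{ASI} \;=\;
     \frac{\operatorname{mean}\{I(\tau) : |\tau| \le 0.5\ \mathrm{s}\}}
          {\operatorname{mean}\{I(\tau) : 5\ \mathrm{s} \le |\tau| \le 30\ \mathrm{s}\}}.$$

   Co-incident bursting concentrates dependency at zero lag, so the
   numerator far exceeds the baseline and ASI ≫ 1; bursting with
   independent or strongly jittered timing leaves both sets at the chance
   level and ASI ≈ 1. A small floor (10⁻⁴ bits) on the baseline mean keeps
   the ratio finite; results flag when it engages.

### Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `band` | 0.5–20 | Hz | analysis band; covers neonatal burst energy |
| `preemphasis` | 0.95 | – | high-frequency weighting; 0 disables |
| `frame_rate` | 16 | Hz | envelope sampling rate |
| `smooth_sec` | 1.0 | s | envelope moving-average length |
| `n_levels` (Q) | 8 | – | quantization levels |
| `numerator_max_lag` | 0.5 | s | half-width of the near-zero lag set |
| `baseline_lag_range` | 5–30 | s | chance-coincidence lag band |
| `baseline_lag_step` | 0.25 | s | baseline lag grid spacing |
| `min_window_sec` | 150 | s | shortest admissible window |

All of these sit in `asi_config()` and can be replaced wholesale, so other
parameterizations of the index (e.g. the original Matlab settings, which
are not printed in the open literature) can be dropped in. The numerator
lag set lives on the full frame grid; the baseline is sampled every
0.25 s, which is dense relative to the ≥1-s timescale on which the
baseline dependency varies and four times cheaper than the frame grid.
The two lag sets are symmetric about zero, which makes
`compute_asi(a, b)` exactly equal to `compute_asi(b, a)`.

The 150-s minimum window reflects that ASI is a statistical estimate of
the dependency of intermittent, pseudoperiodic activity: below roughly
two minutes the mutual-information estimates destabilize. The plug-in MI
estimator carries the usual positive bias of roughly
$(Q-1)^2 / (2N \ln 2)$ bits at sample size $N$; because the bias afflicts
numerator and baseline lags almost equally, it largely cancels in the
ratio, which is why independent envelopes score close to 1 rather than
close to 0/0.

## Windowed schemes and test–retest stability

Clinical recordings yield two 10-min quiet-sleep epochs per subject
(annotation tags `QS1`, `QS2`). A `window_scheme()` subdivides each epoch
into 1×10 min, 2×5 min, 4×2.5 min, 2×2.5 min or 1×5 min windows whose
per-window ASI values are averaged (`windowed_asi_mean()`). Test–retest
stability of a scheme over a cohort is the **mean squared difference**

$$\mathrm{MSD} = \frac{1}{n}\sum_{i=1}^{n}
  \left(\mathrm{ASI}_{1,i} - \mathrm{ASI}_{2,i}\right)^2,$$

the average squared disagreement between a subject's two epoch-level
estimates; `optimization_grid()` tabulates it over all derivation pairs ×
schemes and reports the most stable cell. Windows containing annotated
artifacts or non-finite samples are rejected outright (no interpolation —
the reference condition is manually selected clean epochs); `"strict"`
mode (the default) fails the epoch, `"tolerant"` mode averages surviving
windows and reports the count.

`epoch_sources_compare()` contrasts MSD when the two epochs are
subsequent (same sleep period) versus separated (different periods), with
a two-sided Mann–Whitney U test on the per-subject squared differences.
Because tied squared differences are common and `stats::wilcox.test`
cannot give exact p-values under ties, the package enumerates the exact
permutation distribution of U whenever $\binom{n_1+n_2}{n_1} \le 20000$
and otherwise uses the normal approximation with tie correction.

## Classification

Per subject, the classification statistic is the **minimum of the two
epoch means** (`asi_class()`) — the lowest synchrony level the subject
exhibited. Classification predicts *abnormal* when this statistic falls
at or below the threshold (default 3.6, the clinically proposed operating
point, retained as-is and never silently re-fitted; ties at the threshold
are called abnormal, the conservative choice for screening).
`asi_roc()` builds the staircase ROC over all score cut points — its
trapezoid AUC equals the pair-counting Mann–Whitney statistic
$U/(n_1 n_2)$ with half-credit for ties, an identity the test suite
asserts — and `youden_threshold()` reports the operating point maximizing
sensitivity + specificity − 1. `data_budget_study()` evaluates ROC/AUC
across total-EEG budgets (5/10/20 min), window lengths and
epoch-combination rules (mean/min/max); budgets of ≤10 min use the first
epoch only, so the combine rule only matters at 20 min.
`group_difference_test()` is a two-sided Welch t-test (no
variance-equality assumption is defensible here), and `pma_regression()`
checks that the statistic needs no postmenstrual-age correction near term
by OLS of score on PMA with a slope CI.

## The synthetic generator

Clinical neonatal EEG is not publicly shareable, so the package ships a
generator that plants a known degree of interhemispheric synchrony:

- `burst_model()`: bursts arrive as an alternating renewal process —
  exponential inter-burst gaps alternating with truncated-normal burst
  durations, so bursts never overlap and the long-run burst-state
  fraction is `burst_rate × burst_duration_mean / 60`. Defaults (6
  bursts/min, 5 ± 1 s long, inter-burst amplitude 15% of burst amplitude,
  0.5–10 Hz carrier, ~200 µV peak-to-peak bursts, 256 Hz sampling) give a
  roughly 50% duty cycle matching tracé alternant morphology; the
  literature prints no quantitative burst statistics for this population,
  so these are stipulated once here, not fitted.
- `synchrony_plant()`: the right hemisphere reuses the left burst train
  shifted by a fixed onset lag plus per-burst Gaussian jitter, with
  bursts dropped at a miss probability. Jitter (or missing) is the
  synchronous→asynchronous dial: 0.2 s mimics a healthy recording, 8 s
  destroys temporal co-incidence while leaving every marginal property of
  each channel unchanged.
- Each channel carries an independent band-limited Gaussian carrier
  (synthesized spectrally) multiplied by its hemisphere's gate, with
  0.5-s raised-cosine burst edges so the envelope is not dominated by
  switching transients. Homotopic bipolar derivations therefore keep the
  burst structure while no two channels are copies of each other.
- `cohort_spec()`/`generate_cohort()` assemble cohorts (default 14 normal
  + 17 abnormal, PMA uniform in 36–42 weeks, 1200-s records with two
  annotated 10-min quiet-sleep epochs). PMA is assigned but does not
  influence the signal by default; an optional `pma_effect` hook can
  inject an age→jitter trend for power studies. All generators are pure
  functions of their seeds.

What the generator does *not* emulate: sleep-state cycling, age-specific
graphoelements (delta brushes, encoches frontales), realistic artifact
taxonomies (only a single high-amplitude transient injector is provided),
spatially varying synchrony, or non-stationary brain-state drift. Passing
the planted-label recovery tests therefore shows that the chain detects
burst-timing asynchrony under this signal model — it does not certify
clinical performance. Classification figures reported for this index on
clinical material derive from private recordings and are not quantities
this package can reproduce.

## Numerical and design choices

- **Degenerate inputs.** Constant (flat) envelopes cannot be quantized
  and raise a degenerate-signal error; all-NaN or annotated-artifact
  windows are rejected, not patched; lags with fewer than 100 overlapping
  frames are dropped with a warning, and an all-dropped profile is an
  error.
- **Ties.** Rank ties are broken by position (`ties.method = "first"`),
  which preserves exact invariance under strictly monotone transforms;
  tied classification scores form a single ROC step (half-credit in the
  AUC); scores exactly at the threshold classify abnormal.
- **Windows** are half-open `[start, end)` seconds from record start,
  matching the annotation convention, and scheme windows are contiguous
  from the epoch start.
- **EDF.** Files are written as EDF+C with one-second records, 16-bit
  samples over a symmetric integer physical range (so the write and read
  mappings coincide exactly), and TAL-encoded annotations; labels
  normalize case- and prefix-insensitively to canonical 10–20 names, and
  unknown labels pass through untouched, failing only when a derivation
  needs them. No R EDF reader was available to build on, so the package
  carries its own minimal implementation.
- **Problem sizes.** The test suite exercises 10 synthetic cohorts (31
  subjects each) for the end-to-end recovery, stability-ordering and
  data-budget properties, and 20 cohorts for the age-null coverage check;
  the acceptance script analyzes 5 cohorts plus a full 5×5
  pair-by-scheme stability grid on the first. These sizes give stable
  averages for the qualitative orderings being asserted.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_normal = 4, n_abnormal = 4, seed = 1)
res <- run_pipeline(pipeline_config(), spec, out_dir = tempfile("asi"))
res$grid$argmin
res$scores
res$roc$auc
```

The pipeline writes per-subject summaries, the MSD grid, ROC points,
predictions, metrics JSON, the resolved configuration and a plain-text
report, each stamped with the configuration hash; re-running into the
same directory with a changed configuration refuses to overwrite unless
asked.

## Limitations

Beyond the generator's idealizations listed above: quiet-sleep epochs
must be supplied as annotations (no automated sleep staging); only
bipolar homotopic derivations are supported (no referential variant); the
default ASI constants are this package's stand-ins for unpublished
originals, so absolute index values are comparable only within a fixed
configuration — which is why every output records the configuration hash.
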