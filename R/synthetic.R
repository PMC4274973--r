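#' Burst model for discontinuous neonatal EEG
#'
#' Parameters of the alternating burst / inter-burst background (trace
#' alternant, trace discontinu): high-amplitude seconds-long bursts over a
#' suppressed inter-burst floor.
#'
#' @param burst_rate burst onsets per minute.
#' @param burst_duration_mean,burst_duration_sd burst length, seconds.
#' @param interburst_amplitude_ratio inter-burst amplitude relative to
#'   burst amplitude, in (0, 1).
#' @param burst_band carrier band `c(low, high)` in Hz.
#' @param fs sampling rate, Hz.
#' @param burst_amplitude_sd carrier standard deviation inside a burst,
#'   microvolts (~33 uV gives ~200 uV peak-to-peak).
#' @param ramp_sec raised-cosine edge ramp, seconds.
#' @return list of class `burst_model`.
#' @export
burst_model <- function(burst_rate = 6, burst_duration_mean = 5,
                        burst_duration_sd = 1,
                        interburst_amplitude_ratio = 0.15,
                        burst_band = c(0.5, 10), fs = 256,
                        burst_amplitude_sd = 33, ramp_sec = 0.5) {
  stopifnot(burst_rate >= 0, burst_duration_mean > 0, burst_duration_sd >= 0,
            interburst_amplitude_ratio > 0, interburst_amplitude_ratio <= 1,
            burst_band[1] > 0, burst_band[2] > burst_band[1],
            burst_band[2] < fs / 2, fs > 0, burst_amplitude_sd > 0,
            ramp_sec >= 0)
  structure(list(burst_rate = burst_rate,
                 burst_duration_mean = burst_duration_mean,
                 burst_duration_sd = burst_duration_sd,
                 interburst_amplitude_ratio = interburst_amplitude_ratio,
                 burst_band = burst_band, fs = fs,
                 burst_amplitude_sd = burst_amplitude_sd,
                 ramp_sec = ramp_sec),
            class = "burst_model")
}

#' Interhemispheric synchrony plant
#'
#' Controls how right-hemisphere burst timing relates to the left: a fixed
#' onset lag, per-burst Gaussian jitter, and a probability that a burst
#' appears in one hemisphere only. Increasing jitter or miss probability
#' moves a record along the synchronous -> asynchronous continuum.
#'
#' @param onset_lag_mean fixed right-vs-left onset offset, seconds.
#' @param onset_jitter_sd per-burst onset jitter SD, seconds (>= 0).
#' @param miss_prob probability in \[0, 1\] that a left burst has no right
#'   counterpart.
#' @return list of class `synchrony_plant`.
#' @export
synchrony_plant <- function(onset_lag_mean = 0, onset_jitter_sd = 0,
                            miss_prob = 0) {
  stopifnot(onset_jitter_sd >= 0, miss_prob >= 0, miss_prob <= 1)
  structure(list(onset_lag_mean = onset_lag_mean,
                 onset_jitter_sd = onset_jitter_sd, miss_prob = miss_prob),
            class = "synchrony_plant")
}

# channels every generated record must expose so that all five homotopic
# bipolar derivations are constructible
required_channels <- function() c("Fp1", "Fp2", "C3", "C4", "O1", "O2", "T3", "T4")

# alternating renewal process: exponential inter-burst gaps (so onsets are
# Poisson-like) alternating with truncated-normal burst durations; bursts
# never overlap by construction and the long-run burst-state fraction is
# rate * duration_mean / 60
draw_bursts <- function(model, duration) {
  if (model$burst_rate <= 0)
    return(data.frame(onset = numeric(0), dur = numeric(0)))
  cycle <- 60 / model$burst_rate
  gap_mean <- max(cycle - model$burst_duration_mean, 1e-3)
  onsets <- numeric(0); durs <- numeric(0)
  t <- rexp(1, rate = 1 / gap_mean)
  while (t < duration) {
    d <- max(0.5, rnorm(1, model$burst_duration_mean, model$burst_duration_sd))
    onsets <- c(onsets, t); durs <- c(durs, d)
    t <- t + d + rexp(1, rate = 1 / gap_mean)
  }
  data.frame(onset = onsets, dur = durs)
}

# linear convolution via FFT (kernels are short relative to the signal)
fft_conv <- function(x, k) {
  m <- length(x) + length(k) - 1L
  N <- stats::nextn(m, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(N - length(x))))
  K <- stats::fft(c(k, numeric(N - length(k))))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(m)] / N
}

# per-sample gate in [ratio, 1]: binary burst indicator smoothed with a
# raised-cosine (Hann) kernel so burst edges ramp over ~ramp_sec
gate_from_bursts <- function(bursts, duration, model) {
  fs <- model$fs
  n <- round(duration * fs)
  ind <- numeric(n)
  if (nrow(bursts)) {
    lo <- pmax(1L, floor(bursts$onset * fs) + 1L)
    hi <- pmin(n, ceiling((bursts$onset + bursts$dur) * fs))
    for (i in seq_len(nrow(bursts))) if (lo[i] <= hi[i]) ind[lo[i]:hi[i]] <- 1
  }
  L <- round(model$ramp_sec * fs)
  if (L >= 2 && any(ind > 0)) {
    k <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
    k <- k / sum(k)
    pad <- L %/% 2L
    xi <- c(rep(ind[1], pad), ind, rep(ind[n], L - pad - 1L))
    sm <- fft_conv(xi, k)
    ind <- pmin(pmax(sm[L - 1L + seq_len(n)], 0), 1)
  }
  r <- model$interburst_amplitude_ratio
  r + (1 - r) * ind
}

#' Generate an envelope gate sequence for one hemisphere
#'
#' Draws burst onsets as a renewal process (exponential inter-burst gaps,
#' truncated-normal durations, no overlap) and returns the per-sample
#' amplitude gate in `[interburst_amplitude_ratio, 1]` with raised-cosine
#' burst edges.
#'
#' @param model a [burst_model()].
#' @param duration record length in seconds (> 0).
#' @param rng_seed integer seed; identical seeds give identical output.
#' @return numeric gate vector of length `round(duration * fs)`.
#' @export
generate_burst_train <- function(model, duration, rng_seed = 1L) {
  if (!is.numeric(duration) || duration <= 0)
    abort("duration must be positive", "asindex_argument_error")
  withr::with_seed(rng_seed, {
    gate_from_bursts(draw_bursts(model, duration), duration, model)
  })
}

# band-limited Gaussian carrier synthesized in the frequency domain
# (brickwall band-pass of white Gaussian noise), scaled to the burst SD
band_mask <- function(n, model) {
  f <- c(0, seq_len(n - 1)) * model$fs / n
  f <- pmin(f, model$fs - f)               # two-sided frequency axis
  f >= model$burst_band[1] & f <= model$burst_band[2]
}

bandpassed_noise <- function(n, model, mask = band_mask(n, model)) {
  x <- Re(stats::fft(stats::fft(rnorm(n)) * mask, inverse = TRUE)) / n
  x / sd(x) * model$burst_amplitude_sd
}

#' Generate a two-hemisphere discontinuous EEG record
#'
#' All left-hemisphere channels share one burst train; right-hemisphere
#' channels share the same train shifted by `onset_lag_mean` plus per-burst
#' Gaussian jitter, with bursts dropped with probability `miss_prob`. Each
#' channel carries an independent band-limited Gaussian carrier modulated
#' by its hemisphere's gate, so homotopic bipolar derivations retain the
#' burst structure. Quiet-sleep epochs are annotated as consecutive 10-min
#' `QS1`, `QS2`, ... intervals.
#'
#' @param model a [burst_model()].
#' @param plant a [synchrony_plant()].
#' @param duration record length, seconds.
#' @param channels 10-20 labels; must include Fp1, Fp2, C3, C4, O1, O2,
#'   T3, T4. Odd-numbered labels are treated as left hemisphere, even as
#'   right; midline (z) labels follow the left gate.
#' @param rng_seed integer seed; output is a pure function of it.
#' @return an [eeg_record()] with attribute `"gates"` holding the left and
#'   right gate sequences (ground truth for testing).
#' @export
generate_record <- function(model, plant, duration = 1200,
                            channels = required_channels(),
                            rng_seed = 1L) {
  if (!is.numeric(duration) || duration <= 0)
    abort("duration must be positive", "asindex_argument_error")
  missing <- setdiff(required_channels(), channels)
  if (length(missing))
    abort(paste0("generator montage must include: ",
                 paste(missing, collapse = ", ")), "asindex_montage_error")
  withr::with_seed(rng_seed, {
    bursts <- draw_bursts(model, duration)
    gate_l <- gate_from_bursts(bursts, duration, model)
    right <- bursts
    if (nrow(right)) {
      right$onset <- right$onset + plant$onset_lag_mean +
        rnorm(nrow(right), 0, plant$onset_jitter_sd)
      keep <- runif(nrow(right)) >= plant$miss_prob
      right <- right[keep & right$onset + right$dur > 0 &
                       right$onset < duration, , drop = FALSE]
      right$dur <- pmin(right$dur, duration - pmax(right$onset, 0))
      right$onset <- pmax(right$onset, 0)
    }
    gate_r <- gate_from_bursts(right, duration, model)
    n <- length(gate_l)
    samples <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
    left_side <- grepl("[1357]$", channels) | grepl("z$", channels,
                                                    ignore.case = TRUE)
    mask <- band_mask(n, model)
    for (j in seq_along(channels)) {
      gate <- if (left_side[j]) gate_l else gate_r
      samples[, j] <- bandpassed_noise(n, model, mask) * gate
    }
    ann <- qs_annotations(duration)
    rec <- eeg_record(samples, model$fs, channels, ann)
    attr(rec, "gates") <- list(left = gate_l, right = gate_r)
    rec
  })
}

# consecutive 10-min quiet-sleep epochs covering the record
qs_annotations <- function(duration, epoch_sec = 600) {
  k <- floor(duration / epoch_sec)
  if (k < 1) return(empty_annotations())
  data.frame(start = (seq_len(k) - 1) * epoch_sec,
             end = seq_len(k) * epoch_sec,
             tag = paste0("QS", seq_len(k)), stringsAsFactors = FALSE)
}

#' Inject high-amplitude transient artifact segments
#'
#' Adds `n_artifacts` short high-amplitude transients at random positions
#' and annotates them with tag `"artifact"` so the quality policy can
#' reject affected windows.
#'
#' @param record an [eeg_record()].
#' @param n_artifacts number of segments.
#' @param artifact_sec segment length, seconds.
#' @param amplitude transient amplitude, microvolts.
#' @param rng_seed integer seed.
#' @return the modified record.
#' @export
inject_artifacts <- function(record, n_artifacts = 1, artifact_sec = 2,
                             amplitude = 500, rng_seed = 1L) {
  dur <- nrow(record$samples) / record$fs
  withr::with_seed(rng_seed, {
    starts <- runif(n_artifacts, 0, dur - artifact_sec)
    for (s in starts) {
      idx <- (floor(s * record$fs) + 1L):min(nrow(record$samples),
                                             ceiling((s + artifact_sec) * record$fs))
      record$samples[idx, ] <- record$samples[idx, ] +
        amplitude * sin(2 * pi * 2 * (idx / record$fs))
    }
    record$annotations <- rbind(record$annotations,
                                data.frame(start = starts,
                                           end = starts + artifact_sec,
                                           tag = "artifact",
                                           stringsAsFactors = FALSE))
  })
  record
}

#' Synthetic cohort specification
#'
#' Describes a cohort of normal and abnormal recordings: group sizes, the
#' synchrony plants, the postmenstrual-age range and the master seed from
#' which per-record seeds are derived. Defaults mirror a cohort of 14
#' normal and 17 abnormal term-age recordings with tight (0.2 s) versus
#' destroyed (8 s jitter) interhemispheric burst timing.
#'
#' @param n_normal,n_abnormal group sizes (>= 0).
#' @param plant_normal,plant_abnormal [synchrony_plant()]s per group.
#' @param model shared [burst_model()].
#' @param pma_range postmenstrual age range `c(lo, hi)` in weeks.
#' @param record_duration record length in seconds (>= 1200 so that two
#'   10-min quiet-sleep epochs exist).
#' @param seed master integer seed.
#' @param pma_effect optional hook `function(pma_weeks)` returning extra
#'   onset jitter (s) added to a record's plant, for power studies; by
#'   default age does not influence the signal.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 14, n_abnormal = 17,
                        plant_normal = synchrony_plant(0, 0.2, 0),
                        plant_abnormal = synchrony_plant(0, 8, 0),
                        model = burst_model(), pma_range = c(36, 42),
                        record_duration = 1200, seed = 1L,
                        pma_effect = NULL) {
  stopifnot(n_normal >= 0, n_abnormal >= 0, record_duration >= 1200,
            length(pma_range) == 2, pma_range[2] >= pma_range[1])
  structure(list(n_normal = n_normal, n_abnormal = n_abnormal,
                 plant_normal = plant_normal, plant_abnormal = plant_abnormal,
                 model = model, pma_range = pma_range,
                 record_duration = record_duration, seed = as.integer(seed),
                 pma_effect = pma_effect),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of class `asi_cohort`; each element has `record`, `group`
#'   (`"normal"`/`"abnormal"`), `pma` (weeks), `subject_id` and the seed
#'   used. Deterministic given `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_normal + spec$n_abnormal
  if (n == 0) return(structure(list(), class = "asi_cohort"))
  groups <- rep(c("normal", "abnormal"), c(spec$n_normal, spec$n_abnormal))
  meta <- withr::with_seed(spec$seed, {
    list(seeds = sample.int(.Machine$integer.max, n),
         pma = runif(n, spec$pma_range[1], spec$pma_range[2]))
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    plant <- if (groups[i] == "normal") spec$plant_normal else spec$plant_abnormal
    if (!is.null(spec$pma_effect))
      plant$onset_jitter_sd <- plant$onset_jitter_sd +
        spec$pma_effect(meta$pma[i])
    out[[i]] <- list(
      record = generate_record(spec$model, plant, spec$record_duration,
                               rng_seed = meta$seeds[i]),
      group = groups[i], pma = meta$pma[i],
      subject_id = sprintf("S%02d", i), seed = meta$seeds[i])
  }
  structure(out, class = "asi_cohort", spec = spec)
}
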