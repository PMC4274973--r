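#' ASI analysis configuration
#'
#' Collects every tunable of the ASI computation chain. Defaults are the
#' package's reference settings; all of them may be overridden so that other
#' parameterizations of the index can be dropped in.
#'
#' @param band numeric length-2, band-pass edges in Hz applied before
#'   envelope extraction. Default `c(0.5, 20)` covers neonatal burst energy.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation is doubled). Default 4.
#' @param preemphasis first-difference pre-emphasis coefficient `alpha` in
#'   `y[t] = x[t] - alpha * x[t-1]`, weighting higher frequencies before the
#'   envelope is taken. `0` disables it. Default 0.95.
#' @param frame_rate rate (Hz) of the decimated amplitude envelope.
#'   Default 16.
#' @param smooth_sec moving-average length in seconds used to smooth the
#'   rectified signal into an envelope. Default 1.0.
#' @param n_levels number of equal-occupancy quantization levels `Q`.
#'   Default 8.
#' @param numerator_max_lag near-zero lag window half-width in seconds; all
#'   frame-grid lags with `|tau| <= numerator_max_lag` form the numerator
#'   lag set. Default 0.5.
#' @param baseline_lag_range long-lag window `c(lo, hi)` in seconds; lags
#'   with `lo <= |tau| <= hi` form the chance-coincidence baseline.
#'   Default `c(5, 30)`.
#' @param baseline_lag_step spacing (s) of the baseline lag grid. The
#'   baseline dependency varies slowly over lags compared to the 1-s
#'   envelope smoothing, so a 0.25-s grid samples it adequately at a
#'   quarter of the cost of the full frame grid. Default 0.25.
#' @param baseline_floor floor (bits) applied to the baseline mean before
#'   division, keeping the index finite; results flag when it engages.
#'   Default 1e-4.
#' @param min_window_sec shortest admissible analysis window in seconds.
#'   The index is a statistical estimate and destabilizes below roughly two
#'   minutes; default 150 (2.5 min).
#'
#' @return a list of class `asi_config`.
#' @export
asi_config <- function(band = c(0.5, 20), filter_order = 4L,
                       preemphasis = 0.95, frame_rate = 16,
                       smooth_sec = 1.0, n_levels = 8L,
                       numerator_max_lag = 0.5,
                       baseline_lag_range = c(5, 30),
                       baseline_lag_step = 0.25,
                       baseline_floor = 1e-4,
                       min_window_sec = 150) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            filter_order >= 1, frame_rate > 0, smooth_sec > 0,
            n_levels >= 2, numerator_max_lag >= 0,
            length(baseline_lag_range) == 2,
            baseline_lag_range[1] > numerator_max_lag,
            baseline_lag_range[2] > baseline_lag_range[1],
            baseline_lag_step > 0, baseline_floor > 0)
  structure(list(band = band, filter_order = as.integer(filter_order),
                 preemphasis = preemphasis, frame_rate = frame_rate,
                 smooth_sec = smooth_sec, n_levels = as.integer(n_levels),
                 numerator_max_lag = numerator_max_lag,
                 baseline_lag_range = baseline_lag_range,
                 baseline_lag_step = baseline_lag_step,
                 baseline_floor = baseline_floor,
                 min_window_sec = min_window_sec),
            class = "asi_config")
}

#' Multichannel EEG record container
#'
#' @param samples numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels channel labels (10-20 names); defaults to the matrix
#'   column names.
#' @param annotations data.frame with columns `start`, `end` (seconds,
#'   half-open `[start, end)` from record start) and `tag`.
#'
#' @return object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, labels = colnames(samples),
                       annotations = empty_annotations()) {
  samples <- as.matrix(samples)
  if (is.null(labels)) abort("channel labels are required", "asindex_montage_error")
  stopifnot(fs > 0, ncol(samples) == length(labels))
  dur <- nrow(samples) / fs
  if (nrow(annotations) &&
      (any(annotations$start < 0) || any(annotations$end > dur + 1e-9) ||
       any(annotations$end <= annotations$start)))
    abort("annotation intervals must lie within the record", "asindex_annotation_error")
  colnames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels,
                 annotations = annotations),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %.1f s @ %g Hz (%s)\n",
              length(x$labels), nrow(x$samples) / x$fs, x$fs,
              paste(x$labels, collapse = ", ")))
  if (nrow(x$annotations))
    cat(sprintf("  %d annotations: %s\n", nrow(x$annotations),
                paste(unique(x$annotations$tag), collapse = ", ")))
  invisible(x)
}

#' @rdname eeg_record
#' @export
empty_annotations <- function() {
  data.frame(start = numeric(0), end = numeric(0), tag = character(0),
             stringsAsFactors = FALSE)
}

#' Homotopic bipolar derivation pair
#'
#' An ordered electrode pair per hemisphere, e.g. left C3->O1 mirrored by
#' right C4->O2. The derived signal is anterior minus posterior electrode.
#'
#' @param left,right character length-2, ordered electrode labels.
#' @param id optional identifier; defaults to e.g. `"C3O1-C4O2"`.
#' @return object of class `derivation_pair`.
#' @export
derivation_pair <- function(left, right, id = NULL) {
  stopifnot(length(left) == 2, length(right) == 2)
  id <- id %||% paste0(paste0(left, collapse = ""), "-",
                       paste0(right, collapse = ""))
  structure(list(left = left, right = right, id = id),
            class = "derivation_pair")
}

#' The five symmetric bipolar derivation pairs assessed for stability
#'
#' Fp1C3-Fp2C4, C3O1-C4O2, Fp1O1-Fp2O2, Fp1T3-Fp2T4 and T3O1-T4O2 —
#' fronto-central, centro-occipital, fronto-occipital, fronto-temporal and
#' temporo-occipital homotopic derivations.
#'
#' @return named list of [derivation_pair()] objects.
#' @export
default_pairs <- function() {
  pairs <- list(
    derivation_pair(c("Fp1", "C3"), c("Fp2", "C4")),
    derivation_pair(c("C3", "O1"), c("C4", "O2")),
    derivation_pair(c("Fp1", "O1"), c("Fp2", "O2")),
    derivation_pair(c("Fp1", "T3"), c("Fp2", "T4")),
    derivation_pair(c("T3", "O1"), c("T4", "O2")))
  names(pairs) <- vapply(pairs, `[[`, character(1), "id")
  pairs
}

#' Derive bipolar signals for a homotopic pair
#'
#' @param record an [eeg_record()].
#' @param pair a [derivation_pair()].
#' @return list with numeric vectors `left` and `right` (microvolts).
#' @export
make_bipolar <- function(record, pair) {
  needed <- c(pair$left, pair$right)
  missing <- setdiff(needed, record$labels)
  if (length(missing))
    abort(paste0("electrode(s) not in record: ", paste(missing, collapse = ", ")),
          "asindex_montage_error")
  s <- record$samples
  list(left = s[, pair$left[1]] - s[, pair$left[2]],
       right = s[, pair$right[1]] - s[, pair$right[2]])
}

#' Band-pass and pre-emphasize an EEG signal
#'
#' Zero-phase (forward-backward) Butterworth band-pass followed by an
#' optional first-difference pre-emphasis weighting higher frequencies.
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate, Hz (>= 64).
#' @param config an [asi_config()].
#' @return filtered signal, same length as `x`.
#' @export
preprocess_eeg <- function(x, fs, config = asi_config()) {
  if (fs < 64) abort("sampling rate below 64 Hz", "asindex_rate_error")
  if (length(x) < 10 * fs)
    abort("signal shorter than 10 s", "asindex_epoch_length_error")
  if (anyNA(x))
    abort("signal contains NA/NaN samples", "asindex_data_quality_error")
  if (config$band[2] >= fs / 2)
    abort("band upper edge must be below Nyquist", "asindex_rate_error")
  bf <- signal::butter(config$filter_order, config$band / (fs / 2),
                       type = "pass")
  # mean removal plus odd-reflection padding keep the zero-phase IIR pass
  # free of edge transients (~3 periods of the lowest passband frequency)
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1L, as.integer(round(3 * fs / config$band[1])))
  xp <- c(2 * xc[1] - xc[(pad + 1L):2], xc,
          2 * xc[n] - xc[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, xp)[pad + seq_len(n)]
  a <- config$preemphasis
  if (a > 0) y <- y - a * c(y[1], y[-length(y)])
  y
}

#' Amplitude envelope of a preprocessed signal
#'
#' Rectifies the signal, smooths it with a centered moving average and
#' decimates it to the envelope frame rate. The moving average acts as the
#' anti-alias filter for the decimation (its cutoff, ~1 Hz for the default
#' 1-s window, is far below the 16-Hz frame rate).
#'
#' @param x preprocessed signal.
#' @param fs sampling rate of `x`, Hz.
#' @param config an [asi_config()] supplying `smooth_sec` and `frame_rate`.
#' @return non-negative numeric envelope sampled at `config$frame_rate`.
#' @export
amplitude_envelope <- function(x, fs, config = asi_config()) {
  if (config$frame_rate > fs)
    abort("frame rate exceeds sampling rate", "asindex_rate_error")
  e <- abs(x)
  w <- max(1L, round(fs * config$smooth_sec))
  sm <- moving_average(e, w)
  n <- length(sm)
  dec <- fs / config$frame_rate
  if (abs(dec - round(dec)) < 1e-9) {
    idx <- seq.int(1L, n, by = as.integer(round(dec)))
    env <- sm[idx]
  } else {
    # non-integer ratio: linear interpolation onto the frame grid
    t_frame <- seq(0, (n - 1) / fs, by = 1 / config$frame_rate)
    env <- approx((seq_len(n) - 1) / fs, sm, xout = t_frame)$y
  }
  env
}

# centered moving average with shrinking windows at the edges, O(n)
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 1L) return(x)
  h <- w %/% 2L
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Equal-occupancy quantization of an amplitude envelope
#'
#' Rank-based quantile binning into `Q` levels, computed on the analysis
#' window itself. Occupancies are equal to within one sample, every strictly
#' monotone transform of the envelope yields identical codes, and amplitude
#' scale is discarded entirely.
#'
#' @param env numeric envelope.
#' @param config an [asi_config()] supplying `n_levels` and `frame_rate`,
#'   or `NULL` with `Q`/`frame_rate` given directly.
#' @param Q,frame_rate direct overrides of the configuration values.
#' @return object of class `quantized_envelope` with integer `codes` in
#'   `0..Q-1`, `frame_rate`, `Q` and the envelope values at level
#'   boundaries (`bin_edges`).
#' @export
quantize_envelope <- function(env, config = asi_config(),
                              Q = config$n_levels,
                              frame_rate = config$frame_rate) {
  n <- length(env)
  if (n < 2 * Q)
    abort("envelope too short for stable quantization", "asindex_epoch_length_error")
  if (diff(range(env)) == 0)
    abort("constant envelope cannot be quantized (flat signal)",
          "asindex_degenerate_signal_error")
  r <- rank(env, ties.method = "first")
  codes <- as.integer(ceiling(r * Q / n) - 1L)
  structure(list(codes = codes, frame_rate = frame_rate, Q = as.integer(Q),
                 bin_edges = unname(quantile(env, probs = seq_len(Q - 1) / Q))),
            class = "quantized_envelope")
}

# plug-in mutual information (bits) of two aligned code vectors in 0..Q-1
mi_bits <- function(a, b, Q) {
  n <- length(a)
  joint <- tabulate(a * Q + b + 1L, nbins = Q * Q)
  pj <- joint / n
  pa <- tabulate(a + 1L, nbins = Q) / n
  pb <- tabulate(b + 1L, nbins = Q) / n
  pp <- as.vector(outer(pb, pa))   # index a*Q + b + 1 walks b fastest
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / pp[nz]))
}

#' Lagged dependency profile of two quantized envelopes
#'
#' For each requested lag `tau`, the plug-in mutual information (bits) of
#' the joint `Q x Q` histogram of `(qa[t], qb[t + tau])`. For co-incident
#' bursting the profile peaks at zero lag and decays toward the chance
#' level at long lags.
#'
#' @param qa,qb [quantize_envelope()] outputs with equal `Q` and
#'   `frame_rate`.
#' @param lags numeric lags in seconds (rounded to the frame grid).
#' @param min_overlap smallest admissible number of overlapping frames per
#'   lag; lags with less overlap are dropped with a warning.
#' @return data.frame with columns `lag` (s) and `mi` (bits).
#' @export
lag_dependency_profile <- function(qa, qb, lags, min_overlap = 100L) {
  stopifnot(inherits(qa, "quantized_envelope"),
            inherits(qb, "quantized_envelope"))
  if (qa$Q != qb$Q || qa$frame_rate != qb$frame_rate)
    abort("envelopes must share Q and frame_rate", "asindex_config_error")
  Q <- qa$Q; fr <- qa$frame_rate
  n <- min(length(qa$codes), length(qb$codes))
  a <- qa$codes[seq_len(n)]; b <- qb$codes[seq_len(n)]
  ks <- as.integer(round(lags * fr))
  mi <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    m <- n - abs(k)
    if (m < min_overlap) next
    if (k >= 0) mi[i] <- mi_bits(a[seq_len(m)], b[seq_len(m) + k], Q)
    else        mi[i] <- mi_bits(a[seq_len(m) - k], b[seq_len(m)], Q)
  }
  keep <- !is.na(mi)
  if (!any(keep))
    abort("no lag had sufficient overlap", "asindex_analysis_error")
  if (!all(keep))
    warning(sprintf("%d lag(s) dropped for insufficient overlap",
                    sum(!keep)), call. = FALSE)
  data.frame(lag = ks[keep] / fr, mi = mi[keep])
}

#' Activation synchrony index of two quantized envelopes
#'
#' The scalar index is the mean lagged mutual information over the
#' near-zero ("numerator") lag set divided by the mean over the long-lag
#' ("baseline") set. Temporally co-incident bursting concentrates
#' dependency at zero lag and drives the index far above one; independent
#' or strongly jittered bursting leaves it near one.
#'
#' @param qa,qb [quantize_envelope()] outputs for the left and right
#'   derivations of one analysis window.
#' @param config an [asi_config()].
#' @param pair,window optional metadata carried into the result.
#' @param check_duration enforce the `min_window_sec` precondition
#'   (default TRUE).
#' @return object of class `asi_result`: `asi`, the `lag_profile`
#'   data.frame, the numerator and baseline lag sets, and a `floored` flag
#'   set when the baseline mean hit the configured floor.
#' @export
compute_asi <- function(qa, qb, config = asi_config(), pair = NULL,
                        window = NULL, check_duration = TRUE) {
  fr <- qa$frame_rate
  n <- min(length(qa$codes), length(qb$codes))
  if (check_duration && n / fr < config$min_window_sec)
    abort(sprintf("analysis window shorter than %g s", config$min_window_sec),
          "asindex_epoch_length_error")
  kmax <- round(config$numerator_max_lag * fr)
  num_lags <- (-kmax:kmax) / fr
  blr <- config$baseline_lag_range
  pos <- seq(blr[1], blr[2], by = config$baseline_lag_step)
  base_lags <- sort(c(-pos, pos))
  prof <- lag_dependency_profile(qa, qb, c(num_lags, base_lags))
  in_num <- abs(prof$lag) <= config$numerator_max_lag + 1e-9
  num_mean <- mean(prof$mi[in_num])
  base_mean <- mean(prof$mi[!in_num])
  floored <- base_mean < config$baseline_floor
  asi <- num_mean / max(base_mean, config$baseline_floor)
  structure(list(asi = asi, lag_profile = prof,
                 numerator_lags = prof$lag[in_num],
                 baseline_lags = prof$lag[!in_num],
                 numerator_mean = num_mean, baseline_mean = base_mean,
                 floored = floored, pair = pair, window = window),
            class = "asi_result")
}

#' @export
print.asi_result <- function(x, ...) {
  cat(sprintf("<asi_result> ASI = %.3f (numerator %.4f bits / baseline %.4f bits%s)\n",
              x$asi, x$numerator_mean, x$baseline_mean,
              if (x$floored) ", baseline floored" else ""))
  if (!is.null(x$pair)) cat("  pair:", x$pair$id, "\n")
  if (!is.null(x$window))
    cat(sprintf("  window: [%g, %g) s\n", x$window[1], x$window[2]))
  invisible(x)
}

#' ASI from a pair of raw bipolar signals
#'
#' Runs the full chain — preprocessing, amplitude envelope, equal-occupancy
#' quantization, lagged-dependency ratio — on one analysis window.
#'
#' @param left,right raw bipolar derivation signals (microvolts).
#' @param fs sampling rate, Hz.
#' @param config an [asi_config()].
#' @inheritParams compute_asi
#' @return an `asi_result`.
#' @export
asi_from_signals <- function(left, right, fs, config = asi_config(),
                             pair = NULL, window = NULL,
                             check_duration = TRUE) {
  qa <- quantize_envelope(amplitude_envelope(preprocess_eeg(left, fs, config),
                                             fs, config), config)
  qb <- quantize_envelope(amplitude_envelope(preprocess_eeg(right, fs, config),
                                             fs, config), config)
  compute_asi(qa, qb, config, pair = pair, window = window,
              check_duration = check_duration)
}
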