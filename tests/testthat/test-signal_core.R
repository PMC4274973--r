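test_that("bipolar derivation is the ordered electrode difference", {
  n <- 64 * 12
  samples <- cbind(C3 = rep(2, n), O1 = rep(0.5, n),
                   C4 = rnorm(n), O2 = rnorm(n))
  rec <- eeg_record(samples, fs = 64)
  pair <- derivation_pair(c("C3", "O1"), c("C4", "O2"))
  sig <- make_bipolar(rec, pair)
  expect_equal(sig$left, rep(1.5, n))
  expect_equal(sig$right, samples[, "C4"] - samples[, "O2"])

  swapped <- make_bipolar(rec, derivation_pair(c("C4", "O2"), c("C3", "O1")))
  expect_equal(swapped$left, sig$right)
  expect_equal(swapped$right, sig$left)

  rec2 <- eeg_record(cbind(C3 = samples[, "C3"], O1 = samples[, "C3"],
                           C4 = samples[, "C4"], O2 = samples[, "O2"]), 64)
  expect_equal(make_bipolar(rec2, pair)$left, rep(0, n))

  expect_error(make_bipolar(rec, derivation_pair(c("F3", "O1"), c("F4", "O2"))),
               "F3", class = "asindex_montage_error")
})

test_that("preprocessing removes DC, attenuates out-of-band tones, and pre-emphasis tilts the spectrum up", {
  fs <- 256
  cfg <- asi_config()
  t <- seq_len(fs * 20) / fs

  dc <- preprocess_eeg(rep(5, fs * 20), fs, cfg)
  expect_lt(max(abs(dc)), 1e-6)

  tone <- sin(2 * pi * 40 * t)
  out <- preprocess_eeg(tone, fs, cfg)
  expect_lt(mean(out^2) / mean(tone^2), 0.01)

  # oracle: periodogram band-power ratio with vs without pre-emphasis
  set.seed(11)
  wn <- rnorm(fs * 20)
  band_power <- function(x, f_lo, f_hi) {
    p <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    sum(p[f >= f_lo & f <= f_hi])
  }
  with_pe <- preprocess_eeg(wn, fs, cfg)
  without_pe <- preprocess_eeg(wn, fs, asi_config(preemphasis = 0))
  ratio <- function(x) band_power(x, 9, 11) / band_power(x, 0.5, 1.5)
  expect_gt(ratio(with_pe), ratio(without_pe))

  expect_error(preprocess_eeg(rnorm(100), fs, cfg),
               class = "asindex_epoch_length_error")
  expect_error(preprocess_eeg(c(rnorm(fs * 20), NA), fs, cfg),
               class = "asindex_data_quality_error")
})

test_that("amplitude envelope tracks slow amplitude modulation and is homogeneous", {
  fs <- 256
  cfg <- asi_config()
  expect_equal(amplitude_envelope(numeric(fs * 20), fs, cfg),
               numeric(fs * 20 / 16))

  set.seed(5)
  t <- seq_len(fs * 60) / fs
  gate <- ifelse(sin(2 * pi * 0.1 * t) > 0, 1, 0.1)   # 0.1-Hz square AM
  x <- rnorm(length(t)) * gate
  env <- amplitude_envelope(x, fs, cfg)
  gate_frames <- gate[seq(1, length(gate), by = fs / cfg$frame_rate)]
  expect_gt(cor(env, gate_frames), 0.9)

  expect_equal(amplitude_envelope(10 * x, fs, cfg), 10 * env)
})

test_that("equal-occupancy quantization is a rank statistic with balanced levels", {
  q <- quantize_envelope(c(1, 2, 3, 4), Q = 2, frame_rate = 1)
  expect_identical(q$codes, c(0L, 0L, 1L, 1L))

  set.seed(3)
  env <- runif(8000)
  q8 <- quantize_envelope(env, Q = 8, frame_rate = 16)
  expect_true(all(tabulate(q8$codes + 1L, 8) == 1000L))

  # rank invariance under strictly monotone transforms
  expect_identical(quantize_envelope(exp(3 * env), Q = 8, frame_rate = 16)$codes,
                   q8$codes)
  expect_identical(quantize_envelope(env^3 + 2, Q = 8, frame_rate = 16)$codes,
                   q8$codes)

  expect_error(quantize_envelope(rep(1, 500), Q = 8, frame_rate = 16),
               class = "asindex_degenerate_signal_error")
  expect_error(quantize_envelope(runif(10), Q = 8, frame_rate = 16),
               class = "asindex_epoch_length_error")
})

test_that("lagged dependency profile matches hand-computed and limiting values", {
  # identical sequences with all levels equally occupied: I(0) = log2(Q)
  set.seed(9)
  codes <- sample(rep(0:7, 50))
  qa <- structure(list(codes = codes, frame_rate = 1, Q = 8L), # nolint
                  class = "quantized_envelope")
  prof <- lag_dependency_profile(qa, qa, 0)
  expect_equal(prof$mi, 3)

  # 2x2 toy joint histogram, hand-computed: perfectly matched binary codes
  qt <- structure(list(codes = rep(c(0L, 1L), 100), frame_rate = 1, Q = 2L),
                  class = "quantized_envelope")
  expect_equal(lag_dependency_profile(qt, qt, 0)$mi, 1)

  # independence: plug-in MI concentrates at the (Q-1)^2 / (2N ln 2) bias
  Q <- 4; N <- 10000
  bias <- (Q - 1)^2 / (2 * N * log(2))
  mis <- vapply(1:40, function(s) {
    set.seed(s)
    a <- structure(list(codes = sample(0:(Q - 1), N, TRUE), frame_rate = 1,
                        Q = Q), class = "quantized_envelope")
    b <- structure(list(codes = sample(0:(Q - 1), N, TRUE), frame_rate = 1,
                        Q = Q), class = "quantized_envelope")
    lag_dependency_profile(a, b, 0)$mi
  }, numeric(1))
  expect_lt(abs(mean(mis) - bias) / bias, 0.3)

  # lags without sufficient overlap are dropped with a warning
  expect_warning(p2 <- lag_dependency_profile(qa, qa, c(0, 399)),
                 "dropped")
  expect_equal(p2$lag, 0)
  expect_error(suppressWarnings(lag_dependency_profile(qa, qa, 399)),
               class = "asindex_analysis_error")
})

test_that("fast MI path matches the naive joint-histogram reference bit-exactly", {
  set.seed(42)
  for (i in 1:25) {
    Q <- sample(2:8, 1)
    n <- sample(50:500, 1)
    a <- sample(0:(Q - 1), n, replace = TRUE)
    b <- sample(0:(Q - 1), n, replace = TRUE)
    qa <- structure(list(codes = a, frame_rate = 1, Q = Q),
                    class = "quantized_envelope")
    qb <- structure(list(codes = b, frame_rate = 1, Q = Q),
                    class = "quantized_envelope")
    lags <- sort(sample(-5:5, 3))
    expect_identical(lag_dependency_profile(qa, qb, lags, min_overlap = 10)$mi,
                     naive_lag_profile(qa, qb, lags))
  }
})

test_that("ASI is scale- and rank-invariant and symmetric under symmetric lag sets", {
  cfg <- asi_config()
  env_l <- structured_env(9600, seed = 21)
  env_r <- structured_env(9600, seed = 22)
  qa <- quantize_at(env_l); qb <- quantize_at(env_r)
  ref <- compute_asi(qa, qb, cfg)

  # positive gain and strictly monotone envelope transforms: exact equality
  expect_identical(compute_asi(quantize_at(7.3 * env_l), qb, cfg)$asi, ref$asi)
  expect_identical(compute_asi(quantize_at(log(env_l)), qb, cfg)$asi, ref$asi)

  # symmetric numerator/baseline lag sets: exact symmetry in the arguments
  expect_identical(compute_asi(qb, qa, cfg)$asi, ref$asi)

  # profile bounds and self-consistency of the reported ratio
  expect_true(all(ref$lag_profile$mi >= 0))
  expect_true(all(ref$lag_profile$mi <= log2(cfg$n_levels) + 1e-12))
  in_num <- abs(ref$lag_profile$lag) <= cfg$numerator_max_lag + 1e-9
  expect_equal(ref$asi,
               mean(ref$lag_profile$mi[in_num]) /
                 max(mean(ref$lag_profile$mi[!in_num]), cfg$baseline_floor))
})

test_that("ASI responds to planted delay and enforces the minimum window", {
  cfg <- asi_config()
  env <- structured_env(9600 + 240, seed = 33)
  qa <- quantize_at(env[1:9600])
  q_delayed <- quantize_at(env[241:(9600 + 240)])   # 15-s shift at 16 Hz
  asi_same <- compute_asi(qa, qa, cfg)$asi
  asi_delay <- compute_asi(qa, q_delayed, cfg)$asi
  expect_gt(asi_same, 5)
  expect_lt(asi_delay, asi_same)

  short <- quantize_at(structured_env(1000, seed = 1))
  expect_error(compute_asi(short, short, cfg),
               class = "asindex_epoch_length_error")
})
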