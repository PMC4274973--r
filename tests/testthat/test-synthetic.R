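test_that("burst gate degenerates correctly and is deterministic", {
  m1 <- burst_model(interburst_amplitude_ratio = 1, fs = 64)
  expect_equal(generate_burst_train(m1, 10, 1), rep(1, 640))

  m0 <- burst_model(burst_rate = 0, fs = 64)
  expect_equal(generate_burst_train(m0, 10, 1), rep(0.15, 640))

  m <- test_model()
  expect_identical(generate_burst_train(m, 60, 7),
                   generate_burst_train(m, 60, 7))
  g <- generate_burst_train(m, 60, 8)
  expect_true(all(g >= 0.15 - 1e-12 & g <= 1 + 1e-12))

  expect_error(generate_burst_train(m, -5, 1), class = "asindex_argument_error")
})

test_that("burst-state fraction converges to rate x duration / 60", {
  m <- burst_model(burst_rate = 6, burst_duration_mean = 5,
                   burst_duration_sd = 1, fs = 64)
  thr <- (1 + m$interburst_amplitude_ratio) / 2
  fracs <- vapply(1:50, function(s)
    mean(generate_burst_train(m, 600, s) > thr), numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.5), 3 * se + 0.01)
})

test_that("a degenerate plant yields identical hemispheric gates; jitter decorrelates them", {
  m <- test_model()
  rec <- generate_record(m, synchrony_plant(0, 0, 0), 1200, rng_seed = 3)
  gates <- attr(rec, "gates")
  expect_identical(gates$left, gates$right)

  # synchrony ordering: zero-lag gate correlation strictly decreases with
  # jitter (20-seed averages), and the jitter-10 cross-correlation peak has
  # left lag zero
  mean_cor <- function(jitter) {
    mean(vapply(1:20, function(s) {
      g <- attr(generate_record(m, synchrony_plant(0, jitter, 0), 1200,
                                rng_seed = s), "gates")
      cor(g$left, g$right)
    }, numeric(1)))
  }
  c0 <- mean_cor(0); c2 <- mean_cor(2); c10 <- mean_cor(10)
  expect_gt(c0, c2)
  expect_gt(c2, c10)

  # oracle: cross-correlate the gates and locate the maximum
  peak_at_zero <- vapply(1:10, function(s) {
    g <- attr(generate_record(m, synchrony_plant(0, 10, 0), 1200,
                              rng_seed = s), "gates")
    cc <- ccf(g$left, g$right, lag.max = 20 * m$fs, plot = FALSE)
    abs(cc$lag[which.max(cc$acf)]) < 0.5 * m$fs
  }, logical(1))
  expect_lt(mean(peak_at_zero), 0.5)
})

test_that("miss probability thins right-hemisphere bursts", {
  m <- test_model()
  thr <- (1 + m$interburst_amplitude_ratio) / 2
  fr_right <- function(miss) {
    mean(vapply(1:20, function(s) {
      g <- attr(generate_record(m, synchrony_plant(0, 0, miss), 1200,
                                rng_seed = s), "gates")
      mean(g$right > thr)
    }, numeric(1)))
  }
  f0 <- fr_right(0); f5 <- fr_right(0.5)
  expect_lt(f5, 0.7 * f0)
})

test_that("expected ASI is non-increasing in planted onset jitter", {
  m <- test_model()
  pair <- default_pairs()[["C3O1-C4O2"]]
  sch <- window_scheme(5, 1)
  mean_asi <- function(jitter) {
    mean(vapply(1:20, function(s) {
      rec <- generate_record(m, synchrony_plant(0, jitter, 0), 300,
                             rng_seed = 3000 + s)
      windowed_asi_mean(rec, pair, c(0, 300), sch)$mean
    }, numeric(1)))
  }
  a0 <- mean_asi(0); a2 <- mean_asi(2); a8 <- mean_asi(8)
  expect_gte(a0, a2)
  expect_gte(a2, a8)
  expect_gt(a0, 2)        # synchronous plants score well above chance
  expect_lt(a8, 2)        # destroyed timing sits near the chance level
})

test_that("record generation is deterministic and validates its montage", {
  m <- test_model()
  plant <- synchrony_plant(0.5, 0.1, 0.05)
  r1 <- generate_record(m, plant, 1200, rng_seed = 11)
  r2 <- generate_record(m, plant, 1200, rng_seed = 11)
  expect_identical(r1$samples, r2$samples)
  expect_equal(r1$annotations$tag, c("QS1", "QS2"))
  expect_equal(r1$annotations$start, c(0, 600))

  expect_error(generate_record(m, plant, 1200, channels = c("C3", "C4")),
               class = "asindex_montage_error")
})

test_that("cohorts have the requested composition and are reproducible", {
  spec <- cohort_spec(n_normal = 2, n_abnormal = 3, model = test_model(),
                      seed = 5)
  co <- generate_cohort(spec)
  expect_length(co, 5)
  expect_equal(vapply(co, `[[`, character(1), "group"),
               rep(c("normal", "abnormal"), c(2, 3)))
  pma <- vapply(co, `[[`, numeric(1), "pma")
  expect_true(all(pma >= 36 & pma <= 42))
  seeds <- vapply(co, `[[`, numeric(1), "seed")
  expect_equal(anyDuplicated(seeds), 0L)

  co2 <- generate_cohort(spec)
  expect_identical(co[[3]]$record$samples, co2[[3]]$record$samples)

  expect_length(generate_cohort(cohort_spec(0, 0, model = test_model())), 0)
})

test_that("artifact injection annotates segments that strict mode rejects", {
  m <- test_model()
  rec <- generate_record(m, synchrony_plant(0, 0.2, 0), 1200, rng_seed = 4)
  rec <- inject_artifacts(rec, n_artifacts = 3, rng_seed = 9)
  expect_equal(sum(rec$annotations$tag == "artifact"), 3)

  pair <- default_pairs()[["C3O1-C4O2"]]
  sch <- window_scheme(2.5, 4)
  expect_error(windowed_asi_mean(rec, pair, c(0, 600), sch),
               class = "asindex_quality_error")
  tol <- suppressMessages(
    windowed_asi_mean(rec, pair, c(0, 600), sch, mode = "tolerant"))
  expect_gte(tol$n_rejected, 1)
  expect_true(is.finite(tol$mean))
})
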