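# Independent reference implementations used as oracles.

# naive O(N * Q^2) plug-in mutual information, bits; term order matches the
# joint-cell index order so agreement with the fast path is bit-exact
naive_mi <- function(a, b, Q) {
  n <- length(a)
  terms <- numeric(0)
  for (ai in 0:(Q - 1)) for (bi in 0:(Q - 1)) {
    nij <- sum(a == ai & b == bi)
    if (nij == 0) next
    pj <- nij / n
    pa <- sum(a == ai) / n
    pb <- sum(b == bi) / n
    terms <- c(terms, pj * log2(pj / (pa * pb)))
  }
  sum(terms)
}

naive_lag_profile <- function(qa, qb, lags) {
  fr <- qa$frame_rate
  n <- min(length(qa$codes), length(qb$codes))
  a <- qa$codes[seq_len(n)]; b <- qb$codes[seq_len(n)]
  vapply(lags, function(tau) {
    k <- as.integer(round(tau * fr))
    m <- n - abs(k)
    if (k >= 0) naive_mi(a[1:m], b[(1 + k):(k + m)], qa$Q)
    else naive_mi(a[(1 - k):(m - k)], b[1:m], qa$Q)
  }, numeric(1))
}

# AUC by brute-force pair counting (low score = positive/abnormal class),
# ties credited 1/2
auc_pair_count <- function(scores, labels) {
  ab <- scores[labels == "abnormal"]; no <- scores[labels == "normal"]
  tot <- 0
  for (x in ab) tot <- tot + sum(x < no) + 0.5 * sum(x == no)
  tot / (length(ab) * length(no))
}

# structured (burst-like) amplitude envelope at the frame rate: the burst
# gate modulated by smoothed positive noise, as a real rectified-EEG
# envelope would be
structured_env <- function(n_frames, seed, frame_rate = 16) {
  model <- burst_model(fs = frame_rate, burst_band = c(0.5, 7))
  g <- generate_burst_train(model, n_frames / frame_rate, rng_seed = seed)
  g <- g[seq_len(n_frames)]
  carrier <- withr::with_seed(seed + 10000, {
    w <- abs(rnorm(n_frames)) + 0.05
    stats::filter(c(w[3:1], w, w[n_frames - (0:2)]), rep(1 / 7, 7),
                  sides = 2)[3 + seq_len(n_frames)]
  })
  g * as.numeric(carrier)
}

quantize_at <- function(env, frame_rate = 16, Q = 8)
  quantize_envelope(env, Q = Q, frame_rate = frame_rate)

# small, fast burst model for unit tests
test_model <- function(fs = 64) burst_model(fs = fs, burst_band = c(0.5, 10))

# short-window config so unit tests can run on small records
fast_config <- function(...) asi_config(min_window_sec = 30, ...)
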