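#' Windowed analysis scheme
#'
#' A scheme subdivides a 10-min quiet-sleep epoch into `n_windows`
#' contiguous windows of `window_min` minutes whose per-window index values
#' are averaged.
#'
#' @param window_min window length in minutes.
#' @param n_windows number of windows.
#' @param id optional identifier, default e.g. `"2.5min_x4"`.
#' @return list of class `window_scheme`.
#' @export
window_scheme <- function(window_min, n_windows, id = NULL) {
  stopifnot(window_min > 0, n_windows >= 1)
  if (window_min * n_windows > 10 + 1e-9)
    abort("scheme exceeds a 10-min epoch", "asindex_config_error")
  id <- id %||% sprintf("%gmin_x%d", window_min, n_windows)
  structure(list(id = id, window_min = window_min,
                 n_windows = as.integer(n_windows)),
            class = "window_scheme")
}

#' The five window schemes of the stability grid
#'
#' One 10-min window, the average of four 2.5-min windows, the average of
#' two 5-min windows, the average of two 2.5-min windows, and a single
#' 5-min window.
#'
#' @return named list of [window_scheme()]s.
#' @export
default_schemes <- function() {
  s <- list(window_scheme(10, 1), window_scheme(2.5, 4), window_scheme(5, 2),
            window_scheme(2.5, 2), window_scheme(5, 1))
  names(s) <- vapply(s, `[[`, character(1), "id")
  s
}

#' Split an epoch into scheme windows
#'
#' @param epoch numeric `c(start, end)` in seconds, half-open.
#' @param scheme a [window_scheme()].
#' @return matrix with columns `start`, `end`; `n_windows` contiguous
#'   equal-length windows beginning at the epoch start.
#' @export
split_epoch <- function(epoch, scheme) {
  need <- scheme$window_min * 60 * scheme$n_windows
  if (diff(epoch) < need - 1e-9)
    abort(sprintf("epoch of %.1f s too short for scheme %s (needs %.1f s)",
                  diff(epoch), scheme$id, need), "asindex_epoch_length_error")
  w <- scheme$window_min * 60
  starts <- epoch[1] + (seq_len(scheme$n_windows) - 1) * w
  cbind(start = starts, end = starts + w)
}

# quality policy: a window is rejected outright if it overlaps an annotated
# artifact or contains non-finite samples in the channels under analysis
# (clean manually-selected epochs are the reference condition; no patching)
window_ok <- function(record, window, channels = NULL) {
  ann <- record$annotations
  if (nrow(ann)) {
    art <- ann[ann$tag == "artifact", , drop = FALSE]
    if (nrow(art) && any(art$start < window[2] & art$end > window[1]))
      return(FALSE)
  }
  idx <- sample_indices(window, record$fs, nrow(record$samples))
  cols <- if (is.null(channels)) seq_len(ncol(record$samples)) else channels
  all(is.finite(record$samples[idx, cols]))
}

sample_indices <- function(window, fs, n) {
  lo <- floor(window[1] * fs) + 1L
  hi <- min(n, floor(window[2] * fs))
  lo:hi
}

#' Preprocessed amplitude envelopes for one derivation pair
#'
#' Derives the bipolar signals, preprocesses them and extracts the
#' amplitude envelopes over the whole record once, so that windowed
#' analyses can slice the envelope instead of refiltering each window
#' (quantization stays per-window).
#'
#' @param record an [eeg_record()].
#' @param pair a [derivation_pair()].
#' @param config an [asi_config()].
#' @return list of class `pair_envelopes`: `left`, `right` envelopes and
#'   `frame_rate`.
#' @export
pair_envelopes <- function(record, pair, config = asi_config()) {
  sig <- make_bipolar(record, pair)
  env <- lapply(sig, function(x)
    amplitude_envelope(preprocess_eeg(x, record$fs, config), record$fs,
                       config))
  structure(list(left = env$left, right = env$right,
                 frame_rate = config$frame_rate),
            class = "pair_envelopes")
}

frame_indices <- function(window, frame_rate, n) {
  lo <- floor(window[1] * frame_rate) + 1L
  hi <- min(n, floor(window[2] * frame_rate))
  lo:hi
}

#' Mean windowed ASI over one epoch
#'
#' Splits the epoch according to the scheme, runs the ASI chain on each
#' window of the bipolar pair (envelope sliced per window, quantization
#' computed on the window itself), and averages. In `"strict"` mode any
#' rejected window (annotated artifact or non-finite samples) aborts the
#' epoch; in `"tolerant"` mode the mean is taken over surviving windows and
#' the rejection count reported.
#'
#' @param record an [eeg_record()].
#' @param pair a [derivation_pair()].
#' @param epoch `c(start, end)` seconds.
#' @param scheme a [window_scheme()].
#' @param config an [asi_config()].
#' @param mode `"strict"` (default) or `"tolerant"` window-rejection mode.
#' @param envelopes optional precomputed [pair_envelopes()] for this
#'   record/pair, to avoid refiltering across schemes.
#' @return list: `mean`, per-window `values`, the `windows` matrix, and
#'   `n_rejected`.
#' @export
windowed_asi_mean <- function(record, pair, epoch, scheme,
                              config = asi_config(),
                              mode = c("strict", "tolerant"),
                              envelopes = NULL) {
  mode <- match.arg(mode)
  windows <- split_epoch(epoch, scheme)
  if (is.null(envelopes)) envelopes <- pair_envelopes(record, pair, config)
  fr <- envelopes$frame_rate
  chans <- intersect(c(pair$left, pair$right), record$labels)
  values <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (!window_ok(record, w, chans)) {
      if (mode == "strict")
        abort(sprintf("window [%g, %g) rejected by quality policy", w[1], w[2]),
              "asindex_quality_error")
      next
    }
    idx <- frame_indices(w, fr, length(envelopes$left))
    qa <- quantize_envelope(envelopes$left[idx], config)
    qb <- quantize_envelope(envelopes$right[idx], config)
    values[i] <- compute_asi(qa, qb, config, pair = pair, window = w)$asi
  }
  n_rej <- sum(is.na(values))
  if (n_rej == nrow(windows))
    abort("all windows rejected", "asindex_quality_error")
  if (n_rej > 0)
    message(sprintf("%d window(s) rejected; mean over %d surviving window(s)",
                    n_rej, nrow(windows) - n_rej))
  list(mean = mean(values, na.rm = TRUE), values = values,
       windows = windows, n_rejected = n_rej)
}

# locate the two analysis epochs from quiet-sleep annotations
qs_epochs <- function(record, qs_tags = c("QS1", "QS2")) {
  ann <- record$annotations
  out <- lapply(qs_tags, function(tag) {
    row <- ann[ann$tag == tag, , drop = FALSE]
    if (nrow(row) != 1)
      abort(paste0("record lacks a unique annotation tagged ", tag),
            "asindex_annotation_error")
    c(row$start, row$end)
  })
  names(out) <- qs_tags
  out
}

#' Per-subject windowed ASI summary for both quiet-sleep epochs
#'
#' Computes the epoch-mean ASI (and per-window values) for each requested
#' scheme over the two annotated 10-min quiet-sleep epochs of one record.
#'
#' @param record an [eeg_record()] with `QS1`/`QS2` annotations.
#' @param pair a [derivation_pair()].
#' @param schemes list of [window_scheme()]s.
#' @param config an [asi_config()].
#' @param qs_tags annotation tags of the two epochs.
#' @inheritParams windowed_asi_mean
#' @param subject_id,group,pma metadata copied into the summary rows.
#' @return data.frame with one row per scheme: `subject_id`, `pair_id`,
#'   `scheme_id`, `asi_epoch1`, `asi_epoch2`, `group`, `pma`, plus
#'   list-columns `pw1`, `pw2` of per-window values.
#' @export
analyze_record <- function(record, pair, schemes = default_schemes(),
                           config = asi_config(),
                           qs_tags = c("QS1", "QS2"),
                           mode = "strict", subject_id = NA_character_,
                           group = NA_character_, pma = NA_real_) {
  epochs <- qs_epochs(record, qs_tags)
  env <- pair_envelopes(record, pair, config)
  rows <- lapply(schemes, function(sc) {
    e1 <- windowed_asi_mean(record, pair, epochs[[1]], sc, config, mode, env)
    e2 <- windowed_asi_mean(record, pair, epochs[[2]], sc, config, mode, env)
    out <- data.frame(subject_id = subject_id, pair_id = pair$id,
                      scheme_id = sc$id, asi_epoch1 = e1$mean,
                      asi_epoch2 = e2$mean, group = group, pma = pma,
                      stringsAsFactors = FALSE)
    out$pw1 <- list(e1$values); out$pw2 <- list(e2$values)
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Windowed ASI summaries for a whole cohort
#'
#' @param cohort an `asi_cohort` from [generate_cohort()], or a list of
#'   elements each holding `record`, `group`, `pma`, `subject_id`.
#' @inheritParams analyze_record
#' @return row-bound [analyze_record()] data.frame across subjects.
#' @export
analyze_cohort <- function(cohort, pair, schemes = default_schemes(),
                           config = asi_config(), qs_tags = c("QS1", "QS2"),
                           mode = "strict") {
  rows <- lapply(seq_along(cohort), function(i) {
    el <- cohort[[i]]
    analyze_record(el$record, pair, schemes, config, qs_tags, mode,
                   subject_id = el$subject_id %||% sprintf("S%02d", i),
                   group = el$group %||% NA_character_,
                   pma = el$pma %||% NA_real_)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Mean-squared difference between repeated epoch-level ASI estimates
#'
#' The test-retest stability criterion: the average over subjects of the
#' squared difference between the first and second epoch-mean ASI,
#' `MSD = (1/n) * sum_i (ASI_1i - ASI_2i)^2`. Lower is more stable.
#'
#' @param summaries data.frame with columns `asi_epoch1` and `asi_epoch2`
#'   (e.g. one scheme's rows of [analyze_cohort()]), or a 2-column matrix
#'   of the paired estimates.
#' @return non-negative scalar.
#' @export
msd <- function(summaries) {
  if (is.matrix(summaries))
    summaries <- data.frame(asi_epoch1 = summaries[, 1],
                            asi_epoch2 = summaries[, 2])
  if (!all(c("asi_epoch1", "asi_epoch2") %in% names(summaries)))
    abort("summaries must carry asi_epoch1 and asi_epoch2", "asindex_argument_error")
  if (nrow(summaries) < 1)
    abort("at least one subject required", "asindex_argument_error")
  bad <- !is.finite(summaries$asi_epoch1) | !is.finite(summaries$asi_epoch2)
  if (any(bad)) {
    ids <- if ("subject_id" %in% names(summaries))
      paste(summaries$subject_id[bad], collapse = ", ") else
        paste(which(bad), collapse = ", ")
    abort(paste0("incomplete subjects (missing epoch mean): ", ids),
          "asindex_incomplete_subject_error")
  }
  mean((summaries$asi_epoch1 - summaries$asi_epoch2)^2)
}

#' Stability optimization grid over derivation pairs and window schemes
#'
#' Computes the test-retest MSD for every (pair, scheme) cell of a cohort,
#' with row/column mean margins, and reports the most stable cell.
#'
#' @param cohort an `asi_cohort`.
#' @param pairs list of [derivation_pair()]s (default all five).
#' @param schemes list of [window_scheme()]s (default all five).
#' @param config an [asi_config()].
#' @param summaries optional precomputed [analyze_cohort()] results for all
#'   pairs (row-bound), to avoid recomputation.
#' @return list with `grid` (pairs x schemes MSD matrix), `margins`
#'   (`mean_per_pair`, `mean_per_scheme`) and `argmin` (`c(pair, scheme)`).
#' @export
optimization_grid <- function(cohort, pairs = default_pairs(),
                              schemes = default_schemes(),
                              config = asi_config(), summaries = NULL) {
  if (is.null(summaries)) {
    summaries <- do.call(rbind, c(lapply(pairs, function(p)
      analyze_cohort(cohort, p, schemes, config)), make.row.names = FALSE))
  }
  pair_ids <- vapply(pairs, `[[`, character(1), "id")
  scheme_ids <- vapply(schemes, `[[`, character(1), "id")
  grid <- matrix(NA_real_, length(pair_ids), length(scheme_ids),
                 dimnames = list(pair_ids, scheme_ids))
  for (p in pair_ids) for (s in scheme_ids) {
    rows <- summaries[summaries$pair_id == p & summaries$scheme_id == s, ]
    if (nrow(rows)) grid[p, s] <- msd(rows)
  }
  if (anyNA(grid))
    warning("partial grid: margins computed over available cells only",
            call. = FALSE)
  amin <- arrayInd(which.min(grid), dim(grid))
  list(grid = grid,
       margins = list(mean_per_pair = rowMeans(grid, na.rm = TRUE),
                      mean_per_scheme = colMeans(grid, na.rm = TRUE)),
       argmin = c(pair = unname(pair_ids[amin[1]]),
                  scheme = unname(scheme_ids[amin[2]])))
}

#' Compare ASI stability between subsequent and separated quiet-sleep epochs
#'
#' Contrasts the test-retest MSD when both 10-min epochs come from the same
#' quiet-sleep period against epochs from two different periods, with a
#' two-sided Mann-Whitney U test on the per-subject squared differences.
#'
#' @param subsequent,separated [analyze_cohort()]-style data.frames (one
#'   scheme) for the two epoch-selection conditions.
#' @return list: `msd_subsequent`, `msd_separated`, `p_value`, `statistic`
#'   (the Mann-Whitney U of the first condition).
#' @export
epoch_sources_compare <- function(subsequent, separated) {
  if (nrow(subsequent) < 2 || nrow(separated) < 2)
    abort("need at least two subjects per condition", "asindex_statistics_error")
  d_sub <- (subsequent$asi_epoch1 - subsequent$asi_epoch2)^2
  d_sep <- (separated$asi_epoch1 - separated$asi_epoch2)^2
  ut <- mann_whitney_u(d_sub, d_sep)
  list(msd_subsequent = mean(d_sub), msd_separated = mean(d_sep),
       p_value = ut$p_value, statistic = ut$statistic)
}

# two-sided Mann-Whitney U: exact permutation distribution (tie-safe) when
# the enumeration is small, otherwise the normal approximation with tie
# correction via wilcox.test
mann_whitney_u <- function(x, y) {
  u_stat <- function(a, b) {
    tot <- 0
    for (v in a) tot <- tot + sum(v > b) + 0.5 * sum(v == b)
    tot
  }
  u_obs <- u_stat(x, y)
  n1 <- length(x); pooled <- c(x, y); n <- length(pooled)
  if (choose(n, n1) <= 20000) {
    idx <- utils::combn(n, n1)
    us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
    p <- min(1, 2 * min(mean(us <= u_obs + 1e-12),
                        mean(us >= u_obs - 1e-12)))
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                  correct = TRUE)$p.value)
  }
  list(statistic = u_obs, p_value = p)
}
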