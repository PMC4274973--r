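# Minimal EDF/EDF+C support: 16-bit signals, one-second data records, one
# annotations channel carrying TAL (time-stamped annotation list) blocks.

canonical_1020 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                    "Fz", "Cz", "Pz", "Oz", "Fpz", "A1", "A2", "M1", "M2")

#' Normalize an EDF channel label to its canonical 10-20 form
#'
#' Strips vendor prefixes (`"EEG "`), reference suffixes (`"-Ref"`,
#' `"-Cz"`) and case differences, e.g. `"EEG Fp1-Cz"` becomes `"Fp1"`.
#' Labels that do not resolve to a 10-20 electrode pass through trimmed and
#' untouched; they only fail later if a derivation needs them.
#'
#' @param label character vector of raw labels.
#' @return character vector of canonical labels.
#' @export
normalize_channel_label <- function(label) {
  vapply(label, function(x) {
    s <- trimws(x)
    s2 <- sub("^EEG[ _]*", "", s, ignore.case = TRUE)
    s2 <- trimws(sub("-.*$", "", s2))
    hit <- match(tolower(s2), tolower(canonical_1020))
    if (!is.na(hit)) canonical_1020[hit] else s
  }, character(1), USE.NAMES = FALSE)
}

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  sprintf(sprintf("%%-%ds", width), s)
}

num_field <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  pad_field(s, width)
}

#' Write an EEG record to an EDF+C file
#'
#' Signals are stored as 16-bit integers in one-second data records with a
#' symmetric physical range per channel (microvolts); annotations go into
#' an `EDF Annotations` channel as TALs with onset, duration and tag.
#'
#' @param record an [eeg_record()].
#' @param path output file path.
#' @param patient,recording EDF header identification strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path, patient = "X", recording = "X") {
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9)
    abort("EDF writer requires an integer sampling rate", "asindex_format_error")
  fs <- as.integer(round(fs))
  x <- record$samples
  n_rec <- as.integer(ceiling(nrow(x) / fs))
  if (nrow(x) < n_rec * fs)          # zero-pad to whole data records
    x <- rbind(x, matrix(0, n_rec * fs - nrow(x), ncol(x)))
  nchan <- ncol(x)
  # integer physical range so the 8-char header field holds it exactly
  pm <- pmax(ceiling(apply(abs(x), 2, max)), 1)
  dig <- sapply(seq_len(nchan), function(j)
    as.integer(round(x[, j] / pm[j] * 32767)))

  ann <- record$annotations
  tals <- character(0)
  if (nrow(ann))
    tals <- sprintf("+%.6g\x15%.6g\x14%s\x14", ann$start,
                    ann$end - ann$start, ann$tag)
  # each TAL is NUL-terminated; all annotation TALs go into record 1
  payload_raw <- do.call(c, c(list(raw(0)),
                              lapply(tals, function(s)
                                c(charToRaw(s), as.raw(0L)))))
  # annotations channel size: record-start TAL (~24 B) + full payload in
  # the first record, even byte count
  ann_bytes <- max(32L, length(payload_raw) + 32L)
  if (ann_bytes %% 2L) ann_bytes <- ann_bytes + 1L
  ann_ns <- ann_bytes %/% 2L

  ns <- nchan + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L * (ns + 1L), 8), pad_field("EDF+C", 44),
    pad_field(n_rec, 8), pad_field(1L, 8), pad_field(ns, 4)),
    con, eos = NULL)
  labs <- c(record$labels, "EDF Annotations")
  writeChar(paste0(vapply(labs, pad_field, character(1), width = 16),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80L * ns), con, eos = NULL)                 # transducer
  writeChar(paste0(c(rep(pad_field("uV", 8), nchan), pad_field("", 8)),
                   collapse = ""), con, eos = NULL)                 # phys dim
  writeChar(paste0(c(vapply(-pm, num_field, character(1)),
                     num_field(-1)), collapse = ""), con, eos = NULL)
  writeChar(paste0(c(vapply(pm, num_field, character(1)),
                     num_field(1)), collapse = ""), con, eos = NULL)
  # symmetric digital range so the write and read mappings coincide
  writeChar(paste0(rep(pad_field(-32767L, 8), ns), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(rep(pad_field(32767L, 8), ns), collapse = ""), con,
            eos = NULL)
  writeChar(strrep(" ", 80L * ns), con, eos = NULL)                 # prefilter
  writeChar(paste0(c(rep(pad_field(fs, 8), nchan), pad_field(ann_ns, 8)),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 32L * ns), con, eos = NULL)                 # reserved

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(nchan))
      writeBin(dig[idx, j], con, size = 2L, endian = "little")
    raw_chunk <- c(charToRaw(sprintf("+%d\x14\x14", r - 1L)), as.raw(0L))
    if (r == 1L) raw_chunk <- c(raw_chunk, payload_raw)
    raw_chunk <- c(raw_chunk, raw(ann_bytes - length(raw_chunk)))
    writeBin(raw_chunk, con)
  }
  invisible(path)
}

parse_tals <- function(bytes) {
  pieces <- split(bytes, cumsum(bytes == as.raw(0L)))
  out <- list()
  for (p in pieces) {
    p <- p[p != as.raw(0L)]
    if (!length(p)) next
    s <- rawToChar(p)
    fields <- strsplit(s, "\x14", fixed = TRUE)[[1]]
    tags <- fields[-1]
    tags <- tags[nzchar(tags)]
    if (!length(tags)) next                       # record-start time stamp
    timing <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
    onset <- as.numeric(timing[1])
    dur <- if (length(timing) > 1) as.numeric(timing[2]) else 0
    for (tg in tags)
      out[[length(out) + 1L]] <- data.frame(start = onset, end = onset + dur,
                                            tag = tg, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_annotations())
  do.call(rbind, out)
}

#' Read an EDF/EDF+ file into an EEG record
#'
#' Channel labels are normalized to canonical 10-20 form, annotations are
#' mapped to half-open `[start, end)` intervals, and channels with
#' mismatched sampling rates are linearly resampled to the lowest common
#' rate with a warning.
#'
#' @param path EDF file path.
#' @return an [eeg_record()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                "asindex_format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  version <- trimws(rd(8))
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(trimws(rd(8))))
  rd(44)
  n_rec <- suppressWarnings(as.integer(trimws(rd(8))))
  rec_dur <- suppressWarnings(as.numeric(trimws(rd(8))))
  ns <- suppressWarnings(as.integer(trimws(rd(4))))
  if (is.na(ns) || is.na(n_rec) || is.na(rec_dur) || version != "0" ||
      is.na(hdr_bytes) || hdr_bytes != 256L * (ns + 1L))
    abort("unparseable EDF header", "asindex_format_error")
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8)); fld(32)

  is_ann <- labels == "EDF Annotations"
  sig <- which(!is_ann)
  data <- lapply(seq_len(ns), function(i)
    if (is_ann[i]) raw(0) else numeric(n_rec * nsamp[i]))
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", nsamp[i] * 2L))
      } else {
        d <- readBin(con, "integer", nsamp[i], size = 2L, signed = TRUE,
                     endian = "little")
        data[[i]][((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <- d
      }
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in sig)
    data[[i]] <- phys_min[i] + (data[[i]] - dig_min[i]) * gain[i]

  rates <- nsamp[sig] / rec_dur
  fs <- min(rates)
  if (length(unique(rates)) > 1) {
    warning("mismatched per-channel rates; resampling to the minimum common rate",
            call. = FALSE)
    n_out <- as.integer(round(n_rec * rec_dur * fs))
    t_out <- (seq_len(n_out) - 1) / fs
    for (k in seq_along(sig)) {
      i <- sig[k]
      t_in <- (seq_along(data[[i]]) - 1) / rates[k]
      data[[i]] <- approx(t_in, data[[i]], xout = t_out, rule = 2)$y
    }
  }
  samples <- do.call(cbind, data[sig])
  colnames(samples) <- normalize_channel_label(labels[sig])
  eeg_record(samples, fs, annotations = parse_tals(ann_raw))
}

#' Write a synthetic cohort as EDF files with ground-truth sidecars
#'
#' Each subject becomes `<id>.edf` plus `<id>.json` holding the group
#' label, postmenstrual age, seed and synchrony-plant parameters.
#'
#' @param cohort an `asi_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return character vector of EDF paths, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(cohort, "spec")
  paths <- vapply(cohort, function(el) {
    p <- file.path(dir, paste0(el$subject_id, ".edf"))
    write_edf(el$record, p, patient = el$subject_id)
    plant <- if (el$group == "normal") spec$plant_normal else spec$plant_abnormal
    jsonlite::write_json(
      list(subject_id = el$subject_id, group = el$group, pma = el$pma,
           seed = el$seed, plant = unclass(plant)),
      sub("\\.edf$", ".json", p), auto_unbox = TRUE, digits = NA)
    p
  }, character(1))
  invisible(paths)
}
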