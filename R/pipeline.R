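#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis. `asi` accepts either
#' an [asi_config()] or a list of overrides for it; the whole object can
#' also be loaded from a YAML file via [load_pipeline_config()].
#'
#' @param pairs list of [derivation_pair()]s analyzed for stability.
#' @param classify_pair id of the pair used for classification
#'   (default the centro-occipital `"C3O1-C4O2"`).
#' @param schemes list of [window_scheme()]s.
#' @param classify_scheme id of the scheme feeding the classifier
#'   (default `"2.5min_x4"`).
#' @param asi an [asi_config()] or list of overrides.
#' @param qs_tags annotation tags of the two quiet-sleep epochs.
#' @param mode window-rejection mode, `"strict"` or `"tolerant"`.
#' @param threshold classification threshold (ASI units).
#' @param seed integer seed for any simulation step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pairs = default_pairs(),
                            classify_pair = "C3O1-C4O2",
                            schemes = default_schemes(),
                            classify_scheme = "2.5min_x4",
                            asi = asi_config(), qs_tags = c("QS1", "QS2"),
                            mode = "strict", threshold = 3.6, seed = 1L) {
  if (!inherits(asi, "asi_config"))
    asi <- do.call(asi_config, asi)
  structure(list(pairs = pairs, classify_pair = classify_pair,
                 schemes = schemes, classify_scheme = classify_scheme,
                 asi = asi, qs_tags = qs_tags, mode = mode,
                 threshold = threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the `pipeline_config` fields
#'   (`pairs` as lists of two 2-electrode vectors, `schemes` as lists with
#'   `window_min`/`n_windows`).
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$pairs))
    args$pairs <- lapply(y$pairs, function(p)
      derivation_pair(unlist(p$left), unlist(p$right)))
  if (!is.null(y$schemes))
    args$schemes <- lapply(y$schemes, function(s)
      window_scheme(s$window_min, s$n_windows))
  if (!is.null(y$asi)) args$asi <- y$asi
  for (f in c("classify_pair", "classify_scheme", "qs_tags", "mode",
              "threshold", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(args$pairs)) names(args$pairs) <-
    vapply(args$pairs, `[[`, character(1), "id")
  if (!is.null(args$schemes)) names(args$schemes) <-
    vapply(args$schemes, `[[`, character(1), "id")
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(serialize_config(config), tmp)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(config) {
  list(pairs = lapply(unname(config$pairs), function(p)
         list(left = p$left, right = p$right)),
       classify_pair = config$classify_pair,
       schemes = lapply(unname(config$schemes), function(s)
         list(window_min = s$window_min, n_windows = s$n_windows)),
       classify_scheme = config$classify_scheme,
       asi = unclass(config$asi), qs_tags = config$qs_tags,
       mode = config$mode, threshold = config$threshold, seed = config$seed)
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulation (or EDF loading), windowed ASI estimation for every
#' configured pair and scheme, the stability grid, min-of-means threshold
#' classification with ROC, group test and age regression, and a report
#' bundle on disk. Deterministic given the configuration and seeds. Every
#' output carries the configuration hash; a run into a directory whose
#' previous outputs used a different configuration refuses to overwrite
#' unless `overwrite = TRUE`.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param inputs a [cohort_spec()] to simulate, or a character vector of
#'   EDF paths (sidecar `<name>.json` files supply `group`/`pma` metadata
#'   when present).
#' @param out_dir output directory.
#' @param overwrite allow re-running with a changed configuration.
#' @return invisible list: `summaries`, `grid`, `scores`, `classification`,
#'   `roc`, `group_test`, `pma_fit`, `config_hash`.
#' @export
run_pipeline <- function(config, inputs, out_dir, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    if (!identical(prev$config_hash, hash) && !overwrite)
      abort("output directory holds results from a different configuration; set overwrite = TRUE",
            "asindex_overwrite_error")
  }

  if (inherits(inputs, "cohort_spec")) {
    cohort <- generate_cohort(inputs)
  } else if (is.character(inputs)) {
    if (!length(inputs)) abort("empty input list", "asindex_argument_error")
    cohort <- lapply(seq_along(inputs), function(i) {
      rec <- read_edf(inputs[i])
      side <- sub("\\.edf$", ".json", inputs[i])
      meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
      list(record = rec,
           group = meta$group %||% NA_character_,
           pma = meta$pma %||% NA_real_,
           subject_id = meta$subject_id %||%
             tools::file_path_sans_ext(basename(inputs[i])))
    })
  } else abort("inputs must be a cohort_spec or EDF paths",
               "asindex_argument_error")

  summaries <- do.call(rbind, c(lapply(config$pairs, function(p)
    analyze_cohort(cohort, p, config$schemes, config$asi, config$qs_tags,
                   config$mode)), make.row.names = FALSE))
  grid <- optimization_grid(cohort, config$pairs, config$schemes,
                            config$asi, summaries = summaries)

  cls_rows <- summaries[summaries$pair_id == config$classify_pair &
                          summaries$scheme_id == config$classify_scheme, ]
  scores <- data.frame(subject_id = cls_rows$subject_id,
                       asi_class = asi_class(cls_rows$asi_epoch1,
                                             cls_rows$asi_epoch2),
                       group = cls_rows$group, pma = cls_rows$pma,
                       stringsAsFactors = FALSE)
  have_labels <- all(scores$group %in% c("normal", "abnormal"))
  classification <- roc <- group_test <- pma_fit <- NULL
  if (have_labels) {
    classification <- classify_asi(scores$asi_class, scores$group,
                                   config$threshold)
    roc <- tryCatch(asi_roc(scores$asi_class, scores$group),
                    asindex_statistics_error = function(e) NULL)
    # secondary statistics need minimum group sizes; skip them gracefully
    group_test <- tryCatch(
      group_difference_test(scores$asi_class[scores$group == "normal"],
                            scores$asi_class[scores$group == "abnormal"]),
      asindex_statistics_error = function(e) NULL)
    pma_fit <- tryCatch(
      pma_regression(scores$asi_class, scores$pma, scores$group),
      asindex_error = function(e) NULL)
  }

  flat <- summaries[, setdiff(names(summaries), c("pw1", "pw2"))]
  write_stamped_csv(flat, file.path(out_dir, "subjects.csv"), hash)
  grid_df <- data.frame(pair = rownames(grid$grid), grid$grid,
                        mean_msd = grid$margins$mean_per_pair,
                        check.names = FALSE)
  write_stamped_csv(grid_df, file.path(out_dir, "msd_grid.csv"), hash)
  if (have_labels) {
    pred_df <- cbind(scores, predicted = classification$predictions)
    write_stamped_csv(pred_df, file.path(out_dir, "predictions.csv"), hash)
    if (!is.null(roc))
      write_stamped_csv(data.frame(threshold = roc$thresholds,
                                   sensitivity = roc$sensitivity,
                                   specificity = roc$specificity),
                        file.path(out_dir, "roc.csv"), hash)
    jsonlite::write_json(
      list(config_hash = hash, threshold = config$threshold,
           accuracy = classification$accuracy,
           sensitivity = classification$sensitivity,
           specificity = classification$specificity,
           auc = roc$auc %||% NA, t_statistic = group_test$statistic %||% NA,
           t_p_value = group_test$p_value %||% NA),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  yaml::write_yaml(serialize_config(config),
                   file.path(out_dir, "resolved_config.yaml"))
  jsonlite::write_json(list(config_hash = hash,
                            n_subjects = length(cohort),
                            files = list.files(out_dir)),
                       manifest_path, auto_unbox = TRUE)

  report <- c(
    sprintf("asindex pipeline report (config %s)", hash),
    sprintf("subjects: %d", length(cohort)),
    sprintf("most stable cell: pair %s, scheme %s (MSD = %.3f)",
            grid$argmin["pair"], grid$argmin["scheme"], min(grid$grid)),
    if (have_labels) c(
      sprintf("classification at ASI <= %.2f: accuracy %.2f%% (%d/%d), sens %.2f, spec %.2f",
              config$threshold, 100 * classification$accuracy,
              length(cohort) - classification$n_misclassified,
              length(cohort), classification$sensitivity,
              classification$specificity),
      if (!is.null(roc)) sprintf("ROC AUC: %.3f", roc$auc),
      if (!is.null(group_test))
        sprintf("group difference (Welch t): t = %.2f, p = %.3g",
                group_test$statistic, group_test$p_value)))
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(summaries = summaries, grid = grid, scores = scores,
                 classification = classification, roc = roc,
                 group_test = group_test, pma_fit = pma_fit,
                 config_hash = hash))
}
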