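# Shared synthetic-cohort study: 31 subjects per cohort (14 tightly
# synchronized normals, 17 abnormals with 8-s burst-onset jitter), two
# 10-min quiet-sleep epochs per subject, centro-occipital derivation.
# Computed once and reused across test files (the heavy part of the suite).

study_pair <- function() default_pairs()[["C3O1-C4O2"]]

run_cohort_seed <- function(seed, schemes = c("2.5min_x4", "10min_x1")) {
  co <- generate_cohort(cohort_spec(seed = seed))
  summ <- analyze_cohort(co, study_pair(), default_schemes()[schemes])
  rows25 <- summ[summ$scheme_id == "2.5min_x4", ]
  out <- list(summ = summ, rows25 = rows25,
              scores = asi_class(rows25$asi_epoch1, rows25$asi_epoch2),
              group = rows25$group, pma = rows25$pma)
  if ("10min_x1" %in% schemes)
    out$rows10 <- summ[summ$scheme_id == "10min_x1", ]
  out
}

cohort_study <- local({
  cache <- NULL
  function(n_seeds = 10) {
    if (is.null(cache)) cache <<- lapply(seq_len(n_seeds), run_cohort_seed)
    cache
  }
})

# additional cohorts used only for the age-dependence null study
pma_extra_study <- local({
  cache <- NULL
  function(seeds = 11:20) {
    if (is.null(cache))
      cache <<- lapply(seeds, run_cohort_seed, schemes = "2.5min_x4")
    cache
  }
})
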