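#' Per-subject classification statistic: minimum of the two epoch means
#'
#' The lower of a subject's two epoch-mean ASI values, representing the
#' lowest synchrony level observed in that subject.
#'
#' @param mean1,mean2 epoch-mean ASI values (vectorized).
#' @return `pmin(mean1, mean2)`.
#' @export
asi_class <- function(mean1, mean2) {
  if (any(!is.finite(mean1)) || any(!is.finite(mean2)))
    abort("both epoch means must be present and finite",
          "asindex_incomplete_subject_error")
  pmin(mean1, mean2)
}

#' Threshold classification of ASI scores
#'
#' Predicts `"abnormal"` when the score is at or below the threshold (low
#' synchrony = abnormal; ties at the threshold are called abnormal, the
#' conservative choice for screening). Abnormal is the positive class for
#' sensitivity.
#'
#' @param scores per-subject classification statistic (see [asi_class()]).
#' @param labels `"normal"`/`"abnormal"` reference labels.
#' @param threshold decision threshold in ASI units (default 3.6, the
#'   clinically proposed operating point).
#' @return list: `predictions`, `accuracy`, `sensitivity`, `specificity`
#'   (NA when a class is absent), `confusion` table, `threshold`,
#'   `n_misclassified`.
#' @export
classify_asi <- function(scores, labels, threshold = 3.6) {
  stopifnot(length(scores) == length(labels), threshold >= 0)
  labels <- match.arg(labels, c("normal", "abnormal"), several.ok = TRUE)
  pred <- ifelse(scores <= threshold, "abnormal", "normal")
  tp <- sum(pred == "abnormal" & labels == "abnormal")
  tn <- sum(pred == "normal" & labels == "normal")
  n_ab <- sum(labels == "abnormal"); n_no <- sum(labels == "normal")
  conf <- table(predicted = factor(pred, c("abnormal", "normal")),
                reference = factor(labels, c("abnormal", "normal")))
  list(predictions = pred,
       accuracy = (tp + tn) / length(labels),
       sensitivity = if (n_ab) tp / n_ab else NA_real_,
       specificity = if (n_no) tn / n_no else NA_real_,
       confusion = conf, threshold = threshold,
       n_misclassified = length(labels) - tp - tn)
}

#' ROC curve for ASI-based classification
#'
#' Staircase ROC over all distinct score cut points, with low scores
#' indicating the positive (abnormal) class; tied scores form a single
#' threshold step. The trapezoid AUC equals the Mann-Whitney U statistic
#' normalized by `n1 * n2` (ties counted 1/2).
#'
#' @inheritParams classify_asi
#' @return list of class `asi_roc`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, group sizes.
#' @export
asi_roc <- function(scores, labels) {
  labels <- match.arg(labels, c("normal", "abnormal"), several.ok = TRUE)
  ab <- scores[labels == "abnormal"]; no <- scores[labels == "normal"]
  if (!length(ab) || !length(no))
    abort("both classes must be present", "asindex_statistics_error")
  ths <- sort(unique(scores))
  sens <- vapply(ths, function(t) mean(ab <= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(no <= t), numeric(1))
  # trapezoid over the staircase including the (0,0) and (1,1) anchors
  x <- c(0, fpr, 1); y <- c(0, sens, 1)
  auc <- sum(diff(x) * (head2(y) + y[-1]) / 2)
  structure(list(thresholds = ths, sensitivity = sens,
                 specificity = 1 - fpr, auc = auc,
                 n_abnormal = length(ab), n_normal = length(no)),
            class = "asi_roc")
}

head2 <- function(x) x[-length(x)]

#' @export
print.asi_roc <- function(x, ...) {
  cat(sprintf("<asi_roc> AUC = %.3f (%d abnormal vs %d normal, %d cut points)\n",
              x$auc, x$n_abnormal, x$n_normal, length(x$thresholds)))
  invisible(x)
}

#' Threshold maximizing Youden's J
#'
#' @param roc an [asi_roc()] result.
#' @return list: `threshold` (score value; classification uses `<=`),
#'   `youden_j`, `sensitivity`, `specificity` at that point.
#' @export
youden_threshold <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  i <- which.max(j)
  list(threshold = roc$thresholds[i], youden_j = j[i],
       sensitivity = roc$sensitivity[i], specificity = roc$specificity[i])
}

# per-subject score for one (budget, window length, combine rule) regime,
# from an analyze_cohort() data.frame holding that window length's scheme
regime_scores <- function(rows, budget_min, window_min, rule) {
  per_epoch_k <- max(1L, as.integer(round(min(budget_min, 10) / window_min)))
  m1 <- vapply(rows$pw1, function(v) mean(v[seq_len(per_epoch_k)]), numeric(1))
  if (budget_min > 10) {
    m2 <- vapply(rows$pw2, function(v) mean(v[seq_len(per_epoch_k)]), numeric(1))
    switch(rule, mean = (m1 + m2) / 2, min = pmin(m1, m2), max = pmax(m1, m2))
  } else m1
}

#' Classification performance across data-budget regimes
#'
#' Evaluates ROC/AUC for every combination of total EEG budget, analysis
#' window length and epoch-combination rule, mirroring the question of how
#' much classification degrades when less clean EEG is available. Budgets
#' of at most 10 min draw windows from the first epoch only; the 20-min
#' budget combines the two epoch means with the rule.
#'
#' @param summaries [analyze_cohort()] results containing, for each window
#'   length, the scheme with the maximal number of windows (2.5min_x4,
#'   5min_x2, 10min_x1).
#' @param budgets total EEG lengths in minutes (default 5, 10, 20).
#' @param window_lengths ASI window lengths in minutes (default 2.5, 5, 10).
#' @param rules epoch combination rules (default mean, min, max).
#' @return data.frame with one row per realizable regime: `budget_min`,
#'   `window_min`, `rule`, `auc`; ROC objects in attribute `"rocs"`.
#'   Unrealizable combinations (window longer than budget) are skipped
#'   with a warning.
#' @export
data_budget_study <- function(summaries, budgets = c(5, 10, 20),
                              window_lengths = c(2.5, 5, 10),
                              rules = c("mean", "min", "max")) {
  scheme_of <- c("2.5" = "2.5min_x4", "5" = "5min_x2", "10" = "10min_x1")
  out <- list(); rocs <- list(); skipped <- 0L
  for (b in budgets) for (w in window_lengths) {
    if (w > min(b, 10)) { skipped <- skipped + 1L; next }
    rows <- summaries[summaries$scheme_id == scheme_of[[as.character(w)]], ]
    if (!nrow(rows))
      abort(sprintf("summaries lack scheme %s", scheme_of[[as.character(w)]]),
            "asindex_argument_error")
    for (r in rules) {
      sc <- regime_scores(rows, b, w, r)
      roc <- asi_roc(sc, rows$group)
      key <- sprintf("b%g_w%g_%s", b, w, r)
      rocs[[key]] <- roc
      out[[key]] <- data.frame(budget_min = b, window_min = w, rule = r,
                               auc = roc$auc, stringsAsFactors = FALSE)
    }
  }
  if (skipped)
    warning(sprintf("%d regime(s) skipped (window exceeds budget)", skipped),
            call. = FALSE)
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "rocs") <- rocs
  res
}

#' Welch two-sample t-test between group ASI scores
#'
#' @param normal,abnormal numeric score vectors (n >= 2 each).
#' @return list: `statistic` (t), `df`, `p_value`, group means.
#' @export
group_difference_test <- function(normal, abnormal) {
  if (length(normal) < 2 || length(abnormal) < 2)
    abort("need n >= 2 per group", "asindex_statistics_error")
  if (sd(normal) == 0 && sd(abnormal) == 0) {
    same <- isTRUE(all.equal(mean(normal), mean(abnormal)))
    return(list(statistic = if (same) 0 else sign(mean(normal) - mean(abnormal)) * Inf,
                df = NA_real_, p_value = if (same) 1 else 0,
                mean_normal = mean(normal), mean_abnormal = mean(abnormal)))
  }
  tt <- t.test(normal, abnormal, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_normal = mean(normal),
       mean_abnormal = mean(abnormal))
}

#' Age dependence of the classification statistic
#'
#' Ordinary least-squares regression of the per-subject score on
#' postmenstrual age, per group and pooled — the check that the index
#' needs no age correction near term.
#'
#' @param scores per-subject classification statistic.
#' @param pma postmenstrual ages, weeks.
#' @param group optional `"normal"`/`"abnormal"` labels; per-group fits
#'   are added when given.
#' @param conf_level confidence level of the slope CI (default 0.95).
#' @return data.frame with one row per fit (`pooled`, then each group):
#'   `slope`, `intercept`, `r`, `p_value`, `ci_lo`, `ci_hi`, `n`.
#' @export
pma_regression <- function(scores, pma, group = NULL, conf_level = 0.95) {
  if (length(unique(pma)) < 2)
    abort("PMA range is degenerate", "asindex_argument_error")
  fit_one <- function(s, a, label) {
    if (length(s) < 3)
      abort("need n >= 3 for regression", "asindex_statistics_error")
    fit <- lm(s ~ a)
    ci <- confint(fit, "a", level = conf_level)
    sm <- summary(fit)
    data.frame(fit = label, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), r = cor(a, s),
               p_value = sm$coefficients[2, 4],
               ci_lo = ci[1], ci_hi = ci[2], n = length(s),
               stringsAsFactors = FALSE)
  }
  out <- fit_one(scores, pma, "pooled")
  if (!is.null(group)) {
    for (g in unique(group))
      out <- rbind(out, fit_one(scores[group == g], pma[group == g], g))
  }
  rownames(out) <- NULL
  out
}
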