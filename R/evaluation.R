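#' Draw leave-individuals-out train/test split plans
#'
#' Each run samples `n_train` individuals without replacement for training
#' and leaves the remainder for testing (8 of 12 by default, i.e. 67%/33% of
#' individuals). Runs are independent draws, so repeated partitions are
#' possible and allowed.
#'
#' @param individuals Character vector of individual ids.
#' @param n_train Number of training individuals per run.
#' @param n_runs Number of runs.
#' @param seed Integer seed controlling the whole plan sequence.
#' @return A list of class `split_plan`; each element has `run_id`, `train`
#'   and `test`.
#' @export
make_splits <- function(individuals, n_train = 8, n_runs = 100, seed = 1L) {
  individuals <- unique(as.character(individuals))
  if (n_train >= length(individuals))
    stop(sprintf("n_train (%d) must be smaller than the number of individuals (%d)",
                 n_train, length(individuals)))
  set.seed(seed)
  plans <- lapply(seq_len(n_runs), function(r) {
    tr <- sort(sample(individuals, n_train))
    list(run_id = r, train = tr, test = sort(setdiff(individuals, tr)))
  })
  structure(plans, class = "split_plan", seed = seed)
}

#' Rank-based area under the ROC curve
#'
#' AUC computed from the score ranking via the Mann-Whitney identity; tied
#' scores contribute 1/2 through midranks.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Logical (or 0/1) class labels.
#' @return AUC in [0, 1], or `NA` with a warning if only one class is
#'   present.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Youden-optimal threshold on (scores, labels): maximizes sens + spec - 1
# over the observed scores; positives are predicted at score >= threshold.
.youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1
  }, 0)
  cand[which.max(j)]
}

#' Classification accuracy measures for buzz predictions
#'
#' Segments are labelled positive when at least one buzz was observed; the
#' score for segment-level presence is the model-implied probability of one
#' or more buzzes, `1 - exp(-lambda)`. AUC uses the full score ranking
#' ([auc_rank()]); sensitivity (presences correctly predicted), specificity
#' (absences correctly predicted) and precision (true positives over
#' predicted positives) are computed at a single operating threshold,
#' chosen on training data by Youden's J by default or fixed at probability
#' 0.5.
#'
#' @param observed Observed buzz counts on the evaluation segments.
#' @param lambda Predicted mean counts on the evaluation segments.
#' @param rule Threshold rule: `"youden"` (chosen on the training data) or
#'   `"fixed"` (probability 0.5).
#' @param train_observed,train_lambda Training counts and predictions used
#'   to pick the Youden threshold; when omitted, the evaluation data are
#'   used (apparent performance).
#' @param threshold Optional explicit threshold on the probability score,
#'   overriding `rule`.
#' @return A list: `auc`, `sensitivity`, `specificity`, `precision`,
#'   `threshold`, and the `confusion` counts (tp, fp, tn, fn).
#' @export
accuracy_measures <- function(observed, lambda,
                              rule = c("youden", "fixed"),
                              train_observed = NULL, train_lambda = NULL,
                              threshold = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(observed) == length(lambda))
  labels <- observed >= 1
  score <- 1 - exp(-lambda)
  if (is.null(threshold)) {
    threshold <- if (rule == "fixed") {
      0.5
    } else if (!is.null(train_observed)) {
      .youden_threshold(1 - exp(-train_lambda), train_observed >= 1)
    } else {
      .youden_threshold(score, labels)
    }
  }
  auc <- auc_rank(score, labels)
  pred <- score >= threshold
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels)
  fn <- sum(!pred & labels)
  list(auc = auc,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       threshold = threshold,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Cross-validated sensitivity analysis of a buzz model
#'
#' For every split plan: refits the model on the training individuals'
#' segments, predicts held-out individuals at the population level (random
#' intercept 0), picks the operating threshold on the training data, and
#' computes the four accuracy measures on the pooled test segments, plus the
#' Wald p value of each predictor. Runs whose fit fails (or whose test set
#' is single-class, leaving AUC undefined) are recorded and excluded from
#' the medians.
#'
#' @param metric_table Segment metric table.
#' @param predictors Character vector of predictor metric names.
#' @param splits A [make_splits()] plan.
#' @param response Response column (buzz counts).
#' @param group Grouping column (individual id).
#' @param rule Threshold rule, see [accuracy_measures()].
#' @param p_cutoff Significance level used for the per-predictor tally
#'   across runs.
#' @param nagq Passed to [buzz_glmm()].
#' @return A list of class `sensitivity_analysis`: `per_run` (one row per
#'   successful run: measures, threshold and per-predictor p values),
#'   `summary` (median and SD of each measure), `significance` (per
#'   predictor, the number of runs with p < `p_cutoff` and the number of
#'   runs), `n_failed`, and `failures` (messages).
#' @export
sensitivity_analysis <- function(metric_table, predictors, splits,
                                 response = "buzz_count",
                                 group = "individual_id",
                                 rule = c("youden", "fixed"),
                                 p_cutoff = 0.01, nagq = 1L) {
  rule <- match.arg(rule)
  stopifnot(inherits(splits, "split_plan"), length(predictors) >= 1)
  f <- stats::reformulate(predictors, response)
  rows <- list()
  failures <- character()
  for (plan in splits) {
    res <- tryCatch({
      tr <- metric_table[metric_table[[group]] %in% plan$train, ,
                         drop = FALSE]
      te <- metric_table[metric_table[[group]] %in% plan$test, ,
                         drop = FALSE]
      if (!nrow(tr) || !nrow(te))
        stop("empty train or test set")
      m <- buzz_glmm(f, tr, group = group, nagq = nagq)
      lam_tr <- predict(m, tr, type = "lambda")
      lam_te <- predict(m, te, type = "lambda")
      acc <- accuracy_measures(te[[response]], lam_te, rule = rule,
                               train_observed = tr[[response]],
                               train_lambda = lam_tr)
      pv <- stats::setNames(rep(NA_real_, length(predictors)), predictors)
      present <- intersect(predictors, rownames(m$coefficients))
      pv[present] <- m$coefficients[present, "p value"]
      row <- data.frame(run_id = plan$run_id, auc = acc$auc,
                        sensitivity = acc$sensitivity,
                        specificity = acc$specificity,
                        precision = acc$precision,
                        threshold = acc$threshold)
      for (p in predictors)
        row[[paste0("p_", p)]] <- pv[p]
      row
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures,
                    sprintf("run %d: %s", plan$run_id, res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  per_run <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run_id = integer(), auc = numeric(),
               sensitivity = numeric(), specificity = numeric(),
               precision = numeric(), threshold = numeric())
  measures <- c("auc", "sensitivity", "specificity", "precision")
  summary <- data.frame(
    measure = measures,
    median = vapply(measures, function(m)
      stats::median(per_run[[m]], na.rm = TRUE), 0),
    sd = vapply(measures, function(m)
      stats::sd(per_run[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  signif_tab <- data.frame(
    predictor = predictors,
    n_significant = vapply(predictors, function(p) {
      pv <- per_run[[paste0("p_", p)]]
      if (is.null(pv)) 0L else sum(pv < p_cutoff, na.rm = TRUE)
    }, 0L),
    n_runs = nrow(per_run), row.names = NULL)
  structure(list(per_run = per_run, summary = summary,
                 significance = signif_tab,
                 n_failed = length(failures), failures = failures,
                 rule = rule, predictors = predictors),
            class = "sensitivity_analysis")
}

#' @export
print.sensitivity_analysis <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %d successful runs, %d failed (%s threshold)\n",
              nrow(x$per_run), x$n_failed, x$rule))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %.2f (%.2f)\n", s$measure[i], s$median[i], s$sd[i]))
  cat("  runs significant (p < 0.01):\n")
  for (i in seq_len(nrow(x$significance)))
    cat(sprintf("    %-30s %d/%d\n", x$significance$predictor[i],
                x$significance$n_significant[i], x$significance$n_runs[i]))
  invisible(x)
}

#' Per-dive accounting of observed versus predicted buzzes
#'
#' Aggregates per-segment observed and predicted (rounded) buzz counts to
#' the dive level: total observed, total predicted, absolute difference and
#' percentage difference `100 * |obs - pred| / obs` (undefined and reported
#' as `NA` when a dive has no observed buzzes). Also tallies, per segment,
#' exact, over- and under-predictions.
#'
#' @param segments Data frame with `individual_id`, `dive_id`, observed
#'   counts and predictions.
#' @param observed Column name of observed counts.
#' @param predicted Column name of predicted counts (rounded to integers
#'   internally).
#' @return A list: `per_dive` (one row per dive), `segment_tally` (counts of
#'   exact/over/under segments), and `summary` (medians and SDs across dives
#'   of absolute difference, percentage difference, observed buzzes per dive
#'   and segments per dive).
#' @export
dive_level_accounting <- function(segments, observed = "buzz_count",
                                  predicted = "predicted_count") {
  stopifnot(all(c("individual_id", "dive_id", observed, predicted) %in%
                  names(segments)))
  obs <- segments[[observed]]
  pred <- round(segments[[predicted]])
  key <- interaction(segments$individual_id, segments$dive_id, drop = TRUE)
  per_dive <- data.frame(
    individual_id = tapply(as.character(segments$individual_id), key,
                           `[`, 1),
    dive_id = tapply(segments$dive_id, key, `[`, 1),
    n_segments = as.integer(tapply(obs, key, length)),
    observed = as.numeric(tapply(obs, key, sum)),
    predicted = as.numeric(tapply(pred, key, sum)))
  per_dive$abs_difference <- abs(per_dive$observed - per_dive$predicted)
  per_dive$pct_difference <- ifelse(per_dive$observed > 0,
                                    100 * per_dive$abs_difference /
                                      per_dive$observed, NA_real_)
  rownames(per_dive) <- NULL
  segment_tally <- c(exact = sum(pred == obs),
                     over = sum(pred > obs),
                     under = sum(pred < obs))
  med_sd <- function(x) c(median = stats::median(x, na.rm = TRUE),
                          sd = stats::sd(x, na.rm = TRUE))
  summary <- rbind(abs_difference = med_sd(per_dive$abs_difference),
                   pct_difference = med_sd(per_dive$pct_difference),
                   observed_per_dive = med_sd(per_dive$observed),
                   segments_per_dive = med_sd(per_dive$n_segments))
  list(per_dive = per_dive, segment_tally = segment_tally,
       summary = as.data.frame(summary))
}

#' Compare models on all dive data versus bottom-phase segments only
#'
#' Runs the same cross-validated sensitivity analysis twice with identical
#' split plans: once on all segments and once restricted to segments whose
#' phase label is `bottom`. Pairing by run id makes the accuracy measures
#' directly comparable; bottom-only runs that fail (e.g. single-class test
#' sets once descent/ascent absences are removed) are recorded in that
#' report's failure log.
#'
#' @inheritParams sensitivity_analysis
#' @return A list with elements `all_data` and `bottom_only`, each a
#'   [sensitivity_analysis()] report.
#' @export
bottom_phase_comparison <- function(metric_table, predictors, splits,
                                    response = "buzz_count",
                                    group = "individual_id",
                                    rule = c("youden", "fixed"),
                                    p_cutoff = 0.01, nagq = 1L) {
  rule <- match.arg(rule)
  stopifnot("phase" %in% names(metric_table))
  all_data <- sensitivity_analysis(metric_table, predictors, splits,
                                   response, group, rule, p_cutoff, nagq)
  bottom <- metric_table[metric_table$phase == "bottom", , drop = FALSE]
  bottom_only <- sensitivity_analysis(bottom, predictors, splits,
                                      response, group, rule, p_cutoff, nagq)
  list(all_data = all_data, bottom_only = bottom_only)
}
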