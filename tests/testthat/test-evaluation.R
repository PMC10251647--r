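test_that("split plans are disjoint, exhaustive and reproducible", {
  ids <- sprintf("w%02d", 1:12)
  s1 <- make_splits(ids, n_train = 8, n_runs = 20, seed = 5)
  s2 <- make_splits(ids, n_train = 8, n_runs = 20, seed = 5)
  expect_length(s1, 20)
  for (k in seq_along(s1)) {
    expect_length(s1[[k]]$test, 4)
    expect_length(intersect(s1[[k]]$train, s1[[k]]$test), 0)
    expect_setequal(c(s1[[k]]$train, s1[[k]]$test), ids)
    expect_identical(s1[[k]], s2[[k]])
  }
  expect_error(make_splits(ids, n_train = 12), "smaller")
})

test_that("test-set membership frequency matches the sampling design", {
  ids <- sprintf("w%02d", 1:12)
  splits <- make_splits(ids, n_train = 8, n_runs = 1000, seed = 9)
  counts <- table(unlist(lapply(splits, `[[`, "test")))
  # each individual is in the test set with probability 4/12
  p <- 4 / 12
  se <- sqrt(p * (1 - p) * 1000)
  expect_true(all(abs(counts - 1000 * p) < 4 * se))
})

test_that("accuracy measures handle separation, ties and one-class inputs", {
  perfect <- accuracy_measures(observed = c(0, 0, 1, 2),
                               lambda = c(0.01, 0.02, 3, 4))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$precision, 1)

  tied <- accuracy_measures(observed = c(0, 1, 0, 1), lambda = rep(1, 4))
  expect_equal(tied$auc, 0.5)

  expect_warning(one <- accuracy_measures(observed = c(1, 2, 3),
                                          lambda = 1:3), "one class")
  expect_true(is.na(one$auc))
})

test_that("rank AUC equals the pairwise-comparison oracle", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    scores <- sample(round(runif(n, 0, 1), sample(c(1, 2), 1)))  # force ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(auc_rank(scores, labels), auc_pairwise(scores, labels))
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:20) {
    scores <- runif(50)
    labels <- runif(50) < 0.4
    if (!any(labels) || all(labels)) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_rank(scores, labels), ref)
  }
})

test_that("confusion identities hold at the chosen threshold", {
  set.seed(29)
  obs <- rpois(200, 0.8)
  lam <- exp(rnorm(200, log(0.8), 0.6))
  acc <- accuracy_measures(obs, lam)
  cm <- acc$confusion
  expect_equal(sum(cm), 200)
  expect_equal(acc$sensitivity, cm["tp"] / (cm["tp"] + cm["fn"]),
               ignore_attr = TRUE)
  expect_equal(acc$specificity, cm["tn"] / (cm["tn"] + cm["fp"]),
               ignore_attr = TRUE)
  expect_equal(acc$precision, cm["tp"] / (cm["tp"] + cm["fp"]),
               ignore_attr = TRUE)
})

test_that("a single-run sensitivity analysis reports that run's values", {
  dep <- simulate_deployment(small_sim(33, n_individuals = 6))
  mt <- deployment_segments(dep, 180)
  splits <- make_splits(unique(mt$individual_id), n_train = 4, n_runs = 1,
                        seed = 2)
  sa <- suppressWarnings(
    sensitivity_analysis(mt, c("average_depth", "variance_depth"), splits))
  expect_equal(nrow(sa$per_run), 1)
  expect_equal(sa$summary$median[sa$summary$measure == "auc"],
               sa$per_run$auc)
  expect_equal(sa$summary$sd[sa$summary$measure == "auc"], NA_real_)
})

test_that("dive accounting conserves totals and tallies segments", {
  segs <- data.frame(individual_id = "w1", dive_id = 1,
                     buzz_count = c(3, 2, 0), predicted_count = c(2, 2, 1))
  acct <- dive_level_accounting(segs)
  expect_equal(acct$per_dive$abs_difference, 0)
  expect_equal(unname(acct$segment_tally), c(1, 1, 1))  # exact, over, under

  perfect <- data.frame(individual_id = rep(c("a", "b"), each = 3),
                        dive_id = rep(1:2, 3), buzz_count = 0:5,
                        predicted_count = 0:5)
  pacct <- dive_level_accounting(perfect)
  expect_true(all(pacct$per_dive$abs_difference == 0))
  expect_equal(sum(pacct$per_dive$observed), sum(perfect$buzz_count))

  # percentage difference undefined for dives without observed buzzes
  none <- data.frame(individual_id = "w", dive_id = 1,
                     buzz_count = c(0, 0), predicted_count = c(1, 0))
  expect_true(is.na(dive_level_accounting(none)$per_dive$pct_difference))
})

test_that("per-dive medians computed two ways coincide", {
  dep <- simulate_deployment(small_sim(37))
  mt <- deployment_segments(dep, 180)
  m <- buzz_glmm(buzz_count ~ average_depth + variance_depth +
                   variance_vertical_velocity, mt)
  mt$predicted_count <- predict(m, mt, type = "count")
  acct <- dive_level_accounting(mt)
  # independent loop
  loop <- c()
  for (id in unique(mt$individual_id)) {
    for (dv in unique(mt$dive_id[mt$individual_id == id])) {
      sub <- mt[mt$individual_id == id & mt$dive_id == dv, ]
      loop <- c(loop, abs(sum(sub$buzz_count) -
                            sum(round(sub$predicted_count))))
    }
  }
  expect_equal(sort(acct$per_dive$abs_difference), sort(loop))
  expect_equal(acct$summary["abs_difference", "median"], median(loop))
  # conservation across the accounting
  expect_equal(sum(acct$per_dive$observed), sum(mt$buzz_count))
})

test_that("bottom-only comparison pairs runs and degrades gracefully", {
  dep <- simulate_deployment(small_sim(43, n_individuals = 6))
  mt <- deployment_segments(dep, 180)
  splits <- make_splits(unique(mt$individual_id), n_train = 4, n_runs = 4,
                        seed = 3)
  cmp <- suppressWarnings(
    bottom_phase_comparison(mt, c("average_depth",
                                  "variance_vertical_velocity"), splits))
  ok <- intersect(cmp$all_data$per_run$run_id,
                  cmp$bottom_only$per_run$run_id)
  expect_true(all(ok %in% 1:4))
  # when every segment is bottom phase the two analyses coincide
  bot <- mt[mt$phase == "bottom", ]
  cmp2 <- suppressWarnings(
    bottom_phase_comparison(bot, c("average_depth",
                                   "variance_vertical_velocity"), splits))
  expect_equal(cmp2$all_data$per_run, cmp2$bottom_only$per_run)
})
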