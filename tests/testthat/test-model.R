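# deterministic segment-style table with a known Poisson structure
make_count_table <- function(n_per_group = 120, groups = 4, seed = 1,
                             beta = c(0.4, 0.5, -0.3), b_sd = 0) {
  set.seed(seed)
  n <- n_per_group * groups
  g <- rep(sprintf("g%02d", 1:groups), each = n_per_group)
  x1 <- rnorm(n, 500, 120)
  x2 <- rnorm(n, 50, 20)
  b <- rnorm(groups, 0, b_sd)
  eta <- beta[1] + beta[2] * scale(x1)[, 1] + beta[3] * scale(x2)[, 1] +
    b[match(g, unique(g))]
  data.frame(individual_id = g, x1 = x1, x2 = x2,
             buzz_count = rpois(n, exp(eta)))
}

test_that("single-group fit equals an independent IRLS Poisson regression", {
  tab <- make_count_table(groups = 1, n_per_group = 400, seed = 2)
  expect_warning(m <- buzz_glmm(buzz_count ~ x1 + x2, tab),
                 "fewer than 2 groups")
  expect_equal(m$sigma2_alpha, 0)
  X <- cbind(1, scale(tab$x1)[, 1], scale(tab$x2)[, 1])
  oracle <- irls_poisson(X, tab$buzz_count)
  expect_equal(unname(coef(m)), oracle, tolerance = 1e-6)
})

test_that("intercept-only model on constant counts recovers log k", {
  tab <- data.frame(individual_id = rep(c("a", "b"), each = 30),
                    buzz_count = 3)
  m <- buzz_glmm(buzz_count ~ 1, tab)
  expect_equal(unname(coef(m)["(Intercept)"]), log(3), tolerance = 1e-5)
  expect_equal(m$sigma2_alpha, 0, tolerance = 1e-6)
})

test_that("AIC equals -2 logLik + 2 (fixed parameters + variance)", {
  tab <- make_count_table(seed = 3, b_sd = 0.3)
  m <- buzz_glmm(buzz_count ~ x1 + x2, tab)
  k <- nrow(m$coefficients) + 1  # + random-intercept variance
  expect_equal(m$aic, -2 * m$logLik + 2 * k)
  expect_equal(AIC(logLik(m)), m$aic)

  tab1 <- make_count_table(groups = 1, seed = 3)
  m1 <- suppressWarnings(buzz_glmm(buzz_count ~ x1 + x2, tab1))
  expect_equal(m1$aic, -2 * m1$logLik + 2 * nrow(m1$coefficients))
})

test_that("standardization uses training statistics only", {
  tab <- make_count_table(seed = 4)
  m <- buzz_glmm(buzz_count ~ x1 + x2, tab)
  expect_equal(unname(m$standardization$center["x1"]), mean(tab$x1))
  # a shifted test set keeps a nonzero standardized mean
  shifted <- tab
  shifted$x1 <- shifted$x1 + 200
  eta <- predict(m, shifted, type = "link")
  eta0 <- predict(m, tab, type = "link")
  expect_equal(mean(eta - eta0),
               unname(coef(m)["x1"] * 200 / m$standardization$scale["x1"]),
               tolerance = 1e-10)
  # zero-variance predictor is dropped with a warning
  tab$flat <- 5
  expect_warning(mz <- buzz_glmm(buzz_count ~ x1 + flat, tab),
                 "zero-variance")
  expect_false("flat" %in% mz$predictors)
})

test_that("constant shifts of a raw predictor do not change the fit", {
  tab <- make_count_table(seed = 5, b_sd = 0.2)
  m1 <- buzz_glmm(buzz_count ~ x1 + x2, tab)
  tab2 <- tab
  tab2$x1 <- tab2$x1 + 1000
  m2 <- buzz_glmm(buzz_count ~ x1 + x2, tab2)
  expect_equal(coef(m1), coef(m2), tolerance = 1e-6)
})

test_that("prediction applies the link and rounds ties to even", {
  tab <- make_count_table(seed = 6)
  m <- buzz_glmm(buzz_count ~ x1 + x2, tab)
  # predictors at the training mean -> lambda = exp(intercept)
  at_mean <- data.frame(x1 = mean(tab$x1), x2 = mean(tab$x2))
  expect_equal(unname(predict(m, at_mean, type = "lambda")),
               exp(unname(coef(m)["(Intercept)"])), tolerance = 1e-12)
  # monotonicity in a positive-coefficient predictor
  lo <- data.frame(x1 = 400, x2 = 50)
  hi <- data.frame(x1 = 700, x2 = 50)
  stopifnot(coef(m)["x1"] > 0)
  expect_gt(predict(m, hi, type = "lambda"),
            predict(m, lo, type = "lambda"))
  expect_error(predict(m, data.frame(x1 = 1)), "x2")
  expect_equal(round(c(0.5, 1.5, 2.5)), c(0, 2, 2))  # documented tie rule
})

test_that("marginal and conditional R2 behave at the boundaries", {
  tab <- make_count_table(groups = 1, seed = 7)
  m <- suppressWarnings(buzz_glmm(buzz_count ~ x1 + x2, tab))
  expect_equal(m$r2[["marginal"]], m$r2[["conditional"]])  # sigma2 = 0

  m0 <- buzz_glmm(buzz_count ~ 1, make_count_table(seed = 8, b_sd = 0.3))
  expect_equal(m0$r2[["marginal"]], 0)
  expect_gte(m0$r2[["conditional"]], m0$r2[["marginal"]])

  mt <- make_count_table(seed = 9, b_sd = 0.3)
  mm <- buzz_glmm(buzz_count ~ x1 + x2, mt)
  expect_true(all(mm$r2 >= 0 & mm$r2 <= 1))
  expect_lte(mm$r2[["marginal"]], mm$r2[["conditional"]])
  # the trigamma variant gives the same ordering
  r2t <- r_squared(mm, method = "trigamma")
  expect_lte(r2t[["marginal"]], r2t[["conditional"]])
})

test_that("backward selection drops noise and keeps a minimal model", {
  tab <- make_count_table(seed = 10, b_sd = 0.2)
  set.seed(11)
  tab$noise <- rnorm(nrow(tab))
  sel <- backward_select(buzz_count ~ x1 + x2 + noise, tab)
  expect_false("noise" %in% sel$predictors)
  expect_true(all(c("x1", "x2") %in% sel$predictors))
  expect_equal(sel$selection$steps$dropped, "noise")
  expect_lt(sel$selection$steps$aic_after[1],
            sel$selection$steps$aic_before[1])

  # an already-minimal model is returned unchanged
  one <- backward_select(buzz_count ~ x1, tab)
  expect_equal(one$predictors, "x1")
  expect_equal(nrow(one$selection$steps), 0)
})

test_that("simulate and residuals are consistent with the fit", {
  tab <- make_count_table(seed = 12, b_sd = 0.2)
  m <- buzz_glmm(buzz_count ~ x1 + x2, tab)
  r <- residuals(m)
  expect_equal(r, tab$buzz_count - m$fitted_lambda)
  sims <- simulate(m, nsim = 20, seed = 1)
  expect_equal(dim(sims), c(nrow(tab), 20))
  # simulated totals straddle the fitted total
  tot <- colSums(sims)
  expect_gt(max(tot), sum(m$fitted_lambda) - 3 * sqrt(sum(m$fitted_lambda)))
  expect_lt(min(tot), sum(m$fitted_lambda) + 3 * sqrt(sum(m$fitted_lambda)))
})

test_that("true parameters are recovered from a simulated deployment", {
  cfg <- sim_config(seed = 71)
  dep <- simulate_deployment(cfg)
  tab <- deployment_segments(dep, 180, drop_first = FALSE,
                             foraging_only = FALSE)
  m <- buzz_glmm(buzz_count ~ average_depth + variance_depth +
                   variance_vertical_velocity, tab)
  truth <- cfg$true_coefficients
  est <- coef(m)
  expect_equal(sign(est[c("average_depth", "variance_depth",
                          "variance_vertical_velocity")]),
               sign(truth[c("average_depth", "variance_depth",
                            "variance_vertical_velocity")]),
               ignore_attr = TRUE)
  se <- m$coefficients[, "Std. Error"]
  z <- abs(est[names(truth)[-1]] - truth[-1]) / se[names(truth)[-1]]
  expect_true(all(z < 4))
})
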