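#' Fit a Poisson mixed model of buzz counts per dive segment
#'
#' The modelling core of the package: a generalized linear mixed model with
#' Poisson response and log link relating the number of buzzes (prey-capture
#' attempts) in a dive segment to segment-level dive metrics, with a random
#' intercept per individual to absorb between-whale differences in buzz
#' rate. Predictors are z-scored before fitting (statistics stored in the
#' object and reapplied to any new data), so coefficients are comparable
#' across metrics with very different natural scales. Estimation uses the
#' Laplace approximation via \pkg{lme4}; with a single grouping level the
#' random-intercept variance is unidentifiable and the model collapses to an
#' ordinary Poisson regression with `sigma2_alpha = 0`.
#'
#' @param formula Fixed-effects formula, e.g.
#'   `buzz_count ~ average_depth + variance_depth +
#'   variance_vertical_velocity`. The random intercept is added internally
#'   from `group`.
#' @param data Segment metric table ([segment_metrics()] output or
#'   compatible data frame).
#' @param group Name of the grouping column (the individual).
#' @param standardize Z-score the predictors from `data` (default). Zero-SD
#'   predictors are dropped with a warning.
#' @param nagq Number of adaptive Gauss-Hermite quadrature points (1 =
#'   Laplace).
#' @param r2_method Residual-variance approximation for the
#'   Nakagawa-Schielzeth R-squared: `"lognormal"` (default) or
#'   `"trigamma"`. See [r_squared()].
#'
#' @return An object of class `buzz_glmm` with components including
#'   `coefficients` (matrix: Estimate, Std. Error, z value, p value),
#'   `sigma2_alpha` (random-intercept variance), `logLik`, `aic`, `r2`
#'   (marginal and conditional), `standardization` (centers and scales),
#'   and the underlying `fit`.
#' @examples
#' sim <- simulate_deployment(sim_config(n_individuals = 4, seed = 42))
#' tab <- deployment_segments(sim, segment_duration = 180)
#' m <- buzz_glmm(buzz_count ~ average_depth + variance_depth +
#'                  variance_vertical_velocity, tab)
#' summary(m)
#' @export
buzz_glmm <- function(formula, data, group = "individual_id",
                      standardize = TRUE, nagq = 1L,
                      r2_method = c("lognormal", "trigamma")) {
  r2_method <- match.arg(r2_method)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  response <- all.vars(formula[[2]])
  predictors <- attr(stats::terms(formula, data = data), "term.labels")
  if (!response %in% names(data))
    stop("response '", response, "' not found in data")
  missing_p <- setdiff(predictors, names(data))
  if (length(missing_p))
    stop("predictor(s) not found in data: ", paste(missing_p, collapse = ", "))
  if (!group %in% names(data))
    stop("grouping column '", group, "' not found in data")

  d <- data[c(response, predictors, group)]
  d[[group]] <- factor(d[[group]])
  ngroups <- nlevels(d[[group]])
  if (ngroups < 2)
    warning("fewer than 2 groups: random-intercept variance is ",
            "unidentifiable; fitting an ordinary Poisson regression")
  tab <- table(d[[group]])
  if (ngroups >= 2 && any(tab < 10))
    warning("group(s) with fewer than 10 segments: ",
            paste(names(tab)[tab < 10], collapse = ", "))

  std <- list(center = stats::setNames(numeric(0), character(0)),
              scale = stats::setNames(numeric(0), character(0)))
  if (standardize && length(predictors)) {
    ctr <- vapply(d[predictors], mean, 0)
    scl <- vapply(d[predictors], stats::sd, 0)
    bad <- predictors[scl == 0 | !is.finite(scl)]
    if (length(bad)) {
      warning("dropping zero-variance predictor(s): ",
              paste(bad, collapse = ", "))
      predictors <- setdiff(predictors, bad)
      ctr <- ctr[predictors]
      scl <- scl[predictors]
    }
    for (p in predictors)
      d[[p]] <- (d[[p]] - ctr[p]) / scl[p]
    std <- list(center = ctr, scale = scl)
  }

  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  # a constant response makes the mixed fit degenerate (sigma2 = 0 exactly);
  # treat it like the single-group case
  mixed <- ngroups >= 2 && stats::var(d[[response]]) > 0
  if (mixed) {
    f <- stats::as.formula(paste(response, "~", rhs,
                                 "+ (1 |", group, ")"))
    fit <- withCallingHandlers(
      lme4::glmer(f, data = d, family = stats::poisson(), nAGQ = nagq,
                  control = lme4::glmerControl(
                    check.response.not.const = "ignore")),
      warning = function(w) {
        if (grepl("failed to converge", conditionMessage(w)))
          stop("GLMM failed to converge: ", conditionMessage(w),
               call. = FALSE)
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        # singular (sigma2 -> 0) fits are legitimate boundary estimates
        if (grepl("boundary \\(singular\\)", conditionMessage(m)))
          invokeRestart("muffleMessage")
      })
    co <- summary(fit)$coefficients
    sigma2 <- as.numeric(lme4::VarCorr(fit)[[group]][1])
    ll <- as.numeric(stats::logLik(fit))
    aic <- stats::AIC(fit)
    fitted_lambda <- stats::fitted(fit)
    X <- lme4::getME(fit, "X")
    beta <- lme4::fixef(fit)
  } else {
    f <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::glm(f, data = d, family = stats::poisson())
    co <- summary(fit)$coefficients
    sigma2 <- 0
    ll <- as.numeric(stats::logLik(fit))
    aic <- stats::AIC(fit)
    fitted_lambda <- stats::fitted(fit)
    X <- stats::model.matrix(fit)
    beta <- stats::coef(fit)
  }
  colnames(co) <- c("Estimate", "Std. Error", "z value", "p value")
  eta_fixed <- as.vector(X %*% beta)

  obj <- structure(list(call = match.call(),
                        formula = formula,
                        response = response,
                        predictors = predictors,
                        group = group,
                        ngroups = ngroups,
                        mixed = mixed,
                        nobs = nrow(d),
                        standardization = std,
                        coefficients = co,
                        sigma2_alpha = sigma2,
                        logLik = ll,
                        aic = aic,
                        fit = fit,
                        eta_fixed = eta_fixed,
                        observed = d[[response]],
                        fitted_lambda = as.vector(fitted_lambda),
                        r2_method = r2_method),
                   class = "buzz_glmm")
  obj$r2 <- r_squared(obj, method = r2_method)
  obj
}

#' Nakagawa-Schielzeth R-squared for a fitted buzz model
#'
#' Marginal R2 is the variance explained by the fixed effects alone,
#' conditional R2 by fixed plus random effects:
#' `R2m = s2f / (s2f + s2a + s2d)` and
#' `R2c = (s2f + s2a) / (s2f + s2a + s2d)`, where `s2f` is the variance of
#' the fixed-effect linear predictor, `s2a` the random-intercept variance,
#' and `s2d` the observation-level (residual) variance on the latent log
#' scale. For a log-link Poisson model `s2d` is approximated as
#' `log(1 + 1/lambda_bar)` (log-normal approximation, default) or
#' `trigamma(lambda_bar)`, with `lambda_bar = exp(beta0 + s2a/2)`.
#'
#' @param model A fitted [buzz_glmm()].
#' @param method `"lognormal"` or `"trigamma"`.
#' @return Named numeric vector `c(marginal, conditional)`, both in [0, 1]
#'   with `marginal <= conditional`.
#' @export
r_squared <- function(model, method = c("lognormal", "trigamma")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "buzz_glmm"))
  s2f <- if (length(model$predictors)) stats::var(model$eta_fixed) else 0
  s2a <- model$sigma2_alpha
  b0 <- model$coefficients["(Intercept)", "Estimate"]
  lambda_bar <- exp(b0 + s2a / 2)
  s2d <- switch(method,
                lognormal = log1p(1 / lambda_bar),
                trigamma = trigamma(lambda_bar))
  tot <- s2f + s2a + s2d
  c(marginal = if (tot > 0) s2f / tot else 0,
    conditional = if (tot > 0) (s2f + s2a) / tot else 0)
}

#' Backward AIC selection over segment-metric predictors
#'
#' Starting from the full model, repeatedly refits all models with one
#' predictor removed and drops the predictor whose removal lowers AIC the
#' most; stops when no single removal lowers AIC. The full selection trace
#' is kept on the returned model.
#'
#' @inheritParams buzz_glmm
#' @param trace Print progress.
#' @return The selected [buzz_glmm()], with a `selection` element: a data
#'   frame of steps (predictor dropped, AIC before/after) and the candidate
#'   AICs examined at each step.
#' @export
backward_select <- function(formula, data, group = "individual_id",
                            standardize = TRUE, nagq = 1L, trace = FALSE,
                            r2_method = c("lognormal", "trigamma")) {
  r2_method <- match.arg(r2_method)
  response <- all.vars(formula[[2]])
  preds <- attr(stats::terms(formula, data = data), "term.labels")
  refit <- function(p) {
    f <- stats::reformulate(if (length(p)) p else "1", response)
    tryCatch(
      buzz_glmm(f, data, group = group, standardize = standardize,
                nagq = nagq, r2_method = r2_method),
      error = function(e)
        stop("fit failed for sub-model {", paste(p, collapse = ", "),
             "}: ", conditionMessage(e), call. = FALSE))
  }
  current <- refit(preds)
  steps <- list()
  candidates <- list()
  repeat {
    p <- current$predictors
    if (!length(p)) break
    aics <- vapply(p, function(drop_p) refit(setdiff(p, drop_p))$aic, 0)
    candidates[[length(candidates) + 1L]] <-
      data.frame(step = length(steps) + 1L, dropped_candidate = p,
                 aic = unname(aics))
    best <- which.min(aics)
    if (aics[best] >= current$aic) break
    if (trace)
      message(sprintf("dropping %s: AIC %.2f -> %.2f",
                      p[best], current$aic, aics[best]))
    steps[[length(steps) + 1L]] <-
      data.frame(step = length(steps) + 1L, dropped = p[best],
                 aic_before = current$aic, aic_after = unname(aics[best]))
    current <- refit(setdiff(p, p[best]))
  }
  current$selection <- list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(step = integer(), dropped = character(),
                 aic_before = numeric(), aic_after = numeric()),
    candidates = if (length(candidates)) do.call(rbind, candidates) else
      data.frame(step = integer(), dropped_candidate = character(),
                 aic = numeric()),
    start_predictors = preds)
  current
}

#' @export
print.buzz_glmm <- function(x, ...) {
  cat("Poisson mixed model of buzz counts per dive segment\n")
  cat("  formula: ", deparse(x$formula), " + (1 | ", x$group, ")\n",
      sep = "")
  cat(sprintf("  %d segments, %d individuals\n", x$nobs, x$ngroups))
  cat(sprintf("  AIC %.1f, random-intercept variance %.4f\n",
              x$aic, x$sigma2_alpha))
  cat(sprintf("  R2 marginal %.3f, conditional %.3f (%s)\n",
              x$r2["marginal"], x$r2["conditional"], x$r2_method))
  cat("  coefficients (standardized predictors):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.buzz_glmm <- function(object, ...) {
  structure(list(model = object), class = "summary.buzz_glmm")
}

#' @export
print.summary.buzz_glmm <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$selection) && nrow(m$selection$steps)) {
    cat("  backward selection dropped: ",
        paste(m$selection$steps$dropped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.buzz_glmm <- function(object, ...) {
  stats::setNames(object$coefficients[, "Estimate"],
                  rownames(object$coefficients))
}

#' @export
logLik.buzz_glmm <- function(object, ...) {
  structure(object$logLik,
            df = nrow(object$coefficients) + as.integer(object$mixed),
            class = "logLik")
}

#' Predict expected buzz counts for new segments
#'
#' Applies the model's stored standardization to `newdata` and evaluates the
#' fixed-effect linear predictor; the random intercept of individuals not
#' seen in training is set to its population mean of 0, which is the correct
#' prediction for held-out individuals in leave-individuals-out validation.
#'
#' @param object A fitted [buzz_glmm()].
#' @param newdata Data frame containing the model's predictors.
#' @param type `"lambda"` for the expected count `exp(eta)`, `"count"` for
#'   the nearest integer (ties to even), `"link"` for the linear predictor.
#' @param ... Unused.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
predict.buzz_glmm <- function(object, newdata,
                              type = c("lambda", "count", "link"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    eta <- object$eta_fixed
  } else {
    missing_p <- setdiff(object$predictors, names(newdata))
    if (length(missing_p))
      stop("newdata lacks predictor(s): ", paste(missing_p, collapse = ", "))
    eta <- rep(object$coefficients["(Intercept)", "Estimate"],
               nrow(newdata))
    for (p in object$predictors) {
      x <- newdata[[p]]
      if (p %in% names(object$standardization$center))
        x <- (x - object$standardization$center[p]) /
          object$standardization$scale[p]
      eta <- eta + object$coefficients[p, "Estimate"] * x
    }
  }
  switch(type,
         link = eta,
         lambda = exp(eta),
         count = round(exp(eta)))
}

#' @export
residuals.buzz_glmm <- function(object, type = c("response", "pearson"),
                                ...) {
  type <- match.arg(type)
  r <- object$observed - object$fitted_lambda
  if (type == "pearson")
    r <- r / sqrt(object$fitted_lambda)
  r
}

#' Simulate buzz counts from a fitted model
#'
#' Draws Poisson counts at the fitted (or predicted) means. For new data,
#' fresh per-individual random intercepts are drawn from
#' `N(0, sqrt(sigma2_alpha))`, one per distinct individual per simulation.
#'
#' @param object A fitted [buzz_glmm()].
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param newdata Optional data frame of segments to simulate for; defaults
#'   to the training segments (using their fitted means, which include the
#'   estimated random intercepts).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated counts.
#' @export
simulate.buzz_glmm <- function(object, nsim = 1, seed = NULL,
                               newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) {
    lam <- matrix(object$fitted_lambda, nrow = object$nobs, ncol = nsim)
  } else {
    eta <- predict(object, newdata, type = "link")
    grp <- factor(newdata[[object$group]])
    lam <- vapply(seq_len(nsim), function(s) {
      b <- stats::rnorm(nlevels(grp), 0, sqrt(object$sigma2_alpha))
      exp(eta + b[as.integer(grp)])
    }, numeric(length(eta)))
    lam <- matrix(lam, ncol = nsim)
  }
  out <- as.data.frame(apply(lam, 2, function(l) stats::rpois(length(l), l)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Observed-versus-fitted plot for a buzz model
#'
#' @param x A fitted [buzz_glmm()].
#' @param jitter_amount Vertical jitter applied to the integer observed
#'   counts for readability.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.buzz_glmm <- function(x, jitter_amount = 0.15, ...) {
  obs <- x$observed + stats::runif(x$nobs, -jitter_amount, jitter_amount)
  graphics::plot(x$fitted_lambda, obs,
                 xlab = "fitted mean buzz count (lambda)",
                 ylab = "observed buzz count (jittered)",
                 main = "Observed vs fitted buzz counts", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Segment metric table straight from a synthetic deployment
#'
#' Convenience wrapper running the processing chain (dive detection, phase
#' labelling, segmentation, metrics) over every individual of a simulated
#' deployment.
#'
#' @param deployment A [simulate_deployment()] result.
#' @param segment_duration Window length in seconds.
#' @param threshold Dive detection threshold (m).
#' @param drop_first Exclude each individual's first dive.
#' @param reversal_tolerance_s Phase-labelling reversal tolerance (s).
#' @param foraging_only Keep foraging dives only.
#' @return A metric table as from [segment_metrics()].
#' @export
deployment_segments <- function(deployment, segment_duration = 180,
                                threshold = 25, drop_first = TRUE,
                                reversal_tolerance_s = 10,
                                foraging_only = TRUE) {
  stopifnot(inherits(deployment, "deployment"))
  segs <- lapply(deployment$depth_series, function(s) {
    dv <- detect_dives(s, deployment$buzz_events, threshold = threshold,
                       drop_first = drop_first,
                       reversal_tolerance_s = reversal_tolerance_s)
    segment_dives(dv, s, deployment$buzz_events, segment_duration,
                  foraging_only = foraging_only)
  })
  segment_metrics(segs)
}
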