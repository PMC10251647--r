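# Independent oracles and fixtures, deliberately naive: per-definition loops
# and brute-force algorithms that the vectorized implementation is checked
# against.

# Poisson regression by hand-rolled iteratively reweighted least squares
# (log link). X includes the intercept column.
irls_poisson <- function(X, y, tol = 1e-10, max_iter = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.1)
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- as.vector(beta_new)
      break
    }
    beta <- as.vector(beta_new)
  }
  as.vector(beta)
}

# AUC by exhaustive pairwise comparison, ties counted 1/2
auc_pairwise <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# every segment metric recomputed by a literal per-definition loop
naive_metrics <- function(depths, dive_max_depth, steady_quantum = 0.1,
                          wiggle_threshold = 20) {
  n <- length(depths)
  vv <- numeric(0)
  for (t in seq_len(n - 1)) vv <- c(vv, depths[t + 1] - depths[t])
  va <- numeric(0)
  if (length(vv) >= 2)
    for (t in seq_len(length(vv) - 1)) va <- c(va, abs(vv[t + 1] - vv[t]))
  infl <- integer(0)
  for (t in seq(2, max(n - 1, 1))) {
    if (t >= 2 && t <= n - 1) {
      a <- depths[t] - depths[t - 1]
      b <- depths[t + 1] - depths[t]
      if ((a > 0 && b < 0) || (a < 0 && b > 0)) infl <- c(infl, t)
    }
  }
  wig <- 0
  if (length(infl) >= 2)
    for (k in 2:length(infl))
      if (abs(depths[infl[k]] - depths[infl[k - 1]]) > wiggle_threshold)
        wig <- wig + 1
  steady <- 0
  q <- round(depths / steady_quantum) * steady_quantum
  for (t in seq_len(n)[-1]) if (q[t] == q[t - 1]) steady <- steady + 1
  tot <- sum(abs(vv))
  net <- abs(depths[n] - depths[1])
  c(average_depth = sum(depths) / n,
    maximum_depth = max(depths),
    variance_depth = if (n >= 2) sum((depths - mean(depths))^2) / (n - 1) else 0,
    depth_difference = net,
    time_gt_60pct = sum(depths > 0.6 * dive_max_depth) / n,
    time_gt_70pct = sum(depths > 0.7 * dive_max_depth) / n,
    time_gt_80pct = sum(depths > 0.8 * dive_max_depth) / n,
    time_gt_90pct = sum(depths > 0.9 * dive_max_depth) / n,
    average_vertical_velocity = if (length(vv)) sum(vv) / length(vv) else 0,
    variance_vertical_velocity =
      if (length(vv) >= 2) sum((vv - mean(vv))^2) / (length(vv) - 1) else 0,
    average_vertical_acceleration =
      if (length(va)) sum(va) / length(va) else 0,
    variance_vertical_acceleration =
      if (length(va) >= 2) sum((va - mean(va))^2) / (length(va) - 1) else 0,
    inflections = length(infl),
    wiggles = wig,
    steady_points = steady,
    sinuosity = if (tot == 0) 1 else net / tot)
}

# random segment generator for oracle sweeps: mixes smooth ramps, jitter,
# quantized depths (exercising steady points) and sign changes
random_segment <- function(n = NULL) {
  if (is.null(n)) n <- sample(c(5, 10, 30, 60, 180), 1)
  kind <- sample(4, 1)
  d <- switch(kind,
              cumsum(runif(n, -3, 5)) + 300,                    # drifting
              300 + 50 * sin(seq_len(n) / runif(1, 2, 15)) +
                rnorm(n, 0, 5),                                 # wiggly
              round(300 + cumsum(rnorm(n, 0, 2)), 1),           # quantized
              rep(round(runif(1, 100, 500), 1), n) +
                sample(c(0, 0.05), n, replace = TRUE))          # near-flat
  pmax(d, 26)
}

# a depth series with a prescribed sequence of dives: each dive a simple
# descend/flat/ascend trapezoid to `depth` m with `bottom_s` flat seconds
make_series <- function(dive_depths, bottom_s = 120, id = "w1",
                        surface_s = 90, speed = 2) {
  depths <- rep(0, surface_s)
  spans <- list()
  for (d in dive_depths) {
    down <- seq(speed, d, by = speed)
    flat <- rep(d, bottom_s)
    up <- seq(d - speed, speed, by = -speed)
    start <- length(depths) + 1
    depths <- c(depths, down, flat, up, rep(0, surface_s))
    spans[[length(spans) + 1]] <- c(start, start + length(down) +
                                      length(flat) + length(up) - 1)
  }
  list(series = depth_series(seq_along(depths) - 1, depths, id, 1),
       spans = spans)
}

# small, fast simulation settings used across tests (fewer, shorter dives
# than the full study scale)
small_sim <- function(seed, n_individuals = 5, ...) {
  sim_config(n_individuals = n_individuals,
             dives_per_individual_mean = 4,
             bottom_duration_range = c(400, 800),
             seed = seed, ...)
}
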