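test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(bottom_depth_range = c(20, 900)), "25")
  expect_error(sim_config(bottom_depth_range = c(900, 500)), "min < max")
  expect_error(sim_config(random_intercept_sd = -1), "SD")
  expect_error(sim_config(bottom_depth_range = c(500, 1900),
                          descent_speed = c(0.6, 0.1),
                          ascent_speed = c(0.6, 0.1),
                          bottom_duration_range = c(1200, 2100)),
               "cap")
})

test_that("intercept-only generation yields the expected mean count", {
  cfg <- sim_config(n_individuals = 1, dives_per_individual_mean = 6,
                    true_coefficients = c(intercept = log(2),
                                          average_depth = 0,
                                          variance_depth = 0,
                                          variance_vertical_velocity = 0),
                    random_intercept_sd = 0, seed = 11)
  dep <- simulate_deployment(cfg)
  w <- dep$truth$windows
  expect_gt(nrow(w), 20)
  expect_true(all(abs(w$lambda - 2) < 1e-12))
  # mean count within 3 SE of the Poisson mean 2
  se <- sqrt(2 / nrow(w))
  expect_lt(abs(mean(w$count) - 2), 3 * se)
})

test_that("a zero-dive configuration yields an empty deployment", {
  dep <- simulate_deployment(sim_config(n_individuals = 2,
                                        dives_per_individual_mean = 0,
                                        seed = 3))
  expect_equal(nrow(dep$buzz_events), 0)
  expect_equal(nrow(dep$truth$windows), 0)
  expect_length(dep$depth_series, 2)
  # export of the empty deployment writes header-only buzz table
  dir <- withr::local_tempdir()
  export_tdr_csv(dep, dir)
  bz <- read.csv(file.path(dir, "buzzes.csv"))
  expect_equal(nrow(bz), 0)
  expect_named(bz, c("individual_id", "start_s", "end_s"))
})

test_that("total buzzes agree with the analytic expectation", {
  cfg <- sim_config(seed = 21)
  dep <- simulate_deployment(cfg)
  w <- dep$truth$windows
  # independent recomputation of every window's Poisson mean by a plain loop
  b <- dep$truth$random_intercepts
  ctr <- dep$truth$standardization$center
  scl <- dep$truth$standardization$scale
  beta <- cfg$true_coefficients
  lam <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    eta <- beta["intercept"] + b[w$individual_id[i]] +
      beta["average_depth"] * (w$average_depth[i] - ctr["average_depth"]) /
        scl["average_depth"] +
      beta["variance_depth"] * (w$variance_depth[i] - ctr["variance_depth"]) /
        scl["variance_depth"] +
      beta["variance_vertical_velocity"] *
        (w$variance_vertical_velocity[i] -
           ctr["variance_vertical_velocity"]) /
        scl["variance_vertical_velocity"]
    lam[i] <- exp(eta)
  }
  expect_equal(lam, w$lambda, tolerance = 1e-12, ignore_attr = TRUE)
  expected_total <- sum(lam)
  expect_lt(abs(nrow(dep$buzz_events) - expected_total),
            3 * sqrt(expected_total))
})

test_that("identical config and seed give byte-identical exports", {
  cfg <- small_sim(5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_tdr_csv(simulate_deployment(cfg), d1)
  export_tdr_csv(simulate_deployment(cfg), d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("descent speeds match the configured distribution", {
  cfg <- sim_config(n_individuals = 12, dives_per_individual_mean = 20,
                    bottom_duration_range = c(60, 120), seed = 8)
  dep <- simulate_deployment(cfg)
  speeds <- c()
  for (s in dep$depth_series) {
    dv <- detect_dives(s, dep$buzz_events, drop_first = FALSE)
    for (k in seq_len(nrow(dv))) {
      lab <- dv$phase_labels[[k]]
      d <- s$depth_m[dv$start_index[k]:(dv$end_index[k] - 1)]
      desc <- which(lab == "descent")
      if (length(desc) > 30)
        speeds <- c(speeds, mean(diff(d[desc])))
    }
  }
  expect_gt(length(speeds), 200)
  se <- sd(speeds) / sqrt(length(speeds))
  expect_lt(abs(mean(speeds) - cfg$descent_speed[1]), 3 * se + 0.02)
})

test_that("buzzes lie inside dives and never overlap", {
  dep <- simulate_deployment(sim_config(seed = 13))
  bz <- dep$buzz_events
  expect_true(all(bz$end_s > bz$start_s))
  for (id in names(dep$depth_series)) {
    s <- dep$depth_series[[id]]
    b <- bz[bz$individual_id == id, ]
    b <- b[order(b$start_s), ]
    # depth at each buzz start exceeds the dive threshold
    expect_true(all(s$depth_m[floor(b$start_s) + 1] > 25))
    if (nrow(b) > 1)
      expect_true(all(b$start_s[-1] >= b$end_s[-nrow(b)] - 1e-9))
  }
})

test_that("depth series round-trip through CSV to tag precision", {
  dep <- simulate_deployment(small_sim(9))
  dir <- withr::local_tempdir()
  export_tdr_csv(dep, dir)
  back <- read_tdr_csv(dir)
  expect_identical(names(back$depth_series), names(dep$depth_series))
  for (id in names(dep$depth_series))
    expect_equal(back$depth_series[[id]]$depth_m,
                 round(dep$depth_series[[id]]$depth_m, 3),
                 tolerance = 1e-3)
  expect_equal(nrow(back$buzz_events), nrow(dep$buzz_events))
})

test_that("high-rate export writes rate-times-duration rows", {
  cfg <- small_sim(4, n_individuals = 2, high_rate_hz = 20)
  dep <- simulate_deployment(cfg)
  dir <- withr::local_tempdir()
  export_tdr_csv(dep, dir)
  for (id in names(dep$depth_series)) {
    n1 <- nrow(dep$depth_series[[id]])
    hi <- read.csv(file.path(dir, paste0("depth_", id, ".csv")))
    expect_equal(nrow(hi), 20 * n1)
  }
  # and the reader + decimator restore the 1 Hz series
  back <- read_tdr_csv(dir)
  s <- downsample_depth(back$depth_series[[1]], 1)
  expect_equal(s$depth_m,
               round(dep$depth_series[[1]]$depth_m, 4),
               tolerance = 1e-3)
})
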