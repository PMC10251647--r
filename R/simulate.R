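#' Simulation configuration for a synthetic biologging deployment
#'
#' Builds and validates the configuration driving [simulate_deployment()].
#' Defaults emulate a deployment of time-depth tags on deep-diving,
#' echolocating whales: foraging dives with bottom depths concentrated at
#' 500--900 m, descent and ascent vertical speeds around 1.35 +/- 0.21 and
#' 1.60 +/- 0.19 m/s, about 9 foraging dives per individual across 12
#' individuals, and buzz counts (prey-capture attempts) generated from a
#' log-link Poisson model on standardized dive metrics with per-individual
#' random intercepts.
#'
#' @param n_individuals Number of tagged individuals (>= 2 unless you are
#'   constructing degenerate test cases; >= 1 accepted).
#' @param dives_per_individual_mean Mean number of dives per individual;
#'   realized counts are Poisson draws.
#' @param descent_speed,ascent_speed Length-2 numeric `c(mean, sd)` of the
#'   per-dive vertical transit speed in m/s. Draws are truncated below at
#'   0.5 m/s.
#' @param bottom_depth_range Length-2 range (m) from which each dive's target
#'   bottom depth is drawn uniformly; must lie within (25, 2000) m.
#' @param bottom_duration_range Length-2 range (s) of the bottom-phase
#'   duration, drawn uniformly per dive.
#' @param bottom_walk_sd Standard deviation (m per 1-s step) of the reflected
#'   random walk simulating depth excursions during the bottom phase.
#' @param true_coefficients Named numeric vector of the generating model on
#'   the standardized-predictor log-link scale: `intercept`, `average_depth`,
#'   `variance_depth`, `variance_vertical_velocity`.
#' @param random_intercept_sd SD of the per-individual random intercept on
#'   the log scale.
#' @param segment_duration_for_generation Window length (s) at which buzz
#'   counts are generated.
#' @param high_rate_hz Optional high sampling rate (20 or 25 Hz) for exports;
#'   `NULL` keeps everything at 1 Hz.
#' @param surface_duration_range Length-2 range (s) of surface intervals
#'   between dives (minimum 60 s enforced).
#' @param buzz_duration_range Length-2 range (s) of individual buzz event
#'   durations.
#' @param max_dive_duration Hard cap (s) on the dive duration implied by the
#'   configuration; configurations whose deepest/slowest dive would exceed it
#'   are rejected as inconsistent.
#' @param seed Integer seed; every stochastic draw in the generator flows
#'   from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_deployment()]
#' @export
sim_config <- function(n_individuals = 12,
                       dives_per_individual_mean = 9,
                       descent_speed = c(mean = 1.35, sd = 0.21),
                       ascent_speed = c(mean = 1.60, sd = 0.19),
                       bottom_depth_range = c(500, 900),
                       bottom_duration_range = c(1200, 2100),
                       bottom_walk_sd = 1.0,
                       true_coefficients = c(intercept = -0.8,
                                             average_depth = 0.955,
                                             variance_depth = -0.356,
                                             variance_vertical_velocity = 0.187),
                       random_intercept_sd = 0.2,
                       segment_duration_for_generation = 180,
                       high_rate_hz = NULL,
                       surface_duration_range = c(120, 480),
                       buzz_duration_range = c(5, 10),
                       max_dive_duration = 3600,
                       seed = 1L) {
  stopifnot(length(n_individuals) == 1, n_individuals >= 1,
            length(dives_per_individual_mean) == 1,
            dives_per_individual_mean >= 0,
            length(descent_speed) == 2, length(ascent_speed) == 2,
            length(bottom_depth_range) == 2, length(bottom_duration_range) == 2,
            length(seed) == 1)
  if (descent_speed[2] < 0 || ascent_speed[2] < 0 || random_intercept_sd < 0 ||
      bottom_walk_sd < 0)
    stop("all SD fields must be >= 0")
  if (bottom_depth_range[1] <= 25 || bottom_depth_range[2] >= 2000 ||
      bottom_depth_range[1] >= bottom_depth_range[2])
    stop("bottom_depth_range must lie within (25, 2000) m with min < max")
  if (bottom_duration_range[1] > bottom_duration_range[2] ||
      bottom_duration_range[1] < 0)
    stop("bottom_duration_range must be non-negative and ordered")
  if (surface_duration_range[1] < 60)
    stop("surface intervals must be at least 60 s")
  req <- c("intercept", "average_depth", "variance_depth",
           "variance_vertical_velocity")
  if (!all(req %in% names(true_coefficients)))
    stop("true_coefficients must name: ", paste(req, collapse = ", "))
  if (!is.null(high_rate_hz)) {
    stopifnot(length(high_rate_hz) == 1, high_rate_hz >= 1,
              high_rate_hz == as.integer(high_rate_hz))
  }
  # implied worst-case dive duration at mean transit speeds: deepest bottom,
  # longest bottom phase; inconsistent speed/depth settings are rejected here
  implied <- bottom_depth_range[2] / descent_speed[1] +
    bottom_duration_range[2] +
    bottom_depth_range[2] / ascent_speed[1]
  if (implied > max_dive_duration)
    stop(sprintf(paste0("configuration implies dives of up to %.0f s, ",
                        "exceeding the %.0f s cap; adjust depths, speeds or ",
                        "bottom durations"), implied, max_dive_duration))
  structure(list(n_individuals = as.integer(n_individuals),
                 dives_per_individual_mean = dives_per_individual_mean,
                 descent_speed = unname(descent_speed),
                 ascent_speed = unname(ascent_speed),
                 bottom_depth_range = unname(bottom_depth_range),
                 bottom_duration_range = unname(bottom_duration_range),
                 bottom_walk_sd = bottom_walk_sd,
                 true_coefficients = true_coefficients[req],
                 random_intercept_sd = random_intercept_sd,
                 segment_duration_for_generation =
                   as.integer(segment_duration_for_generation),
                 high_rate_hz = high_rate_hz,
                 surface_duration_range = unname(surface_duration_range),
                 buzz_duration_range = unname(buzz_duration_range),
                 max_dive_duration = max_dive_duration,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic deployment configuration\n")
  cat(sprintf("  individuals: %d, mean dives/individual: %.1f\n",
              x$n_individuals, x$dives_per_individual_mean))
  cat(sprintf("  descent %.2f +/- %.2f m/s, ascent %.2f +/- %.2f m/s\n",
              x$descent_speed[1], x$descent_speed[2],
              x$ascent_speed[1], x$ascent_speed[2]))
  cat(sprintf("  bottom depth %g-%g m, bottom duration %g-%g s\n",
              x$bottom_depth_range[1], x$bottom_depth_range[2],
              x$bottom_duration_range[1], x$bottom_duration_range[2]))
  cat(sprintf("  generation window %d s, random-intercept SD %.2f, seed %d\n",
              x$segment_duration_for_generation, x$random_intercept_sd,
              x$seed))
  cat("  true coefficients (standardized log scale):\n")
  print(round(x$true_coefficients, 3))
  invisible(x)
}

# truncated normal draw: redraw below `lower` (transit speeds must stay
# positive or dive durations explode)
.rtnorm <- function(n, mean, sd, lower = 0.5) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

# reflected random walk around [lo, hi]
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Simulate a synthetic tag deployment
#'
#' Generates 1 Hz depth traces and buzz events for `config$n_individuals`
#' whales. Each dive descends at a speed drawn from the descent distribution,
#' holds a bottom phase simulated as a reflected random walk around the drawn
#' bottom depth, and ascends at a drawn ascent speed; dives are separated by
#' surface intervals of at least 60 s with depths jittered within 0.5 m of
#' the surface. Buzz counts are generated per complete window of
#' `segment_duration_for_generation` seconds within each dive (samples deeper
#' than 25 m): the window's average depth, depth variance and
#' vertical-velocity variance are standardized deployment-wide and a count is
#' drawn from `Poisson(exp(intercept + b_i + sum(beta * x)))`, where `b_i` is
#' the individual's random intercept. The drawn number of non-overlapping
#' buzz events (5--10 s each) is then placed uniformly within the window.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `deployment`: a list with
#'   \describe{
#'     \item{depth_series}{named list of [depth_series()] objects (1 Hz).}
#'     \item{buzz_events}{data frame `individual_id`, `start_s`, `end_s`.}
#'     \item{truth}{the config, realized per-individual random intercepts,
#'       the deployment-wide standardization statistics, and a per-window
#'       table of true predictors, Poisson means `lambda` and drawn counts.}
#'   }
#' @export
simulate_deployment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gen_dur <- config$segment_duration_for_generation
  ids <- sprintf("sw%02d", seq_len(config$n_individuals))
  b <- stats::rnorm(config$n_individuals, 0, config$random_intercept_sd)
  names(b) <- ids

  series <- vector("list", length(ids))
  names(series) <- ids
  dive_spans <- list()  # per-individual list of c(start_idx, end_idx) 1-based

  for (i in seq_along(ids)) {
    depths <- .surface_block(sample(config$surface_duration_range[1]:
                                      config$surface_duration_range[2], 1))
    spans <- list()
    n_dives <- stats::rpois(1, config$dives_per_individual_mean)
    for (d in seq_len(n_dives)) {
      v_d <- .rtnorm(1, config$descent_speed[1], config$descent_speed[2])
      v_a <- .rtnorm(1, config$ascent_speed[1], config$ascent_speed[2])
      target <- stats::runif(1, config$bottom_depth_range[1],
                             config$bottom_depth_range[2])
      bot_dur <- sample(config$bottom_duration_range[1]:
                          config$bottom_duration_range[2], 1)
      desc <- pmin(v_d * seq_len(ceiling(target / v_d)), target)
      walk <- target + cumsum(stats::rnorm(bot_dur, 0, config$bottom_walk_sd))
      walk <- .reflect(walk, config$bottom_depth_range[1],
                       config$bottom_depth_range[2])
      last <- walk[length(walk)]
      asc <- last - v_a * seq_len(ceiling(last / v_a))
      asc <- asc[asc > 0]
      dive <- c(desc, walk, asc)
      start_idx <- length(depths) + 1L
      depths <- c(depths, dive)
      spans[[d]] <- c(start_idx, length(depths))
      depths <- c(depths,
                  .surface_block(sample(config$surface_duration_range[1]:
                                          config$surface_duration_range[2], 1)))
    }
    series[[i]] <- depth_series(time_s = seq_along(depths) - 1,
                                depth_m = depths, individual_id = ids[i],
                                rate_hz = 1)
    dive_spans[[ids[i]]] <- spans
  }

  # pass 2: windows deeper than 25 m within each dive, raw predictors
  win <- list()
  for (id in ids) {
    depths <- series[[id]]$depth_m
    for (d in seq_along(dive_spans[[id]])) {
      span <- dive_spans[[id]][[d]]
      idx <- span[1]:span[2]
      deep <- idx[depths[idx] > 25]
      if (length(deep) < gen_dur) next
      n_win <- length(deep) %/% gen_dur
      for (w in seq_len(n_win)) {
        sel <- deep[((w - 1) * gen_dur + 1):(w * gen_dur)]
        dd <- depths[sel]
        win[[length(win) + 1L]] <- list(
          id, d, w, sel[1] - 1, sel[length(sel)],
          mean(dd), stats::var(dd), stats::var(diff(dd)))
      }
    }
  }

  buzz <- data.frame(individual_id = character(), start_s = numeric(),
                     end_s = numeric())
  truth_windows <- data.frame()
  std <- NULL
  if (length(win)) {
    wt <- data.frame(
      individual_id = vapply(win, `[[`, "", 1),
      dive = vapply(win, `[[`, 0, 2),
      window = vapply(win, `[[`, 0, 3),
      start_s = vapply(win, `[[`, 0, 4),
      end_s = vapply(win, `[[`, 0, 5),
      average_depth = vapply(win, `[[`, 0, 6),
      variance_depth = vapply(win, `[[`, 0, 7),
      variance_vertical_velocity = vapply(win, `[[`, 0, 8))
    preds <- c("average_depth", "variance_depth",
               "variance_vertical_velocity")
    std <- list(center = vapply(wt[preds], mean, 0),
                scale = vapply(wt[preds], stats::sd, 0))
    z <- sweep(sweep(as.matrix(wt[preds]), 2, std$center), 2, std$scale, "/")
    beta <- config$true_coefficients
    eta <- beta["intercept"] + b[wt$individual_id] +
      as.vector(z %*% beta[preds])
    wt$lambda <- exp(eta)
    wt$count <- stats::rpois(nrow(wt), wt$lambda)
    ev <- vector("list", nrow(wt))
    for (r in seq_len(nrow(wt))) {
      if (wt$count[r] > 0)
        ev[[r]] <- .place_buzzes(wt$count[r], wt$start_s[r], gen_dur,
                                 config$buzz_duration_range,
                                 wt$individual_id[r])
    }
    ev <- ev[!vapply(ev, is.null, TRUE)]
    if (length(ev)) buzz <- do.call(rbind, ev)
    truth_windows <- wt
  }
  rownames(buzz) <- NULL
  rownames(truth_windows) <- NULL

  structure(list(depth_series = series,
                 buzz_events = buzz,
                 truth = list(config = config,
                              random_intercepts = b,
                              standardization = std,
                              windows = truth_windows)),
            class = "deployment")
}

.surface_block <- function(n) pmax(stats::runif(n, -0.5, 0.5), 0)

# place k non-overlapping buzzes uniformly within [start, start + dur)
.place_buzzes <- function(k, start, dur, dur_range, id) {
  len <- stats::runif(k, dur_range[1], dur_range[2])
  avail <- dur - 1e-6
  if (sum(len) > avail) len <- len * avail / sum(len)
  free <- avail - sum(len)
  gaps <- sort(stats::runif(k, 0, free))
  starts <- start + gaps + c(0, cumsum(len[-k]))
  data.frame(individual_id = id, start_s = starts, end_s = starts + len)
}

#' @export
print.deployment <- function(x, ...) {
  n_samp <- sum(vapply(x$depth_series, nrow, 0L))
  cat(sprintf(paste0("Synthetic deployment: %d individuals, %d depth samples",
                     " (1 Hz), %d buzzes over %d generation windows\n"),
              length(x$depth_series), n_samp, nrow(x$buzz_events),
              nrow(x$truth$windows)))
  invisible(x)
}

#' Export a deployment as time-depth recorder CSV files
#'
#' Writes one depth file per individual (`depth_<id>.csv` with columns
#' `time_s`, `depth_m`) and a single buzz table (`buzzes.csv` with columns
#' `individual_id`, `start_s`, `end_s`). When the configuration requests a
#' high sampling rate, depth traces are linearly interpolated to that rate so
#' that downstream decimation back to 1 Hz can be exercised; otherwise files
#' are written at 1 Hz. Values are written with 4 decimal places, so
#' write-then-read round-trips are exact to well below tag resolution.
#'
#' @param deployment A [simulate_deployment()] result.
#' @param path Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_tdr_csv <- function(deployment, path) {
  stopifnot(inherits(deployment, "deployment"))
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  hz <- deployment$truth$config$high_rate_hz
  files <- character()
  for (id in names(deployment$depth_series)) {
    s <- deployment$depth_series[[id]]
    if (!is.null(hz) && hz > 1) {
      n <- nrow(s)
      t_out <- seq(0, n - 1 / hz, by = 1 / hz)
      d_out <- stats::approx(s$time_s, s$depth_m, xout = t_out,
                             rule = 2)$y
      out <- data.frame(time_s = round(t_out, 4), depth_m = round(d_out, 4))
    } else {
      out <- data.frame(time_s = s$time_s, depth_m = round(s$depth_m, 4))
    }
    f <- file.path(path, paste0("depth_", id, ".csv"))
    utils::write.csv(out, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  bz <- deployment$buzz_events
  bz$start_s <- round(bz$start_s, 4)
  bz$end_s <- round(bz$end_s, 4)
  f <- file.path(path, "buzzes.csv")
  utils::write.csv(bz, f, row.names = FALSE, quote = FALSE)
  invisible(c(files, f))
}

#' Read time-depth recorder CSV files
#'
#' Reads the dialect written by [export_tdr_csv()]: `depth_<id>.csv` files
#' and an optional `buzzes.csv`. The sampling rate is inferred from the time
#' step of each depth file.
#'
#' @param path Directory containing the files.
#' @return A list with `depth_series` (named list of [depth_series()]) and
#'   `buzz_events` (data frame; zero rows if no buzz table present).
#' @export
read_tdr_csv <- function(path) {
  stopifnot(dir.exists(path))
  dfiles <- sort(list.files(path, pattern = "^depth_.*\\.csv$",
                            full.names = TRUE))
  if (!length(dfiles))
    stop("no depth_<id>.csv files found in ", path)
  series <- list()
  for (f in dfiles) {
    id <- sub("^depth_(.*)\\.csv$", "\\1", basename(f))
    d <- utils::read.csv(f)
    if (nrow(d) >= 2) {
      rate <- round(1 / stats::median(diff(d$time_s)))
    } else {
      rate <- 1
    }
    series[[id]] <- depth_series(d$time_s, d$depth_m, id, rate)
  }
  bf <- file.path(path, "buzzes.csv")
  buzz <- if (file.exists(bf)) utils::read.csv(bf) else
    data.frame(individual_id = character(), start_s = numeric(),
               end_s = numeric())
  list(depth_series = series, buzz_events = buzz)
}
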