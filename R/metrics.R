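#' Per-step vertical velocity
#'
#' Signed first difference of a 1 Hz depth trace: positive while descending,
#' negative while ascending, in m/s.
#'
#' @param depths Depth samples (>= 2) at 1 Hz.
#' @return Numeric vector of length `length(depths) - 1`.
#' @export
vertical_velocity <- function(depths) {
  if (length(depths) < 2)
    stop("vertical velocity needs at least 2 samples")
  diff(depths)
}

#' Names of the segment-level dive metrics
#'
#' The 16 metrics computed per segment by [compute_metrics()], in the column
#' order used throughout the package.
#' @return Character vector.
#' @export
metric_names <- function() {
  c("average_depth", "maximum_depth", "variance_depth", "depth_difference",
    "time_gt_60pct", "time_gt_70pct", "time_gt_80pct", "time_gt_90pct",
    "average_vertical_velocity", "variance_vertical_velocity",
    "average_vertical_acceleration", "variance_vertical_acceleration",
    "inflections", "wiggles", "steady_points", "sinuosity")
}

#' Compute the dive-metric suite for one segment
#'
#' Computes 16 segment-level metrics from a segment's 1 Hz depth samples:
#' depth summaries (average, maximum, variance, absolute start-to-end
#' difference), the fraction of time spent deeper than 60/70/80/90% of the
#' parent dive's maximum depth, average and variance of the per-step
#' vertical velocity and of the vertical acceleration (the absolute
#' difference of consecutive velocities), counts of inflection points
#' (strict local depth extrema), wiggles (inflections differing by more than
#' `wiggle_threshold` metres from the previous inflection; the first
#' inflection of a segment can never be one), steady points (consecutive
#' samples equal after quantization to `steady_quantum` metres, the typical
#' tag depth resolution), and vertical sinuosity (absolute net depth change
#' divided by total absolute depth change; 1 means a straight vertical path,
#' and a segment with zero total change is defined as 1).
#'
#' @param depths The segment's 1 Hz depth samples.
#' @param dive_max_depth Maximum depth (m) of the parent dive (> 0).
#' @param velocity `"signed"` (default) uses the signed per-step velocity in
#'   the velocity average/variance; `"absolute"` uses its magnitude
#'   (sensitivity switch).
#' @param steady_quantum Depth quantization step (m) for steady-point
#'   equality.
#' @param wiggle_threshold Depth difference (m) an inflection must exceed
#'   relative to the previous inflection to count as a wiggle.
#' @return Named numeric vector, names as in [metric_names()].
#' @export
compute_metrics <- function(depths, dive_max_depth,
                            velocity = c("signed", "absolute"),
                            steady_quantum = 0.1, wiggle_threshold = 20) {
  velocity <- match.arg(velocity)
  n <- length(depths)
  if (n == 0)
    stop("cannot compute metrics on a zero-length segment")
  stopifnot(dive_max_depth > 0)
  vv <- if (n >= 2) diff(depths) else numeric()
  vv_used <- if (velocity == "absolute") abs(vv) else vv
  va <- if (length(vv) >= 2) abs(diff(vv)) else numeric()

  q <- round(depths / steady_quantum) * steady_quantum
  steady <- if (n >= 2) sum(q[-1] == q[-n]) else 0L

  infl_idx <- integer()
  if (n >= 3) {
    prev <- depths[2:(n - 1)] - depths[1:(n - 2)]
    nxt <- depths[3:n] - depths[2:(n - 1)]
    infl_idx <- which((prev > 0 & nxt < 0) | (prev < 0 & nxt > 0)) + 1L
  }
  wiggles <- 0L
  if (length(infl_idx) >= 2) {
    dinf <- abs(diff(depths[infl_idx]))
    wiggles <- sum(dinf > wiggle_threshold)
  }

  total <- sum(abs(vv))
  net <- abs(depths[n] - depths[1])
  sinuosity <- if (total == 0) 1 else net / total

  .v <- function(x) if (length(x) >= 2) stats::var(x) else 0
  .m <- function(x) if (length(x)) mean(x) else 0
  c(average_depth = mean(depths),
    maximum_depth = max(depths),
    variance_depth = .v(depths),
    depth_difference = net,
    time_gt_60pct = mean(depths > 0.6 * dive_max_depth),
    time_gt_70pct = mean(depths > 0.7 * dive_max_depth),
    time_gt_80pct = mean(depths > 0.8 * dive_max_depth),
    time_gt_90pct = mean(depths > 0.9 * dive_max_depth),
    average_vertical_velocity = .m(vv_used),
    variance_vertical_velocity = .v(vv_used),
    average_vertical_acceleration = .m(va),
    variance_vertical_acceleration = .v(va),
    inflections = length(infl_idx),
    wiggles = wiggles,
    steady_points = steady,
    sinuosity = sinuosity)
}

#' Build the segment metric table
#'
#' Applies [compute_metrics()] to every row of a `segment_table`, yielding
#' the flat table modelling stages consume: one row per segment with
#' identifiers, phase, observed buzz count and the 16 metrics.
#'
#' @param segments A `segment_table` from [segment_dives()], or a list of
#'   them (e.g. one per individual), which is concatenated.
#' @inheritParams compute_metrics
#' @return A data frame with columns `individual_id`, `dive_id`,
#'   `segment_id`, `segment_duration`, `start_s`, `phase`, `buzz_count`,
#'   `dive_max_depth` and the metric columns.
#' @export
segment_metrics <- function(segments, velocity = c("signed", "absolute"),
                            steady_quantum = 0.1, wiggle_threshold = 20) {
  velocity <- match.arg(velocity)
  if (is.list(segments) && !is.data.frame(segments))
    segments <- do.call(rbind, segments)
  base <- segments[c("individual_id", "dive_id", "segment_id",
                     "segment_duration", "start_s", "phase", "buzz_count",
                     "dive_max_depth")]
  if (!nrow(segments)) {
    m <- matrix(numeric(), 0, length(metric_names()),
                dimnames = list(NULL, metric_names()))
    return(cbind(base, as.data.frame(m)))
  }
  m <- t(vapply(seq_len(nrow(segments)), function(i) {
    compute_metrics(segments$depths[[i]], segments$dive_max_depth[i],
                    velocity, steady_quantum, wiggle_threshold)
  }, stats::setNames(numeric(length(metric_names())), metric_names())))
  out <- cbind(base, as.data.frame(m))
  rownames(out) <- NULL
  out
}

#' Default ecological priority order of the metrics
#'
#' Used by [screen_collinearity()] to decide which member of a correlated
#' pair to keep: metrics judged more ecologically informative for predicting
#' prey-capture attempts (depth of foraging, vertical manoeuvring) rank
#' ahead of the redundant bottom-time ratios.
#' @return Character vector (a permutation of [metric_names()]).
#' @export
default_metric_priority <- function() {
  c("average_depth", "variance_depth", "variance_vertical_velocity",
    "maximum_depth", "depth_difference", "average_vertical_velocity",
    "average_vertical_acceleration", "variance_vertical_acceleration",
    "sinuosity", "wiggles", "inflections", "steady_points",
    "time_gt_60pct", "time_gt_70pct", "time_gt_80pct", "time_gt_90pct")
}

#' Screen candidate predictors for collinearity
#'
#' Computes pairwise Pearson correlations between candidate metrics and
#' greedily retains, in priority order, each metric whose absolute
#' correlation with every already-retained metric is below `threshold`
#' (i.e. of any pair at or above the threshold, the lower-priority metric is
#' dropped). Zero-variance metrics are excluded up front with a warning.
#'
#' @param metric_table Output of [segment_metrics()] (>= 3 rows).
#' @param metrics Candidate metric names (default: all 16).
#' @param threshold Absolute correlation at or above which a pair is
#'   considered collinear.
#' @param priority Ordered character vector ranking the candidates;
#'   candidates missing from it are appended in input order.
#' @return A list with `retained` (character, in priority order), `dropped`
#'   (data frame: metric, correlated with, r), and `correlations` (the full
#'   Pearson matrix over non-degenerate candidates).
#' @export
screen_collinearity <- function(metric_table, metrics = metric_names(),
                                threshold = 0.7,
                                priority = default_metric_priority()) {
  stopifnot(all(metrics %in% names(metric_table)))
  if (nrow(metric_table) < 3)
    stop("need at least 3 segments to screen collinearity")
  sds <- vapply(metric_table[metrics], stats::sd, 0)
  degenerate <- metrics[sds == 0 | !is.finite(sds)]
  if (length(degenerate)) {
    warning("excluding zero-variance metric(s): ",
            paste(degenerate, collapse = ", "))
    metrics <- setdiff(metrics, degenerate)
  }
  ord <- c(intersect(priority, metrics), setdiff(metrics, priority))
  cm <- stats::cor(metric_table[ord])
  retained <- character()
  dropped <- data.frame(metric = character(), correlated_with = character(),
                        r = numeric())
  for (m in ord) {
    if (length(retained)) {
      r <- cm[m, retained]
      hit <- which(abs(r) >= threshold)
      if (length(hit)) {
        worst <- hit[which.max(abs(r[hit]))]
        dropped <- rbind(dropped,
                         data.frame(metric = m,
                                    correlated_with = retained[worst],
                                    r = unname(r[worst])))
        next
      }
    }
    retained <- c(retained, m)
  }
  list(retained = retained, dropped = dropped, correlations = cm)
}
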