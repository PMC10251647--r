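#' Construct a depth series
#'
#' A per-individual, uniformly sampled time-depth trace. Times must be
#' strictly increasing with a constant step of `1/rate_hz` (to within 1e-6);
#' small negative depths (sensor noise down to -1 m) are clipped to 0 on
#' ingest, larger negatives are rejected.
#'
#' @param time_s Sample times in seconds since record start.
#' @param depth_m Depths in metres, positive downward.
#' @param individual_id Identifier of the tagged individual.
#' @param rate_hz Sampling rate in Hz.
#' @return A data frame of class `depth_series` with columns `time_s`,
#'   `depth_m` and attributes `individual_id` and `rate_hz`.
#' @export
depth_series <- function(time_s, depth_m, individual_id, rate_hz = 1) {
  stopifnot(length(time_s) == length(depth_m), rate_hz > 0)
  if (length(time_s) >= 2) {
    dt <- diff(time_s)
    if (any(dt <= 0) || any(abs(dt - 1 / rate_hz) > 1e-6))
      stop("time_s must increase uniformly by 1/rate_hz")
  }
  if (any(!is.finite(depth_m)))
    stop("depths must be finite")
  if (any(depth_m < -1))
    stop("depths below -1 m are not plausible sensor noise")
  depth_m <- pmax(depth_m, 0)
  structure(data.frame(time_s = time_s, depth_m = depth_m),
            individual_id = as.character(individual_id),
            rate_hz = rate_hz,
            class = c("depth_series", "data.frame"))
}

#' Downsample a depth series by decimation
#'
#' Reduces a high-rate depth trace to `target_hz` by keeping the first
#' sample of each block (decimation, not averaging: time-depth recorders log
#' instantaneous pressure). The output length is
#' `floor(n / (rate_hz / target_hz))`.
#'
#' @param series A [depth_series()].
#' @param target_hz Target rate; `rate_hz` must be an integer multiple of it.
#' @return A [depth_series()] at `target_hz`. A series already at the target
#'   rate is returned unchanged.
#' @export
downsample_depth <- function(series, target_hz = 1) {
  stopifnot(inherits(series, "depth_series"))
  rate <- attr(series, "rate_hz")
  if (rate == target_hz)
    return(series)
  ratio <- rate / target_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("rate %g Hz is not an integer multiple of target %g Hz",
                 rate, target_hz))
  ratio <- round(ratio)
  keep <- seq(1L, by = ratio, length.out = nrow(series) %/% ratio)
  depth_series(series$time_s[keep], series$depth_m[keep],
               attr(series, "individual_id"), target_hz)
}

#' Label descent, bottom and ascent phases of a dive
#'
#' Phases follow the sign of the 1 Hz depth rate `r(t) = depth(t) -
#' depth(t-1)`: the descent is the maximal initial run of positive rates and
#' the ascent the maximal final run of negative rates, each ignoring brief
#' reversal episodes of at most `reversal_tolerance_s` seconds provided the
#' phase then resumes for longer than the tolerance (so the jittery,
#' sign-alternating bottom phase is not absorbed); the bottom phase is
#' whatever lies between (possibly empty). The deepest boundary
#' sample is assigned to the descent, so labels always appear in the order
#' descent, bottom, ascent and every sample gets exactly one label.
#'
#' @param depths 1 Hz depth samples of one dive (length >= 3).
#' @param reversal_tolerance_s Maximum duration (s) of a contrary-rate
#'   episode absorbed into the surrounding phase.
#' @return Character vector (`"descent"`, `"bottom"`, `"ascent"`) of the same
#'   length as `depths`.
#' @export
label_phases <- function(depths, reversal_tolerance_s = 10) {
  n <- length(depths)
  if (n < 3)
    stop("a dive must span at least 3 samples to be phase-labelled")
  r <- diff(depths)
  d_steps <- .phase_run(r > 0, reversal_tolerance_s)
  a_steps <- .phase_run(rev(r) < 0, reversal_tolerance_s)
  # steps 1..d_steps are descent -> samples 1..d_steps+1 (deepest boundary
  # sample goes to the descent); last a_steps steps -> samples n-a_steps+1..n
  d_end <- max(min(d_steps + 1L, n - 2L), 1L)
  a_start <- min(max(n - a_steps + 1L, d_end + 1L), n)
  lab <- rep("bottom", n)
  lab[seq_len(d_end)] <- "descent"
  lab[a_start:n] <- "ascent"
  lab
}

# Length of the maximal prefix of TRUE steps. A FALSE episode of at most
# `tol` steps is absorbed only when the phase resumes for longer than `tol`
# steps afterwards: this ignores brief reversals within a sustained descent/
# ascent without swallowing a jittery bottom phase, whose same-direction
# runs are themselves short.
.phase_run <- function(ok, tol) {
  if (!length(ok) || !ok[1])
    return(0L)
  runs <- rle(ok)
  len <- runs$lengths[1]
  i <- 2L
  while (i < length(runs$lengths)) {
    # runs alternate, so runs i (FALSE) and i+1 (TRUE)
    if (runs$lengths[i] > tol || runs$lengths[i + 1L] <= tol)
      break
    len <- len + runs$lengths[i] + runs$lengths[i + 1L]
    i <- i + 2L
  }
  len
}

#' Detect dives in a 1 Hz depth series
#'
#' A candidate dive is a maximal run of samples deeper than `threshold`
#' (default 25 m). The chronologically first dive of each individual is
#' excluded when `drop_first` (tag-deployment disturbance); a dive is flagged
#' as foraging when at least one buzz starts inside it. All remaining
#' candidate dives are returned with flags, so non-foraging dives stay
#' available for reporting; modelling stages keep only foraging dives.
#'
#' @param series A 1 Hz [depth_series()].
#' @param buzzes Buzz event table (`individual_id`, `start_s`, `end_s`).
#' @param threshold Dive depth threshold in metres.
#' @param drop_first Exclude the individual's first candidate dive.
#' @param reversal_tolerance_s Passed to [label_phases()].
#' @return A data frame of class `dive_table`: one row per dive with columns
#'   `individual_id`, `dive_id`, `start_index`, `end_index` (1-based,
#'   half-open into the series), `start_s`, `end_s`, `duration_s`,
#'   `max_depth`, `n_buzzes`, `is_foraging`, and a list column
#'   `phase_labels`. Zero rows when the series never exceeds the threshold.
#' @export
detect_dives <- function(series, buzzes, threshold = 25, drop_first = TRUE,
                         reversal_tolerance_s = 10) {
  stopifnot(inherits(series, "depth_series"))
  if (attr(series, "rate_hz") != 1)
    stop("detect_dives expects a 1 Hz series; downsample first")
  id <- attr(series, "individual_id")
  deep <- series$depth_m > threshold
  runs <- rle(deep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- which(runs$values & runs$lengths >= 3L)
  empty <- data.frame(individual_id = character(), dive_id = integer(),
                      start_index = integer(), end_index = integer(),
                      start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), max_depth = numeric(),
                      n_buzzes = integer(), is_foraging = logical())
  empty$phase_labels <- list()
  class(empty) <- c("dive_table", "data.frame")
  if (!length(sel))
    return(empty)
  bz <- buzzes[buzzes$individual_id == id, , drop = FALSE]
  out <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i0 <- starts[sel[k]]
    i1 <- ends[sel[k]]
    dd <- series$depth_m[i0:i1]
    t0 <- series$time_s[i0]
    t1 <- series$time_s[i1] + 1  # half-open end time
    nb <- sum(bz$start_s >= t0 & bz$start_s < t1)
    rec <- data.frame(individual_id = id, dive_id = k,
                      start_index = i0, end_index = i1 + 1L,
                      start_s = t0, end_s = t1, duration_s = t1 - t0,
                      max_depth = max(dd), n_buzzes = nb,
                      is_foraging = nb >= 1L)
    rec$phase_labels <- list(label_phases(dd, reversal_tolerance_s))
    out[[k]] <- rec
  }
  dives <- do.call(rbind, out)
  if (drop_first)
    dives <- dives[-1L, , drop = FALSE]
  rownames(dives) <- NULL
  class(dives) <- c("dive_table", "data.frame")
  dives
}

#' Cut dives into fixed-duration segments
#'
#' Each dive is partitioned into consecutive, non-overlapping windows of
#' `segment_duration` seconds starting at the dive's first sample; the
#' trailing incomplete window is discarded. A buzz is assigned to the
#' segment whose half-open window `[start, end)` contains its start time, so
#' totals are conserved; the phase of a segment is the phase label of its
#' first second.
#'
#' @param dives A `dive_table` from [detect_dives()].
#' @param series The [depth_series()] the dives index into.
#' @param buzzes Buzz event table.
#' @param segment_duration Window length in seconds (positive; 30, 60, 180
#'   and 300 s are the durations typically analysed).
#' @param foraging_only Keep segments of foraging dives only (default), as
#'   used for modelling.
#' @return A data frame of class `segment_table`: `individual_id`, `dive_id`,
#'   `segment_id`, `segment_duration`, `start_s`, `phase`, `buzz_count`,
#'   `dive_max_depth`, plus a list column `depths` with the segment's 1 Hz
#'   samples.
#' @export
segment_dives <- function(dives, series, buzzes, segment_duration,
                          foraging_only = TRUE) {
  stopifnot(inherits(dives, "data.frame"))
  if (length(segment_duration) != 1 || segment_duration <= 0)
    stop("segment_duration must be a single positive number of seconds")
  if (foraging_only)
    dives <- dives[dives$is_foraging, , drop = FALSE]
  id <- attr(series, "individual_id")
  bz <- buzzes[buzzes$individual_id == id, , drop = FALSE]
  dive_id <- integer(); seg_id <- integer(); start_s <- numeric()
  phase <- character(); buzz_count <- integer(); maxd <- numeric()
  depth_list <- list()
  for (k in seq_len(nrow(dives))) {
    n <- dives$end_index[k] - dives$start_index[k]
    n_seg <- n %/% segment_duration
    if (n_seg < 1) next
    labs <- dives$phase_labels[[k]]
    for (j in seq_len(n_seg)) {
      off <- (j - 1L) * segment_duration
      idx <- dives$start_index[k] + off + seq_len(segment_duration) - 1L
      w0 <- dives$start_s[k] + off
      w1 <- w0 + segment_duration
      dive_id <- c(dive_id, dives$dive_id[k])
      seg_id <- c(seg_id, j)
      start_s <- c(start_s, w0)
      phase <- c(phase, labs[off + 1L])
      buzz_count <- c(buzz_count,
                      sum(bz$start_s >= w0 & bz$start_s < w1))
      maxd <- c(maxd, dives$max_depth[k])
      depth_list[[length(depth_list) + 1L]] <- series$depth_m[idx]
    }
  }
  segs <- data.frame(individual_id = rep(id, length(dive_id)),
                     dive_id = dive_id, segment_id = seg_id,
                     segment_duration = rep(segment_duration,
                                            length(dive_id)),
                     start_s = start_s,
                     phase = phase, buzz_count = buzz_count,
                     dive_max_depth = maxd,
                     stringsAsFactors = FALSE)
  segs$depths <- depth_list
  rownames(segs) <- NULL
  class(segs) <- c("segment_table", "data.frame")
  segs
}
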