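#' Tracking ratio of a gaze recording
#'
#' Fraction of samples with a valid eye detection, computed on the raw
#' acquisition validity flags (before any interpolation): it is a gate on
#' acquisition quality, not on post-processing.
#'
#' @param recording A `gaze_recording`.
#' @return A fraction in \[0, 1\].
#' @export
compute_tracking_ratio <- function(recording) {
  n <- nrow(recording$samples)
  if (n < 1) stop("recording has no samples")
  mean(recording$samples$raw_valid %||% recording$samples$valid)
}

#' Exclude recordings below a tracking-ratio threshold
#'
#' Recordings whose tracking ratio meets the threshold (>=, so exactly
#' 80% is kept) are retained; the rest are excluded from analysis.
#'
#' @param recordings List of `gaze_recording`.
#' @param threshold Minimum tracking ratio, default 0.80.
#' @return A list with `kept`, `excluded` (lists of recordings) and
#'   `report` (data.frame: id, tracking_ratio, included).
#' @export
apply_exclusion <- function(recordings, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(recordings)) {
    return(list(kept = list(), excluded = list(),
                report = data.frame(id = character(),
                                    tracking_ratio = numeric(),
                                    included = logical())))
  }
  ratio <- vapply(recordings, compute_tracking_ratio, numeric(1))
  inc <- ratio >= threshold
  list(kept = recordings[inc], excluded = recordings[!inc],
       report = data.frame(
         id = vapply(recordings, function(r) r$id %||% NA_character_,
                     character(1)),
         tracking_ratio = ratio, included = inc,
         stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike correction by invalidation and short-gap interpolation
#'
#' A sample is flagged as a spike when the angular velocity both into and
#' out of it exceeds `v_max_deg_s` (an out-and-back excursion no real eye
#' movement produces; saccades peak well below the default 1000 deg/s).
#' Spike samples are invalidated, then every invalid gap no longer than
#' `max_gap_ms` is refilled by linear interpolation in time between the
#' nearest valid neighbours (one-sided fill with the nearest valid value
#' at the recording edges). Longer gaps — blinks and signal loss — are
#' left invalid. Timestamps are never modified. The raw acquisition
#' validity is preserved in a `raw_valid` column so that tracking-ratio
#' and blink computations remain defined on the unprocessed flags.
#'
#' @param recording A `gaze_recording`.
#' @param v_max_deg_s Velocity threshold in deg/s.
#' @param max_gap_ms Longest gap (ms) that is interpolated.
#' @return The corrected `gaze_recording`, with `raw_valid` and
#'   `interpolated` columns added to `samples` and counters
#'   `n_spikes`, `n_interpolated` attached.
#' @export
despike <- function(recording, v_max_deg_s = 1000, max_gap_ms = 75) {
  stopifnot(v_max_deg_s > 0)
  s <- recording$samples
  if (is.null(s$raw_valid)) s$raw_valid <- s$valid
  geom <- recording$geometry
  n <- nrow(s)
  valid <- s$valid
  iv <- which(valid)
  spike <- logical(n)
  if (length(iv) >= 3) {
    dx <- diff(s$x_px[iv]); dy <- diff(s$y_px[iv])
    dt <- diff(s$t_ms[iv])
    v <- px_to_deg(sqrt(dx^2 + dy^2), geom) / (dt / 1000)  # deg/s
    fast <- v > v_max_deg_s
    # velocity into sample iv[k+1] is v[k]; out of it is v[k+1]
    mid <- which(fast[-length(fast)] & fast[-1]) + 1L
    spike[iv[mid]] <- TRUE
    # edge samples have only one velocity to judge by; blame the edge
    # sample unless the adjacent interior sample is already implicated
    m <- length(fast)
    if (fast[1] && !fast[2]) spike[iv[1]] <- TRUE
    if (fast[m] && !fast[m - 1]) spike[iv[m + 1L]] <- TRUE
  }
  valid[spike] <- FALSE
  s$x_px[spike] <- NA_real_
  s$y_px[spike] <- NA_real_

  interp <- logical(n)
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dt_nom <- if (n > 1) stats::median(diff(s$t_ms)) else 0
  for (k in which(!runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    gap_ms <- (i1 - i0 + 1L) * dt_nom
    if (gap_ms > max_gap_ms) next
    left <- if (i0 > 1) i0 - 1L else NA_integer_
    right <- if (i1 < n) i1 + 1L else NA_integer_
    if (is.na(left) && is.na(right)) next
    idx <- i0:i1
    if (is.na(left)) {       # one-sided fill at the start
      s$x_px[idx] <- s$x_px[right]; s$y_px[idx] <- s$y_px[right]
    } else if (is.na(right)) {
      s$x_px[idx] <- s$x_px[left]; s$y_px[idx] <- s$y_px[left]
    } else {
      w <- (s$t_ms[idx] - s$t_ms[left]) / (s$t_ms[right] - s$t_ms[left])
      s$x_px[idx] <- s$x_px[left] + w * (s$x_px[right] - s$x_px[left])
      s$y_px[idx] <- s$y_px[left] + w * (s$y_px[right] - s$y_px[left])
    }
    valid[idx] <- TRUE
    interp[idx] <- TRUE
  }
  s$valid <- valid
  s$interpolated <- interp | (s$interpolated %||% FALSE)
  recording$samples <- s
  attr(recording, "n_spikes") <- sum(spike)
  attr(recording, "n_interpolated") <- sum(interp)
  recording
}

#' Light median filtering of gaze coordinates
#'
#' Running median (default window 3) applied to the valid gaze samples to
#' suppress single-sample measurement noise. Optional in the pipeline.
#'
#' @param recording A `gaze_recording`.
#' @param window Odd window length.
#' @return The filtered recording.
#' @export
median_filter <- function(recording, window = 3) {
  s <- recording$samples
  iv <- which(s$valid)
  if (length(iv) > window) {
    s$x_px[iv] <- stats::runmed(s$x_px[iv], window)
    s$y_px[iv] <- stats::runmed(s$y_px[iv], window)
  }
  recording$samples <- s
  recording
}

#' Detect blinks as bounded runs of invalid samples
#'
#' A blink is a maximal contiguous run of invalid samples whose duration
#' falls within physiological bounds; shorter runs are tracking dropouts
#' and longer runs signal loss. Detection uses the raw acquisition
#' validity (`raw_valid` if present), so interpolation never hides a
#' blink. Run duration is the number of samples times the nominal sample
#' interval.
#'
#' @param recording A `gaze_recording`.
#' @param min_ms,max_ms Blink duration bounds (default 75-500 ms).
#' @return A data.frame of blink events: `t_start`, `t_end`,
#'   `duration_ms`, time-ordered and non-overlapping.
#' @export
detect_blinks <- function(recording, min_ms = 75, max_ms = 500) {
  stopifnot(min_ms > 0, min_ms < max_ms)
  s <- recording$samples
  valid <- s$raw_valid %||% s$valid
  n <- length(valid)
  empty <- data.frame(t_start = numeric(), t_end = numeric(),
                      duration_ms = numeric())
  if (n < 1 || all(valid)) return(empty)
  dt_nom <- if (n > 1) stats::median(diff(s$t_ms)) else 0
  runs <- rle(!valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  dur <- runs$lengths[keep] * dt_nom
  ok <- dur >= min_ms & dur <= max_ms
  if (!any(ok)) return(empty)
  data.frame(t_start = s$t_ms[starts[keep[ok]]],
             t_end = s$t_ms[starts[keep[ok]]] + dur[ok],
             duration_ms = dur[ok])
}

#' Full quality-control pass over one recording
#'
#' Computes the tracking ratio on the raw flags, then applies spike
#' correction and (optionally) median filtering. Blink detection is left
#' to feature extraction, which runs it on the raw validity.
#'
#' @param recording A `gaze_recording`.
#' @param v_max_deg_s,max_gap_ms See [despike()].
#' @param median_window Odd window for [median_filter()]; `0` disables.
#' @return The cleaned recording with a `qc` attribute
#'   (tracking_ratio, n_spikes, n_interpolated).
#' @export
clean_recording <- function(recording, v_max_deg_s = 1000,
                            max_gap_ms = 75, median_window = 3) {
  ratio <- compute_tracking_ratio(recording)
  out <- despike(recording, v_max_deg_s, max_gap_ms)
  if (median_window >= 3) out <- median_filter(out, median_window)
  attr(out, "qc") <- list(tracking_ratio = ratio,
                          n_spikes = attr(out, "n_spikes"),
                          n_interpolated = attr(out, "n_interpolated"))
  out
}
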