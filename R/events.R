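# Fixation/saccade classification and saccadic latency.

# Largest pairwise distance among points (px). Uses the convex hull for
# large point sets since the diameter is attained on the hull.
max_pairwise_dist <- function(x, y) {
  n <- length(x)
  if (n <= 1) return(0)
  if (n > 60) {
    h <- tryCatch(grDevices::chull(x, y), error = function(e) seq_len(n))
    x <- x[h]; y <- y[h]
  }
  max(stats::dist(cbind(x, y)))
}

# Convex-hull area (px^2) by the shoelace formula; degenerate sets -> 0.
hull_area <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Dispersion-threshold (I-DT) fixation and saccade classification
#'
#' Classic I-DT over the valid samples of a cleaned recording. A window
#' spanning at least `min_duration_ms` is opened; if its dispersion
#' ((max x - min x) + (max y - min y), converted to visual degrees) is at
#' or below `dispersion_deg` the window grows until the threshold is
#' violated and the window is emitted as a fixation, otherwise the window
#' slides one sample. Runs of invalid samples split the data into chunks
#' that are classified independently — no event spans a gap. The interval
#' between two consecutive fixations of a chunk becomes a saccade when the
#' displacement between their centroids exceeds the dispersion threshold.
#'
#' Each fixation carries its centroid, duration, dispersion (largest
#' pairwise sample distance, px) and convex-hull area (px^2); each saccade
#' its amplitude (deg), median inter-sample velocity (deg/s), direction
#' angle (deg, screen convention) and saccadic plane (+/-22.5 degree bins:
#' horizontal, vertical, diagonal).
#'
#' @param recording A cleaned `gaze_recording`.
#' @param dispersion_deg Dispersion threshold in degrees (default 1.0).
#' @param min_duration_ms Minimum fixation duration (default 100 ms).
#' @return A data.frame of events, time-ordered, with columns `kind`,
#'   `t_start`, `t_end`, `duration_ms`, `centroid_x`, `centroid_y`,
#'   `dispersion_px`, `area_px2`, `n_samples`, `amplitude_deg`,
#'   `median_vel_deg_s`, `angle_deg`, `plane`, `seq_idx`, `pos_idx`
#'   (stimulus attribution is `NA` until [attribute_events()]).
#' @export
idt_classify <- function(recording, dispersion_deg = 1.0,
                         min_duration_ms = 100) {
  stopifnot(dispersion_deg > 0, min_duration_ms > 0)
  s <- recording$samples
  geom <- recording$geometry
  thresh_px <- deg_to_px(dispersion_deg, geom)
  dt_nom <- if (nrow(s) > 1) stats::median(diff(s$t_ms)) else Inf
  min_win <- floor(min_duration_ms / dt_nom + 1e-9) + 1

  runs <- rle(s$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (ch in which(runs$values)) {
    idx <- starts[ch]:ends[ch]
    if (length(idx) < min_win) next
    x <- s$x_px[idx]; y <- s$y_px[idx]; t <- s$t_ms[idx]
    n <- length(idx)
    fix <- list()
    i <- 1L
    while (i + min_win - 1L <= n) {
      j <- i + min_win - 1L
      xmin <- min(x[i:j]); xmax <- max(x[i:j])
      ymin <- min(y[i:j]); ymax <- max(y[i:j])
      if ((xmax - xmin) + (ymax - ymin) <= thresh_px) {
        while (j < n) {
          nx <- x[j + 1L]; ny <- y[j + 1L]
          xmin2 <- min(xmin, nx); xmax2 <- max(xmax, nx)
          ymin2 <- min(ymin, ny); ymax2 <- max(ymax, ny)
          if ((xmax2 - xmin2) + (ymax2 - ymin2) > thresh_px) break
          xmin <- xmin2; xmax <- xmax2; ymin <- ymin2; ymax <- ymax2
          j <- j + 1L
        }
        fix[[length(fix) + 1L]] <- c(i, j)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    if (!length(fix)) next
    i0v <- vapply(fix, `[`, numeric(1), 1)
    i1v <- vapply(fix, `[`, numeric(1), 2)
    cx <- vapply(fix, function(f) mean(x[f[1]:f[2]]), numeric(1))
    cy <- vapply(fix, function(f) mean(y[f[1]:f[2]]), numeric(1))
    nf <- length(fix)
    fx_rows <- list(
      kind = rep("fixation", nf), t_start = t[i0v], t_end = t[i1v],
      duration_ms = t[i1v] - t[i0v], centroid_x = cx, centroid_y = cy,
      dispersion_px = vapply(fix, function(f)
        max_pairwise_dist(x[f[1]:f[2]], y[f[1]:f[2]]), numeric(1)),
      area_px2 = vapply(fix, function(f)
        hull_area(x[f[1]:f[2]], y[f[1]:f[2]]), numeric(1)),
      n_samples = i1v - i0v + 1,
      amplitude_deg = rep(NA_real_, nf),
      median_vel_deg_s = rep(NA_real_, nf),
      angle_deg = rep(NA_real_, nf), plane = rep(NA_character_, nf))
    out[[length(out) + 1L]] <- fx_rows
    if (nf > 1) {
      disp <- sqrt(diff(cx)^2 + diff(cy)^2)
      sac_f <- which(disp > thresh_px) + 1L   # saccade into fixation f
      if (length(sac_f)) {
        p0 <- i1v[sac_f - 1L]; p1 <- i0v[sac_f]
        vel <- vapply(seq_along(sac_f), function(k) {
          r <- p0[k]:p1[k]
          stats::median(px_to_deg(
            sqrt(diff(x[r])^2 + diff(y[r])^2), geom) /
            (diff(t[r]) / 1000))
        }, numeric(1))
        ang <- atan2(y[p1] - y[p0], x[p1] - x[p0]) * 180 / pi
        out[[length(out) + 1L]] <- list(
          kind = rep("saccade", length(sac_f)),
          t_start = t[p0], t_end = t[p1], duration_ms = t[p1] - t[p0],
          centroid_x = x[p0], centroid_y = y[p0],
          dispersion_px = rep(NA_real_, length(sac_f)),
          area_px2 = rep(NA_real_, length(sac_f)),
          n_samples = p1 - p0 + 1,
          amplitude_deg = px_to_deg(
            sqrt((x[p1] - x[p0])^2 + (y[p1] - y[p0])^2), geom),
          median_vel_deg_s = vel, angle_deg = ang %% 360,
          plane = saccade_plane(ang))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), t_start = numeric(),
                      t_end = numeric(), duration_ms = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      dispersion_px = numeric(), area_px2 = numeric(),
                      n_samples = integer(), amplitude_deg = numeric(),
                      median_vel_deg_s = numeric(),
                      angle_deg = numeric(), plane = character(),
                      seq_idx = integer(), pos_idx = integer(),
                      stringsAsFactors = FALSE))
  } else {
    fields <- names(out[[1]])
    ev <- as.data.frame(
      stats::setNames(lapply(fields, function(f)
        unlist(lapply(out, `[[`, f), use.names = FALSE)), fields),
      stringsAsFactors = FALSE)
    ev <- ev[order(ev$t_start), ]
    rownames(ev) <- NULL
  }
  ev$seq_idx <- NA_integer_
  ev$pos_idx <- NA_integer_
  ev
}

#' Attribute events to stimuli
#'
#' Assigns each event the sequence/position of the stimulus whose
#' presentation interval (onset to next onset) contains the event start.
#' A fixation that begins on the previous target and continues past the
#' next onset therefore stays attributed to the stimulus it was serving.
#'
#' @param events Events from [idt_classify()].
#' @param stimuli The `stimuli` table of a `gaze_recording`.
#' @return The events with `seq_idx`/`pos_idx` filled (NA before the
#'   first onset).
#' @export
attribute_events <- function(events, stimuli) {
  if (!nrow(events)) return(events)
  k <- findInterval(events$t_start, stimuli$onset_ms)
  events$seq_idx <- ifelse(k >= 1, stimuli$seq_idx[pmax(k, 1)],
                           NA_integer_)
  events$pos_idx <- ifelse(k >= 1, stimuli$pos_idx[pmax(k, 1)],
                           NA_integer_)
  events
}

#' Saccadic latency per stimulus
#'
#' For each stimulus onset, the latency is the start time (relative to
#' onset) of the first saccade that (a) begins after the onset and before
#' the next one, and (b) points within `max_angle` degrees of the
#' direction from its own start position to the new target — rejecting
#' intrusive saccades away from the target. Stimuli with no qualifying
#' saccade yield `NA`, excluded from downstream aggregation.
#'
#' @param events Events from [idt_classify()].
#' @param stimuli The `stimuli` table of a `gaze_recording`.
#' @param max_angle Direction gate in degrees (default 45).
#' @return Numeric vector of latencies (ms), one per stimulus.
#' @export
saccadic_latency <- function(events, stimuli, max_angle = 45) {
  sac <- events[events$kind == "saccade", , drop = FALSE]
  n_stim <- nrow(stimuli)
  lat <- rep(NA_real_, n_stim)
  if (!nrow(sac)) return(lat)
  next_onset <- c(stimuli$onset_ms[-1], Inf)
  for (k in seq_len(n_stim)) {
    cand <- sac[sac$t_start > stimuli$onset_ms[k] &
                sac$t_start < next_onset[k], , drop = FALSE]
    if (!nrow(cand)) next
    tgt_ang <- atan2(stimuli$target_y[k] - cand$centroid_y,
                     stimuli$target_x[k] - cand$centroid_x) * 180 / pi
    ok <- angle_diff(cand$angle_deg, tgt_ang %% 360) <= max_angle
    if (any(ok)) lat[k] <- cand$t_start[which(ok)[1]] - stimuli$onset_ms[k]
  }
  lat
}
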