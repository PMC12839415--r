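#' The 31-feature oculometric dictionary
#'
#' Names and metadata of the 31 features computed per participant: 6
#' time-related (total test time, mean response time per workload
#' position, mean and SD of saccadic latency) and 25 eye-movement-related
#' (per-position fixation time/size/area means and SDs, per-plane median
#' saccadic velocities, blink rate and median duration, pupil-size SD and
#' coefficient of variation). `log` marks the features designated for
#' logarithmic transformation during preprocessing.
#'
#' @return A data.frame with columns `name` (column name used in feature
#'   tables), `display` (human-readable label), `category` (`time` or
#'   `eye`), `subgroup`, `position` (workload position 1-3 or NA) and
#'   `log`.
#' @examples
#' table(ocat_feature_dictionary()$category)
#' @export
ocat_feature_dictionary <- function() {
  time <- data.frame(
    name = c("total_test_time_s", "mean_time_number_1_s",
             "mean_time_number_2_s", "mean_time_number_3_s",
             "mean_latency_ms", "sd_latency_ms"),
    display = c(
      "Total Test Time (s)",
      "Mean Time for Number 1 (low cognitive workload) (s)",
      "Mean Time for Number 2 (medium cognitive workload) (s)",
      "Mean Time for Number 3 (high cognitive workload) (s)",
      "(Log-) Mean Latency Time (ms)",
      "(Log-) Standard Deviation of Latency Time (ms)"),
    category = "time", subgroup = "time",
    position = c(NA, 1, 2, 3, NA, NA),
    log = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  fx <- do.call(rbind, lapply(1:3, function(k) data.frame(
    name = sprintf(c("mean_fix_time_%d_ms", "sd_fix_time_%d_ms",
                     "mean_fix_size_%d_mm", "sd_fix_size_%d_mm",
                     "mean_fix_area_%d_mm2", "sd_fix_area_%d_mm2"), k),
    display = sprintf(c(
      "Mean Fixation Time for Number %d (ms)",
      "(Log-) Standard Deviation of Fixation Time for Number %d (ms)",
      "Mean Fixation Size for Number %d (mm)",
      "(Log-) Standard Deviation of Fixation Size for Number %d (mm)",
      "Mean Fixation Area for Number %d (mm^2)",
      "(Log-) Standard Deviation of Fixation Area for Number %d (mm^2)"),
      k),
    category = "eye", subgroup = "fixations", position = k,
    log = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)))
  rest <- data.frame(
    name = c("median_sacc_vel_diagonal_deg_s",
             "median_sacc_vel_horizontal_deg_s",
             "median_sacc_vel_vertical_deg_s",
             "blink_rate_per_min", "median_blink_duration_ms",
             "pupil_sd_mm", "pupil_cv"),
    display = c("Median Diagonal Saccadic Velocity (deg/s)",
                "Median Horizontal Saccadic Velocity (deg/s)",
                "Median Vertical Saccadic Velocity (deg/s)",
                "Blink Rate (number of blinks per minute)",
                "Median Blink Duration (ms)",
                "Standard Deviation of Pupil Size (mm)",
                "Coefficient of Variation of Pupil Size"),
    category = "eye",
    subgroup = c("saccades", "saccades", "saccades", "blinks", "blinks",
                 "pupil", "pupil"),
    position = NA, log = FALSE, stringsAsFactors = FALSE)
  rbind(time, fx, rest)
}

#' Time-related features of a session
#'
#' Total test time is last click minus first onset (s). Per-position
#' response times are click-minus-onset averaged over sequences (s).
#' Latency mean/SD are over the non-missing per-stimulus saccadic
#' latencies (ms); the log transform happens later in preprocessing.
#'
#' @param recording A `gaze_recording`.
#' @param latencies Per-stimulus latencies from [saccadic_latency()].
#' @return Named numeric vector of 6 features.
#' @export
time_features <- function(recording, latencies) {
  st <- recording$stimuli; cl <- recording$clicks
  if (nrow(cl) != nrow(st)) {
    stop("every stimulus needs exactly one click (", nrow(st),
         " stimuli, ", nrow(cl), " clicks)")
  }
  rt <- (cl$t_ms - st$onset_ms) / 1000
  lat <- latencies[!is.na(latencies)]
  c(total_test_time_s = (max(cl$t_ms) - min(st$onset_ms)) / 1000,
    mean_time_number_1_s = mean(rt[st$pos_idx == 1]),
    mean_time_number_2_s = mean(rt[st$pos_idx == 2]),
    mean_time_number_3_s = mean(rt[st$pos_idx == 3]),
    mean_latency_ms = if (length(lat)) mean(lat) else NA_real_,
    sd_latency_ms = if (length(lat) > 1) stats::sd(lat) else NA_real_)
}

#' Per-position fixation features
#'
#' For each workload position, fixation time (ms), size (largest pairwise
#' sample distance, mm) and area (convex-hull area, mm^2) are pooled over
#' all attributed fixations across sequences; mean and SD of each are
#' reported. Positions with no fixations give `NA` with a warning.
#'
#' @param events Attributed events (see [attribute_events()]).
#' @param geometry A [screen_geometry()].
#' @return Named numeric vector of 18 features.
#' @export
fixation_features <- function(events, geometry = screen_geometry()) {
  fx <- events[events$kind == "fixation" & !is.na(events$pos_idx), ,
               drop = FALSE]
  out <- numeric(0)
  for (k in 1:3) {
    f <- fx[fx$pos_idx == k, , drop = FALSE]
    if (!nrow(f)) {
      warning("no fixations attributed to position ", k)
      v <- rep(NA_real_, 6)
    } else {
      tm <- f$duration_ms
      sz <- px_to_mm(f$dispersion_px, geometry)
      ar <- f$area_px2 * geometry$mm_per_px^2
      sd0 <- function(z) if (length(z) > 1) stats::sd(z) else 0
      v <- c(mean(tm), sd0(tm), mean(sz), sd0(sz), mean(ar), sd0(ar))
    }
    names(v) <- sprintf(c("mean_fix_time_%d_ms", "sd_fix_time_%d_ms",
                          "mean_fix_size_%d_mm", "sd_fix_size_%d_mm",
                          "mean_fix_area_%d_mm2", "sd_fix_area_%d_mm2"),
                        k)
    out <- c(out, v)
  }
  out
}

#' Per-plane median saccadic velocities
#'
#' Each saccade's median inter-sample velocity is grouped by its plane
#' (horizontal/vertical/diagonal, +/-22.5 degree direction bins) and the
#' per-plane median is reported. Empty planes give `NA` with a warning.
#'
#' @param events Events from [idt_classify()].
#' @return Named numeric vector of 3 features.
#' @export
saccade_velocity_features <- function(events) {
  sac <- events[events$kind == "saccade", , drop = FALSE]
  med <- function(plane) {
    v <- sac$median_vel_deg_s[sac$plane == plane]
    if (!length(v)) {
      warning("no saccades in the ", plane, " plane")
      return(NA_real_)
    }
    stats::median(v)
  }
  c(median_sacc_vel_diagonal_deg_s = med("diagonal"),
    median_sacc_vel_horizontal_deg_s = med("horizontal"),
    median_sacc_vel_vertical_deg_s = med("vertical"))
}

#' Blink rate and median blink duration
#'
#' @param blinks Blink events from [detect_blinks()].
#' @param duration_s Recording duration in seconds.
#' @return Named numeric vector: blinks per minute and median duration
#'   (ms; `NA` with a warning when there are no blinks).
#' @export
blink_features <- function(blinks, duration_s) {
  stopifnot(duration_s > 0)
  n <- nrow(blinks)
  if (n == 0) warning("no blinks detected; median duration is NA")
  c(blink_rate_per_min = 60 * n / duration_s,
    median_blink_duration_ms = if (n) stats::median(blinks$duration_ms)
                               else NA_real_)
}

#' Pupil-size variability features
#'
#' SD and coefficient of variation (SD/mean) of pupil diameter over valid
#' samples; blink samples carry no pupil value and are excluded.
#'
#' @param recording A `gaze_recording`.
#' @return Named numeric vector: `pupil_sd_mm`, `pupil_cv`.
#' @export
pupil_features <- function(recording) {
  p <- recording$samples$pupil_mm
  p <- p[recording$samples$valid & !is.na(p)]
  if (length(p) < 2) stop("fewer than 2 valid pupil samples")
  s <- stats::sd(p)
  c(pupil_sd_mm = s, pupil_cv = s / mean(p))
}

#' Extract the full feature vector of one participant
#'
#' Runs event classification, latency estimation, blink detection and the
#' component feature functions on a cleaned recording and assembles the
#' 31-feature dictionary plus age. Deterministic given its inputs.
#'
#' @param recording A cleaned `gaze_recording` (see [clean_recording()]).
#' @param age Participant age in years.
#' @param dispersion_deg,min_duration_ms I-DT settings.
#' @param blink_min_ms,blink_max_ms Blink duration bounds.
#' @return A one-row data.frame with the 31 dictionary columns plus
#'   `age`.
#' @export
extract_features <- function(recording, age,
                             dispersion_deg = 1.0, min_duration_ms = 100,
                             blink_min_ms = 75, blink_max_ms = 500) {
  ev <- idt_classify(recording, dispersion_deg, min_duration_ms)
  ev <- attribute_events(ev, recording$stimuli)
  lat <- saccadic_latency(ev, recording$stimuli)
  blinks <- detect_blinks(recording, blink_min_ms, blink_max_ms)
  dur_s <- diff(range(recording$samples$t_ms)) / 1000
  vals <- c(time_features(recording, lat),
            fixation_features(ev, recording$geometry),
            saccade_velocity_features(ev),
            blink_features(blinks, dur_s),
            pupil_features(recording))
  dict <- ocat_feature_dictionary()
  stopifnot(identical(names(vals), dict$name))
  out <- as.data.frame(as.list(vals))
  out$age <- age
  out
}

#' Extract the feature table of a whole cohort
#'
#' Cleans every recording, applies the tracking-ratio exclusion and
#' extracts the feature vector of each included participant.
#'
#' @param cohort A list as returned by [generate_cohort()] (fields
#'   `recordings` and `metadata`).
#' @param qc_threshold Tracking-ratio inclusion threshold.
#' @param ... Passed to [extract_features()].
#' @return A list with `features` (data.frame: id, label, age, 31
#'   features) and `qc` (QC report data.frame with spike/interpolation
#'   counts).
#' @export
extract_cohort_features <- function(cohort, qc_threshold = 0.80, ...) {
  md <- cohort$metadata
  cleaned <- lapply(cohort$recordings, clean_recording)
  excl <- apply_exclusion(cleaned, qc_threshold)
  qc <- excl$report
  qc$n_spikes <- vapply(cleaned, function(r) attr(r, "qc")$n_spikes,
                        numeric(1))
  qc$n_interpolated <- vapply(cleaned,
                              function(r) attr(r, "qc")$n_interpolated,
                              numeric(1))
  rows <- lapply(excl$kept, function(r) {
    i <- match(r$id, md$id)
    cbind(data.frame(id = r$id, label = md$group[i],
                     stringsAsFactors = FALSE),
          extract_features(r, age = md$age[i], ...))
  })
  list(features = do.call(rbind, rows), qc = qc)
}
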