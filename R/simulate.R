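#' Simulate a raw gaze recording for one participant
#'
#' Forward model of a single addition-test session. For each stimulus the
#' eye keeps fixating the previous target until the participant's saccadic
#' latency (plus trial-to-trial noise) has elapsed, then performs a
#' main-sequence-shaped saccade to the new target (duration 21 ms +
#' 2.2 ms/deg, smoothstep position profile) and dwells there until the
#' next stimulus. Dwells are composed of sub-fixations whose durations
#' follow a Gamma distribution with mean equal to the profile's fixation
#' duration scale, separated by small relocations around the target;
#' within a sub-fixation gaze samples carry isotropic Gaussian jitter
#' (profile jitter SD). Blinks arrive as a Poisson process at the profile
#' blink rate and blank the validity flag for their duration; isolated
#' invalid samples and rare tracking spikes (valid but physiologically
#' implausible jumps) are added to exercise quality control. Pupil size is
#' baseline + a workload-dependent increment (positions 1-3) + Gaussian
#' noise. The participant clicks to advance `think time x workload
#' multiplier` after each onset.
#'
#' @param profile A [sample_participant()] profile.
#' @param script An `ocat_task` from [generate_task_script()].
#' @param geometry A [screen_geometry()].
#' @param seed Optional seed; the recording is deterministic given it.
#' @param id Participant identifier stored in the recording.
#' @return An object of class `gaze_recording`: a list with `samples`
#'   (data.frame: t_ms, x_px, y_px, pupil_mm, valid), `stimuli`
#'   (onset_ms, target_x, target_y, seq_idx, pos_idx), `clicks`
#'   (t_ms, seq_idx, pos_idx), `geometry` and `id`.
#' @export
simulate_gaze <- function(profile, script, geometry = screen_geometry(),
                          seed = NULL, id = "P000") {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(script, "ocat_task"))
  local_seed(seed, {
    dt <- 1000 / geometry$fs
    n_stim <- nrow(script)
    disp_jump_px <- deg_to_px(c(0.8, 2.0), geometry)  # relocation range

    subfix_segments <- function(a, b, tx, ty, hold_from = Inf) {
      # fill [a, b] with sub-fixations around target (tx, ty); once a
      # boundary would fall past `hold_from` (a new stimulus is on
      # screen), gaze holds the current centre until the targeting
      # saccade — no exploratory relocations during the latency window
      segs <- list(); t0 <- a
      cx <- tx + stats::rnorm(1, 0, 0.3 * profile$jitter_sd_px)
      cy <- ty + stats::rnorm(1, 0, 0.3 * profile$jitter_sd_px)
      while (t0 < b) {
        dur <- stats::rgamma(1, shape = 4,
                             scale = profile$fix_scale_ms / 4)
        dur <- min(max(dur, 80), 1500)
        t1 <- t0 + dur
        if (t1 >= hold_from) t1 <- b
        segs[[length(segs) + 1L]] <-
          list(t0 = t0, t1 = min(t1, b), type = "fix",
               cx = cx, cy = cy)
        t0 <- t1
        r <- stats::runif(1, disp_jump_px[1], disp_jump_px[2])
        th <- stats::runif(1, 0, 2 * pi)
        cx <- tx + r * cos(th)
        cy <- ty + r * sin(th)
      }
      segs
    }

    segs <- list()
    onset <- numeric(n_stim); click <- numeric(n_stim)
    protect <- matrix(0, n_stim, 2)  # blink-suppression windows
    cur_target <- c(geometry$width_px / 2, geometry$height_px / 2)
    dwell_start <- 0
    t_next_onset <- 400
    for (i in seq_len(n_stim)) {
      onset[i] <- t_next_onset
      lat <- max(80, stats::rnorm(1, profile$latency_ms,
                                  profile$latency_noise_sd))
      fly_t0 <- onset[i] + lat
      amp_deg <- px_to_deg(
        sqrt((script$target_x[i] - cur_target[1])^2 +
             (script$target_y[i] - cur_target[2])^2), geometry)
      fly_ms <- 21 + 2.2 * amp_deg
      segs <- c(segs, subfix_segments(dwell_start, fly_t0,
                                      cur_target[1], cur_target[2],
                                      hold_from = onset[i]))
      segs[[length(segs) + 1L]] <-
        list(t0 = fly_t0, t1 = fly_t0 + fly_ms, type = "flight",
             fx = cur_target[1], fy = cur_target[2],
             tx = script$target_x[i], ty = script$target_y[i])
      dwell_start <- fly_t0 + fly_ms
      protect[i, ] <- c(onset[i] - 50, dwell_start + 150)
      mult <- profile$workload_mult[script$pos_idx[i]]
      think <- stats::rnorm(1, profile$think_ms * mult,
                            0.12 * profile$think_ms * mult)
      think <- max(think, lat + fly_ms + 250)
      click[i] <- onset[i] + think
      t_next_onset <- click[i] + stats::runif(1, 120, 250)
      cur_target <- c(script$target_x[i], script$target_y[i])
    }
    t_end <- click[n_stim] + 500
    segs <- c(segs, subfix_segments(dwell_start, t_end + dt,
                                    cur_target[1], cur_target[2]))

    t <- seq(0, t_end, by = dt)
    n <- length(t)
    seg_t0 <- vapply(segs, `[[`, numeric(1), "t0")
    seg_id <- findInterval(t, seg_t0)
    idx_by_seg <- split(seq_len(n), seg_id)
    x <- numeric(n); y <- numeric(n)
    for (k in seq_along(segs)) {
      idx <- idx_by_seg[[as.character(k)]]
      if (is.null(idx)) next
      s <- segs[[k]]
      if (s$type == "fix") {
        x[idx] <- s$cx + stats::rnorm(length(idx), 0, profile$jitter_sd_px)
        y[idx] <- s$cy + stats::rnorm(length(idx), 0, profile$jitter_sd_px)
      } else {
        u <- (t[idx] - s$t0) / (s$t1 - s$t0)
        w <- 3 * u^2 - 2 * u^3
        x[idx] <- s$fx + w * (s$tx - s$fx) + stats::rnorm(length(idx), 0, 2)
        y[idx] <- s$fy + w * (s$ty - s$fy) + stats::rnorm(length(idx), 0, 2)
      }
    }
    x <- pmin(pmax(x, 0), geometry$width_px - 1e-6)
    y <- pmin(pmax(y, 0), geometry$height_px - 1e-6)

    # pupil: baseline + workload increment of the active stimulus + noise
    stim_of_t <- findInterval(t, onset)
    incr <- c(0, profile$pupil_workload_mm[script$pos_idx])[stim_of_t + 1L]
    pupil <- profile$pupil_mm + incr +
      stats::rnorm(n, 0, profile$pupil_noise_sd)

    valid <- rep(TRUE, n)
    n_blinks <- stats::rpois(1, profile$blink_rate * t_end / 60000)
    if (n_blinks > 0) {
      # full blinks last ~100-450 ms (the detector's 75-500 ms window
      # with margin) and cannot overlap: lids have a refractory gap.
      # Blinking is also suppressed while a new target is being
      # acquired; colliding onsets are redrawn, preserving the count.
      b_dur <- rtrunc_norm(n_blinks, profile$blink_dur_ms, 40, 100, 450)
      placed <- numeric(0)
      b_start <- vapply(b_dur, function(d) {
        for (try in 1:25) {
          s <- stats::runif(1, 0, t_end - 500)
          hit <- any(s < protect[, 2] & s + d > protect[, 1]) ||
            any(abs(s - placed) < 600)
          if (!hit) break
        }
        placed <<- c(placed, s)
        s
      }, numeric(1))
      for (j in seq_len(n_blinks)) {
        valid[t >= b_start[j] & t < b_start[j] + b_dur[j]] <- FALSE
      }
    }
    iso <- stats::runif(n) < profile$invalid_rate
    valid[iso] <- FALSE
    spikes <- which(stats::runif(n) < profile$spike_rate & valid)
    if (length(spikes)) {
      x[spikes] <- stats::runif(length(spikes), 0, geometry$width_px)
      y[spikes] <- stats::runif(length(spikes), 0, geometry$height_px)
    }
    x[!valid] <- NA_real_; y[!valid] <- NA_real_
    pupil[!valid] <- NA_real_

    structure(
      list(samples = data.frame(t_ms = t, x_px = x, y_px = y,
                                pupil_mm = pupil, valid = valid),
           stimuli = data.frame(onset_ms = onset,
                                target_x = script$target_x,
                                target_y = script$target_y,
                                seq_idx = script$seq_idx,
                                pos_idx = script$pos_idx),
           clicks = data.frame(t_ms = click, seq_idx = script$seq_idx,
                               pos_idx = script$pos_idx),
           geometry = geometry, id = id),
      class = "gaze_recording")
  })
}

#' Generate a full synthetic cohort of gaze recordings
#'
#' Draws all participant profiles from the spec's master seed, then
#' simulates one session per participant (each with its own task script).
#' Identical spec (including seed) yields identical recordings.
#'
#' @param spec A [cohort_spec()].
#' @param geometry A [screen_geometry()].
#' @return A list with `recordings` (list of `gaze_recording`), `metadata`
#'   (data.frame: id, age, group, drs) and `profiles` (data.frame of the
#'   generating latent parameters, one row per participant).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_cn = 3, n_pmci = 1, seed = 7))
#' coh$metadata
#' @export
generate_cohort <- function(spec, geometry = screen_geometry()) {
  stopifnot(inherits(spec, "cohort_spec"))
  pr <- sample_cohort_profiles(spec)
  n <- nrow(pr$metadata)
  seeds <- derive_seeds(spec$seed + 1L, max(2L * n, 2L))
  recordings <- lapply(seq_len(n), function(i) {
    script <- generate_task_script(spec$n_sequences, geometry = geometry,
                                   seed = seeds[i])
    simulate_gaze(pr$profiles[[i]], script, geometry,
                  seed = seeds[n + i], id = pr$metadata$id[i])
  })
  lat_fields <- c("latency_ms", "fix_scale_ms", "jitter_sd_px",
                  "blink_rate", "blink_dur_ms", "pupil_mm",
                  "pupil_noise_sd", "think_ms")
  profiles <- cbind(
    pr$metadata,
    as.data.frame(lapply(stats::setNames(lat_fields, lat_fields),
                         function(f) vapply(pr$profiles, `[[`,
                                            numeric(1), f))))
  list(recordings = recordings, metadata = pr$metadata,
       profiles = profiles)
}
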