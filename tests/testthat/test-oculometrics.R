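test_that("a stationary trace is one fixation spanning the trace", {
  set.seed(1)
  n <- 120   # 1 s at 120 Hz
  rec <- make_recording(960 + rnorm(n, 0, 2), 540 + rnorm(n, 0, 2))
  ev <- idt_classify(rec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "fixation")
  expect_equal(ev$t_start, 0)
  expect_equal(ev$t_end, (n - 1) * 1000 / 120)
})

test_that("two clusters ten degrees apart give 2 fixations + 1 saccade", {
  set.seed(2)
  gap_px <- deg_to_px(10)
  x <- c(500 + rnorm(60, 0, 2), 500 + gap_px + rnorm(60, 0, 2))
  y <- 540 + rnorm(120, 0, 2)
  ev <- idt_classify(make_recording(x, y))
  expect_equal(sum(ev$kind == "fixation"), 2)
  expect_equal(sum(ev$kind == "saccade"), 1)
  sac <- ev[ev$kind == "saccade", ]
  expect_equal(sac$amplitude_deg, 10, tolerance = 0.5)
  expect_equal(sac$plane, "horizontal")
})

test_that("traces shorter than the minimum duration give no fixation", {
  rec <- make_recording(rep(100, 6), rep(100, 6))  # ~42 ms
  expect_equal(nrow(idt_classify(rec)), 0)
})

test_that("I-DT matches the exhaustive window-scan reference", {
  set.seed(7)
  for (rep_i in 1:6) {
    # random mixture of dwell clusters, drifts and dropouts
    n <- sample(300:1800, 1)
    centers_x <- stats::runif(6, 100, 1800)
    centers_y <- stats::runif(6, 100, 950)
    seg <- sort(sample(n - 2, 5)) ; seg <- c(0, seg, n)
    x <- numeric(n); y <- numeric(n)
    for (k in 1:6) {
      idx <- (seg[k] + 1):seg[k + 1]
      x[idx] <- centers_x[k] + rnorm(length(idx), 0, 4)
      y[idx] <- centers_y[k] + rnorm(length(idx), 0, 4)
    }
    valid <- stats::runif(n) > 0.02
    rec <- make_recording(x, y, valid = valid)
    ev <- idt_classify(rec)
    fx <- ev[ev$kind == "fixation", ]
    ref <- idt_reference(rec)
    expect_equal(nrow(fx), length(ref))
    if (length(ref)) {
      t <- rec$samples$t_ms
      expect_equal(fx$t_start,
                   vapply(ref, function(w) t[w[1]], numeric(1)))
      expect_equal(fx$t_end,
                   vapply(ref, function(w) t[w[2]], numeric(1)))
    }
  }
})

test_that("fixations are disjoint and meet the minimum duration", {
  prof <- sample_participant("CN", cohort_spec(seed = 3), seed = 8)
  rec <- clean_recording(simulate_gaze(prof,
                                       generate_task_script(3, seed = 8),
                                       seed = 8))
  fx <- idt_classify(rec)
  fx <- fx[fx$kind == "fixation", ]
  expect_true(all(fx$duration_ms >= 100 - 1e-9))
  expect_true(all(diff(fx$t_start) > 0))
  expect_true(all(fx$t_start[-1] >= fx$t_end[-nrow(fx)]))
})

test_that("saccadic latency finds the first target-directed saccade", {
  # fixation at left, onset at 500 ms, saccade starting 180 ms later
  set.seed(4)
  lat_start <- 500 + 180
  t_total <- 1.5 * 120
  x <- numeric(t_total); y <- numeric(t_total)
  t <- (seq_len(t_total) - 1) * 1000 / 120
  tgt <- c(1500, 540)
  pre <- t < lat_start
  fly <- t >= lat_start & t < lat_start + 50
  x[pre] <- 300 + rnorm(sum(pre), 0, 2)
  y[pre] <- 540 + rnorm(sum(pre), 0, 2)
  u <- (t[fly] - lat_start) / 50
  x[fly] <- 300 + u * (tgt[1] - 300)
  y[fly] <- 540
  x[!pre & !fly] <- tgt[1] + rnorm(sum(!pre & !fly), 0, 2)
  y[!pre & !fly] <- tgt[2] + rnorm(sum(!pre & !fly), 0, 2)
  stim <- data.frame(onset_ms = 500, target_x = tgt[1],
                     target_y = tgt[2], seq_idx = 1L, pos_idx = 1L)
  rec <- make_recording(x, y, stimuli = stim)
  ev <- idt_classify(rec)
  lat <- saccadic_latency(ev, stim)
  expect_equal(lat, 180, tolerance = 10)

  # a stimulus with no subsequent saccade yields NA
  stim2 <- rbind(stim, data.frame(onset_ms = 1300, target_x = 300,
                                  target_y = 540, seq_idx = 1L,
                                  pos_idx = 2L))
  expect_true(is.na(saccadic_latency(ev, stim2)[2]))
})

test_that("latency recovers the generating parameter on simulation", {
  spec <- cohort_spec(seed = 5)
  prof <- sample_participant("CN", spec, seed = 10)
  lats <- unlist(lapply(1:12, function(s) {
    rec <- clean_recording(simulate_gaze(
      prof, generate_task_script(3, seed = s), seed = s))
    ev <- attribute_events(idt_classify(rec), rec$stimuli)
    saccadic_latency(ev, rec$stimuli)
  }))
  expect_equal(mean(lats, na.rm = TRUE), prof$latency_ms,
               tolerance = 0.15 * prof$latency_ms)
})

test_that("time features follow click/onset bookkeeping", {
  prof <- sample_participant("CN", cohort_spec(seed = 6), seed = 11)
  rec <- simulate_gaze(prof, generate_task_script(1, seed = 11),
                       seed = 11)
  tf <- time_features(rec, rep(NA_real_, 3))
  rt <- (rec$clicks$t_ms - rec$stimuli$onset_ms) / 1000
  # single sequence: per-position means equal the raw times
  expect_equal(unname(tf[c("mean_time_number_1_s", "mean_time_number_2_s",
                           "mean_time_number_3_s")]), rt)
  expect_equal(unname(tf["total_test_time_s"]),
               (max(rec$clicks$t_ms) - rec$stimuli$onset_ms[1]) / 1000)
  # missing click is an invalid recording
  rec$clicks <- rec$clicks[-2, ]
  expect_error(time_features(rec, rep(NA_real_, 3)), "click")
})

test_that("per-position response times increase with workload", {
  # workload multipliers 1 / 1.2 / 1.5 must show up as ordered means
  coh <- generate_cohort(cohort_spec(n_cn = 25, n_pmci = 0, seed = 21))
  tf <- t(vapply(coh$recordings, function(r)
    time_features(r, NA_real_)[2:4], numeric(3)))
  m <- colMeans(tf)
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("fixation features handle degenerate geometry", {
  ev <- data.frame(kind = "fixation", t_start = 0, t_end = 200,
                   duration_ms = 200, centroid_x = 10, centroid_y = 10,
                   dispersion_px = 12, area_px2 = 40, n_samples = 25,
                   amplitude_deg = NA, median_vel_deg_s = NA,
                   angle_deg = NA, plane = NA, seq_idx = 1L,
                   pos_idx = 1L)
  w <- capture_warnings(out <- fixation_features(ev))
  expect_length(w, 2)                      # positions 2 and 3 are empty
  expect_match(w, "position 2", all = FALSE)
  # a single fixation has zero SD for time, size and area
  expect_equal(unname(out[c("sd_fix_time_1_ms", "sd_fix_size_1_mm",
                            "sd_fix_area_1_mm2")]), c(0, 0, 0))
  expect_equal(unname(out["mean_fix_time_1_ms"]), 200)
  expect_true(all(is.na(out[grepl("_2_|_3_", names(out))])))

  # collinear samples: positive size, zero hull area
  x <- seq(100, 130, length.out = 20); y <- rep(50, 20)
  ev2 <- idt_classify(make_recording(x, y))
  expect_equal(ev2$area_px2, 0)
  expect_gt(ev2$dispersion_px, 0)
})

test_that("per-plane velocity medians match a brute-force median", {
  sac <- function(vel, ang) data.frame(
    kind = "saccade", t_start = 0, t_end = 1, duration_ms = 1,
    centroid_x = 0, centroid_y = 0, dispersion_px = NA, area_px2 = NA,
    n_samples = 2, amplitude_deg = 5, median_vel_deg_s = vel,
    angle_deg = ang, plane = saccade_plane(ang), seq_idx = NA,
    pos_idx = NA)
  ev <- do.call(rbind, list(sac(200, 0), sac(220, 180), sac(180, 5),
                            sac(300, 90), sac(310, 270),
                            sac(150, 45), sac(170, 225)))
  w0 <- capture_warnings(v0 <- saccade_velocity_features(ev[1:3, ]))
  expect_match(w0, "vertical", all = FALSE)  # diagonal also empty
  expect_equal(unname(v0["median_sacc_vel_horizontal_deg_s"]), 200)
  v <- saccade_velocity_features(ev)
  expect_equal(unname(v["median_sacc_vel_horizontal_deg_s"]),
               median(c(200, 220, 180)))
  expect_equal(unname(v["median_sacc_vel_vertical_deg_s"]),
               median(c(300, 310)))
  expect_equal(unname(v["median_sacc_vel_diagonal_deg_s"]),
               median(c(150, 170)))
  # mirrored constructions with equal speeds give equal medians
  mir <- do.call(rbind, list(sac(250, 10), sac(250, 190),
                             sac(250, 80), sac(250, 260),
                             sac(250, 40), sac(250, 220)))
  vm <- saccade_velocity_features(mir)
  expect_true(all(vm == 250))
})

test_that("blink features are rate and median duration", {
  b <- data.frame(t_start = c(1, 2, 3) * 1000,
                  t_end = c(1.08, 2.1, 3.12) * 1000,
                  duration_ms = c(80, 100, 120))
  out <- blink_features(b, duration_s = 30)
  expect_equal(unname(out["blink_rate_per_min"]), 6)
  expect_equal(unname(out["median_blink_duration_ms"]), 100)
  out5 <- blink_features(b[c(1, 1, 1, 2, 3), ], duration_s = 30)
  expect_equal(unname(out5["blink_rate_per_min"]), 10)
  expect_warning(z <- blink_features(b[0, ], 30), "no blinks")
  expect_equal(unname(z["blink_rate_per_min"]), 0)
  expect_true(is.na(z["median_blink_duration_ms"]))
})

test_that("pupil variability features behave under scaling", {
  set.seed(9)
  n <- 7200
  p <- 3.5 + rnorm(n, 0, 0.1)
  rec <- make_recording(rep(1, n), rep(1, n), pupil = p)
  out <- pupil_features(rec)
  expect_equal(unname(out["pupil_sd_mm"]), 0.1, tolerance = 0.01)
  # scaling the pupil scales SD but not CV
  rec2 <- rec; rec2$samples$pupil_mm <- 2 * rec$samples$pupil_mm
  out2 <- pupil_features(rec2)
  expect_equal(unname(out2["pupil_sd_mm"]), 2 * unname(out["pupil_sd_mm"]))
  expect_equal(unname(out2["pupil_cv"]), unname(out["pupil_cv"]),
               tolerance = 1e-12)
  const <- make_recording(rep(1, 10), rep(1, 10),
                          pupil = rep(3, 10))
  expect_equal(unname(pupil_features(const)), c(0, 0))
  one <- make_recording(1, 1, pupil = 3)
  expect_error(pupil_features(one), "valid pupil")
})
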