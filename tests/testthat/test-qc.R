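test_that("tracking ratio is the valid-sample fraction", {
  rec <- make_recording(rep(100, 120), rep(100, 120))
  expect_equal(compute_tracking_ratio(rec), 1.0)
  v <- rep(TRUE, 120); v[1:24] <- FALSE
  rec <- make_recording(rep(100, 120), rep(100, 120), valid = v)
  expect_equal(compute_tracking_ratio(rec), 0.8)
  expect_error(compute_tracking_ratio(make_recording(numeric(0),
                                                     numeric(0))),
               "no samples")
})

test_that("the 80% exclusion boundary keeps exactly-at-threshold data", {
  mk <- function(n_valid, n = 100) {
    v <- rep(FALSE, n); v[seq_len(n_valid)] <- TRUE
    r <- make_recording(rep(100, n), rep(100, n), valid = v)
    r$id <- paste0("R", n_valid)
    r
  }
  res <- apply_exclusion(list(mk(79), mk(80), mk(100)))
  expect_equal(res$report$included, c(FALSE, TRUE, TRUE))
  expect_equal(length(res$kept), 2)
  expect_equal(length(res$excluded), 1)
  expect_equal(res$excluded[[1]]$id, "R79")
  empty <- apply_exclusion(list())
  expect_equal(length(empty$kept), 0)
  expect_equal(nrow(empty$report), 0)
})

test_that("a single-sample spike is replaced by its neighbours' midpoint", {
  # stationary at (100, 100) except one sample thrown across the screen
  x <- rep(100, 50); y <- rep(100, 50)
  x[25] <- 1800; y[25] <- 900
  rec <- make_recording(x, y)
  out <- despike(rec)
  expect_equal(attr(out, "n_spikes"), 1)
  expect_equal(out$samples$x_px[25], 100)
  expect_equal(out$samples$y_px[25], 100)
  expect_true(out$samples$valid[25])
  expect_true(out$samples$interpolated[25])
  # raw validity kept for the acquisition-quality view
  expect_true(all(out$samples$raw_valid))
})

test_that("spike-free recordings pass through unchanged", {
  prof <- sample_participant("CN", cohort_spec(seed = 2), seed = 3)
  prof$spike_rate <- 0; prof$invalid_rate <- 0
  rec <- simulate_gaze(prof, generate_task_script(2, seed = 3), seed = 3)
  out <- despike(rec)
  expect_equal(attr(out, "n_spikes"), 0)
  expect_equal(out$samples$x_px, rec$samples$x_px)
})

test_that("an edge spike is filled one-sided from the nearest valid value", {
  x <- rep(200, 30); y <- rep(300, 30)
  x[1] <- 1900; y[1] <- 50
  out <- despike(make_recording(x, y))
  expect_equal(out$samples$x_px[1], 200)
  expect_equal(out$samples$y_px[1], 300)
})

test_that("despiking is idempotent", {
  for (seed in 1:3) {
    prof <- sample_participant("PMCI", cohort_spec(seed = 1),
                               seed = seed)
    rec <- simulate_gaze(prof, generate_task_script(3, seed = seed),
                         seed = seed)
    once <- despike(rec)
    twice <- despike(once)
    expect_identical(once$samples, twice$samples)
  }
})

test_that("blink detection applies the duration bounds", {
  n <- 240
  v <- rep(TRUE, n); v[100:111] <- FALSE          # 12 samples = 100 ms
  rec <- make_recording(rep(500, n), rep(500, n), valid = v)
  b <- detect_blinks(rec)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_ms, 100, tolerance = 1e-9)
  v2 <- rep(TRUE, n); v2[50:51] <- FALSE          # 16.7 ms: too short
  expect_equal(nrow(detect_blinks(make_recording(rep(1, n), rep(1, n),
                                                 valid = v2))), 0)
  expect_equal(nrow(detect_blinks(make_recording(rep(1, n),
                                                 rep(1, n)))), 0)
})

test_that("blink counts match a brute-force run scan", {
  set.seed(42)
  for (rep_i in 1:10) {
    n <- 800
    v <- stats::runif(n) > 0.06
    rec <- make_recording(rep(10, n), rep(10, n), valid = v)
    b <- detect_blinks(rec, min_ms = 20, max_ms = 200)
    # brute force: walk the flags and count qualifying runs
    cnt <- 0; run <- 0
    for (i in seq_len(n + 1)) {
      if (i <= n && !v[i]) {
        run <- run + 1
      } else if (run > 0) {
        d <- run * 1000 / 120
        if (d >= 20 && d <= 200) cnt <- cnt + 1
        run <- 0
      }
    }
    expect_equal(nrow(b), cnt)
  }
})

test_that("tracking ratio is computed on raw flags, not interpolation", {
  v <- rep(TRUE, 100); v[40:48] <- FALSE   # 75 ms gap: interpolatable
  rec <- make_recording(rep(5, 100), rep(5, 100), valid = v)
  cleaned <- clean_recording(rec)
  expect_equal(attr(cleaned, "qc")$tracking_ratio, 0.91)
  expect_equal(compute_tracking_ratio(rec), 0.91)
  # even after interpolation the ratio reflects acquisition quality
  expect_equal(compute_tracking_ratio(cleaned), 0.91)
})
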