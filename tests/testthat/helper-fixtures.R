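# Hand-built recordings and independent reference implementations used
# as oracles across the suite.

# Construct a gaze_recording from raw vectors (defaults: 120 Hz, all
# valid, constant pupil, no events).
make_recording <- function(x, y, fs = 120, valid = NULL, pupil = NULL,
                           stimuli = NULL, clicks = NULL,
                           geometry = screen_geometry(fs = fs)) {
  n <- length(x)
  t <- (seq_len(n) - 1) * 1000 / fs
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(pupil)) pupil <- rep(3.5, n)
  x[!valid] <- NA_real_; y[!valid] <- NA_real_; pupil[!valid] <- NA_real_
  if (is.null(stimuli)) {
    stimuli <- data.frame(onset_ms = numeric(), target_x = numeric(),
                          target_y = numeric(), seq_idx = integer(),
                          pos_idx = integer())
  }
  if (is.null(clicks)) {
    clicks <- data.frame(t_ms = numeric(), seq_idx = integer(),
                         pos_idx = integer())
  }
  structure(list(samples = data.frame(t_ms = t, x_px = x, y_px = y,
                                      pupil_mm = pupil, valid = valid),
                 stimuli = stimuli, clicks = clicks,
                 geometry = geometry, id = "TEST"),
            class = "gaze_recording")
}

# Exhaustive window-scan I-DT reference: same greedy semantics as the
# package implementation but recomputing dispersion from scratch at every
# extension, with no incremental state. Returns fixation index windows
# per valid chunk, on the whole recording.
idt_reference <- function(recording, dispersion_deg = 1.0,
                          min_duration_ms = 100) {
  s <- recording$samples
  geom <- recording$geometry
  thresh_px <- deg_to_px(dispersion_deg, geom)
  dt_nom <- stats::median(diff(s$t_ms))
  min_win <- floor(min_duration_ms / dt_nom + 1e-9) + 1
  disp <- function(ii) {
    (max(s$x_px[ii]) - min(s$x_px[ii])) +
      (max(s$y_px[ii]) - min(s$y_px[ii]))
  }
  runs <- rle(s$valid)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  fixes <- list()
  for (ch in which(runs$values)) {
    lo <- starts[ch]; hi <- ends[ch]
    i <- lo
    while (i + min_win - 1L <= hi) {
      j <- i + min_win - 1L
      if (disp(i:j) <= thresh_px) {
        while (j < hi && disp(i:(j + 1L)) <= thresh_px) j <- j + 1L
        fixes[[length(fixes) + 1L]] <- c(i, j)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  fixes
}

# Brute-force average precision: enumerate every distinct threshold,
# compute precision/recall by counting, and accumulate the step-wise sum.
auprc_bruteforce <- function(y_true, scores, positive = "PMCI") {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; ap <- 0
  P <- sum(y_true == positive)
  for (tt in th) {
    sel <- scores >= tt
    tp <- sum(sel & y_true == positive)
    r <- tp / P
    p <- tp / sum(sel)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# A tiny standardized two-class table with a known informative feature,
# for model tests.
toy_training <- function(n = 60, seed = 1, effect = 2) {
  set.seed(seed)
  label <- rep(c("CN", "PMCI"), c(0.7 * n, 0.3 * n))
  data.frame(
    label = label,
    f1 = stats::rnorm(n) + ifelse(label == "PMCI", effect, 0),
    f2 = stats::rnorm(n))
}
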