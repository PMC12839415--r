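#' Generate a synthetic addition-task script
#'
#' Builds the stimulus plan for a simulated oculo-cognitive addition test
#' session: `n_sequences` three-number addition sequences whose digits
#' appear one at a time at different screen locations. Within a sequence
#' the three positions carry increasing cognitive workload (low, medium,
#' high). Consecutive targets are placed so that, over a full script, the
#' implied saccade transitions cover the horizontal, vertical and diagonal
#' planes (planes are defined by +/-22.5 degree bins around the axes).
#'
#' @param n_sequences Number of addition sequences (>= 1). The default
#'   session of 3 sequences (9 stimuli) lasts under a minute.
#' @param layout_policy Target placement scheme. `"grid"` (default) draws
#'   targets from a 3x3 grid of anchor points with jitter, cycling the
#'   planned transition plane through horizontal, vertical, diagonal so
#'   all three planes occur whenever the script has >= 3 transitions.
#' @param geometry A [screen_geometry()].
#' @param seed Optional integer seed; the script is deterministic given it.
#' @return A data.frame of class `ocat_task` with one row per stimulus:
#'   `seq_idx`, `pos_idx` (1-3), `workload` (low/medium/high), `digit`,
#'   `target_x`, `target_y`, and `plane_in` — the plane of the transition
#'   leading into this stimulus (NA for the first).
#' @examples
#' script <- generate_task_script(3, seed = 1)
#' table(script$plane_in)
#' @export
generate_task_script <- function(n_sequences = 3, layout_policy = "grid",
                                 geometry = screen_geometry(), seed = NULL) {
  if (!is.numeric(n_sequences) || n_sequences < 1) {
    stop("`n_sequences` must be >= 1")
  }
  layout_policy <- match.arg(layout_policy, "grid")
  n_sequences <- as.integer(n_sequences)
  local_seed(seed, {
    anchors_x <- c(0.15, 0.5, 0.85) * geometry$width_px
    anchors_y <- c(0.15, 0.5, 0.85) * geometry$height_px
    # worst-case jitter displacement between two targets, per axis
    jx <- 2 * 0.02 * geometry$width_px
    jy <- 2 * 0.02 * geometry$height_px
    n_stim <- 3L * n_sequences
    # grid cells as (row, col); planned plane cycles h, v, d across the
    # n_stim - 1 transitions so coverage holds for any n_sequences >= 2
    planes <- c("horizontal", "vertical", "diagonal")
    cell <- matrix(NA_integer_, n_stim, 2)
    cell[1, ] <- c(sample(3L, 1), sample(3L, 1))
    plane_in <- rep(NA_character_, n_stim)
    for (i in seq_len(n_stim)[-1]) {
      plane <- planes[((i - 2L) %% 3L) + 1L]
      cur <- cell[i - 1L, ]
      cand <- switch(plane,
        horizontal = cbind(cur[1], setdiff(1:3, cur[2])),
        vertical   = cbind(setdiff(1:3, cur[1]), cur[2]),
        diagonal   = {
          grid <- expand.grid(row = 1:3, col = 1:3)
          grid <- grid[grid$row != cur[1] & grid$col != cur[2], ]
          # keep moves that stay in the diagonal bin under worst-case
          # target jitter
          dx <- abs(anchors_x[grid$col] - anchors_x[cur[2]])
          dy <- abs(anchors_y[grid$row] - anchors_y[cur[1]])
          ok <- (dy - jy) / (dx + jx) > tan(22.5 * pi / 180) &
                (dy + jy) / (dx - jx) < tan(67.5 * pi / 180)
          as.matrix(grid[ok, , drop = FALSE])
        })
      pick <- cand[sample(nrow(cand), 1), ]
      cell[i, ] <- as.integer(pick)
      plane_in[i] <- plane
    }
    jit_x <- stats::runif(n_stim, -0.02, 0.02) * geometry$width_px
    jit_y <- stats::runif(n_stim, -0.02, 0.02) * geometry$height_px
    out <- data.frame(
      seq_idx = rep(seq_len(n_sequences), each = 3L),
      pos_idx = rep(1:3, n_sequences),
      workload = rep(c("low", "medium", "high"), n_sequences),
      digit = sample(1:9, n_stim, replace = TRUE),
      target_x = pmin(pmax(anchors_x[cell[, 2]] + jit_x, 1),
                      geometry$width_px - 1),
      target_y = pmin(pmax(anchors_y[cell[, 1]] + jit_y, 1),
                      geometry$height_px - 1),
      plane_in = plane_in,
      stringsAsFactors = FALSE)
    class(out) <- c("ocat_task", "data.frame")
    out
  })
}

#' Classify a movement direction into a saccadic plane
#'
#' Angles within 22.5 degrees of the horizontal axis are `horizontal`,
#' within 22.5 degrees of the vertical axis `vertical`, otherwise
#' `diagonal`. Screen coordinates (y increasing downwards) are assumed, but
#' the binning is symmetric so the y convention does not matter.
#'
#' @param angle_deg Direction angle(s) in degrees.
#' @return Character vector of planes.
#' @export
saccade_plane <- function(angle_deg) {
  a <- angle_deg %% 180
  ifelse(a < 22.5 | a >= 157.5, "horizontal",
         ifelse(a >= 67.5 & a < 112.5, "vertical", "diagonal"))
}
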