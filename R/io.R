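#' Read and write gaze recordings as plain-text CSV
#'
#' A recording is stored as two files: `<stem>.csv` with the sample stream
#' (t_ms, x_px, y_px, pupil_mm, valid) and `<stem>_events.csv` with the
#' event log (kind in {onset, click}, t_ms, seq_idx, pos_idx, target_x_px,
#' target_y_px; target columns are empty for clicks).
#'
#' @param recording A `gaze_recording`.
#' @param stem File path stem (without extension).
#' @param geometry Geometry attached on read (the CSV dialect does not
#'   carry it).
#' @return `write_recording` returns the stem invisibly; `read_recording`
#'   returns a `gaze_recording`.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "gaze_recording"))
  utils::write.csv(recording$samples, paste0(stem, ".csv"),
                   row.names = FALSE)
  ev <- rbind(
    data.frame(kind = "onset", t_ms = recording$stimuli$onset_ms,
               seq_idx = recording$stimuli$seq_idx,
               pos_idx = recording$stimuli$pos_idx,
               target_x_px = recording$stimuli$target_x,
               target_y_px = recording$stimuli$target_y),
    data.frame(kind = "click", t_ms = recording$clicks$t_ms,
               seq_idx = recording$clicks$seq_idx,
               pos_idx = recording$clicks$pos_idx,
               target_x_px = NA_real_, target_y_px = NA_real_))
  ev <- ev[order(ev$t_ms), ]
  utils::write.csv(ev, paste0(stem, "_events.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem, geometry = screen_geometry()) {
  samples <- utils::read.csv(paste0(stem, ".csv"))
  samples$valid <- as.logical(samples$valid)
  ev <- utils::read.csv(paste0(stem, "_events.csv"))
  on_ev <- ev[ev$kind == "onset", ]
  cl_ev <- ev[ev$kind == "click", ]
  structure(
    list(samples = samples,
         stimuli = data.frame(onset_ms = on_ev$t_ms,
                              target_x = on_ev$target_x_px,
                              target_y = on_ev$target_y_px,
                              seq_idx = on_ev$seq_idx,
                              pos_idx = on_ev$pos_idx),
         clicks = data.frame(t_ms = cl_ev$t_ms, seq_idx = cl_ev$seq_idx,
                             pos_idx = cl_ev$pos_idx),
         geometry = geometry, id = basename(stem)),
    class = "gaze_recording")
}

#' Read a cohort specification from a YAML config file
#'
#' Top-level keys map to [cohort_spec()] arguments; `cn` and `pmci` are
#' optional mappings of parameter name to `[mean, sd, lo, hi]`.
#'
#' @param path YAML file path.
#' @return A `cohort_spec`.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        c("n_cn", "n_pmci", "seed", "effect_scale",
                          "n_sequences"))]
  args$cn <- lapply(cfg$cn, unlist)
  args$pmci <- lapply(cfg$pmci, unlist)
  do.call(cohort_spec, args)
}
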