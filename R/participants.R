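#' Specify a synthetic screening cohort
#'
#' Defines the group sizes and group-wise parameter distributions from
#' which synthetic participants are drawn. Dementia Rating Scale (DRS)
#' scores follow group-wise truncated normals that respect the clinical
#' labelling rule (cognitively normal, CN, means DRS >= 140; possible mild
#' cognitive impairment, PMCI, means DRS < 140): CN ~ N(142.1, 1.5)
#' truncated to [140, 144], PMCI ~ N(135.9, 3.2) truncated to [100, 139].
#'
#' Oculomotor latent parameters are drawn per participant from group
#' distributions. The PMCI group differs from CN by configurable effect
#' sizes, all scaled by `effect_scale` (defaults: +40 ms saccadic latency,
#' x1.3 fixation duration, x1.4 fixation jitter SD, +4 blinks/min, x1.5
#' pupil noise SD, x1.25 think time, +3 years age). `effect_scale = 0`
#' yields a null cohort whose groups differ only in DRS and label.
#'
#' @param n_cn,n_pmci Group sizes.
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @param effect_scale Multiplier on all CN-vs-PMCI latent effects.
#' @param n_sequences Addition sequences per session (see
#'   [generate_task_script()]).
#' @param cn Named list overriding CN parameter distributions; each entry
#'   is `c(mean, sd, lo, hi)`.
#' @param pmci Named list overriding PMCI distributions (after effects are
#'   applied).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cn = 166, n_pmci = 40, seed = 1,
                        effect_scale = 1, n_sequences = 3,
                        cn = list(), pmci = list()) {
  stopifnot(n_cn >= 0, n_pmci >= 0)
  # c(mean, sd, lo, hi) per latent parameter, CN group
  base <- list(
    age            = c(64.9, 8.9, 21, 99),
    drs            = c(142.1, 1.5, 140, 144),
    latency_ms     = c(200, 40, 100, 400),
    fix_scale_ms   = c(250, 50, 120, 600),
    jitter_sd_px   = c(6, 1.5, 2, 20),
    blink_rate     = c(15, 7, 2, 40),
    blink_dur_ms   = c(160, 40, 80, 450),
    pupil_mm       = c(3.5, 0.4, 2, 6),
    pupil_noise_sd = c(0.10, 0.04, 0.02, 0.30),
    think_ms       = c(1800, 350, 800, 4000))
  base[names(cn)] <- cn
  s <- effect_scale
  eff <- base
  eff$age[1] <- base$age[1] + 3 * s
  eff$age[2] <- base$age[2] + 0.2 * s
  eff$drs <- c(135.9, 3.2, 100, 139)
  eff$latency_ms[1:2] <- base$latency_ms[1:2] + c(40, 0) * s
  eff$fix_scale_ms[1:2] <- base$fix_scale_ms[1:2] * (1 + 0.3 * s)
  eff$jitter_sd_px[1:2] <- base$jitter_sd_px[1:2] * (1 + 0.4 * s)
  eff$blink_rate[1] <- base$blink_rate[1] + 4 * s
  eff$pupil_noise_sd[1:2] <- base$pupil_noise_sd[1:2] * (1 + 0.5 * s)
  eff$think_ms[1:2] <- base$think_ms[1:2] * (1 + 0.25 * s)
  eff[names(pmci)] <- pmci
  if (base$drs[3] < 140) {
    stop("CN DRS truncation must keep all mass at >= 140 (label rule)")
  }
  if (eff$drs[4] >= 140) {
    stop("PMCI DRS truncation must keep all mass below 140 (label rule)")
  }
  structure(
    list(n_cn = n_cn, n_pmci = n_pmci, seed = seed,
         effect_scale = effect_scale, n_sequences = n_sequences,
         params = list(CN = base, PMCI = eff),
         # fixed session-level constants shared by all participants
         workload_mult = c(1, 1.2, 1.5),
         pupil_workload_mm = c(0.05, 0.10, 0.18),
         latency_noise_sd = 30,
         invalid_rate = 0.004,
         spike_rate = 0.001),
    class = "cohort_spec")
}

#' Draw one synthetic participant profile
#'
#' Samples age, DRS and the latent oculomotor parameters from the group
#' distributions of a [cohort_spec()]. DRS is rounded to an integer inside
#' the truncation bounds, so the label rule (CN iff DRS >= 140) always
#' holds.
#'
#' @param group `"CN"` or `"PMCI"`.
#' @param spec A [cohort_spec()].
#' @param seed Optional seed.
#' @return A list of class `participant_profile`.
#' @export
sample_participant <- function(group = c("CN", "PMCI"),
                               spec = cohort_spec(), seed = NULL) {
  group <- match.arg(group)
  p <- spec$params[[group]]
  local_seed(seed, {
    draw <- function(v) rtrunc_norm(1, v[1], v[2], v[3], v[4])
    drs <- round(draw(p$drs))
    drs <- min(max(drs, ceiling(p$drs[3])), floor(p$drs[4]))
    prof <- list(
      group = group,
      age = draw(p$age),
      drs = as.integer(drs),
      latency_ms = draw(p$latency_ms),
      fix_scale_ms = draw(p$fix_scale_ms),
      jitter_sd_px = draw(p$jitter_sd_px),
      blink_rate = draw(p$blink_rate),
      blink_dur_ms = draw(p$blink_dur_ms),
      pupil_mm = draw(p$pupil_mm),
      pupil_noise_sd = draw(p$pupil_noise_sd),
      think_ms = draw(p$think_ms),
      workload_mult = spec$workload_mult,
      pupil_workload_mm = spec$pupil_workload_mm,
      latency_noise_sd = spec$latency_noise_sd,
      invalid_rate = spec$invalid_rate,
      spike_rate = spec$spike_rate)
    stopifnot((prof$drs >= 140) == (group == "CN"))
    class(prof) <- "participant_profile"
    prof
  })
}

#' Draw all participant profiles of a cohort
#'
#' Samples `n_cn + n_pmci` profiles reproducibly from the spec's master
#' seed, without simulating gaze. Used by [generate_cohort()] and directly
#' wherever only demographics/latent parameters are needed (e.g. DRS
#' calibration checks).
#'
#' @param spec A [cohort_spec()].
#' @return A list with `profiles` (list) and `metadata` (data.frame with
#'   id, age, group, drs).
#' @export
sample_cohort_profiles <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cn + spec$n_pmci
  groups <- rep(c("CN", "PMCI"), c(spec$n_cn, spec$n_pmci))
  seeds <- derive_seeds(spec$seed, max(n, 1L) + 1L)
  profiles <- lapply(seq_len(n), function(i) {
    sample_participant(groups[i], spec, seed = seeds[i])
  })
  metadata <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    age = vapply(profiles, `[[`, numeric(1), "age"),
    group = groups,
    drs = vapply(profiles, `[[`, integer(1), "drs"),
    stringsAsFactors = FALSE)
  list(profiles = profiles, metadata = metadata)
}
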