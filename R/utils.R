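# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded operations do not perturb the global
#' random stream. With `seed = NULL` the expression uses the current stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Truncated-normal draws by inverse-CDF sampling
#' @noRd
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  stopifnot(lo < hi, sd > 0)
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi - p_lo < 1e-12) {
    stop("truncated-normal interval [", lo, ", ", hi,
         "] carries essentially no probability mass for mean ", mean,
         ", sd ", sd)
  }
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Derive child seeds from a master seed (kept below 2^31)
#' @noRd
derive_seeds <- function(master, n) {
  local_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Smallest absolute angular difference in degrees, in [0, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
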