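#' Firing-rate profile over normalized epoch time
#'
#' A unit's rate during a cued epoch is modeled as a baseline plus a mixture
#' of Gaussian bumps over normalized epoch time (0-100%). Two bumps give the
#' double-peaked modulation seen for palmar grasp, where an early burst
#' accompanies hand pre-shaping and a later one the closing of the grip.
#'
#' @param base_hz Baseline rate in spikes/s (>= 0).
#' @param centers_pct,sds_pct,amps_hz Parallel vectors describing the bumps:
#'   bump centers and widths in percent of the epoch, amplitudes in spikes/s.
#'   May be empty for a flat profile.
#' @return Object of class `eng_rate_profile`.
#' @export
rate_profile <- function(base_hz = 0, centers_pct = numeric(),
                         sds_pct = numeric(), amps_hz = numeric()) {
  if (base_hz < 0) stop_invalid("base_hz must be nonnegative")
  k <- length(centers_pct)
  if (length(sds_pct) != k || length(amps_hz) != k)
    stop_invalid("bump parameter vectors must have equal length")
  if (k > 0 && any(sds_pct <= 0)) stop_invalid("bump widths must be positive")
  structure(list(base_hz = base_hz, centers_pct = centers_pct,
                 sds_pct = sds_pct, amps_hz = amps_hz),
            class = "eng_rate_profile")
}

#' Evaluate a rate profile at normalized times
#'
#' @param profile An `eng_rate_profile`.
#' @param pct Normalized epoch times in \[0, 100\].
#' @return Rates in spikes/s, floored at zero.
#' @export
eval_rate_profile <- function(profile, pct) {
  r <- rep(profile$base_hz, length(pct))
  for (i in seq_along(profile$centers_pct)) {
    r <- r + profile$amps_hz[i] *
      exp(-(pct - profile$centers_pct[i])^2 / (2 * profile$sds_pct[i]^2))
  }
  pmax(r, 0)
}

# a safe upper bound on the profile's rate
rate_profile_max <- function(profile) {
  profile$base_hz + sum(pmax(profile$amps_hz, 0))
}

#' Sample an inhomogeneous Poisson spike train with dead time
#'
#' Thinning (Lewis-Shedler) sampler: homogeneous candidates at `lambda_max`
#' are kept with probability `rate_fn(t) / lambda_max`, then an absolute
#' refractory period is enforced by discarding any spike closer than
#' `refractory_ms` to the previously retained one. The result is sorted and
#' reproducible for a given seed.
#'
#' @param rate_fn Vectorized function of time (seconds) returning spikes/s;
#'   must never exceed `lambda_max`.
#' @param duration_s Length of the interval `[0, duration_s)`.
#' @param refractory_ms Absolute refractory period in milliseconds (> 0).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param lambda_max Known upper bound on `rate_fn` in spikes/s.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
sample_spike_train <- function(rate_fn, duration_s, refractory_ms, seed,
                               lambda_max) {
  if (duration_s < 0) stop_invalid("duration_s must be nonnegative")
  if (refractory_ms <= 0) stop_invalid("refractory_ms must be positive")
  if (lambda_max < 0) stop_invalid("lambda_max must be nonnegative")
  if (lambda_max == 0 || duration_s == 0) return(numeric())
  local_seed(seed)
  n_cand <- rpois(1, lambda_max * duration_s)
  if (n_cand == 0) return(numeric())
  times <- sort(runif(n_cand, 0, duration_s))
  rates <- rate_fn(times)
  if (any(rates > lambda_max * (1 + 1e-9)))
    stop("internal error: rate_fn exceeds lambda_max during thinning")
  keep <- runif(n_cand) < rates / lambda_max
  times <- times[keep]
  enforce_refractory(times, refractory_ms / 1000)
}

# drop spikes violating an absolute dead time (times must be sorted)
enforce_refractory <- function(times, refractory_s) {
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

# seed the RNG for the calling function only; the caller's frame restores
# the previous global RNG state on exit (same trick as withr::defer)
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  handler <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  do.call(on.exit, list(as.call(list(handler)), add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}
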