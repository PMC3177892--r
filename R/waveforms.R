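#' Parametric spike waveform shape
#'
#' Defines an extracellular spike waveform as a mixture of Gaussian lobes on
#' a finite support. Spike shapes recorded by intrafascicular electrodes
#' differ between nerve fibers (fiber size, conduction speed, distance to the
#' recording site), which is what makes template-based sorting possible; this
#' family gives smooth biphasic and triphasic shapes that stand in for that
#' per-fiber identity.
#'
#' The amplitude of the last lobe is adjusted so that the continuous-time
#' waveform integrates to zero, consistent with an AC-coupled acquisition
#' chain (100 Hz high-pass). After rendering, the waveform is rescaled so
#' that its maximum absolute sample equals `abs(amplitude_uV)`.
#'
#' @param duration_ms Support of the waveform in milliseconds (> 0).
#' @param amplitude_uV Peak absolute amplitude in microvolts. The sign is
#'   carried by the lobe coefficients; `amplitude_uV = 0` renders silence.
#' @param lobes data.frame with columns `center_ms`, `sd_ms`, `amp` (relative
#'   lobe amplitudes; at least 2 lobes so the zero-integral constraint can be
#'   satisfied).
#' @param sampling_rate_hz Sampling rate used to render the shape (> 0).
#' @return An object of class `eng_waveform_shape`.
#' @seealso [render_waveform()]
#' @export
waveform_shape <- function(duration_ms, amplitude_uV, lobes,
                           sampling_rate_hz = 25000) {
  if (!is.numeric(duration_ms) || length(duration_ms) != 1 || duration_ms <= 0)
    stop_invalid("duration_ms must be a positive scalar")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop_invalid("sampling_rate_hz must be positive")
  if (!is.data.frame(lobes) ||
      !all(c("center_ms", "sd_ms", "amp") %in% names(lobes)))
    stop_invalid("lobes must have columns center_ms, sd_ms, amp")
  if (nrow(lobes) < 2)
    stop_invalid("need at least 2 lobes for a zero-integral waveform")
  if (any(lobes$sd_ms <= 0))
    stop_invalid("lobe sd_ms must be positive")
  structure(
    list(duration_ms = duration_ms, amplitude_uV = amplitude_uV,
         lobes = lobes, sampling_rate_hz = sampling_rate_hz),
    class = "eng_waveform_shape"
  )
}

#' Render a waveform shape to samples
#'
#' Evaluates the Gaussian-lobe mixture on a sample grid covering the shape's
#' support. The last lobe's amplitude is replaced by the value that cancels
#' the total (continuous) area of the other lobes, so the rendered waveform
#' has near-zero mean; the result is then scaled to the requested peak
#' amplitude. Rendering is deterministic.
#'
#' @param shape An `eng_waveform_shape`.
#' @return Numeric vector of length `round(duration_ms * fs / 1000)`.
#' @export
render_waveform <- function(shape) {
  if (!inherits(shape, "eng_waveform_shape"))
    stop_invalid("shape must be an eng_waveform_shape")
  fs <- shape$sampling_rate_hz
  n <- round(shape$duration_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  lobes <- shape$lobes
  k <- nrow(lobes)
  G <- vapply(seq_len(k), function(i)
    exp(-(t_ms - lobes$center_ms[i])^2 / (2 * lobes$sd_ms[i]^2)),
    numeric(n))
  G <- matrix(G, nrow = n)
  # solve the last amplitude so the sampled lobes cancel exactly: the
  # rendered waveform has zero discrete integral (AC-coupled chain)
  amp <- lobes$amp
  if (sum(G[, k]) > 0)
    amp[k] <- -sum(amp[-k] * colSums(G[, -k, drop = FALSE])) / sum(G[, k])
  w <- as.numeric(G %*% amp)
  peak <- max(abs(w))
  if (peak == 0 || shape$amplitude_uV == 0) return(rep(0, n))
  w * (abs(shape$amplitude_uV) / peak)
}

#' Library of well-separated default waveform shapes
#'
#' Seven biphasic/triphasic shapes whose pairwise zero-lag normalized
#' cross-correlations are below 0.5, used by the study fixture to give each
#' simulated fiber a distinct waveform. Amplitudes vary across units as they
#' do across fibers at different distances from a recording site.
#'
#' @param sampling_rate_hz Sampling rate for rendering.
#' @return Named list of `eng_waveform_shape` objects.
#' @export
default_waveform_shapes <- function(sampling_rate_hz = 25000) {
  mk <- function(amp_uV, center_ms, sd_ms, amp) {
    waveform_shape(duration_ms = 1.6, amplitude_uV = amp_uV,
                   lobes = data.frame(center_ms = center_ms, sd_ms = sd_ms,
                                      amp = amp),
                   sampling_rate_hz = sampling_rate_hz)
  }
  # lobe parameters chosen so that every pairwise zero-lag correlation of
  # the rendered shapes stays below 0.5 in magnitude and each shape has a
  # single dominant extremum (no secondary lobe above 70% of the peak more
  # than 0.4 ms away), as real extracellular spikes do
  list(
    w1 = mk(55, c(0.343, 0.749, 0.867), c(0.062, 0.297, 0.136),
            c(-0.944, 0.993, 0.439)),
    w2 = mk(45, c(0.648, 0.790, 1.318), c(0.223, 0.123, 0.105),
            c(0.699, 0.874, -0.903)),
    w3 = mk(60, c(0.941, 1.045), c(0.153, 0.099), c(-0.564, -0.515)),
    w4 = mk(40, c(0.628, 0.633, 0.708), c(0.062, 0.279, 0.104),
            c(0.613, -0.894, 0.512)),
    w5 = mk(50, c(0.430, 0.519, 0.721), c(0.066, 0.227, 0.273),
            c(0.482, 0.613, 0.676)),
    w6 = mk(42, c(0.287, 0.475), c(0.250, 0.121), c(0.401, 0.526)),
    w7 = mk(38, c(1.076, 1.199, 1.231), c(0.103, 0.196, 0.085),
            c(-0.533, 0.813, 0.544))
  )
}

# zero-lag normalized cross-correlation of two equal-length vectors
zero_lag_correlation <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}
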