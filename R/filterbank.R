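# Octave-band front end shared by the modulation metrics and the
# syllable-rate estimator.

OCTAVE_CENTERS <- c(125, 250, 500, 1000, 2000, 4000)
HIGHPASS_EDGE <- 6000

# Minimum rate at which the 6 kHz high-pass band fits below Nyquist.
min_sample_rate <- function() 2 * HIGHPASS_EDGE

filterbank_coefs <- function(sample_rate) {
  if (sample_rate <= min_sample_rate()) {
    stop(sprintf(
      "sample rate %g Hz too low for the 6 kHz high-pass band (need > %g Hz)",
      sample_rate, min_sample_rate()), call. = FALSE)
  }
  nyq <- sample_rate / 2
  coefs <- lapply(OCTAVE_CENTERS, function(fc) {
    signal::butter(3, c(fc / sqrt(2), fc * sqrt(2)) / nyq, type = "pass")
  })
  c(coefs, list(signal::butter(6, HIGHPASS_EDGE / nyq, type = "high")))
}

#' Octave-band Butterworth filterbank
#'
#' Splits a signal into the seven analysis bands used by the modulation
#' metrics: six octave-wide Butterworth bandpass filters (overall order 6,
#' i.e. an order-3 low-pass prototype applied as a bandpass) centred at 125,
#' 250, 500, 1000, 2000 and 4000 Hz with band edges at \eqn{f_c/\sqrt{2}}
#' and \eqn{f_c\sqrt{2}}, plus a sixth-order 6 kHz high-pass. Filtering is
#' causal (forward only); the metrics downstream use envelope power, which
#' is insensitive to the filters' group delay.
#'
#' @param signal An [audio_signal] with sample rate above 12 kHz, so every
#'   band edge lies below Nyquist.
#' @return A list of 7 numeric vectors, each the length of the input, with
#'   attribute `"band_centers"` (the 6 kHz high-pass band is labelled by its
#'   edge frequency).
#' @export
octave_filterbank <- function(signal) {
  assert_audio(signal)
  coefs <- filterbank_coefs(signal$sample_rate)
  bands <- lapply(coefs, function(ba) {
    as.numeric(signal::filter(ba, signal$samples))
  })
  attr(bands, "band_centers") <- c(OCTAVE_CENTERS, HIGHPASS_EDGE)
  bands
}

#' Hilbert intensity envelope
#'
#' The magnitude of the analytic signal,
#' \eqn{e(n) = \sqrt{s(n)^2 + H\{s(n)\}^2}}, where \eqn{H} is the Hilbert
#' transform. Non-negative, same length as the input, and bounded below by
#' `|s(n)|`.
#'
#' @param band_signal Numeric vector (one filtered band) or an
#'   [audio_signal].
#' @return Numeric vector of envelope values.
#' @export
intensity_envelope <- function(band_signal) {
  x <- if (is_audio_signal(band_signal)) band_signal$samples else band_signal
  if (!is.numeric(x) || length(x) == 0L) {
    stop("'band_signal' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  hilbert_envelope(x)
}

#' Per-band intensity envelopes
#'
#' Runs the octave filterbank and extracts the Hilbert intensity envelope of
#' every band: the shared acoustic front end for both the modulation
#' spectrum and the syllable-rate estimator.
#'
#' @param signal An [audio_signal].
#' @return A `band_envelopes` object: list with `envelopes` (7 x N matrix,
#'   one row per band), `band_centers`, `sample_rate`, `n_samples`.
#' @seealso [modulation_spectrum()], [estimate_syllable_rate()]
#' @export
band_envelopes <- function(signal) {
  assert_audio(signal)
  bands <- with_stage("filterbank", octave_filterbank(signal))
  env <- with_stage("envelope",
                    t(vapply(bands, hilbert_envelope,
                             numeric(length(signal$samples)))))
  new_band_envelopes(env, signal$sample_rate,
                     band_centers = attr(bands, "band_centers"))
}

new_band_envelopes <- function(env, sample_rate, band_centers = NULL) {
  structure(list(envelopes = env,
                 band_centers = band_centers %||%
                   c(OCTAVE_CENTERS, HIGHPASS_EDGE),
                 sample_rate = sample_rate,
                 n_samples = ncol(env)),
            class = "band_envelopes")
}

#' Assemble band envelopes from a matrix
#'
#' Wraps an existing matrix of non-negative envelope sequences (one row per
#' band) as a `band_envelopes` object, e.g. to feed synthetic envelopes
#' directly into [modulation_spectrum()].
#'
#' @param envelopes Numeric matrix, 7 rows (bands) by N columns (samples),
#'   all values >= 0.
#' @param sample_rate Envelope sample rate in Hz.
#' @return A `band_envelopes` object.
#' @export
as_band_envelopes <- function(envelopes, sample_rate) {
  if (!is.matrix(envelopes) || nrow(envelopes) != 7L) {
    stop("'envelopes' must be a 7-row matrix (one row per band)",
         call. = FALSE)
  }
  if (any(!is.finite(envelopes)) || any(envelopes < 0)) {
    stop("envelopes must be finite and non-negative", call. = FALSE)
  }
  new_band_envelopes(envelopes, sample_rate)
}

#' @export
print.band_envelopes <- function(x, ...) {
  cat(sprintf("<band_envelopes: %d bands x %d samples @ %g Hz>\n",
              nrow(x$envelopes), x$n_samples, x$sample_rate))
  invisible(x)
}
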