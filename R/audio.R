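#' Mono audio signal container
#'
#' Bundles a mono waveform with its sample rate. All analysis functions in
#' the package accept and return `audio_signal` objects.
#'
#' @param samples Numeric vector of linear amplitudes (dimensionless). Must
#'   be finite throughout; a matrix (multi-channel) input is rejected.
#' @param sample_rate Sampling rate in Hz (> 0). Speech material is typically
#'   16 kHz; any rate is accepted here, but the octave filterbank requires
#'   the 6 kHz high-pass band to fit below Nyquist (rate > 12 kHz).
#'
#' @return An object of class `audio_signal`: a list with elements
#'   `samples` and `sample_rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 1000 * seq(0, 1, by = 1 / 16000)), 16000)
#' duration(x)
#' @export
audio_signal <- function(samples, sample_rate) {
  if (is.matrix(samples)) {
    if (ncol(samples) == 1L || nrow(samples) == 1L) {
      samples <- as.vector(samples)
    } else {
      stop("multi-channel audio is not supported; supply a mono signal ",
           "(no silent downmixing is performed)", call. = FALSE)
    }
  }
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("'sample_rate' must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

is_audio_signal <- function(x) inherits(x, "audio_signal")

assert_audio <- function(x, arg = "signal") {
  if (!is_audio_signal(x)) {
    stop(sprintf("'%s' must be an audio_signal (see ?audio_signal)", arg),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz = %.3f s, RMS %.4g>\n",
              length(x$samples), x$sample_rate, duration(x),
              rms(x$samples)))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#'
#' @param x An object with a duration, e.g. an [audio_signal].
#' @param ... Passed to methods.
#' @return Duration in seconds.
#' @export
duration <- function(x, ...) UseMethod("duration")

#' @export
duration.audio_signal <- function(x, ...) length(x$samples) / x$sample_rate

#' Trim leading and trailing silence
#'
#' Frames the signal into non-overlapping windows, measures per-frame RMS in
#' dB relative to the loudest frame, and keeps the contiguous stretch from
#' the first to the last frame whose level exceeds `threshold_db`. Interior
#' samples are untouched; only the edges are removed. Recorded sentences are
#' trimmed this way before any modulation analysis so that leading/trailing
#' room tone does not dilute the envelope statistics.
#'
#' @param signal An [audio_signal].
#' @param threshold_db Frame activity threshold in dB relative to the peak
#'   frame RMS (default -40: frames more than 40 dB below the loudest frame
#'   count as silence).
#' @param frame_ms Frame length in milliseconds (default 10).
#' @return The trimmed [audio_signal]. The result carries the retained
#'   sample range in attribute `"range"`.
#' @examples
#' fs <- 16000
#' tone <- sin(2 * pi * 440 * seq(0, 0.5, by = 1 / fs))
#' padded <- audio_signal(c(numeric(fs / 2), tone, numeric(fs / 2)), fs)
#' duration(trim_silence(padded))
#' @export
trim_silence <- function(signal, threshold_db = -40, frame_ms = 10) {
  assert_audio(signal)
  x <- signal$samples
  if (all(x == 0)) {
    stop("all-silent input: no frame exceeds the silence threshold",
         call. = FALSE)
  }
  flen <- max(1L, round(signal$sample_rate * frame_ms / 1000))
  n_frames <- ceiling(length(x) / flen)
  frame_rms <- vapply(seq_len(n_frames), function(i) {
    rms(x[((i - 1L) * flen + 1L):min(i * flen, length(x))])
  }, numeric(1))
  peak <- max(frame_rms)
  active <- which(db(frame_rms / peak) > threshold_db)
  first <- (active[1L] - 1L) * flen + 1L
  last <- min(active[length(active)] * flen, length(x))
  out <- audio_signal(x[first:last], signal$sample_rate)
  attr(out, "range") <- c(first, last)
  out
}
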