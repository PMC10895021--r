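# Envelope modulation power spectra (Bartlett's method) and the TMP / SRAM
# scalar metrics built on them.

# One-sided periodogram PSD of one segment: |X(f)|^2 / (fs * L), with the
# non-DC, non-Nyquist bins doubled. Units power/Hz, so that after the
# normalization below the modulation spectrum is dimensionless and does not
# depend on the envelope sample rate.
segment_periodogram <- function(seg, fs) {
  L <- length(seg)
  X <- stats::fft(seg)
  p <- Mod(X)^2 / (fs * L)
  half <- floor(L / 2)
  out <- p[1:(half + 1L)]
  if (L %% 2L == 0L) {
    if (half >= 2L) out[2:half] <- 2 * out[2:half]
  } else {
    out[2:(half + 1L)] <- 2 * out[2:(half + 1L)]
  }
  out
}

#' Normalized envelope modulation power spectrum
#'
#' Estimates each band's modulation power spectrum from its intensity
#' envelope by Bartlett's method -- the average of periodograms over
#' non-overlapping windows of `window_s` seconds (default 1 s, giving 1 Hz
#' frequency resolution) -- and normalizes by the average envelope power
#' times the window duration:
#' \deqn{m_i(f) = P_i(f) \Big/ \frac{D}{N}\sum_{n=1}^{N} e_i(n)^2}
#' where \eqn{D} is the window duration and the sum runs over the whole
#' envelope. The normalization makes the spectrum invariant to amplitude
#' scaling of the input signal.
#'
#' Envelopes are first decimated to `env_rate` Hz (default 200, with
#' zero-phase anti-alias filtering), which preserves all modulation content
#' up to 100 Hz -- far above the 25 Hz ceiling the metrics use -- while
#' keeping the FFTs small. Set `env_rate = NULL` to run at the native rate.
#' An envelope shorter than one window is zero-padded to one window; a
#' trailing partial window is discarded whenever at least one full window
#' exists.
#'
#' @param envelopes A `band_envelopes` object (see [band_envelopes()],
#'   [as_band_envelopes()]).
#' @param window_s Bartlett window duration D in seconds (default 1; the
#'   frequency resolution is 1/D Hz).
#' @param env_rate Envelope rate in Hz for the spectral analysis, or `NULL`
#'   for the native rate. Must give at least 26 positive-frequency bins
#'   (`env_rate >= 52` at `window_s = 1`).
#' @return A `modulation_spectrum` object: list with `m` (bands x
#'   frequencies matrix of normalized power), `freqs` (Hz, from 0 in steps
#'   of 1/D), `window_duration`, `n_segments`, `env_rate`.
#' @export
modulation_spectrum <- function(envelopes, window_s = 1, env_rate = 200) {
  if (!inherits(envelopes, "band_envelopes")) {
    stop("'envelopes' must be a band_envelopes object", call. = FALSE)
  }
  if (envelopes$n_samples < 1L) stop("empty envelope", call. = FALSE)
  fs_env <- env_rate %||% envelopes$sample_rate
  L <- round(window_s * fs_env)
  if (L < 52 * window_s) {
    stop("env_rate too low: need modulation bins up to at least 25 Hz",
         call. = FALSE)
  }

  spec_one <- function(e) {
    if (!is.null(env_rate) && env_rate != envelopes$sample_rate) {
      e <- resample_envelope(e, envelopes$sample_rate, fs_env)
    }
    if (length(e) < L) e <- c(e, numeric(L - length(e)))  # pad to one window
    n_seg <- length(e) %/% L
    segs <- matrix(e[seq_len(n_seg * L)], nrow = L)  # trailing part dropped
    P <- rowMeans(apply(segs, 2, segment_periodogram, fs = fs_env))
    denom <- window_s * mean(e^2)  # (D/N) * sum(e^2) over the whole envelope
    m <- if (denom > 0) P / denom else P * 0
    list(m = m, n_seg = n_seg)
  }

  per_band <- apply(envelopes$envelopes, 1, spec_one, simplify = FALSE)
  m <- t(vapply(per_band, `[[`, numeric(floor(L / 2) + 1L), "m"))
  structure(list(m = m,
                 freqs = (0:floor(L / 2)) / window_s,
                 window_duration = window_s,
                 n_segments = per_band[[1L]]$n_seg,
                 env_rate = fs_env),
            class = "modulation_spectrum")
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf(
    "<modulation_spectrum: %d bands, 0-%g Hz @ %g Hz resolution, %d segment%s>\n",
    nrow(x$m), max(x$freqs), 1 / x$window_duration, x$n_segments,
    if (x$n_segments == 1L) "" else "s"))
  invisible(x)
}

metric_value <- function(value, metric, syllable_rate = NULL) {
  structure(list(value = value, metric = metric,
                 syllable_rate = syllable_rate),
            class = "sram_metric")
}

#' @export
print.sram_metric <- function(x, ...) {
  cat(sprintf("%s = %.6g", x$metric, x$value))
  if (!is.null(x$syllable_rate)) {
    cat(sprintf("  (syllable rate %.3g /s)", x$syllable_rate))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.double.sram_metric <- function(x, ...) x$value

band_average_sum <- function(spectrum, k_lo, k_hi = 25) {
  if (k_lo > k_hi) return(0)
  idx <- match(k_lo:k_hi, spectrum$freqs)
  if (anyNA(idx)) {
    stop("spectrum lacks integer modulation bins in ", k_lo, "..", k_hi,
         call. = FALSE)
  }
  sum(colMeans(spectrum$m[, idx, drop = FALSE]))
}

#' Total modulation power (TMP)
#'
#' The band-averaged normalized modulation power summed over integer
#' modulation frequencies 1 to 25 Hz:
#' \deqn{\mathrm{TMP} = \sum_{k=1}^{25} \frac{1}{7}\sum_{i=1}^{7} m_i(k)}
#'
#' @param spectrum A `modulation_spectrum`.
#' @return An `sram_metric` object (use `as.numeric()` for the bare value).
#' @seealso [sram()], [compute_metric()]
#' @export
tmp <- function(spectrum) {
  if (!inherits(spectrum, "modulation_spectrum")) {
    stop("'spectrum' must be a modulation_spectrum", call. = FALSE)
  }
  metric_value(band_average_sum(spectrum, 1), "TMP")
}

#' Syllable-rate-adjusted modulation (SRAM)
#'
#' TMP with the summation's lower edge raised to the integer part of the
#' syllable rate: modulation power below the syllable rate -- which carries
#' prosody rather than intelligibility -- is excluded.
#' \deqn{\mathrm{SRAM} = \sum_{k=\lfloor SR \rfloor}^{25}
#'   \frac{1}{7}\sum_{i=1}^{7} m_i(k)}
#' The lower bound is clamped to 1 when \eqn{\lfloor SR \rfloor < 1}, so
#' SRAM equals TMP for syllable rates below 2/s; when
#' \eqn{\lfloor SR \rfloor > 25} the sum is empty and SRAM is 0.
#'
#' @param spectrum A `modulation_spectrum`.
#' @param syllable_rate Syllable rate in syllables/s (>= 0), from a
#'   transcript ([reference_syllable_rate()]) or estimated acoustically
#'   ([estimate_syllable_rate()]).
#' @return An `sram_metric` object carrying the rate it was gated by.
#' @export
sram <- function(spectrum, syllable_rate) {
  if (!inherits(spectrum, "modulation_spectrum")) {
    stop("'spectrum' must be a modulation_spectrum", call. = FALSE)
  }
  if (inherits(syllable_rate, "syllable_rate")) {
    syllable_rate <- syllable_rate$rate
  }
  if (!is.numeric(syllable_rate) || length(syllable_rate) != 1L ||
      !is.finite(syllable_rate) || syllable_rate < 0) {
    stop("'syllable_rate' must be a single non-negative number",
         call. = FALSE)
  }
  k_lo <- max(1, floor(syllable_rate))
  metric_value(band_average_sum(spectrum, k_lo), "SRAM",
               syllable_rate = syllable_rate)
}

#' Compute TMP or SRAM from a waveform
#'
#' The full metric chain: silence trimming, octave filterbank, Hilbert
#' intensity envelopes, Bartlett modulation spectrum, then [tmp()] (when no
#' syllable rate is supplied) or [sram()]. The metric is computed on the
#' signal as given -- for noisy conditions, on the noisy signal alone (the
#' metric is non-intrusive; no clean reference is used). Deterministic for
#' fixed input.
#'
#' @param signal An [audio_signal].
#' @param syllable_rate Optional syllable rate in syllables/s (or a
#'   `syllable_rate` result object). If supplied the result is SRAM,
#'   otherwise TMP.
#' @param trim Trim edge silence first (default `TRUE`).
#' @param ... Passed to [modulation_spectrum()] (`window_s`, `env_rate`).
#' @return An `sram_metric` object.
#' @examples
#' fs <- 16000
#' x <- make_syllabic_signal(rate = 2, duration = 2, seed = 1)
#' compute_metric(x)                      # TMP
#' compute_metric(x, syllable_rate = 2)   # SRAM
#' @export
compute_metric <- function(signal, syllable_rate = NULL, trim = TRUE, ...) {
  assert_audio(signal)
  if (trim) signal <- with_stage("trim", trim_silence(signal))
  env <- band_envelopes(signal)  # stages tagged internally
  spec <- with_stage("modulation_spectrum", modulation_spectrum(env, ...))
  if (is.null(syllable_rate)) {
    with_stage("tmp", tmp(spec))
  } else {
    with_stage("sram", sram(spec, syllable_rate))
  }
}
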