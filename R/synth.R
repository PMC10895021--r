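# Deterministic synthetic fixtures: speech-like syllabic signals,
# speech-spectrum-shaped noise, and SNR mixing. These stand in for recorded
# sentences so the whole pipeline is testable without any downloads.

# Shape white Gaussian noise in the frequency domain by a magnitude
# response given at arbitrary frequencies (linear interpolation on a log
# frequency axis).
shape_noise <- function(n, fs, freq, mag) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror for negative frequencies
  lf <- log(pmax(f, fs / n / 2))
  g <- stats::approx(log(pmax(freq, 1e-6)), mag, xout = lf, rule = 2)$y
  Re(stats::fft(X * g, inverse = TRUE) / n)
}

#' Long-term average spectrum (Welch estimate)
#'
#' Averaged one-sided periodogram over Hann-windowed segments with 50%
#' overlap: the long-term average spectrum (LTAS) used for noise shaping
#' and for spectral comparisons in tests.
#'
#' @param signal An [audio_signal] or numeric vector.
#' @param sample_rate Required when `signal` is a bare vector.
#' @param n_fft Segment length (default 4096).
#' @return A data.frame with columns `freq` (Hz) and `power`
#'   (power/Hz, one-sided).
#' @export
ltas <- function(signal, sample_rate = NULL, n_fft = 4096) {
  if (is_audio_signal(signal)) {
    x <- signal$samples; fs <- signal$sample_rate
  } else {
    x <- signal; fs <- sample_rate
    if (is.null(fs)) stop("supply 'sample_rate' for a bare vector",
                          call. = FALSE)
  }
  if (length(x) < n_fft) n_fft <- 2^floor(log2(length(x)))
  w <- signal::hanning(n_fft)
  hop <- n_fft %/% 2L
  starts <- seq(1L, length(x) - n_fft + 1L, by = hop)
  u <- mean(w^2)  # window power normalization
  acc <- numeric(n_fft %/% 2L + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + n_fft - 1L)] * w
    acc <- acc + segment_periodogram(seg, fs) / u
  }
  data.frame(freq = (0:(n_fft %/% 2L)) * fs / n_fft,
             power = acc / length(starts))
}

# Fractional-octave smoothing of a power spectrum: each bin becomes the
# mean power over [f / 2^(w/2), f * 2^(w/2)].
octave_smooth <- function(freq, power, width_octaves = 1 / 3) {
  half <- 2^(width_octaves / 2)
  vapply(seq_along(freq), function(i) {
    if (freq[i] <= 0) return(power[i])
    in_band <- freq >= freq[i] / half & freq <= freq[i] * half
    mean(power[in_band])
  }, numeric(1))
}

#' Synthetic syllabic signal
#'
#' A deterministic speech-like test signal: a broadband carrier whose
#' amplitude is gated by a train of raised-cosine (Hann) bursts at a known
#' syllable rate, emulating the vowel-nucleus energy pulses of running
#' speech. An optional slow amplitude "wander" (low-passed noise gain, <= 1
#' Hz) emulates prosodic level drift below the syllable rate. The true
#' burst rate and burst centre times are attached as attributes, so
#' estimator tests have exact ground truth.
#'
#' @param rate Syllable rate in bursts/s; `floor(rate * duration)` bursts
#'   are placed at period `1/rate` (an error if fewer than one fits).
#' @param duration Signal duration in seconds.
#' @param mod_depth Modulation depth in `[0, 1]`: 1 gates the carrier to
#'   silence between bursts, 0 leaves it stationary.
#' @param carrier `"noise"` (spectrally tilted Gaussian noise) or
#'   `"multitone"` (random-phase tones at the octave band centres).
#' @param spectral_tilt Carrier tilt in dB/octave relative to 500 Hz
#'   (default -6, a speech-like roll-off).
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   signals, and the caller's RNG state is untouched.
#' @param sample_rate Output rate in Hz (default 16000).
#' @param burst_width Burst (Hann pulse) width in seconds; default
#'   `min(0.5 / rate, 0.25)` -- a 50% duty cycle, capped at 250 ms because
#'   vowel nuclei do not lengthen in proportion at very slow speaking
#'   rates.
#' @param wander_depth Depth of the slow gain wander in `[0, 1)`
#'   (default 0: none; the clear/conversational contrast fixtures enable
#'   it explicitly).
#' @return An [audio_signal] with attributes `"true_rate"` (bursts/s),
#'   `"burst_times"` (s) and `"spec"` (the generating parameters).
#' @export
make_syllabic_signal <- function(rate, duration, mod_depth = 1,
                                 carrier = c("noise", "multitone"),
                                 spectral_tilt = -6, seed = 1,
                                 sample_rate = 16000,
                                 burst_width = min(0.5 / rate, 0.25),
                                 wander_depth = 0) {
  carrier <- match.arg(carrier)
  if (!is.finite(rate) || rate <= 0 || !is.finite(duration) ||
      duration <= 0) {
    stop("'rate' and 'duration' must be positive", call. = FALSE)
  }
  n_bursts <- floor(rate * duration + 1e-9)
  if (n_bursts < 1) {
    stop("rate * duration < 1: no full syllable burst fits", call. = FALSE)
  }
  if (mod_depth < 0 || mod_depth > 1) stop("'mod_depth' must be in [0, 1]",
                                           call. = FALSE)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate

  with_seed(seed, {
    cx <- switch(carrier,
      noise = {
        f_ref <- 500
        fgrid <- c(1, 62.5, 125, 250, 500, 1000, 2000, 4000, 8000)
        mag <- (pmax(fgrid, 62.5) / f_ref)^(spectral_tilt / (20 * log10(2)))
        shape_noise(n, sample_rate, fgrid, mag)
      },
      multitone = {
        f_ref <- 500
        amps <- (OCTAVE_CENTERS / f_ref)^(spectral_tilt / (20 * log10(2)))
        ph <- stats::runif(length(OCTAVE_CENTERS), 0, 2 * pi)
        rowSums(vapply(seq_along(OCTAVE_CENTERS), function(i) {
          amps[i] * sin(2 * pi * OCTAVE_CENTERS[i] * t + ph[i])
        }, numeric(n)))
      })

    burst_times <- (seq_len(n_bursts) - 0.5) / rate
    gate <- numeric(n)
    half_w <- burst_width / 2
    for (bt in burst_times) {
      idx <- which(t >= bt - half_w & t < bt + half_w)
      gate[idx] <- pmax(gate[idx],
                        0.5 * (1 + cos(pi * (t[idx] - bt) / half_w)))
    }
    env <- (1 - mod_depth) + mod_depth * gate

    if (wander_depth > 0) {
      # slow gain drift built at 100 Hz (2nd-order 1 Hz low-pass), then
      # interpolated up, to keep the narrow filter well-conditioned
      fs_lo <- 100
      n_lo <- max(8L, ceiling(duration * fs_lo) + 4L)
      slow <- stats::rnorm(n_lo)
      ba <- signal::butter(2, 1 / (fs_lo / 2), type = "low")
      slow <- as.numeric(signal::filtfilt(ba, slow))
      if (stats::sd(slow) > 0) slow <- slow / stats::sd(slow)
      slow <- stats::approx((seq_len(n_lo) - 1) / fs_lo, slow, xout = t,
                            rule = 2)$y
      env <- env * pmax(0, 1 + wander_depth * slow)
    }

    x <- cx * env
    x <- x / max(1e-12, rms(x)) * 0.1
    out <- audio_signal(x, sample_rate)
    attr(out, "true_rate") <- n_bursts / duration
    attr(out, "burst_times") <- burst_times
    attr(out, "spec") <- list(rate = rate, duration = duration,
                              mod_depth = mod_depth, carrier = carrier,
                              spectral_tilt = spectral_tilt, seed = seed,
                              burst_width = burst_width,
                              wander_depth = wander_depth)
    out
  })
}

#' Speech-spectrum-shaped noise
#'
#' Gaussian noise spectrally shaped to the long-term average spectrum of a
#' reference signal: the reference's Welch LTAS (4096-point windows) is
#' smoothed over fractional octaves and imposed on white noise in the
#' frequency domain. The output RMS matches the reference RMS.
#'
#' @param reference An [audio_signal] of at least 1 s whose spectrum is to
#'   be matched.
#' @param duration Output duration in seconds.
#' @param seed Integer seed (same seed, same noise).
#' @param smooth_octaves Fractional-octave smoothing width applied to the
#'   reference LTAS (default 1/3 octave).
#' @return An [audio_signal] at the reference's sample rate.
#' @export
make_ssn <- function(reference, duration, seed = 1, smooth_octaves = 1 / 3) {
  assert_audio(reference, "reference")
  if (duration(reference) < 1) {
    stop("'reference' must be at least 1 s long", call. = FALSE)
  }
  fs <- reference$sample_rate
  lt <- ltas(reference)
  sm <- octave_smooth(lt$freq, lt$power, smooth_octaves)
  n <- round(duration * fs)
  with_seed(seed, {
    x <- shape_noise(n, fs, lt$freq, sqrt(pmax(sm, 0)))
    x <- x / max(1e-12, rms(x)) * rms(reference$samples)
    audio_signal(x, fs)
  })
}

#' Mix speech and noise at a target SNR
#'
#' Scales the noise so that the broadband RMS ratio of speech to noise over
#' the speech extent equals the target SNR, then adds it to the speech. The
#' noise must be at least as long as the speech; its leading samples are
#' used.
#'
#' @param speech,noise [audio_signal]s at the same sample rate.
#' @param snr_db Target SNR in dB.
#' @return An [audio_signal] of the mixture, with attributes
#'   `"noise_scale"` (the gain applied to the noise) and `"snr_db"`.
#' @export
mix_at_snr <- function(speech, noise, snr_db) {
  assert_audio(speech, "speech"); assert_audio(noise, "noise")
  if (speech$sample_rate != noise$sample_rate) {
    stop("speech and noise sample rates differ", call. = FALSE)
  }
  n <- length(speech$samples)
  if (length(noise$samples) < n) {
    stop("noise shorter than speech", call. = FALSE)
  }
  rs <- rms(speech$samples)
  nn <- noise$samples[seq_len(n)]
  rn <- rms(nn)
  if (rs == 0 || rn == 0) stop("silent speech or noise", call. = FALSE)
  scale <- rs / (rn * 10^(snr_db / 20))
  out <- audio_signal(speech$samples + scale * nn, speech$sample_rate)
  attr(out, "noise_scale") <- scale
  attr(out, "snr_db") <- snr_db
  out
}
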