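# Shared fixtures and independent oracles for the test suite.

fs_default <- 16000

make_tone <- function(freq, dur = 1, fs = fs_default, amp = 1) {
  audio_signal(amp * sin(2 * pi * freq * (seq_len(round(dur * fs)) - 1) / fs),
               fs)
}

# Independent oracle for the Bartlett modulation spectrum: explicit DFT sums
# (no fft), one-sided periodogram PSD averaged over non-overlapping windows
# of D seconds, normalized by D * mean(e^2) over the whole envelope.
oracle_mod_spectrum <- function(e, fs, D = 1) {
  L <- round(fs * D)
  if (length(e) < L) e <- c(e, numeric(L - length(e)))
  nseg <- length(e) %/% L
  half <- L %/% 2
  n <- 0:(L - 1)
  Pacc <- numeric(half + 1)
  for (si in seq_len(nseg)) {
    seg <- e[((si - 1) * L + 1):(si * L)]
    for (k in 0:half) {
      X <- sum(seg * exp(-2i * pi * k * n / L))
      p <- Mod(X)^2 / (fs * L)
      if (k > 0 && !(L %% 2 == 0 && k == half)) p <- 2 * p
      Pacc[k + 1] <- Pacc[k + 1] + p
    }
  }
  (Pacc / nseg) / (D * mean(e^2))
}

# Random non-negative envelope matrices for spectrum tests (7 bands).
random_envelopes <- function(n, fs = 200, seed = 1) {
  set.seed(seed)
  matrix(abs(stats::rnorm(7 * n, mean = 1, sd = 0.4)), nrow = 7)
}

# The clear-like / conversational-like synthetic family pair: identical
# noise carriers; the clear-like member is slow (2 bursts/s) with full
# modulation depth, the conversational-like member fast (4.5/s) with
# shallower depth; both carry slow prosody-like gain wander.
style_families <- function(duration = 2, seed = 7) {
  list(clear = make_syllabic_signal(2, duration, mod_depth = 1,
                                    seed = seed, wander_depth = 0.3),
       conv = make_syllabic_signal(4.5, duration, mod_depth = 0.65,
                                   seed = seed, wander_depth = 0.3),
       rate_clear = 2, rate_conv = 4.5)
}

snr_grid <- c(-15, -10, -8, -5, 0, 5)
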