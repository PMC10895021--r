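# Shared DSP primitives: analytic signal, anti-aliased resampling.

# Analytic signal via the FFT one-sided-spectrum construction: zero the
# negative frequencies, double the positive ones, keep DC (and Nyquist for
# even lengths) unchanged. The magnitude of the result is the Hilbert
# envelope used throughout the package.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

hilbert_envelope <- function(x) Mod(analytic_signal(x))

# Resample a non-negative envelope from fs_in to fs_out. Downsampling first
# applies a zero-phase Butterworth anti-alias low-pass (order 6, cutoff at
# 45% of the target rate), then interpolates linearly onto the target grid.
# Zero-phase filtering keeps envelope peaks aligned in time with the input,
# which matters for syllable peak picking.
resample_envelope <- function(e, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop("sample rates must be positive")
  n_in <- length(e)
  dur <- n_in / fs_in
  n_out <- max(1L, floor(dur * fs_out + 1e-9))
  if (fs_out < fs_in) {
    wc <- (0.9 * fs_out / 2) / (fs_in / 2)
    ba <- signal::butter(6, wc, type = "low")
    # reflect-pad before zero-phase filtering: the filter's transient spans
    # roughly 1/cutoff, and unpadded filtfilt smears the envelope ends
    pad <- min(n_in - 1L, ceiling(3 / wc))
    ep <- c(rev(e[2:(pad + 1L)]), e, rev(e[(n_in - pad):(n_in - 1L)]))
    ef <- as.numeric(signal::filtfilt(ba, ep))
    e <- ef[(pad + 1L):(pad + n_in)]
  }
  t_in <- (seq_len(n_in) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  out <- stats::approx(t_in, e, xout = pmin(t_out, t_in[n_in]),
                       rule = 2)$y
  pmax(out, 0)
}
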