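test_that("a constant envelope has all modulation power at DC", {
  E <- matrix(2.5, nrow = 7, ncol = 400)
  ms <- modulation_spectrum(as_band_envelopes(E, 200), env_rate = NULL)
  off_dc <- ms$m[, ms$freqs >= 1]
  expect_lt(max(abs(off_dc)), 1e-20)
  expect_equal(as.numeric(tmp(ms)), 0)
})

test_that("the Bartlett spectrum matches the independent DFT oracle", {
  E <- random_envelopes(510, seed = 3)  # 2.55 s at 200 Hz: partial segment
  be <- as_band_envelopes(E, 200)
  ms <- modulation_spectrum(be, env_rate = NULL)
  expect_equal(ms$n_segments, 2L)
  for (i in c(1, 4, 7)) {
    o <- oracle_mod_spectrum(E[i, ], 200)
    rel <- abs(ms$m[i, ] - o) / pmax(abs(o), max(o) * 1e-8)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("a sinusoidally modulated envelope concentrates power at its rate", {
  fs_env <- 200
  t <- (0:(fs_env - 1)) / fs_env  # exactly 1 s
  e <- 1 + 0.5 * cos(2 * pi * 4 * t)
  E <- matrix(rep(e, 7), nrow = 7, byrow = TRUE)
  ms <- modulation_spectrum(as_band_envelopes(E, fs_env), env_rate = NULL)
  o <- oracle_mod_spectrum(e, fs_env)
  expect_equal(ms$m[1, ], o, tolerance = 1e-12)
  off <- ms$m[1, ms$freqs >= 1]
  expect_equal(which.max(off), 4L)  # 4 Hz bin dominates
  expect_gt(off[4], 100 * max(off[-4]))
})

test_that("two identical concatenated windows average to one window's spectrum", {
  set.seed(9)
  e <- abs(stats::rnorm(200, 1, 0.3))
  E1 <- matrix(rep(e, 7), nrow = 7, byrow = TRUE)
  E2 <- matrix(rep(c(e, e), 7), nrow = 7, byrow = TRUE)
  m1 <- modulation_spectrum(as_band_envelopes(E1, 200), env_rate = NULL)
  m2 <- modulation_spectrum(as_band_envelopes(E2, 200), env_rate = NULL)
  expect_equal(m2$m, m1$m, tolerance = 1e-12)
  expect_equal(m2$n_segments, 2L)
})

test_that("decimated and full-rate spectra agree for band-limited envelopes", {
  fs <- 16000
  t <- (0:(2 * fs - 1)) / fs
  e <- 1 + 0.5 * cos(2 * pi * 4 * t) + 0.3 * cos(2 * pi * 10 * t)
  be <- as_band_envelopes(matrix(rep(e, 7), nrow = 7, byrow = TRUE), fs)
  m_full <- modulation_spectrum(be, env_rate = NULL)
  m_dec <- modulation_spectrum(be, env_rate = 200)
  v_full <- m_full$m[1, match(1:25, m_full$freqs)]
  v_dec <- m_dec$m[1, match(1:25, m_dec$freqs)]
  expect_lt(max(abs(v_dec - v_full)) / max(v_full), 0.01)
})

test_that("TMP and SRAM equal brute-force double summations", {
  E <- random_envelopes(600, seed = 13)
  ms <- modulation_spectrum(as_band_envelopes(E, 200), env_rate = NULL)

  brute <- function(k_lo) {
    if (k_lo > 25) return(0)
    acc <- 0
    for (k in k_lo:25) {
      s <- 0
      for (i in 1:7) s <- s + ms$m[i, which(ms$freqs == k)]
      acc <- acc + s / 7
    }
    acc
  }
  expect_equal(as.numeric(tmp(ms)), brute(1), tolerance = 1e-12)
  expect_equal(as.numeric(sram(ms, 4.3)), brute(4), tolerance = 1e-12)
  expect_equal(as.numeric(sram(ms, 26)), 0)
  expect_equal(as.numeric(sram(ms, 1.0)), as.numeric(tmp(ms)))
  expect_equal(as.numeric(sram(ms, 0.5)), as.numeric(tmp(ms)))
  expect_error(sram(ms, -1), "non-negative")

  # uniform unit spectrum sums to 25 by construction
  ms2 <- ms
  ms2$m <- matrix(1, nrow = 7, ncol = ncol(ms$m))
  expect_equal(as.numeric(tmp(ms2)), 25)
})

test_that("metric identities hold across signals and syllable rates", {
  rates <- c(0.5, 1, 1.9, 4.3, 10, 26)
  for (seed in 1:4) {
    x <- make_syllabic_signal(rate = 2 + seed %% 3, duration = 2,
                              seed = seed)
    env <- band_envelopes(x)
    ms <- modulation_spectrum(env)
    t_val <- as.numeric(tmp(ms))
    s_vals <- vapply(rates, function(r) as.numeric(sram(ms, r)),
                     numeric(1))
    expect_true(all(diff(s_vals) <= 1e-12))          # non-increasing in SR
    expect_true(all(s_vals >= 0 & s_vals <= t_val + 1e-12))
    expect_equal(s_vals[1], t_val)                    # floor(SR) <= 1
    expect_equal(s_vals[2], t_val)
    expect_equal(s_vals[6], 0)                        # empty sum
  }
})

test_that("the metric is invariant to amplitude scaling", {
  x <- make_syllabic_signal(rate = 3, duration = 2, seed = 21)
  base_t <- as.numeric(compute_metric(x, trim = FALSE))
  base_s <- as.numeric(compute_metric(x, syllable_rate = 3, trim = FALSE))
  for (alpha in c(0.1, 10)) {
    y <- audio_signal(alpha * x$samples, x$sample_rate)
    expect_equal(as.numeric(compute_metric(y, trim = FALSE)), base_t,
                 tolerance = 1e-6)
    expect_equal(as.numeric(compute_metric(y, syllable_rate = 3,
                                           trim = FALSE)), base_s,
                 tolerance = 1e-6)
  }
})

test_that("syllabic modulation raises TMP above stationary noise", {
  fs <- 16000
  set.seed(31)
  carrier <- stats::rnorm(2 * fs)
  t <- (0:(2 * fs - 1)) / fs
  plain <- audio_signal(carrier, fs)
  modded <- audio_signal(carrier * (1 + cos(2 * pi * 4 * t)) / 2, fs)
  expect_gt(as.numeric(compute_metric(modded, trim = FALSE)),
            as.numeric(compute_metric(plain, trim = FALSE)))
})

test_that("stage failures are reported with their stage name", {
  x <- audio_signal(stats::rnorm(1000), 8000)
  expect_error(compute_metric(x, trim = FALSE), "\\[filterbank\\]")
})
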