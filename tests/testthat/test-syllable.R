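test_that("syllables are counted from ARPAbet vowel phonemes", {
  expect_equal(as.integer(count_syllables("sweet")), 1L)
  expect_equal(as.integer(count_syllables("The orange was very sweet")), 7L)
  expect_equal(as.integer(count_syllables("The clock struck twelve")), 4L)
  expect_error(count_syllables(""), "empty")
  expect_error(count_syllables("   "), "empty")
})

test_that("dictionary counts equal a brute-force stress-digit count", {
  lex <- load_lexicon()
  sentences <- c("The orange was very sweet",
                 "She found her shoes under the table",
                 "The children played in the garden")
  for (s in sentences) {
    words <- toupper(strsplit(s, " ")[[1]])
    brute <- sum(vapply(words, function(w) {
      lengths(regmatches(lex[[w]], gregexpr("[0-2]", lex[[w]])))
    }, integer(1)))
    expect_equal(as.integer(count_syllables(s)), brute)
  }
})

test_that("out-of-vocabulary words fall back to vowel groups with a warning", {
  expect_warning(n <- count_syllables("the zyzzyva was very sweet"),
                 "out-of-vocabulary")
  expect_equal(attr(n, "oov"), "ZYZZYVA")
  # Z-Y-ZZ-Y-VA: vowel groups Y, Y, A -> 3, plus 1+1+2+1
  expect_equal(as.integer(n), 3L + 5L)
})

test_that("the reference rate is the syllable count over the duration", {
  r <- reference_syllable_rate("The orange was very sweet", 3.5)
  expect_equal(r$rate, 2.0)
  expect_equal(r$n_syllables, 7L)
  expect_equal(r$source, "reference")
  expect_equal(reference_syllable_rate("The orange was very sweet", 7)$rate,
               1.0)
  expect_error(reference_syllable_rate("sweet", 0), "positive")
})

test_that("the estimator finds equally spaced bursts", {
  x <- make_syllabic_signal(rate = 3, duration = 1, seed = 2)
  est <- estimate_syllable_rate(x)
  expect_equal(est$source, "estimated")
  expect_lte(abs(est$rate - 3), 1)
  expect_equal(est$rate, est$n_syllables / est$duration)
})

test_that("a steady tone yields at most one syllable", {
  x <- make_tone(1000, dur = 1.5)
  est <- estimate_syllable_rate(x)
  expect_lte(est$rate, 1 / duration(x) + 1e-9)
})

test_that("generator rates 1-8 are recovered within one syllable/s", {
  ok <- 0; total <- 0
  for (r in 1:8) {
    for (seed in 1:3) {
      x <- make_syllabic_signal(rate = r, duration = 2, seed = seed)
      est <- estimate_syllable_rate(x)
      total <- total + 1
      if (abs(est$rate - attr(x, "true_rate")) <= 1) ok <- ok + 1
    }
  }
  expect_gte(ok / total, 0.9)
})

test_that("estimates are invariant to amplitude and scale with time", {
  x <- make_syllabic_signal(rate = 4, duration = 2, seed = 5)
  r1 <- estimate_syllable_rate(x)
  xs <- audio_signal(0.05 * x$samples, x$sample_rate)
  expect_equal(estimate_syllable_rate(xs)$rate, r1$rate)

  # doubling the duration at a fixed rate barely moves the estimate
  x2 <- make_syllabic_signal(rate = 4, duration = 4, seed = 5)
  r2 <- estimate_syllable_rate(x2)
  expect_lt(abs(r2$rate - r1$rate), 0.5 + 1e-9)

  # time-stretching the signal by 2 halves the rate (within one syllable)
  half <- make_syllabic_signal(rate = 2, duration = 4, seed = 5)
  expect_lte(abs(estimate_syllable_rate(half)$rate - 2), 1)
})

test_that("silence gives a degenerate trace and rate zero", {
  x <- audio_signal(rep(0, 16000), 16000)
  expect_warning(est <- estimate_syllable_rate(x), "degenerate")
  expect_equal(est$rate, 0)
  expect_equal(est$n_syllables, 0L)
})

test_that("sr_error implements range-normalized RMSE", {
  expect_equal(sr_error(c(1, 3), c(1, 3)), 0)
  expect_equal(sr_error(c(1, 3), c(1, 2)), sqrt(0.5) / 2)
  # constant offset c over range r gives |c| / r
  ref <- c(1, 2, 4, 5)
  expect_equal(sr_error(ref, ref + 0.8), 0.8 / 4)
  expect_error(sr_error(c(2, 2), c(1, 2)), "constant")
  expect_error(sr_error(numeric(0), numeric(0)), "non-empty")
})

test_that("peak prominence matches hand-computed topography", {
  #            1  2  3   4   5   6   7
  x <- c(0, 3, 1, 2, 0.5, 4, 0)
  pk <- find_peaks(x)
  expect_equal(pk$index, c(2L, 4L, 6L))
  # peak 3 (height 2): left walk min 1 before higher 3; right min 0.5
  # before higher 4 -> prominence 2 - max(1, 0.5) = 1
  expect_equal(pk$prominence[pk$index == 4], 1)
  expect_equal(pk$prominence[pk$index == 6], 4)  # global max: full height
  pk2 <- find_peaks(x, min_prominence = 1.5)
  expect_equal(pk2$index, c(2L, 6L))
})
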