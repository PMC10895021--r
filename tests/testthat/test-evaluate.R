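# Builds a small synthetic corpus on disk: 2 "speakers" x 2 styles x
# (3 SNRs + quiet) = 16 conditions, with scores generated from the
# computed metric through a known monotone transformation.
build_corpus <- function(dir, noise_sd = 0) {
  snrs <- c(-10, -5, 0)
  rows <- list()
  for (sp in c("f", "m")) {
    sp_seed <- if (sp == "f") 100 else 200
    for (st in c("clear", "conversational")) {
      rate <- if (st == "clear") 2 else 4.5
      depth <- if (st == "clear") 1 else 0.65
      clean <- make_syllabic_signal(rate, 1.5, mod_depth = depth,
                                    seed = sp_seed + rate)
      ssn <- make_ssn(clean, 1.5, seed = sp_seed + 7)
      for (snr in c(snrs, NA)) {
        x <- if (is.na(snr)) clean else mix_at_snr(clean, ssn, snr)
        f <- sprintf("%s_%s_%s.wav", sp, st,
                     if (is.na(snr)) "quiet" else paste0("snr", snr))
        write_wav(x, file.path(dir, f), bit_depth = "float")
        rows[[f]] <- data.frame(
          file = f, speaker = sp, style = st,
          snr = if (is.na(snr)) "quiet" else as.character(snr),
          score = NA_real_, syllable_rate = rate)
      }
    }
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # score each condition through a fixed monotone metric -> score map
  metric <- vapply(seq_len(nrow(manifest)), function(i) {
    x <- trim_silence(read_wav(file.path(dir, manifest$file[i])))
    as.numeric(compute_metric(x, manifest$syllable_rate[i], trim = FALSE))
  }, numeric(1))
  score <- logistic4(metric, 0.02, 2, stats::median(metric), 0.98)
  if (noise_sd > 0) {
    set.seed(99)
    score <- pmin(1, pmax(0, score + stats::rnorm(length(score),
                                                  0, noise_sd)))
  }
  manifest$score <- round(score, 4)
  path <- file.path(dir, "manifest.csv")
  write_manifest(manifest, path)
  path
}

test_that("manifests round-trip and are validated collectively", {
  dir <- withr::local_tempdir()
  path <- build_corpus(dir)
  m <- load_manifest(path)
  expect_equal(nrow(m), 16L)
  expect_equal(sum(m$quiet), 4L)

  # round trip preserves the condition table
  path2 <- file.path(dir, "copy.csv")
  write_manifest(m, path2)
  m2 <- load_manifest(path2)
  expect_equal(m2[c("file", "speaker", "style", "snr", "score")],
               m[c("file", "speaker", "style", "snr", "score")])

  raw <- utils::read.csv(path)
  bad <- raw; bad$score <- NULL
  utils::write.csv(bad, file.path(dir, "noscore.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(dir, "noscore.csv")), "score")

  dup <- rbind(raw, raw[1, ])
  utils::write.csv(dup, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(dir, "dup.csv")), "duplicate")

  gone <- raw; gone$file[1] <- "missing_a.wav"; gone$file[2] <- "missing_b.wav"
  utils::write.csv(gone, file.path(dir, "gone.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(dir, "gone.csv")),
               "missing_a.wav.*missing_b.wav")
})

test_that("evaluation is self-consistent on a known metric-score mapping", {
  dir <- withr::local_tempdir()
  path <- build_corpus(dir, noise_sd = 0.01)
  ev <- suppressWarnings(evaluate_manifest(path, metric = "sram"))
  expect_s3_class(ev, "sram_eval")
  expect_lt(ev$sigma$overall, 0.05)
  expect_equal(nrow(ev$conditions), 16L)
  # predictions preserve the metric rank ordering
  ord <- order(ev$conditions$metric_mean)
  expect_true(all(diff(ev$conditions$predicted[ord]) >= -1e-12))
  expect_s3_class(ev$transform, "transform_fit")
  expect_true(is.data.frame(ev$srt))
  expect_output(print(ev), "sigma")
})

test_that("degenerate manifests are refused", {
  dir <- withr::local_tempdir()
  path <- build_corpus(dir)
  m <- load_manifest(path)
  expect_error(evaluate_manifest(m[1, , drop = FALSE]), "single condition")
})

test_that("rate estimation from manifest audio is refused for noisy conditions", {
  dir <- withr::local_tempdir()
  path <- build_corpus(dir)
  m <- load_manifest(path)
  m$syllable_rate <- NULL
  expect_error(evaluate_manifest(m, metric = "sram"),
               "syllable_rate|transcript")
  expect_error(evaluate_manifest(m, metric = "sram",
                                 allow_estimation = TRUE),
               "refusing to estimate")
})

test_that("a deposit directory is adapted into a manifest skeleton", {
  dir <- withr::local_tempdir()
  expect_error(zenodo_manifest(file.path(dir, "nope")), "no such")
  dir.create(file.path(dir, "empty"))
  expect_error(zenodo_manifest(file.path(dir, "empty")), "empty")

  x <- make_tone(500, dur = 0.2)
  for (sp in c("female", "male")) {
    for (st in c("clear", "conv")) {
      for (cond in c("quiet", "snr-8")) {
        d <- file.path(dir, sp, st, cond)
        dir.create(d, recursive = TRUE)
        write_wav(x, file.path(d, "s01.wav"))
        write_wav(x, file.path(d, "s02.wav"))
      }
    }
  }
  writeLines("notes", file.path(dir, "README.txt"))
  expect_warning(man <- zenodo_manifest(dir), "non-WAV")
  expect_equal(nrow(man), 8L)  # 2 speakers x 2 styles x 2 conditions
  expect_setequal(unique(man$speaker), c("female", "male"))
  expect_setequal(unique(man$snr), c("quiet", "-8"))
  expect_true(all(vapply(strsplit(man$file, ";"), length,
                         integer(1)) == 2L))
  expect_true(all(is.na(man$score)))
})
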