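# End-to-end evaluation of a condition manifest: per-sentence metrics,
# per-condition averaging, transformation fitting, SRT curves and the
# clear-speech benefit.

#' Evaluate an objective metric against a condition manifest
#'
#' Runs the full evaluation workflow over a manifest (see
#' [load_manifest()]): computes the objective metric for every sentence of
#' every condition on the condition's (possibly noisy) audio, averages it
#' per condition, fits the four-parameter transformation from metric to
#' intelligibility ([fit_transform()]), scores it by normalized RMS error
#' overall and per speaker/style, then fits two-parameter psychometric
#' curves ([fit_srt()]) per (speaker, style) to both the human scores and
#' the transformed predictions (quiet conditions excluded from SRT fits)
#' and reports speech reception thresholds and the clear-speech benefit per
#' speaker.
#'
#' The syllable rate used by SRAM comes, per condition, from (in order of
#' precedence) a `syllable_rate` manifest column, a `transcript` column
#' (reference rate over each sentence's trimmed duration), or -- only when
#' `allow_estimation = TRUE` -- blind estimation on the audio. Estimation
#' is refused for noisy (non-quiet) conditions, since the estimator is
#' defined for clean speech.
#'
#' @param manifest A manifest path or the data.frame from
#'   [load_manifest()].
#' @param metric `"sram"` or `"tmp"`.
#' @param allow_estimation Permit blind rate estimation for quiet
#'   conditions lacking transcripts (default `FALSE`).
#' @param trim_threshold_db,trim_frame_ms Silence-trimming parameters
#'   passed to [trim_silence()].
#' @return An object of class `sram_eval`: list with `conditions` (the
#'   manifest plus `metric_mean` and `predicted`), `transform`
#'   (`transform_fit`), `sigma` (overall and per speaker/style, as
#'   fractions), `srt` (data.frame of per-(speaker, style) SRTs, human and
#'   predicted), `delta_srt` (per-speaker clear-speech benefit, human and
#'   predicted, dB) and `metric`.
#' @export
evaluate_manifest <- function(manifest, metric = c("sram", "tmp"),
                              allow_estimation = FALSE,
                              trim_threshold_db = -40, trim_frame_ms = 10) {
  metric <- match.arg(metric)
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (nrow(manifest) < 2L) {
    stop("manifest has a single condition: nothing can be fitted",
         call. = FALSE)
  }

  condition_rate <- function(row, trimmed) {
    if (!is.null(row$syllable_rate) && is.finite(row$syllable_rate)) {
      return(row$syllable_rate)
    }
    if (!is.null(row$transcript) && !is.na(row$transcript) &&
        nzchar(row$transcript)) {
      return(reference_syllable_rate(row$transcript,
                                     duration(trimmed))$rate)
    }
    if (!allow_estimation) {
      stop("no syllable rate for condition (", row$speaker, ", ",
           row$style, ", ", row$snr, "): supply a 'syllable_rate' or ",
           "'transcript' column, or set allow_estimation = TRUE for ",
           "quiet conditions", call. = FALSE)
    }
    if (!row$quiet) {
      stop("refusing to estimate the syllable rate from noisy audio ",
           "(condition ", row$speaker, ", ", row$style, ", ", row$snr,
           "); the estimator is defined for clean speech", call. = FALSE)
    }
    estimate_syllable_rate(trimmed)$rate
  }

  manifest$metric_mean <- vapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    vals <- vapply(row$files[[1L]], function(f) {
      x <- read_wav(f)
      trimmed <- trim_silence(x, trim_threshold_db, trim_frame_ms)
      rate <- if (metric == "sram") condition_rate(row, trimmed) else NULL
      as.numeric(compute_metric(trimmed, syllable_rate = rate,
                                trim = FALSE))
    }, numeric(1))
    mean(vals)
  }, numeric(1))

  tf <- fit_transform(manifest$metric_mean, manifest$score)
  manifest$predicted <- tf$fitted

  sigma <- list(overall = tf$sigma)
  for (sp in unique(manifest$speaker)) {
    idx <- manifest$speaker == sp
    sigma[[paste0("speaker_", sp)]] <-
      nrmse(manifest$score[idx], manifest$predicted[idx])
  }
  for (st in unique(manifest$style)) {
    idx <- manifest$style == st
    sigma[[paste0("style_", st)]] <-
      nrmse(manifest$score[idx], manifest$predicted[idx])
  }

  srt_rows <- list()
  for (sp in unique(manifest$speaker)) {
    for (st in unique(manifest$style)) {
      idx <- manifest$speaker == sp & manifest$style == st & !manifest$quiet
      if (sum(idx) < 3L) next
      f_h <- fit_srt(manifest$snr_db[idx], manifest$score[idx])
      f_p <- fit_srt(manifest$snr_db[idx], manifest$predicted[idx])
      srt_rows[[paste(sp, st)]] <- data.frame(
        speaker = sp, style = st, srt_human = f_h$srt,
        srt_predicted = f_p$srt, k_human = f_h$k, k_predicted = f_p$k)
    }
  }
  srt <- do.call(rbind, c(srt_rows, list(make.row.names = FALSE)))

  delta_rows <- list()
  if (!is.null(srt)) {
    for (sp in unique(srt$speaker)) {
      cl <- srt[srt$speaker == sp & srt$style == "clear", ]
      cv <- srt[srt$speaker == sp & srt$style == "conversational", ]
      if (nrow(cl) == 1L && nrow(cv) == 1L) {
        delta_rows[[sp]] <- data.frame(
          speaker = sp,
          delta_srt_human = clear_benefit(cl$srt_human, cv$srt_human),
          delta_srt_predicted = clear_benefit(cl$srt_predicted,
                                              cv$srt_predicted))
      }
    }
  }
  delta <- do.call(rbind, c(delta_rows, list(make.row.names = FALSE)))

  structure(list(conditions = manifest, transform = tf, sigma = sigma,
                 srt = srt, delta_srt = delta, metric = toupper(metric)),
            class = "sram_eval")
}

#' @export
print.sram_eval <- function(x, ...) {
  cat(sprintf("%s evaluation over %d conditions\n", x$metric,
              nrow(x$conditions)))
  cat(sprintf("  sigma (overall) = %.2f%%\n", 100 * x$sigma$overall))
  print(x$transform)
  if (!is.null(x$srt)) {
    cat("  SRTs (dB):\n")
    print(x$srt[, c("speaker", "style", "srt_human", "srt_predicted")],
          row.names = FALSE, digits = 3)
  }
  if (!is.null(x$delta_srt)) {
    cat("  Clear-speech benefit (dB):\n")
    print(x$delta_srt, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
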