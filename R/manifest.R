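# Condition manifests: CSV mapping audio files to evaluation conditions
# (speaker, style, SNR-or-quiet) and mean human intelligibility scores.

MANIFEST_REQUIRED <- c("file", "speaker", "style", "snr", "score")

#' Read and validate a condition manifest
#'
#' A manifest is a UTF-8 comma-separated file with a header and columns
#' `file`, `speaker`, `style` (`clear` or `conversational`), `snr` (a
#' number in dB or the word `quiet`), `score` (mean intelligibility in
#' `[0, 1]`), and optionally `transcript` and `syllable_rate`. Each row is
#' one condition; the `file` column may hold several audio paths separated
#' by `;` when a condition has multiple sentences. Paths are resolved
#' relative to the manifest's directory. Problems (missing columns,
#' malformed values, duplicate conditions, unreadable audio) are collected
#' and reported together.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every referenced audio file exists
#'   (default `TRUE`).
#' @return A data.frame of validated conditions with list-column `files`
#'   (resolved paths), `snr_db` (numeric, `NA` for quiet) and `quiet`
#'   (logical) added.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(MANIFEST_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  if (!nrow(df)) stop("manifest has no rows", call. = FALSE)

  df$style <- tolower(trimws(df$style))
  bad_style <- !df$style %in% c("clear", "conversational")
  if (any(bad_style)) {
    problems <- c(problems, paste0(
      "style must be 'clear' or 'conversational' (rows ",
      paste(which(bad_style), collapse = ", "), ")"))
  }
  snr_chr <- tolower(trimws(as.character(df$snr)))
  df$quiet <- snr_chr == "quiet"
  df$snr_db <- suppressWarnings(as.numeric(snr_chr))
  bad_snr <- !df$quiet & !is.finite(df$snr_db)
  if (any(bad_snr)) {
    problems <- c(problems, paste0(
      "snr must be a number or 'quiet' (rows ",
      paste(which(bad_snr), collapse = ", "), ")"))
  }
  df$score <- suppressWarnings(as.numeric(df$score))
  bad_score <- !is.finite(df$score) | df$score < 0 | df$score > 1
  if (any(bad_score)) {
    problems <- c(problems, paste0("score must lie in [0, 1] (rows ",
                                   paste(which(bad_score), collapse = ", "),
                                   ")"))
  }
  key <- paste(df$speaker, df$style, snr_chr, sep = "|")
  if (anyDuplicated(key)) {
    problems <- c(problems, paste0(
      "duplicate (speaker, style, snr) condition(s): ",
      paste(unique(key[duplicated(key)]), collapse = "; ")))
  }

  base_dir <- dirname(normalizePath(path))
  df$files <- lapply(strsplit(df$file, ";", fixed = TRUE), function(fs) {
    fs <- trimws(fs)
    ifelse(grepl("^(/|[A-Za-z]:)", fs), fs, file.path(base_dir, fs))
  })
  if (check_files) {
    missing_files <- unique(unlist(lapply(df$files, function(fs) {
      fs[!file.exists(fs)]
    })))
    if (length(missing_files)) {
      problems <- c(problems, paste0("missing audio file(s): ",
                                     paste(missing_files, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid manifest ", path, ":\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  df
}

#' Write a condition manifest
#'
#' Writes the standard manifest columns as CSV. Round-trips with
#' [load_manifest()].
#'
#' @param manifest Data.frame with at least the required manifest columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  cols <- intersect(c(MANIFEST_REQUIRED, "transcript", "syllable_rate"),
                    names(manifest))
  utils::write.csv(manifest[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Build a manifest from a downloaded recordings deposit
#'
#' Scans a local directory of WAV recordings (for instance a
#' user-downloaded copy of a published clear/conversational speech corpus)
#' and assembles a manifest skeleton by parsing speaker, style and SNR
#' tokens out of the file paths. Nothing is downloaded. Recognized tokens,
#' case-insensitively anywhere in the relative path: `female`/`male` or
#' `f`/`m` path components (speaker); `clear`/`conv`(`ersational`)
#' (style); `quiet` or a signed number following `snr` -- a dash right
#' after `snr` reads as a minus sign (`snr-8` and `snr_-8` both mean -8 dB;
#' write `snr_8` for +8 dB) -- or a number followed by `dB`. Files without
#' all three tokens, and
#' non-WAV files, are skipped with a warning. Scores are left `NA` for the
#' user to fill in from their listening data.
#'
#' @param directory Root of the deposit.
#' @return A manifest data.frame (one row per recognized condition, files
#'   joined by `;`), with `score = NA`.
#' @export
zenodo_manifest <- function(directory) {
  if (!dir.exists(directory)) {
    stop("no such directory: ", directory, call. = FALSE)
  }
  all_files <- list.files(directory, recursive = TRUE, full.names = FALSE)
  if (!length(all_files)) {
    stop("empty deposit directory: ", directory, call. = FALSE)
  }
  wavs <- all_files[grepl("\\.wav$", all_files, ignore.case = TRUE)]
  stray <- setdiff(all_files, wavs)
  if (length(stray)) {
    warning(length(stray), " non-WAV file(s) ignored", call. = FALSE)
  }
  if (!length(wavs)) {
    stop("no WAV files found under ", directory, "; expected a layout ",
         "with speaker (female/male), style (clear/conversational) and ",
         "SNR (snr<dB> or quiet) tokens in the file paths", call. = FALSE)
  }

  parse_one <- function(p) {
    lp <- tolower(p)
    parts <- strsplit(lp, "[/_.-]+")[[1L]]
    speaker <- if (any(parts %in% c("female", "f"))) "female"
               else if (any(parts %in% c("male", "m"))) "male" else NA
    style <- if (any(grepl("^clear", parts))) "clear"
             else if (any(grepl("^conv", parts))) "conversational" else NA
    snr <- if (any(parts == "quiet")) "quiet" else {
      # a dash right after "snr" is a minus sign: snr-8 means -8 dB
      m <- regmatches(lp, regexpr("snr[_=]?(-?[0-9]+)", lp))
      if (length(m)) sub("snr[_=]?", "", m) else {
        m2 <- regmatches(lp, regexpr("(-[0-9]+|[0-9]+)(?=db)", lp,
                                     perl = TRUE))
        if (length(m2)) m2 else NA
      }
    }
    c(speaker = speaker, style = style, snr = snr)
  }
  meta <- t(vapply(wavs, parse_one, character(3)))
  ok <- !apply(is.na(meta), 1, any)
  if (!any(ok)) {
    stop("could not parse speaker/style/SNR from any file name under ",
         directory, "; expected patterns like ",
         "'female/clear/snr-8/xxx.wav' or 'male_conv_quiet_01.wav'",
         call. = FALSE)
  }
  if (any(!ok)) {
    warning(sum(!ok), " WAV file(s) without recognizable ",
            "speaker/style/SNR tokens skipped", call. = FALSE)
  }
  d <- data.frame(file = wavs[ok], speaker = meta[ok, 1L],
                  style = meta[ok, 2L], snr = meta[ok, 3L],
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(file ~ speaker + style + snr, data = d,
                          FUN = paste, collapse = ";")
  agg$score <- NA_real_
  agg[order(agg$speaker, agg$style, agg$snr),
      c("file", "speaker", "style", "snr", "score")]
}
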