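# Syllable rate: reference (transcript) and blind acoustic estimation.

.lexicon_cache <- new.env(parent = emptyenv())

#' Load an ARPAbet pronunciation lexicon
#'
#' Reads a tab-separated lexicon of `WORD<TAB>PHONEMES` lines in ARPAbet
#' notation, keeping the first pronunciation listed for each word. By
#' default a small hand-curated lexicon bundled with the package is used
#' (about 180 everyday words of the kind found in standardized audiometric
#' sentence lists); pass the path of a full CMU Pronouncing Dictionary
#' style file for broad coverage.
#'
#' @param path Lexicon file, or `NULL` for the bundled one.
#' @return Named character vector mapping uppercase words to
#'   space-separated phoneme strings.
#' @export
load_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "arpabet_lexicon_mini.tsv",
                                package = "sram", mustWork = TRUE)
  key <- normalizePath(path)
  if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";;;")]
  # CMUdict uses "WORD  PHONES" with spaces; the bundled file uses a tab
  m <- regmatches(lines, regexpr("[\t ]+", lines), invert = TRUE)
  words <- toupper(vapply(m, `[`, character(1), 1L))
  phones <- vapply(m, `[`, character(1), 2L)
  first <- !duplicated(sub("\\(\\d+\\)$", "", words))
  lex <- stats::setNames(phones[first], sub("\\(\\d+\\)$", "", words[first]))
  .lexicon_cache[[key]] <- lex
  lex
}

tokenize_words <- function(transcript) {
  w <- toupper(transcript)
  w <- gsub("[^A-Z' ]+", " ", w)
  w <- strsplit(trimws(w), "\\s+")[[1L]]
  w[nzchar(w)]
}

# Orthographic fallback for out-of-vocabulary words: each maximal run of
# vowel letters counts as one syllable nucleus.
vowel_group_count <- function(word) {
  m <- gregexpr("[AEIOUY]+", word)[[1L]]
  if (m[1L] == -1L) 1L else length(m)
}

#' Count syllables in a transcript
#'
#' Translates each word to ARPAbet phonemes via the pronunciation lexicon
#' and counts every vowel phoneme (a phoneme carrying a stress digit) as
#' one syllable. The first listed pronunciation is used. Words missing from
#' the lexicon fall back, with a warning, to counting orthographic vowel
#' groups; their names are attached as attribute `"oov"`.
#'
#' @param transcript Character scalar: the sentence text.
#' @param lexicon Named phoneme vector from [load_lexicon()], or `NULL` for
#'   the bundled lexicon.
#' @return Integer syllable count, with attribute `"oov"` listing any
#'   out-of-vocabulary words.
#' @examples
#' count_syllables("The orange was very sweet")  # 7
#' @export
count_syllables <- function(transcript, lexicon = NULL) {
  if (!is.character(transcript) || length(transcript) != 1L) {
    stop("'transcript' must be a single character string", call. = FALSE)
  }
  words <- tokenize_words(transcript)
  if (!length(words)) stop("empty transcript", call. = FALSE)
  lex <- if (is.character(lexicon) && !is.null(names(lexicon))) lexicon
         else load_lexicon(lexicon)
  oov <- character(0)
  counts <- vapply(words, function(w) {
    phones <- if (w %in% names(lex)) lex[[w]] else NA_character_
    if (is.na(phones)) {
      oov <<- c(oov, w)
      return(vowel_group_count(w))
    }
    sum(grepl("[0-2]$", strsplit(phones, " +")[[1L]]))
  }, integer(1))
  if (length(oov)) {
    warning("out-of-vocabulary word(s), counted by orthographic vowel ",
            "groups: ", paste(unique(oov), collapse = ", "), call. = FALSE)
  }
  structure(sum(counts), oov = unique(oov))
}

syllable_rate_result <- function(rate, n_syllables, duration, source,
                                 peak_times = NULL, oov = character(0)) {
  structure(list(rate = rate, n_syllables = n_syllables,
                 duration = duration, source = source,
                 peak_times = peak_times, oov = oov),
            class = "syllable_rate")
}

#' @export
print.syllable_rate <- function(x, ...) {
  cat(sprintf("<syllable rate: %.3g /s (%d syllables / %.3g s, %s)>\n",
              x$rate, x$n_syllables, x$duration, x$source))
  invisible(x)
}

#' Reference syllable rate from a transcript
#'
#' The gold-standard rate: transcript syllable count (from the
#' pronunciation lexicon, see [count_syllables()]) divided by the speech
#' duration after silence trimming.
#'
#' @param transcript Sentence text.
#' @param trimmed_duration Speech duration in seconds (> 0), normally
#'   `duration(trim_silence(x))`.
#' @param lexicon Optional lexicon (see [count_syllables()]).
#' @return A `syllable_rate` object with `source = "reference"`.
#' @export
reference_syllable_rate <- function(transcript, trimmed_duration,
                                    lexicon = NULL) {
  if (!is.numeric(trimmed_duration) || length(trimmed_duration) != 1L ||
      !is.finite(trimmed_duration) || trimmed_duration <= 0) {
    stop("'trimmed_duration' must be a positive duration in seconds",
         call. = FALSE)
  }
  n <- count_syllables(transcript, lexicon)
  syllable_rate_result(as.integer(n) / trimmed_duration, as.integer(n),
                       trimmed_duration, "reference",
                       oov = attr(n, "oov"))
}

# Eq.-style temporal correlation of one 100 Hz envelope: a Hann-weighted
# local product sum, |sum_k w_k e(n) e(n+l)| / K with l = k - floor(K/2) - 1,
# envelope taken as 0 beyond its ends. Emphasizes sustained high-energy
# stretches (vowel nuclei) over transients.
temporal_correlation <- function(e, K = 11) {
  n <- length(e)
  w <- signal::hanning(K)
  half <- K %/% 2L
  acc <- numeric(n)
  for (k in seq_len(K)) {
    l <- k - half - 1L
    shifted <- numeric(n)
    if (l >= 0L) {
      if (n - l >= 1L) shifted[1:(n - l)] <- e[(1L + l):n]
    } else {
      shifted[(1L - l):n] <- e[1:(n + l)]
    }
    acc <- acc + w[k] * shifted
  }
  abs(e * acc) / K
}

#' Estimate the syllable rate from clean speech audio
#'
#' Blind acoustic estimation for when no transcript is available. The
#' signal is passed through the 7-band octave filterbank; band envelopes
#' are extracted by Hilbert transform, down-sampled to `frame_rate` Hz
#' (default 100, anti-aliased) and low-passed by a second-order Butterworth
#' filter with a 25 Hz cutoff. The `n_select` (default 4) highest-energy
#' band envelopes enter a Hann-windowed temporal correlation (window length
#' `K = 11` frames), whose pairwise products are averaged into a sub-band
#' correlation trace; after min-max normalization, peaks with topographic
#' prominence above `prominence` (default 0.07) are counted as syllables,
#' and the rate is the peak count divided by the signal duration.
#'
#' The estimator is designed for clean (not noise-mixed) speech-like
#' signals; on noisy audio prefer the transcript-based reference rate.
#'
#' @param signal An [audio_signal] (already trimmed of edge silence).
#' @param frame_rate Envelope frame rate in Hz (default 100).
#' @param lowpass_hz Envelope low-pass cutoff in Hz (default 25).
#' @param n_select Number of highest-energy bands used (default 4).
#' @param K Hann correlation window length in frames (default 11).
#' @param prominence Peak prominence threshold on the normalized trace
#'   (default 0.07).
#' @return A `syllable_rate` object with `source = "estimated"` and the
#'   peak times in seconds.
#' @export
estimate_syllable_rate <- function(signal, frame_rate = 100,
                                   lowpass_hz = 25, n_select = 4,
                                   K = 11, prominence = 0.07) {
  assert_audio(signal)
  dur <- duration(signal)
  env <- band_envelopes(signal)
  E <- with_stage("downsample", t(apply(env$envelopes, 1, resample_envelope,
                                        fs_in = signal$sample_rate,
                                        fs_out = frame_rate)))
  if (lowpass_hz < frame_rate / 2) {
    ba <- signal::butter(2, lowpass_hz / (frame_rate / 2), type = "low")
    E <- t(apply(E, 1, function(e) as.numeric(signal::filter(ba, e))))
  }
  energy <- rowSums(E^2)
  sel <- order(energy, decreasing = TRUE)[seq_len(n_select)]
  Y <- t(apply(E[sel, , drop = FALSE], 1, temporal_correlation, K = K))
  M <- nrow(Y)
  z <- numeric(ncol(Y))
  for (j in 1:(M - 1L)) for (l in (j + 1L):M) z <- z + Y[j, ] * Y[l, ]
  z <- z * 2 / (M * (M - 1))
  if (max(z) == min(z)) {
    warning("degenerate correlation trace (silent or constant input); ",
            "returning rate 0", call. = FALSE)
    return(syllable_rate_result(0, 0L, dur, "estimated",
                                peak_times = numeric(0)))
  }
  z <- (z - min(z)) / (max(z) - min(z))
  pk <- find_peaks(z, min_prominence = prominence)
  syllable_rate_result(nrow(pk) / dur, nrow(pk), dur, "estimated",
                       peak_times = (pk$index - 1) / frame_rate)
}

#' Normalized RMS error between reference and estimated syllable rates
#'
#' Root-mean-square difference between paired reference and estimated
#' rates, normalized by the range of the reference rates.
#'
#' @param ref,est Equal-length numeric vectors of rates (syllables/s).
#' @return The normalized error (a fraction; multiply by 100 for percent).
#' @export
sr_error <- function(ref, est) {
  if (length(ref) == 0L || length(ref) != length(est)) {
    stop("'ref' and 'est' must be equal-length, non-empty", call. = FALSE)
  }
  r <- max(ref) - min(ref)
  if (r <= 0) {
    stop("reference rates are constant: range normalization undefined",
         call. = FALSE)
  }
  sqrt(mean((ref - est)^2)) / r
}
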