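# Minimal RIFF/WAVE reader and writer.
#
# Supports the formats speech corpora actually use: integer PCM at 16 or
# 24 bits and IEEE float at 32 or 64 bits, mono only. Multi-channel files
# are rejected explicitly rather than silently downmixed, because channel
# averaging changes envelope statistics.

#' Read a mono WAV file
#'
#' Reads integer PCM (16/24-bit) and IEEE float (32/64-bit) RIFF/WAVE files.
#' Integer samples are scaled to `[-1, 1)` by the full-scale value of the
#' bit depth. Multi-channel files raise an error naming the file.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop(path, ": not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop(path, ": not a WAVE file", call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little")
      )
      if (fmt$audio_format == 65534L && size >= 40L) {
        # WAVE_FORMAT_EXTENSIBLE: true format is the GUID's leading bytes
        fmt$audio_format <- readBin(body[25:26], "integer", 1, 2,
                                    signed = FALSE, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size, origin = "current")
    }
    if (size %% 2L == 1L) seek(con, 1, origin = "current")  # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(path, ": missing fmt/data chunk", call. = FALSE)
  }
  if (fmt$channels != 1L) {
    stop(path, ": has ", fmt$channels, " channels; only mono input is ",
         "supported (downmix explicitly before analysis)", call. = FALSE)
  }

  samples <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) %/% 3
        b <- matrix(as.integer(data_raw[seq_len(3 * n)]), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        stop(path, ": unsupported PCM bit depth ", fmt$bits, call. = FALSE)
      }
    },
    "3" = {  # IEEE float
      readBin(data_raw, "double", length(data_raw) %/% (fmt$bits / 8),
              size = fmt$bits / 8, endian = "little")
    },
    stop(path, ": unsupported WAV format code ", fmt$audio_format,
         call. = FALSE)
  )
  audio_signal(samples, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param signal An [audio_signal].
#' @param path Output path.
#' @param bit_depth `16` or `24` for integer PCM (values are clipped to
#'   `[-1, 1)`), or `"float"` for 32-bit IEEE float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = 16) {
  assert_audio(signal)
  x <- signal$samples
  fs <- as.integer(round(signal$sample_rate))

  if (identical(bit_depth, "float")) {
    fmt_code <- 3L; bits <- 32L
    payload <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  } else if (bit_depth == 16) {
    fmt_code <- 1L; bits <- 16L
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    payload <- writeBin(q, raw(), size = 2, endian = "little")
  } else if (bit_depth == 24) {
    fmt_code <- 1L; bits <- 24L
    q <- pmax(-8388608, pmin(8388607, round(x * 8388608)))
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    payload <- as.raw(as.integer(b))
  } else {
    stop("bit_depth must be 16, 24 or \"float\"", call. = FALSE)
  }

  block_align <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4,
           endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * block_align, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(payload), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}
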