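#' @title WAV input/output
#' @name wav_io
#' @description
#' Minimal RIFF/WAVE reader and writer supporting mono/stereo PCM 16-bit
#' and IEEE float32 files, the two encodings used for the package's
#' stimulus clips. Samples are exchanged as numeric vectors in \[-1, 1\].
NULL

#' Construct an audio clip
#'
#' @param samples numeric vector in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @return object of class `audio_clip` with fields `samples`,
#'   `sample_rate`, `duration_ms`.
#' @export
audio_clip <- function(samples, sample_rate) {
  if (sample_rate <= 0) stop("sample rate must be positive")
  if (!length(samples)) stop("clip must contain at least one sample")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 duration_ms = 1000 * length(samples) / sample_rate),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("audio_clip: %d samples @ %g Hz (%.0f ms), peak %.3f\n",
              length(x$samples), x$sample_rate, x$duration_ms,
              max(abs(x$samples))))
  invisible(x)
}

#' Write an audio clip as WAV
#'
#' @param clip an `audio_clip`.
#' @param path output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- clip$samples
  fs <- as.integer(round(clip$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  if (format == "pcm16") {
    bytes_per <- 2L; fmt_code <- 1L
    data_size <- n * bytes_per
  } else {
    bytes_per <- 4L; fmt_code <- 3L
    data_size <- n * bytes_per
  }
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path input path (mono or stereo PCM16/float32; stereo is
#'   averaged to mono).
#' @return an `audio_clip`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt_code <- NULL; fs <- NULL; bits <- NULL; nchan <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      nchan <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("malformed WAV: data before fmt")
      if (fmt_code == 1L && bits == 16L) {
        raw16 <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
        samples <- raw16 / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)")
      }
      break
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  if (nchan > 1L) {
    samples <- rowMeans(matrix(samples, ncol = nchan, byrow = TRUE))
  }
  audio_clip(samples, fs)
}
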