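# Minimal RIFF/WAVE I/O for mono recordings (PCM 16/24-bit and IEEE
# float32). Chunk-walks the container so extra chunks (LIST, fact) are
# tolerated.

#' Read a mono WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float 32-bit mono files.
#' Integer PCM is rescaled to \[-1, 1). Stereo or other multi-channel
#' files are rejected: auscultation recordings are single-channel and a
#' silent mixdown would change amplitudes.
#'
#' @param path Path to a `.wav` file.
#' @param label Label for the resulting recording; defaults to the file name.
#' @return An `avf_audio` object.
#' @export
read_wav <- function(path, label = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop(path, ": not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop(path, ": not a WAVE file")
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(raw_fmt[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop(path, ": data chunk before fmt chunk")
      samples <- .decode_wav_data(readBin(con, "raw", sz), fmt, path)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop(path, ": no data chunk found")
  audio_recording(samples, fmt$sample_rate, label)
}

.decode_wav_data <- function(raw_data, fmt, path) {
  if (fmt$n_channels != 1L)
    stop(path, ": expected mono audio, found ", fmt$n_channels, " channels")
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(raw_data, "integer", length(raw_data) / 2, 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(raw_data) / 3
    b <- matrix(as.integer(raw_data), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v[seq_len(n)] / 8388608
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(raw_data, "double", length(raw_data) / 4, 4, endian = "little")
  } else {
    stop(path, sprintf(": unsupported WAV encoding (format %d, %d bit)",
                       fmt$audio_format, fmt$bits))
  }
}

#' Write a recording to a mono WAV file
#'
#' @param rec An `avf_audio` object.
#' @param path Output path.
#' @param bits 16 (PCM, samples clipped to \[-1, 1\]) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16) {
  stopifnot(inherits(rec, "avf_audio"), bits %in% c(16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(rec$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(rec$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")    # block align
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    x <- pmin(pmax(rec$samples, -1), 32767 / 32768)
    writeBin(as.integer(round(x * 32768)), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(rec$samples), con, 4, endian = "little")
  }
  invisible(path)
}
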