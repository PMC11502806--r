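#' Write a waveform to a WAV file (with JSON sidecar metadata)
#'
#' Writes a mono RIFF/WAVE file, 16-bit PCM (`format = "pcm16"`) or 32-bit
#' IEEE float (`format = "float32"`). Because WAV cannot carry the phoneme
#' boundaries and syllable-onset reference points, they are written to a JSON
#' sidecar `<path>.json` alongside the audio.
#'
#' @param w a `waveform`; samples are expected in roughly [-1, 1] (PCM output
#'   is clipped to that range).
#' @param path output file path.
#' @param format `"pcm16"` or `"float32"`.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("pcm16", "float32"), sidecar = TRUE) {
  stopifnot(inherits(w, "waveform"))
  format <- match.arg(format)
  n <- length(w$samples)
  if (format == "pcm16") {
    bits <- 16L; fmt_code <- 1L; block <- 2L
  } else {
    bits <- 32L; fmt_code <- 3L; block <- 4L
  }
  data_bytes <- n * block
  con <- file(path, "wb")
  on.exit(close(con))
  wstr <- function(s) writeChar(s, con, eos = NULL)
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wstr("RIFF"); w32(36L + data_bytes); wstr("WAVE")
  wstr("fmt "); w32(16L); w16(fmt_code); w16(1L)          # mono
  w32(as.integer(w$rate_hz)); w32(as.integer(w$rate_hz) * block)
  w16(block); w16(bits)
  wstr("data"); w32(data_bytes)
  if (format == "pcm16") {
    s <- pmin(pmax(w$samples, -1), 1)
    writeBin(as.integer(round(s * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(w$samples), con, size = 4, endian = "little")
  }
  if (sidecar) {
    meta <- list(rate_hz = w$rate_hz,
                 boundaries = if (nrow(w$boundaries) > 0)
                   unname(apply(w$boundaries, 1, function(r)
                     list(as.numeric(r[["time_s"]]), r[["label"]])))
                 else list(),
                 syllable_onsets = w$syllable_onsets)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' Parses a RIFF/WAVE file (16-bit PCM or 32-bit float, mono) and, when
#' present, the JSON sidecar with boundary/onset metadata.
#'
#' @param path WAV file path.
#' @return a `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rstr <- function(k) readChar(con, k, useBytes = TRUE)
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (rstr(4) != "RIFF") stop("not a RIFF file")
  r32()
  if (rstr(4) != "WAVE") stop("not a WAVE file")
  fmt_code <- NA_integer_; rate <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- rstr(4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- r32()
    if (id == "fmt ") {
      fmt_code <- r16(); nch <- r16(); rate <- r32(); r32(); r16()
      bits <- r16()
      if (size > 16) readBin(con, "raw", size - 16)
      if (nch != 1L) stop("only mono WAV is supported")
    } else if (id == "data") {
      if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, "integer", n = size / 2, size = 2,
                           endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", n = size / 4, size = 4,
                           endian = "little")
      } else stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)")
    } else {
      readBin(con, "raw", size)
    }
    if (!is.null(samples) && !is.na(rate)) break
  }
  if (is.null(samples)) stop("no data chunk found")
  bnd <- NULL; ons <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
    if (length(meta$boundaries) > 0)
      bnd <- data.frame(
        time_s = vapply(meta$boundaries, function(b) as.numeric(b[[1]]), 0),
        label = vapply(meta$boundaries, function(b) as.character(b[[2]]), ""),
        stringsAsFactors = FALSE)
    if (!is.null(meta$syllable_onsets))
      ons <- as.numeric(unlist(meta$syllable_onsets))
  }
  waveform(samples, rate, boundaries = bnd, syllable_onsets = ons)
}
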