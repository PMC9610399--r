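#' Construct an AudioClip
#'
#' @param samples numeric vector (mono) or samples-by-channels matrix of
#'   amplitudes in \[-1, 1\].
#' @param sampleRate sample rate in Hz.
#' @param sourceId identifier recorded with the clip.
#' @return an [AudioClip-class].
#' @export
audioClip <- function(samples, sampleRate, sourceId = "") {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  new("AudioClip", samples = samples, sampleRate = as.numeric(sampleRate),
      sourceId = as.character(sourceId))
}

.read_exact <- function(con, what, n, size, path, signed = TRUE) {
  x <- readBin(con, what, n = n, size = size, signed = signed,
               endian = "little")
  if (length(x) < n)
    stop("truncated WAV file: ", path, call. = FALSE)
  x
}

#' Read a PCM WAV file
#'
#' Parses a RIFF/WAVE file with 8/16/24/32-bit integer or 32-bit float
#' encoding. Integer samples are scaled to \[-1, 1\] by the full-scale
#' integer (so 16-bit -32768 maps to -1.0); no loudness normalization is
#' applied. The header's sample rate and channel count are preserved.
#'
#' @param path path to a RIFF/WAVE PCM file.
#' @return an [AudioClip-class].
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("no such WAV file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  .read_exact(con, integer(), 1L, 4L, path)
  wave <- rawToChar(readBin(con, "raw", 4))
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    size <- .read_exact(con, integer(), 1L, 4L, path)
    cid <- rawToChar(id)
    if (cid == "fmt ") {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(fmt_raw[1:2], integer(), 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], integer(), 1, 2, signed = FALSE, endian = "little"),
        rate = readBin(fmt_raw[5:8], integer(), 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], integer(), 1, 2, signed = FALSE, endian = "little")
      )
    } else if (cid == "data") {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size)
        stop("truncated WAV file: ", path, call. = FALSE)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("truncated WAV file (missing fmt/data chunk): ", path, call. = FALSE)
  if (!fmt$format %in% c(1L, 3L))
    stop("unsupported WAV encoding (format tag ", fmt$format,
         "); only integer PCM and 32-bit float are supported: ", path,
         call. = FALSE)
  n <- length(data_raw) %/% (fmt$bits %/% 8L)
  x <- if (fmt$format == 3L) {
    if (fmt$bits != 32L) stop("float WAV must be 32-bit: ", path, call. = FALSE)
    readBin(data_raw, numeric(), n, 4, endian = "little")
  } else if (fmt$bits == 8L) {
    (readBin(data_raw, integer(), n, 1, signed = FALSE) - 128) / 128
  } else if (fmt$bits == 16L) {
    readBin(data_raw, integer(), n, 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    i1 <- b[seq(1, length(b), 3)]; i2 <- b[seq(2, length(b), 3)]
    i3 <- b[seq(3, length(b), 3)]
    v <- i1 + 256 * i2 + 65536 * i3
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else if (fmt$bits == 32L) {
    readBin(data_raw, integer(), n, 4, endian = "little") / 2^31
  } else stop("unsupported bit depth: ", fmt$bits, call. = FALSE)
  x <- pmin(pmax(x, -1), 1)
  m <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  audioClip(m, fmt$rate, sourceId = basename(path))
}

#' Write an AudioClip as a PCM WAV file
#'
#' @param clip an [AudioClip-class].
#' @param path output path.
#' @param bitsPerSample 8, 16, 24 or 32 for integer PCM, or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(clip, path, bitsPerSample = 16) {
  x <- t(samples(clip))            # interleave: channel-major per frame
  nch <- nChannels(clip)
  rate <- as.integer(sampleRate(clip))
  float <- identical(bitsPerSample, "float32")
  bits <- if (float) 32L else as.integer(bitsPerSample)
  if (!float && !bits %in% c(8L, 16L, 24L, 32L))
    stop("bitsPerSample must be 8, 16, 24, 32 or 'float32'", call. = FALSE)
  bytes <- bits %/% 8L
  nbyte <- length(x) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbyte), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(if (float) 3L else 1L, nch), con, size = 2, endian = "little")
  writeBin(c(rate, rate * nch * bytes), con, size = 4, endian = "little")
  writeBin(c(nch * bytes, bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbyte), con, size = 4, endian = "little")
  v <- as.numeric(x)
  if (float) {
    writeBin(v, con, size = 4, endian = "little")
  } else if (bits == 8L) {
    writeBin(as.integer(pmin(pmax(round(v * 128) + 128, 0), 255)), con, size = 1)
  } else if (bits == 24L) {
    iv <- pmin(pmax(round(v * 2^23), -2^23), 2^23 - 1)
    iv <- ifelse(iv < 0, iv + 2^24, iv)
    b <- rbind(iv %% 256, (iv %/% 256) %% 256, iv %/% 65536)
    writeBin(as.raw(as.vector(b)), con)
  } else {
    full <- 2^(bits - 1)
    writeBin(as.integer(pmin(pmax(round(v * full), -full), full - 1)),
             con, size = bytes, endian = "little")
  }
  invisible(path)
}

#' Convert a clip to mono
#'
#' Channels are mixed down by their arithmetic mean; mono input is returned
#' unchanged. Duration and sample rate are preserved.
#'
#' @param clip an [AudioClip-class].
#' @return a mono [AudioClip-class].
#' @export
toMono <- function(clip) {
  if (nChannels(clip) == 1L) return(clip)
  audioClip(rowMeans(samples(clip)), sampleRate(clip), clip@sourceId)
}

#' Resample a mono clip
#'
#' Band-limited rational-factor (polyphase FIR) resampling via
#' [signal::resample()]. The output length is `round(n * target / orig)`.
#'
#' @param clip a mono [AudioClip-class].
#' @param targetRate target sample rate in Hz.
#' @return the resampled [AudioClip-class].
#' @export
resampleClip <- function(clip, targetRate) {
  if (length(targetRate) != 1L || !is.finite(targetRate) || targetRate <= 0)
    stop("targetRate must be a single positive number", call. = FALSE)
  if (nChannels(clip) != 1L)
    stop("resampleClip expects a mono clip; call toMono() first", call. = FALSE)
  orig <- sampleRate(clip)
  if (orig == targetRate) return(clip)
  g <- .gcd(as.integer(round(targetRate)), as.integer(round(orig)))
  p <- as.integer(round(targetRate)) %/% g
  q <- as.integer(round(orig)) %/% g
  x <- as.numeric(samples(clip))
  y <- signal::resample(x, p = p, q = q)
  nOut <- round(length(x) * targetRate / orig)
  if (length(y) >= nOut) y <- y[seq_len(nOut)] else y <- c(y, numeric(nOut - length(y)))
  y <- pmin(pmax(y, -1), 1)
  audioClip(y, targetRate, clip@sourceId)
}

.gcd <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Read a clip manifest
#'
#' @param path CSV file with columns clip_path, individual_id, age_group
#'   (juvenile/adult) and sex (female/male).
#' @return a data.frame.
#' @export
readClipManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clip_path", "individual_id", "age_group", "sex")
  if (!all(need %in% names(m)))
    stop("clip manifest must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- !m$age_group %in% c("juvenile", "adult") | !m$sex %in% c("female", "male")
  if (any(bad))
    stop("invalid labels in manifest rows: ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  m
}
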