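#' Slice a signal into overlapping frames
#'
#' With `centered = TRUE` (the default, and the convention that yields 173
#' frames for a 2-s segment at 44,100 Hz with hop 512) the signal is
#' reflect-padded by `nFft/2` samples at each end and frame `t` covers
#' samples `[t*hop - nFft/2, t*hop + nFft/2)`, giving
#' `1 + floor(length/hop)` frames.
#'
#' @param x numeric signal.
#' @param nFft frame length in samples (default 1024).
#' @param hop hop (stride) between adjacent frame starts (default 512).
#' @param centered use centered framing with reflect padding (default TRUE).
#' @return a matrix with one frame per row (`nFrames x nFft`).
#' @export
frameSignal <- function(x, nFft = 1024, hop = 512, centered = TRUE) {
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  if (nFft <= 0 || hop <= 0 || hop > nFft)
    stop("need nFft > 0 and 0 < hop <= nFft", call. = FALSE)
  if (centered) {
    pad <- nFft %/% 2L
    if (length(x) <= pad)
      stop("signal too short for centered framing (need > nFft/2 samples)",
           call. = FALSE)
    xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(length(x) - pad):(length(x) - 1L)]))
    nFrames <- 1L + length(x) %/% hop
  } else {
    if (length(x) < nFft) stop("signal shorter than one frame", call. = FALSE)
    xp <- x
    nFrames <- 1L + (length(x) - nFft) %/% hop
  }
  starts <- (seq_len(nFrames) - 1L) * hop
  idx <- outer(starts, seq_len(nFft), `+`)
  matrix(xp[idx], nrow = nFrames, ncol = nFft)
}

#' Hamming window
#'
#' `w[k] = 0.54 - 0.46 cos(2*pi*k/(n-1))`, `k = 0..n-1`.
#'
#' @param n window length (>= 2).
#' @return numeric vector of length `n`.
#' @export
hammingWindow <- function(n) {
  if (n < 2) stop("window length must be >= 2", call. = FALSE)
  k <- 0:(n - 1)
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

#' One-sided power spectrum of windowed frames
#'
#' @param frames matrix of (windowed) frames, one per row.
#' @return matrix `nFrames x (nFft/2 + 1)` of squared FFT magnitudes at the
#'   nonnegative frequencies.
#' @export
powerSpectrum <- function(frames) {
  nFft <- ncol(frames)
  spec <- stats::mvfft(t(frames))
  t(Mod(spec[seq_len(nFft %/% 2L + 1L), , drop = FALSE])^2)
}

.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `nMels` peak-normalized triangular filters with centers equally spaced
#' on the HTK mel scale `mel(f) = 2595*log10(1 + f/700)`. Filter i rises
#' from its left neighbor's center to 1 at its own center and falls to 0
#' at its right neighbor's center.
#'
#' @param sampleRate sample rate in Hz.
#' @param nFft FFT length (determines the default frequency grid).
#' @param nMels number of filters (default 64).
#' @param fMin,fMax band edges in Hz (defaults 0 and Nyquist).
#' @param freqs optional explicit frequency grid at which to evaluate the
#'   filters; defaults to the FFT bin frequencies.
#' @return matrix `nMels x length(freqs)` with attribute `"centers"` (the
#'   filter center frequencies in Hz).
#' @export
melFilterbank <- function(sampleRate = 44100, nFft = 1024, nMels = 64,
                          fMin = 0, fMax = sampleRate / 2, freqs = NULL) {
  if (fMin < 0 || fMin >= fMax || fMax > sampleRate / 2 + 1e-9)
    stop("need 0 <= fMin < fMax <= sampleRate/2", call. = FALSE)
  if (is.null(freqs))
    freqs <- (0:(nFft %/% 2L)) * sampleRate / nFft
  edges <- .mel_to_hz(seq(.hz_to_mel(fMin), .hz_to_mel(fMax), length.out = nMels + 2L))
  fb <- matrix(0, nMels, length(freqs))
  for (m in seq_len(nMels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    rise <- (freqs - lo) / (ce - lo)
    fall <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(rise, fall))
  }
  attr(fb, "centers") <- edges[2:(nMels + 1L)]
  fb
}

#' Log mel-filterbank energies
#'
#' @param power power-spectrum matrix (`nFrames x (nFft/2+1)`).
#' @param fb mel filterbank from [melFilterbank()].
#' @param floor positive lower clamp applied before the natural log
#'   (default 1e-10).
#' @param params extraction parameters stored with the result.
#' @return a [LogMelSpectrum-class] (`effectiveFrames = nFrames`).
#' @export
logMel <- function(power, fb, floor = 1e-10,
                   params = list(sampleRate = 44100, nFft = 1024,
                                 hop = 512, nMels = nrow(fb))) {
  if (ncol(power) != ncol(fb))
    stop("power spectrum has ", ncol(power), " bins but filterbank expects ",
         ncol(fb), call. = FALSE)
  v <- log(pmax(power %*% t(fb), floor))
  new("LogMelSpectrum", values = v, effectiveFrames = nrow(v), params = params)
}

#' Zero-pad a log-mel spectrum to a fixed frame count
#'
#' Rows of zeros are appended after the last real frame; the original rows
#' and `effectiveFrames` are unchanged. This is how sub-2-second segments
#' are expanded to the fixed network input length.
#'
#' @param spec a [LogMelSpectrum-class].
#' @param targetFrames target row count (default 173).
#' @return the padded [LogMelSpectrum-class].
#' @export
padLogMel <- function(spec, targetFrames = 173) {
  n <- nrow(spec@values)
  if (n > targetFrames)
    stop("spectrum has ", n, " frames, more than the target ", targetFrames,
         "; segment the audio first", call. = FALSE)
  if (n == targetFrames) return(spec)
  spec@values <- rbind(spec@values,
                       matrix(0, targetFrames - n, ncol(spec@values)))
  spec
}

#' Orthonormal DCT-II matrix
#'
#' @param n transform size.
#' @return `n x n` orthonormal DCT-II matrix `C` such that `C %*% v`
#'   transforms a column vector; `t(C)` is its inverse.
#' @export
dctMatrix <- function(n) {
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  C
}

#' MFCC matrix from a log-mel spectrum
#'
#' Applies a per-frame orthonormal DCT-II across the mel axis and keeps the
#' first `nCoeffs` coefficients. With `nCoeffs` equal to the mel count the
#' transform is invertible, so no envelope information is lost; the full
#' 64-coefficient matrix is the network input.
#'
#' @param spec a [LogMelSpectrum-class] (typically padded to 173 frames).
#' @param nCoeffs number of cepstral coefficients to keep (default 64).
#' @return numeric matrix `nFrames x nCoeffs`.
#' @export
mfcc <- function(spec, nCoeffs = 64) {
  nm <- ncol(spec@values)
  if (nCoeffs > nm)
    stop("nCoeffs (", nCoeffs, ") exceeds the number of mel bins (", nm, ")",
         call. = FALSE)
  C <- dctMatrix(nm)
  (spec@values %*% t(C))[, seq_len(nCoeffs), drop = FALSE]
}

#' Log-mel spectrum of a call segment
#'
#' The full front end for one segment: framing (1024-sample frames, hop
#' 512, centered), Hamming window, FFT power spectrum, 64 triangular mel
#' filters, natural log with floor, zero padding to `targetFrames` rows.
#'
#' @param segment a [CallSegment-class] (or bare numeric vector at 44,100 Hz).
#' @param nFft,hop,nMels,floor,targetFrames front-end parameters.
#' @return a padded [LogMelSpectrum-class].
#' @export
segmentLogMel <- function(segment, nFft = 1024, hop = 512, nMels = 64,
                          floor = 1e-10, targetFrames = 173) {
  x <- if (is(segment, "CallSegment")) samples(segment) else as.numeric(segment)
  fr <- frameSignal(x, nFft = nFft, hop = hop, centered = TRUE)
  fr <- sweep(fr, 2L, hammingWindow(nFft), `*`)
  pw <- powerSpectrum(fr)
  fb <- melFilterbank(.RATE, nFft = nFft, nMels = nMels)
  sp <- logMel(pw, fb, floor = floor,
               params = list(sampleRate = .RATE, nFft = nFft, hop = hop,
                             nMels = nMels))
  padLogMel(sp, targetFrames)
}

#' Featurize a list of call segments
#'
#' @param segments list of [CallSegment-class] objects.
#' @param ... passed to [segmentLogMel()].
#' @return a [CallFeatureSet-class].
#' @export
featurizeSegments <- function(segments, ...) {
  lm <- lapply(segments, segmentLogMel, ...)
  man <- do.call(rbind, lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    data.frame(segment_id = paste0(s@sourceClip, "#", s@segmentIndex),
               individual_id = s@individualId, age_group = s@ageGroup,
               sex = s@sex, source_clip = s@sourceClip,
               segment_index = s@segmentIndex, needs_padding = s@needsPadding,
               effective_frames = lm[[i]]@effectiveFrames,
               stringsAsFactors = FALSE)
  }))
  new("CallFeatureSet", logmel = lm, manifest = man)
}

#' Featurize a recorded dataset
#'
#' Reads every clip in a manifest, converts to mono, resamples to
#' 44,100 Hz, cuts into 2-s segments and extracts padded log-mel spectra.
#'
#' @param manifest data.frame from [readClipManifest()] (or its CSV path);
#'   `clip_path` entries are resolved relative to `baseDir` when given.
#' @param baseDir optional directory that clip paths are relative to.
#' @param ... passed to [segmentClip()].
#' @return a [CallFeatureSet-class].
#' @export
featurizeDataset <- function(manifest, baseDir = NULL, ...) {
  if (is.character(manifest)) manifest <- readClipManifest(manifest)
  segs <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$clip_path[i]
    if (!is.null(baseDir)) p <- file.path(baseDir, p)
    clip <- resampleClip(toMono(readWav(p)), .RATE)
    segs <- c(segs, segmentClip(clip, manifest$individual_id[i],
                                manifest$age_group[i], manifest$sex[i], ...))
  }
  featurizeSegments(segs)
}

#' Stack MFCC matrices of selected segments into an array
#'
#' @param fs a [CallFeatureSet-class].
#' @param idx integer indices into the feature set (may repeat).
#' @return numeric array `173 x 64 x length(idx)`.
#' @export
mfccArray <- function(fs, idx = seq_along(fs@logmel)) {
  C <- dctMatrix(ncol(fs@logmel[[1]]@values))
  out <- array(0, c(nrow(fs@logmel[[1]]@values), nrow(C), length(idx)))
  for (j in seq_along(idx))
    out[, , j] <- fs@logmel[[idx[j]]]@values %*% t(C)
  out
}

#' Subset a CallFeatureSet
#'
#' @param x a [CallFeatureSet-class].
#' @param i integer indices (may repeat; repeated rows become copies).
#' @param j,drop,... unused.
#' @return a [CallFeatureSet-class].
#' @export
setMethod("[", "CallFeatureSet", function(x, i, j, ..., drop = FALSE) {
  new("CallFeatureSet", logmel = x@logmel[i],
      manifest = x@manifest[i, , drop = FALSE])
})
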