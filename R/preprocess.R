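.RATE <- 44100L
.SEG_SAMPLES <- 2L * 44100L

#' Cut a clip into non-overlapping 2-second segments
#'
#' All but possibly the last segment have exactly `segSeconds` of audio;
#' a short final segment is retained with `needsPadding = TRUE` (the
#' padding itself is applied later, in the log-mel domain). Trailing
#' fragments shorter than `minTailSeconds` are discarded as artifacts;
#' set `minTailSeconds = 0` for strictly lossless segmentation.
#'
#' @param clip a mono [AudioClip-class] at 44,100 Hz.
#' @param individualId,ageGroup,sex caller labels to attach to every segment.
#' @param segSeconds segment duration in seconds (default 2).
#' @param minTailSeconds minimum retained length of the final short
#'   segment, in seconds (default 0.2).
#' @return a list of [CallSegment-class] objects.
#' @export
segmentClip <- function(clip, individualId, ageGroup, sex,
                        segSeconds = 2, minTailSeconds = 0.2) {
  if (nChannels(clip) != 1L || sampleRate(clip) != .RATE)
    stop("segmentClip expects a mono clip at 44,100 Hz", call. = FALSE)
  x <- as.numeric(samples(clip))
  if (length(x) == 0L) stop("empty clip", call. = FALSE)
  segLen <- as.integer(round(segSeconds * .RATE))
  nSeg <- ceiling(length(x) / segLen)
  out <- vector("list", nSeg)
  keep <- logical(nSeg)
  for (i in seq_len(nSeg)) {
    lo <- (i - 1L) * segLen + 1L
    hi <- min(i * segLen, length(x))
    s <- x[lo:hi]
    keep[i] <- length(s) >= minTailSeconds * .RATE
    if (!keep[i]) next
    out[[i]] <- new("CallSegment", samples = s,
                    individualId = as.character(individualId),
                    ageGroup = ageGroup, sex = sex,
                    sourceClip = clip@sourceId,
                    segmentIndex = i - 1L,
                    needsPadding = length(s) < segLen)
  }
  out[keep]
}

#' Mix background noise into a segment at a target SNR
#'
#' A random contiguous excerpt of the noise pool is scaled so that
#' `10*log10(P_signal / P_noise)` equals `snrDb` and added to the segment.
#' Labels and length are unchanged. `snrDb = Inf` returns the input
#' unmodified. Uses the R random number generator; seed with [set.seed()]
#' for reproducibility.
#'
#' @param segment a [CallSegment-class].
#' @param noise a mono [AudioClip-class] at 44,100 Hz, at least as long as
#'   the segment.
#' @param snrDb target signal-to-noise ratio in decibels (default 10).
#' @return the noisy [CallSegment-class].
#' @export
mixBackground <- function(segment, noise, snrDb = 10) {
  if (is.infinite(snrDb) && snrDb > 0) return(segment)
  if (nChannels(noise) != 1L || sampleRate(noise) != .RATE)
    stop("noise must be mono at 44,100 Hz", call. = FALSE)
  s <- samples(segment)
  nz <- as.numeric(samples(noise))
  if (length(nz) < length(s))
    stop("noise pool shorter than segment", call. = FALSE)
  start <- sample.int(length(nz) - length(s) + 1L, 1L)
  ex <- nz[start:(start + length(s) - 1L)]
  pn <- mean(ex^2)
  if (pn == 0) stop("degenerate noise: excerpt has zero power", call. = FALSE)
  ps <- mean(s^2)
  g <- sqrt(ps / (pn * 10^(snrDb / 10)))
  out <- segment
  out@samples <- s + g * ex
  out
}
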