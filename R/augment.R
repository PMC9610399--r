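#' Construct an augmentation policy
#'
#' Defaults: Gaussian noise at 0.1 of each spectrum's standard deviation,
#' two frequency masks of width up to 8 mel bins, one time mask of width up
#' to 20 frames, and the per-class replication factors used to balance the
#' study's population (six extra copies per male segment to meet the female
#' count, two per juvenile, one per adult, none per female).
#'
#' @param gaussianSigma noise std as a fraction of the spectrum's own std.
#' @param nFreqMasks,maxFreqWidth frequency-mask count and max width (bins).
#' @param nTimeMasks,maxTimeWidth time-mask count and max width (frames).
#' @param replication named vector of per-class replication factors.
#' @return an [AugmentationPolicy-class].
#' @export
augmentationPolicy <- function(gaussianSigma = 0.1, nFreqMasks = 2,
                               maxFreqWidth = 8, nTimeMasks = 1,
                               maxTimeWidth = 20,
                               replication = c(male = 6, female = 0,
                                               juvenile = 2, adult = 1)) {
  new("AugmentationPolicy", gaussianSigma = gaussianSigma,
      nFreqMasks = as.integer(nFreqMasks), maxFreqWidth = as.integer(maxFreqWidth),
      nTimeMasks = as.integer(nTimeMasks), maxTimeWidth = as.integer(maxTimeWidth),
      replication = replication)
}

#' Add Gaussian noise to a log-mel spectrum
#'
#' Independent N(0, sigma^2) noise is added to every real (non-padded)
#' entry; padded rows stay exactly zero. Uses the R RNG.
#'
#' @param spec a [LogMelSpectrum-class].
#' @param sigma absolute noise standard deviation (log-energy units).
#' @return the noisy [LogMelSpectrum-class].
#' @export
addGaussianNoise <- function(spec, sigma) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(spec)
  ef <- spec@effectiveFrames
  nm <- ncol(spec@values)
  spec@values[seq_len(ef), ] <- spec@values[seq_len(ef), , drop = FALSE] +
    matrix(stats::rnorm(ef * nm, sd = sigma), ef, nm)
  spec
}

.draw_masks <- function(nMasks, maxWidth, axisLen) {
  out <- matrix(0L, nMasks, 2L, dimnames = list(NULL, c("start", "width")))
  for (i in seq_len(nMasks)) {
    w <- sample.int(maxWidth + 1L, 1L) - 1L          # Uniform{0..maxWidth}
    f0 <- sample.int(axisLen - w + 1L, 1L) - 1L      # Uniform{0..axisLen-w}
    out[i, ] <- c(f0, w)
  }
  out
}

#' SpecAugment frequency masking
#'
#' For each mask a width `w ~ Uniform{0..maxWidth}` and a start
#' `f0 ~ Uniform{0..nMels-w}` are drawn and mel columns `[f0, f0+w)` are
#' set to zero; all other entries are untouched. The drawn masks are
#' attached as attribute `"masks"` (0-based starts) for auditing.
#'
#' @param spec a [LogMelSpectrum-class].
#' @param nMasks number of masks.
#' @param maxWidth maximum mask width in mel bins (<= number of mel bins).
#' @return the masked [LogMelSpectrum-class].
#' @export
freqMask <- function(spec, nMasks = 2, maxWidth = 8) {
  nm <- ncol(spec@values)
  if (maxWidth > nm) stop("maxWidth exceeds the mel axis", call. = FALSE)
  masks <- .draw_masks(nMasks, maxWidth, nm)
  for (i in seq_len(nrow(masks)))
    if (masks[i, "width"] > 0L)
      spec@values[, (masks[i, "start"] + 1L):(masks[i, "start"] + masks[i, "width"])] <- 0
  attr(spec@values, "masks") <- masks
  spec
}

#' SpecAugment time masking
#'
#' Same contract as [freqMask()] but on the frame (time) axis, restricted
#' to the real frames: masks never land in the zero-padded region.
#'
#' @param spec a [LogMelSpectrum-class].
#' @param nMasks number of masks.
#' @param maxWidth maximum mask width in frames; clamped to the number of
#'   real frames.
#' @return the masked [LogMelSpectrum-class].
#' @export
timeMask <- function(spec, nMasks = 1, maxWidth = 20) {
  ef <- spec@effectiveFrames
  maxWidth <- min(maxWidth, ef)
  masks <- .draw_masks(nMasks, maxWidth, ef)
  for (i in seq_len(nrow(masks)))
    if (masks[i, "width"] > 0L)
      spec@values[(masks[i, "start"] + 1L):(masks[i, "start"] + masks[i, "width"]), ] <- 0
  attr(spec@values, "masks") <- masks
  spec
}

.augment_once <- function(spec, policy) {
  ef <- spec@effectiveFrames
  sdv <- stats::sd(spec@values[seq_len(ef), ])
  spec <- addGaussianNoise(spec, policy@gaussianSigma * sdv)
  spec <- freqMask(spec, policy@nFreqMasks, policy@maxFreqWidth)
  spec <- timeMask(spec, policy@nTimeMasks, policy@maxTimeWidth)
  attr(spec@values, "masks") <- NULL
  spec
}

#' Expand a training collection by per-class replicated augmentation
#'
#' Every segment of class c receives `replication[c]` independently
#' augmented variants (Gaussian noise plus frequency/time masks, fresh
#' randomness each time); originals are retained, so the output holds
#' `sum_c n_c * (1 + r(c))` segments. Augmented copies keep their parent's
#' labels and individual ID, so copies of a held-out individual can never
#' leak into training.
#'
#' @param fs a [CallFeatureSet-class] (training segments only).
#' @param policy an [AugmentationPolicy-class].
#' @param task `"age"` (classes juvenile/adult) or `"sex"` (female/male).
#' @return the expanded [CallFeatureSet-class].
#' @export
balanceDataset <- function(fs, policy, task = c("age", "sex")) {
  task <- match.arg(task)
  cls <- if (task == "age") fs@manifest$age_group else fs@manifest$sex
  unknown <- setdiff(unique(cls), names(policy@replication))
  if (length(unknown) > 0L)
    stop("no replication factor for class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  reps <- policy@replication[cls]
  extraIdx <- rep(seq_along(cls), times = reps)
  lm <- c(fs@logmel, lapply(extraIdx, function(i) .augment_once(fs@logmel[[i]], policy)))
  man <- rbind(fs@manifest, fs@manifest[extraIdx, , drop = FALSE])
  man$augmented <- c(rep(FALSE, nrow(fs@manifest)), rep(TRUE, length(extraIdx)))
  rownames(man) <- NULL
  new("CallFeatureSet", logmel = lm, manifest = man)
}
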