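#' @import methods
NULL

#' AudioClip: a sampled waveform
#'
#' The raw unit of ingestion: one recording held as a samples-by-channels
#' matrix of amplitudes in \[-1, 1\], together with its sample rate in Hz and
#' an opaque source identifier.
#'
#' @slot samples numeric matrix, one column per channel, amplitudes in \[-1, 1\].
#' @slot sampleRate positive integer-valued sample rate in Hz.
#' @slot sourceId character scalar identifying the origin of the clip.
#' @exportClass AudioClip
setClass("AudioClip",
  representation(samples = "matrix", sampleRate = "numeric", sourceId = "character"),
  prototype(samples = matrix(numeric(0), 0, 1), sampleRate = 44100, sourceId = "")
)

setValidity("AudioClip", function(object) {
  msg <- NULL
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (nrow(object@samples) == 0L)
    msg <- c(msg, "clip contains no samples")
  if (nrow(object@samples) > 0L) {
    rng <- range(object@samples)
    if (!all(is.finite(rng)))
      msg <- c(msg, "samples must be finite")
    else if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
      msg <- c(msg, "amplitudes must lie in [-1, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' CallSegment: a fixed-duration mono call excerpt
#'
#' The unit of classification: at most 2 s of mono audio at 44,100 Hz cut
#' from a parent clip, carrying the caller's labels. Segments shorter than
#' 2 s are flagged for zero padding, which is applied later in the log-mel
#' domain.
#'
#' @slot samples numeric vector of mono amplitudes at 44,100 Hz.
#' @slot individualId,ageGroup,sex caller labels inherited from the parent
#'   clip; `ageGroup` is `"juvenile"` or `"adult"`, `sex` is `"female"` or
#'   `"male"`.
#' @slot sourceClip identifier of the parent clip.
#' @slot segmentIndex 0-based position of the segment within the parent.
#' @slot needsPadding TRUE iff the segment is shorter than 2 s.
#' @exportClass CallSegment
setClass("CallSegment",
  representation(samples = "numeric", individualId = "character",
                 ageGroup = "character", sex = "character",
                 sourceClip = "character", segmentIndex = "integer",
                 needsPadding = "logical")
)

setValidity("CallSegment", function(object) {
  msg <- NULL
  n <- length(object@samples)
  if (n == 0L || n > 2L * 44100L)
    msg <- c(msg, "segment length must be in (0, 2 s] at 44,100 Hz")
  if (!identical(object@needsPadding, n < 2L * 44100L))
    msg <- c(msg, "needsPadding must equal (length < 2 s)")
  if (!object@ageGroup %in% c("juvenile", "adult"))
    msg <- c(msg, "ageGroup must be 'juvenile' or 'adult'")
  if (!object@sex %in% c("female", "male"))
    msg <- c(msg, "sex must be 'female' or 'male'")
  if (is.null(msg)) TRUE else msg
})

#' LogMelSpectrum: frames-by-mel log-energy matrix
#'
#' @slot values numeric matrix (frames x mel bins) of natural-log energies;
#'   rows past `effectiveFrames` are zero padding.
#' @slot effectiveFrames number of real (non-padded) frames.
#' @slot params list of extraction parameters (sampleRate, nFft, hop, nMels).
#' @exportClass LogMelSpectrum
setClass("LogMelSpectrum",
  representation(values = "matrix", effectiveFrames = "integer", params = "list")
)

setValidity("LogMelSpectrum", function(object) {
  msg <- NULL
  if (!all(is.finite(object@values)))
    msg <- c(msg, "log-mel values must be finite (log floor applied)")
  if (object@effectiveFrames < 1L || object@effectiveFrames > nrow(object@values))
    msg <- c(msg, "effectiveFrames must be in [1, nrow(values)]")
  if (is.null(msg)) TRUE else msg
})

#' AugmentationPolicy: noise, masking and per-class replication settings
#'
#' @slot gaussianSigma Gaussian noise level, as a fraction of each
#'   spectrum's own standard deviation.
#' @slot nFreqMasks,maxFreqWidth number and maximum width (mel bins) of
#'   frequency masks.
#' @slot nTimeMasks,maxTimeWidth number and maximum width (frames) of time
#'   masks; time masks are restricted to the non-padded frames.
#' @slot replication named numeric vector of per-class replication factors,
#'   e.g. `c(male = 6, female = 0, juvenile = 2, adult = 1)`: each original
#'   of class c gains `replication[c]` independently augmented variants.
#' @exportClass AugmentationPolicy
setClass("AugmentationPolicy",
  representation(gaussianSigma = "numeric", nFreqMasks = "integer",
                 maxFreqWidth = "integer", nTimeMasks = "integer",
                 maxTimeWidth = "integer", replication = "numeric")
)

setValidity("AugmentationPolicy", function(object) {
  msg <- NULL
  if (object@gaussianSigma < 0) msg <- c(msg, "gaussianSigma must be >= 0")
  if (any(c(object@nFreqMasks, object@maxFreqWidth, object@nTimeMasks,
            object@maxTimeWidth) < 0L))
    msg <- c(msg, "mask counts and widths must be >= 0")
  if (any(object@replication < 0) || any(object@replication != round(object@replication)))
    msg <- c(msg, "replication factors must be nonnegative integers")
  if (is.null(msg)) TRUE else msg
})

#' CallFeatureSet: a featurized segment collection
#'
#' Holds the (padded) log-mel spectra of a set of call segments together
#' with a manifest of per-segment metadata. This is the container the
#' split/augment/train machinery operates on.
#'
#' @slot logmel list of 173 x 64 log-mel matrices, one per segment.
#' @slot manifest data.frame with columns segment_id, individual_id,
#'   age_group, sex, source_clip, segment_index, needs_padding,
#'   effective_frames.
#' @exportClass CallFeatureSet
setClass("CallFeatureSet",
  representation(logmel = "list", manifest = "data.frame")
)

setValidity("CallFeatureSet", function(object) {
  msg <- NULL
  if (length(object@logmel) != nrow(object@manifest))
    msg <- c(msg, "one log-mel matrix per manifest row required")
  need <- c("segment_id", "individual_id", "age_group", "sex", "effective_frames")
  if (!all(need %in% names(object@manifest)))
    msg <- c(msg, paste("manifest must contain columns:", paste(need, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' SplitPlan: one repetition's train/test assignment
#'
#' @slot testIndividuals,trainIndividuals character vectors of individual IDs;
#'   disjoint when `mutuallyExclusive` is TRUE.
#' @slot testSegments,trainSegments integer indices into the feature set's
#'   manifest; test indices may repeat (round-robin copying of small test
#'   pools up to the target size).
#' @slot mutuallyExclusive whether the split is individual-exclusive.
#' @slot repetitionIndex 0-based repetition number.
#' @slot seed the RNG seed that produced this plan.
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(testIndividuals = "character", trainIndividuals = "character",
                 testSegments = "integer", trainSegments = "integer",
                 mutuallyExclusive = "logical", repetitionIndex = "integer",
                 seed = "integer")
)

setValidity("SplitPlan", function(object) {
  msg <- NULL
  if (object@mutuallyExclusive &&
      length(intersect(object@testIndividuals, object@trainIndividuals)) > 0L)
    msg <- c(msg, "mutually exclusive plan has overlapping individuals")
  if (anyDuplicated(object@trainSegments))
    msg <- c(msg, "train segments must be unique")
  if (is.null(msg)) TRUE else msg
})

#' EvalResult: cross-validation metrics
#'
#' @slot perRepetition data.frame with one row per repetition and columns
#'   repetition, precision, recall, f1.
#' @slot task,arm labels describing what was evaluated.
#' @exportClass EvalResult
setClass("EvalResult",
  representation(perRepetition = "data.frame", task = "character", arm = "character")
)

setValidity("EvalResult", function(object) {
  m <- object@perRepetition
  msg <- NULL
  if (!all(c("precision", "recall", "f1") %in% names(m)))
    msg <- c(msg, "perRepetition needs precision, recall, f1 columns")
  else if (nrow(m) > 0L) {
    v <- unlist(m[c("precision", "recall", "f1")])
    if (any(v < -1e-12 | v > 1 + 1e-12)) msg <- c(msg, "metrics must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' SENetModel: a trained (or untrained) SE-CNN classifier
#'
#' @slot params named list of parameter matrices (convolution kernels,
#'   biases, SE bottleneck weights, dense head).
#' @slot config architecture/optimizer configuration list.
#' @slot classes character vector of the two class labels, in logit order.
#' @slot trainingLog data.frame (epoch, loss) filled by [trainModel()].
#' @exportClass SENetModel
setClass("SENetModel",
  representation(params = "list", config = "list", classes = "character",
                 trainingLog = "data.frame")
)

#' PopulationSpec: synthetic population description
#'
#' Defaults mirror the study population: 8 juvenile females, 3 juvenile
#' males, 13 adult females and 4 adult males (28 captive individuals).
#'
#' @slot groupSizes named integer vector with names
#'   `juvenile_female`, `juvenile_male`, `adult_female`, `adult_male`.
#' @slot callsPerIndividual integer range (min, max) of calls per female
#'   individual.
#' @slot maleCallFraction relative call abundance of males; encodes the
#'   study's report that far fewer male vocalizations were available.
#' @slot durationRange numeric range (min, max) of call durations in seconds.
#' @slot separation scalar in \[0, 1\] scaling every between-class acoustic
#'   difference; 0 is the null model (identical class distributions).
#' @slot seed base RNG seed for the generator.
#' @exportClass PopulationSpec
setClass("PopulationSpec",
  representation(groupSizes = "integer", callsPerIndividual = "integer",
                 maleCallFraction = "numeric", durationRange = "numeric",
                 separation = "numeric", seed = "integer")
)

setValidity("PopulationSpec", function(object) {
  msg <- NULL
  need <- c("juvenile_female", "juvenile_male", "adult_female", "adult_male")
  if (!all(need %in% names(object@groupSizes)))
    msg <- c(msg, paste("groupSizes needs names:", paste(need, collapse = ", ")))
  if (any(object@groupSizes < 0L)) msg <- c(msg, "group sizes must be >= 0")
  if (object@separation < 0 || object@separation > 1)
    msg <- c(msg, "separation must be in [0, 1]")
  if (is.null(msg)) TRUE else msg
})
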