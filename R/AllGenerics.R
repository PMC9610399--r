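#' Accessors for bleatnet objects
#'
#' `samples()` returns the raw amplitude data, `sampleRate()` the rate in
#' Hz, `nChannels()` the channel count and `durationSeconds()` the clip
#' duration. `manifest()` returns the per-segment metadata of a
#' [CallFeatureSet-class] and `logmelValues()` the matrix of a
#' [LogMelSpectrum-class].
#'
#' @param x an object.
#' @return the corresponding slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("durationSeconds", function(x) standardGeneric("durationSeconds"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("logmelValues", function(x) standardGeneric("logmelValues"))
#' @rdname accessors
#' @export
setGeneric("effectiveFrames", function(x) standardGeneric("effectiveFrames"))

#' @rdname accessors
setMethod("samples", "AudioClip", function(x) x@samples)
#' @rdname accessors
setMethod("samples", "CallSegment", function(x) x@samples)
#' @rdname accessors
setMethod("sampleRate", "AudioClip", function(x) x@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "CallSegment", function(x) 44100)
#' @rdname accessors
setMethod("nChannels", "AudioClip", function(x) ncol(x@samples))
#' @rdname accessors
setMethod("durationSeconds", "AudioClip",
          function(x) nrow(x@samples) / x@sampleRate)
#' @rdname accessors
setMethod("durationSeconds", "CallSegment",
          function(x) length(x@samples) / 44100)
#' @rdname accessors
setMethod("manifest", "CallFeatureSet", function(x) x@manifest)
#' @rdname accessors
setMethod("logmelValues", "LogMelSpectrum", function(x) x@values)
#' @rdname accessors
setMethod("effectiveFrames", "LogMelSpectrum", function(x) x@effectiveFrames)

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip '%s': %.3f s, %d Hz, %d channel(s)\n",
              object@sourceId, durationSeconds(object),
              as.integer(object@sampleRate), nChannels(object)))
})

setMethod("show", "CallSegment", function(object) {
  cat(sprintf("CallSegment %s#%d: %.3f s, %s %s%s\n",
              object@sourceClip, object@segmentIndex,
              durationSeconds(object), object@ageGroup, object@sex,
              if (object@needsPadding) " (needs padding)" else ""))
})

setMethod("show", "LogMelSpectrum", function(object) {
  cat(sprintf("LogMelSpectrum: %d x %d (%d real frames)\n",
              nrow(object@values), ncol(object@values), object@effectiveFrames))
})

setMethod("show", "CallFeatureSet", function(object) {
  m <- object@manifest
  cat(sprintf("CallFeatureSet: %d segments from %d individuals\n",
              nrow(m), length(unique(m$individual_id))))
  if (nrow(m) > 0L)
    print(table(age = m$age_group, sex = m$sex))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf(
    "SplitPlan rep %d: %d test segments from {%s}, %d train segments, %s\n",
    object@repetitionIndex, length(object@testSegments),
    paste(object@testIndividuals, collapse = ", "),
    length(object@trainSegments),
    if (object@mutuallyExclusive) "individual-exclusive" else "pooled"))
})

setMethod("show", "EvalResult", function(object) {
  s <- summary(object)
  cat(sprintf("EvalResult [%s/%s], %d repetitions\n", object@arm, object@task,
              nrow(object@perRepetition)))
  cat(sprintf("  precision %.4f +/- %.4f\n  recall    %.4f +/- %.4f\n  F1        %.4f +/- %.4f\n",
              s["precision", "mean"], s["precision", "sd"],
              s["recall", "mean"], s["recall", "sd"],
              s["f1", "mean"], s["f1", "sd"]))
})

setMethod("show", "SENetModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("SENetModel (%s): %d parameters, classes [%s], %d epochs trained\n",
              paste(object@config$channels, collapse = "-"), np,
              paste(object@classes, collapse = ", "),
              nrow(object@trainingLog)))
})

setMethod("show", "PopulationSpec", function(object) {
  cat(sprintf("PopulationSpec: %s (separation %.2f, seed %d)\n",
              paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
                    collapse = ", "),
              object@separation, object@seed))
})

#' Summarize an EvalResult
#'
#' @param object an [EvalResult-class].
#' @param ... ignored.
#' @return a matrix with rows precision/recall/f1 and columns mean/sd.
#' @export
setMethod("summary", "EvalResult", function(object, ...) {
  m <- object@perRepetition
  out <- rbind(
    precision = c(mean(m$precision), stats::sd(m$precision)),
    recall    = c(mean(m$recall), stats::sd(m$recall)),
    f1        = c(mean(m$f1), stats::sd(m$f1))
  )
  colnames(out) <- c("mean", "sd")
  out
})
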