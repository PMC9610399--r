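# Session-cached synthetic corpora used by the generator and pipeline
# tests. Generated once per test run into tempdir() and featurized once.
.corpus_cache <- new.env(parent = emptyenv())

testCorpusDir <- function(separation) {
  key <- sprintf("sep%03d", round(100 * separation))
  dir <- file.path(tempdir(), paste0("bleatnet_corpus_", key))
  if (!file.exists(file.path(dir, "manifest.csv")))
    generateDataset(populationSpec(separation = separation, seed = 11L), dir)
  dir
}

testCorpus <- function(separation) {
  key <- sprintf("sep%03d", round(100 * separation))
  if (!is.null(.corpus_cache[[key]])) return(.corpus_cache[[key]])
  dir <- testCorpusDir(separation)
  fs <- featurizeDataset(file.path(dir, "manifest.csv"), baseDir = dir)
  .corpus_cache[[key]] <- fs
  fs
}

# autocorrelation pitch estimate (Hz) for a mono 44,100-Hz waveform;
# searches 110-900 Hz, robust to formant shaping of the harmonics
acfPitch <- function(x, rate = 44100) {
  x <- x - mean(x)
  n <- min(length(x), rate)           # at most 1 s
  x <- x[seq_len(n)]
  ac <- stats::acf(x, lag.max = 400, plot = FALSE)$acf[-1]
  lags <- 49:400                      # 110 Hz .. 900 Hz
  rate / lags[which.max(ac[lags])]
}

# a small labelled feature set built directly in feature space (no audio),
# for split/augment bookkeeping tests
toyFeatureSet <- function(nPerIndividual, individuals, ageGroups, sexes,
                          nFrames = 173, nMels = 64, seed = 1) {
  set.seed(seed)
  rows <- list(); lm <- list()
  for (i in seq_along(individuals)) {
    for (j in seq_len(nPerIndividual[i])) {
      ef <- sample(80:173, 1)
      v <- matrix(0, nFrames, nMels)
      v[seq_len(ef), ] <- rnorm(ef * nMels)
      lm[[length(lm) + 1L]] <- new("LogMelSpectrum", values = v,
                                   effectiveFrames = as.integer(ef),
                                   params = list())
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = sprintf("%s#%d", individuals[i], j),
        individual_id = individuals[i], age_group = ageGroups[i],
        sex = sexes[i], source_clip = individuals[i], segment_index = j - 1L,
        needs_padding = ef < nFrames, effective_frames = ef,
        stringsAsFactors = FALSE)
    }
  }
  new("CallFeatureSet", logmel = lm, manifest = do.call(rbind, rows))
}
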