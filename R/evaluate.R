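#' Confusion counts for binary labels
#'
#' @param predicted,true equal-length label vectors.
#' @param positiveClass the label treated as positive.
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusionCounts <- function(predicted, true, positiveClass) {
  if (length(predicted) != length(true))
    stop("predicted and true labels differ in length", call. = FALSE)
  pp <- predicted == positiveClass
  tp_ <- true == positiveClass
  c(tp = sum(pp & tp_), fp = sum(pp & !tp_),
    fn = sum(!pp & tp_), tn = sum(!pp & !tp_))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2PR/(P+R)`; each is defined as 0 when its denominator is 0
#' (in particular `f1 = 0` when `tp = 0`).
#'
#' @param counts named vector from [confusionCounts()].
#' @return the metric value in \[0, 1\].
#' @name metrics
NULL

#' @rdname metrics
#' @export
precisionScore <- function(counts) {
  d <- counts[["tp"]] + counts[["fp"]]
  if (d == 0) 0 else counts[["tp"]] / d
}

#' @rdname metrics
#' @export
recallScore <- function(counts) {
  d <- counts[["tp"]] + counts[["fn"]]
  if (d == 0) 0 else counts[["tp"]] / d
}

#' @rdname metrics
#' @export
f1Score <- function(counts) {
  p <- precisionScore(counts)
  r <- recallScore(counts)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Build train/test split plans
#'
#' Individual-exclusive mode (`mutuallyExclusive = TRUE`): per repetition,
#' `nTestIndividuals` individuals are drawn uniformly without replacement;
#' their segments form the test pool, copied round-robin up to `nTest`
#' when too few or subsampled down to `nTest` when too many; the remaining
#' individuals' segments are subsampled to `nTrain`. Pooled mode
#' (`mutuallyExclusive = FALSE`): segments are pooled and split
#' `nTrain`/`nTest` with no individual constraint.
#'
#' @param man segment manifest (data.frame with `individual_id`), or a
#'   [CallFeatureSet-class].
#' @param mutuallyExclusive forbid individual overlap between sides.
#' @param nReps number of repetitions (default 10).
#' @param nTest,nTrain fixed test/train sizes (defaults 100 and 540).
#' @param nTestIndividuals number of held-out individuals (default 4).
#' @param seed base seed; repetition r uses `seed + r`.
#' @return list of [SplitPlan-class] objects.
#' @export
makeSplits <- function(man, mutuallyExclusive = TRUE, nReps = 10,
                       nTest = 100, nTrain = 540, nTestIndividuals = 4,
                       seed = 1L) {
  if (is(man, "CallFeatureSet")) man <- manifest(man)
  ids <- unique(man$individual_id)
  if (mutuallyExclusive && length(ids) <= nTestIndividuals)
    stop("need more than ", nTestIndividuals, " individuals", call. = FALSE)
  lapply(seq_len(nReps), function(r) {
    repSeed <- as.integer(seed + r)
    set.seed(repSeed)
    if (mutuallyExclusive) {
      testInd <- sample(ids, nTestIndividuals)
      trainInd <- setdiff(ids, testInd)
      testPool <- which(man$individual_id %in% testInd)
      testSeg <- if (length(testPool) >= nTest) sample(testPool, nTest)
                 else rep(testPool, length.out = nTest)
      trainPool <- which(man$individual_id %in% trainInd)
      if (length(trainPool) < nTrain)
        stop("train pool has only ", length(trainPool), " segments; ",
             nTrain, " required (short by ", nTrain - length(trainPool), ")",
             call. = FALSE)
      trainSeg <- sample(trainPool, nTrain)
    } else {
      if (nrow(man) < nTrain + nTest)
        stop("pool has only ", nrow(man), " segments; ", nTrain + nTest,
             " required", call. = FALSE)
      pool <- sample.int(nrow(man), nTrain + nTest)
      trainSeg <- pool[seq_len(nTrain)]
      testSeg <- pool[(nTrain + 1L):(nTrain + nTest)]
      trainInd <- unique(man$individual_id[trainSeg])
      testInd <- unique(man$individual_id[testSeg])
    }
    new("SplitPlan", testIndividuals = as.character(testInd),
        trainIndividuals = as.character(trainInd),
        testSegments = as.integer(testSeg), trainSegments = as.integer(trainSeg),
        mutuallyExclusive = mutuallyExclusive, repetitionIndex = r - 1L,
        seed = repSeed)
  })
}

.ARMS <- list(
  E1  = list(exclusive = FALSE, augment = FALSE, loss = "cross_entropy"),
  E2A = list(exclusive = TRUE,  augment = FALSE, loss = "cross_entropy"),
  E2B = list(exclusive = TRUE,  augment = TRUE,  loss = "cross_entropy"),
  E2C = list(exclusive = TRUE,  augment = TRUE,  loss = "focal")
)

.task_labels <- function(man, task) {
  if (task == "age") man$age_group else man$sex
}

.positive_class <- function(task) if (task == "age") "adult" else "female"

.task_classes <- function(task) {
  if (task == "age") c("juvenile", "adult") else c("male", "female")
}

.run_one_rep <- function(fs, plan, task, augment, loss, policy, config,
                         positiveClass) {
  man <- manifest(fs)
  trainFs <- fs[plan@trainSegments]
  if (augment) trainFs <- balanceDataset(trainFs, policy, task)
  Xtr <- mfccArray(trainFs)
  ytr <- .task_labels(manifest(trainFs), task)
  model <- buildModel(config, .task_classes(task))
  model <- trainModel(model, Xtr, ytr, loss = loss, seed = plan@seed)
  Xte <- mfccArray(fs, plan@testSegments)
  pred <- predictClasses(model, Xte)
  truth <- .task_labels(man, task)[plan@testSegments]
  cc <- confusionCounts(pred, truth, positiveClass)
  c(precision = precisionScore(cc), recall = recallScore(cc), f1 = f1Score(cc))
}

#' Run one evaluation experiment arm
#'
#' Arms mirror the study design: E1 pools segments without the individual
#' constraint (cross-validated over ten random 540/100 splits); E2A adds
#' the individual-exclusive constraint; E2B adds per-class balanced
#' augmentation; E2C additionally swaps cross entropy for focal loss.
#' Augmentation is applied to the training side only, after splitting.
#' Metrics are computed per repetition and summarized as mean and standard
#' deviation.
#'
#' @param arm one of `"E1"`, `"E2A"`, `"E2B"`, `"E2C"`.
#' @param task `"age"` (positive class adult) or `"sex"` (positive class
#'   female).
#' @param fs a [CallFeatureSet-class] for the whole corpus.
#' @param config model configuration from [modelConfig()].
#' @param policy an [AugmentationPolicy-class] (used by E2B/E2C).
#' @param nReps repetitions (default 10).
#' @param nTest,nTrain split sizes (defaults 100/540).
#' @param seed base seed for splits and training.
#' @param positiveClass override the positive class convention.
#' @return an [EvalResult-class].
#' @export
runExperiment <- function(arm = c("E1", "E2A", "E2B", "E2C"),
                          task = c("age", "sex"), fs,
                          config = modelConfig("test"),
                          policy = augmentationPolicy(), nReps = 10,
                          nTest = 100, nTrain = 540, seed = 1L,
                          positiveClass = NULL) {
  arm <- match.arg(arm)
  task <- match.arg(task)
  setup <- .ARMS[[arm]]
  if (is.null(positiveClass)) positiveClass <- .positive_class(task)
  plans <- makeSplits(fs, mutuallyExclusive = setup$exclusive, nReps = nReps,
                      nTest = nTest, nTrain = nTrain, seed = seed)
  rows <- lapply(seq_along(plans), function(r) {
    m <- tryCatch(
      .run_one_rep(fs, plans[[r]], task, setup$augment, setup$loss, policy,
                   config, positiveClass),
      error = function(e) stop("repetition ", r, ": ", conditionMessage(e),
                               call. = FALSE))
    data.frame(repetition = r, precision = m[["precision"]],
               recall = m[["recall"]], f1 = m[["f1"]])
  })
  new("EvalResult", perRepetition = do.call(rbind, rows), task = task, arm = arm)
}

#' Training-set size sweep
#'
#' For each repetition the four test individuals are fixed, a 100-segment
#' test set and a maximal train ordering are drawn once, and nested train
#' subsets of each requested size are used to train and evaluate the full
#' augmentation + focal-loss pipeline (the E2C configuration).
#'
#' @param task `"age"` or `"sex"`.
#' @param fs a [CallFeatureSet-class].
#' @param sizes training-set sizes (default `seq(540, 720, by = 30)`).
#' @param config,policy model and augmentation settings.
#' @param nReps repetitions per size.
#' @param seed base seed.
#' @return named list of [EvalResult-class], one per size.
#' @export
trainingSizeSweep <- function(task = c("age", "sex"), fs,
                              sizes = seq(540, 720, by = 30),
                              config = modelConfig("test"),
                              policy = augmentationPolicy(), nReps = 10,
                              seed = 1L) {
  task <- match.arg(task)
  positiveClass <- .positive_class(task)
  plans <- makeSplits(fs, mutuallyExclusive = TRUE, nReps = nReps,
                      nTest = 100, nTrain = max(sizes), seed = seed)
  res <- lapply(sizes, function(sz) {
    rows <- lapply(seq_along(plans), function(r) {
      plan <- plans[[r]]
      plan@trainSegments <- plan@trainSegments[seq_len(sz)]
      m <- .run_one_rep(fs, plan, task, augment = TRUE, loss = "focal",
                        policy, config, positiveClass)
      data.frame(repetition = r, precision = m[["precision"]],
                 recall = m[["recall"]], f1 = m[["f1"]])
    })
    new("EvalResult", perRepetition = do.call(rbind, rows), task = task,
        arm = sprintf("E3[n=%d]", sz))
  })
  names(res) <- as.character(sizes)
  res
}

#' Write an EvalResult to disk
#'
#' @param res an [EvalResult-class].
#' @param dir output directory (created if needed); writes
#'   `<arm>_<task>_metrics.csv` (per repetition) and
#'   `<arm>_<task>_summary.json` (mean and sd of each metric).
#' @return the summary list, invisibly.
#' @export
writeEvalResult <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0(gsub("[^A-Za-z0-9]", "_", res@arm), "_", res@task))
  utils::write.csv(res@perRepetition, paste0(stem, "_metrics.csv"),
                   row.names = FALSE)
  s <- summary(res)
  out <- list(arm = res@arm, task = res@task,
              precision = list(mean = s["precision", "mean"], sd = s["precision", "sd"]),
              recall = list(mean = s["recall", "mean"], sd = s["recall", "sd"]),
              f1 = list(mean = s["f1", "mean"], sd = s["f1", "sd"]))
  jsonlite::write_json(out, paste0(stem, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
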