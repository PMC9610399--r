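#' Squeeze: global average pool per channel
#'
#' @param fmap numeric array `channels x height x width`.
#' @return numeric vector with one spatial mean per channel.
#' @export
seSqueeze <- function(fmap) {
  apply(fmap, 1L, mean)
}

#' Excite: map channel scalars to channel weights in (0, 1)
#'
#' `w = sigmoid(W2 %*% relu(W1 %*% z + b1) + b2)`; the bottleneck width is
#' `max(1, channels / reduction)`.
#'
#' @param z per-channel scalar vector from [seSqueeze()].
#' @param W1,b1 bottleneck affine map (`bneck x C`, `bneck`).
#' @param W2,b2 expansion affine map (`C x bneck`, `C`).
#' @return per-channel weight vector, each strictly in (0, 1).
#' @export
seExcite <- function(z, W1, b1, W2, b2) {
  h <- pmax(as.vector(W1 %*% z + b1), 0)
  1 / (1 + exp(-(as.vector(W2 %*% h + b2))))
}

#' Rescale: multiply each channel by its weight
#'
#' @param fmap numeric array `channels x height x width`.
#' @param w per-channel weights (length = channels).
#' @return the rescaled feature map.
#' @export
seRescale <- function(fmap, w) {
  if (length(w) != dim(fmap)[1])
    stop("need one weight per channel (", dim(fmap)[1], "), got ", length(w),
         call. = FALSE)
  fmap * array(w, dim(fmap))
}

#' Model configuration
#'
#' Two named presets: `"test"` (a compact net trained for 20 epochs, used
#' throughout the test harness) and `"full"` (a deeper stack trained at
#' the study-scale settings: batch size 32, learning rate 1e-3, 100 epochs).
#' Both take the fixed `173 x 64 x 1` MFCC input, downsample through
#' strided 3x3 convolutions with SE channel attention after every
#' non-stem stage, and end in global average pooling and a 2-way softmax.
#'
#' @param profile `"test"` or `"full"`; ignored fields below override it.
#' @param channels integer vector of per-stage channel widths.
#' @param epochs training epochs.
#' @param useSE include SE blocks (FALSE gives the plain-CNN ablation).
#' @param reduction SE bottleneck reduction ratio (default 16).
#' @param learningRate,batchSize optimizer settings.
#' @param nClasses number of output classes (2).
#' @param seed RNG seed for parameter initialization and batch shuffling.
#' @return a config list for [buildModel()].
#' @export
modelConfig <- function(profile = c("test", "full"), channels = NULL,
                        epochs = NULL, useSE = TRUE, reduction = 16,
                        learningRate = 1e-3, batchSize = 32, nClasses = 2,
                        seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(channels))
    channels <- if (profile == "test") c(4L, 8L, 16L) else c(8L, 16L, 32L, 64L)
  if (is.null(epochs)) epochs <- if (profile == "test") 20L else 100L
  L <- length(channels)
  list(profile = profile, input_h = 173L, input_w = 64L, kernel = 3L,
       n_classes = as.integer(nClasses), channels = as.integer(channels),
       stride_h = as.integer(c(3L, rep(2L, L - 1L))),
       stride_w = as.integer(rep(2L, L)),
       use_se = c(FALSE, rep(isTRUE(useSE), L - 1L)),
       reduction = as.integer(reduction), learning_rate = learningRate,
       batch_size = as.integer(batchSize), epochs = as.integer(epochs),
       seed = as.integer(seed))
}

#' Build an (untrained) SE-CNN classifier
#'
#' Parameters are He-initialized from `config$seed`, so the same seed gives
#' bit-identical initial parameters.
#'
#' @param config list from [modelConfig()].
#' @param classes the two class labels in logit order, e.g.
#'   `c("juvenile", "adult")`.
#' @return an [SENetModel-class].
#' @export
buildModel <- function(config, classes) {
  if (length(classes) != config$n_classes)
    stop("need ", config$n_classes, " class labels", call. = FALSE)
  set.seed(config$seed)
  k <- config$kernel
  ch <- config$channels
  params <- list()
  cin <- 1L
  for (l in seq_along(ch)) {
    fanin <- k * k * cin
    params[[paste0("conv", l, "_W")]] <-
      matrix(stats::rnorm(fanin * ch[l], sd = sqrt(2 / fanin)), fanin, ch[l])
    params[[paste0("conv", l, "_b")]] <- matrix(0, ch[l], 1)
    if (config$use_se[l]) {
      bn <- max(1L, ch[l] %/% config$reduction)
      params[[paste0("conv", l, "_se_W1")]] <-
        matrix(stats::rnorm(bn * ch[l], sd = sqrt(2 / ch[l])), bn, ch[l])
      params[[paste0("conv", l, "_se_b1")]] <- matrix(0, bn, 1)
      params[[paste0("conv", l, "_se_W2")]] <-
        matrix(stats::rnorm(ch[l] * bn, sd = sqrt(2 / bn)), ch[l], bn)
      params[[paste0("conv", l, "_se_b2")]] <- matrix(0, ch[l], 1)
    }
    cin <- ch[l]
  }
  cl <- ch[length(ch)]
  params$dense_W <- matrix(stats::rnorm(config$n_classes * cl, sd = sqrt(1 / cl)),
                           config$n_classes, cl)
  params$dense_b <- matrix(0, config$n_classes, 1)
  new("SENetModel", params = params, config = config,
      classes = as.character(classes),
      trainingLog = data.frame(epoch = integer(0), loss = numeric(0)))
}

#' Number of trainable parameters
#'
#' @param model an [SENetModel-class].
#' @return integer parameter count.
#' @export
countParams <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

.check_input <- function(X, config) {
  d <- dim(X)
  if (is.null(d) || length(d) != 3L || d[1] != config$input_h || d[2] != config$input_w)
    stop("features must form a ", config$input_h, " x ", config$input_w,
         " x N array", call. = FALSE)
  X
}

#' Train a classifier
#'
#' Mini-batch Adam with the configured batch size, learning rate and epoch
#' count; batches are reshuffled every epoch from `seed`, so the same seed
#' and data reproduce the training curve exactly. The loss is focal
#' (class-balanced alpha, gamma 2 by default) or plain cross entropy.
#'
#' @param model an [SENetModel-class] from [buildModel()].
#' @param X feature array `173 x 64 x N` from [mfccArray()].
#' @param labels character vector of length N with values in
#'   `model@classes`.
#' @param loss `"focal"` or `"cross_entropy"`.
#' @param alpha per-class weights (length 2); default: class-balanced for
#'   focal, `c(1, 1)` for cross entropy.
#' @param gamma focusing exponent for focal loss (default 2).
#' @param epochs override `config$epochs` (0 returns the model unchanged).
#' @param seed shuffling seed; defaults to `config$seed`.
#' @return the trained [SENetModel-class] with a filled `trainingLog`.
#' @export
trainModel <- function(model, X, labels, loss = c("focal", "cross_entropy"),
                       alpha = NULL, gamma = 2, epochs = NULL, seed = NULL) {
  loss <- match.arg(loss)
  cfg <- model@config
  .check_input(X, cfg)
  N <- dim(X)[3]
  if (N == 0L || length(labels) != N)
    stop("need one label per feature matrix", call. = FALSE)
  y <- match(labels, model@classes)
  if (anyNA(y))
    stop("labels outside model classes: ",
         paste(setdiff(labels, model@classes), collapse = ", "), call. = FALSE)
  if (is.null(epochs)) epochs <- cfg$epochs
  if (epochs == 0L) return(model)
  if (is.null(alpha))
    alpha <- if (loss == "focal") classBalancedAlpha(labels, model@classes) else c(1, 1)
  if (loss == "cross_entropy") gamma <- 0
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)
  perm <- vapply(seq_len(epochs), function(e) sample.int(N), integer(N))
  fit <- senet_train_cpp(X, y, model@params, cfg, as.numeric(alpha), gamma,
                         perm, cfg$learning_rate, cfg$batch_size)
  model@params <- fit$params
  model@trainingLog <- data.frame(epoch = seq_len(epochs), loss = fit$epoch_loss)
  model
}

#' Class probabilities for a feature batch
#'
#' @param model a trained [SENetModel-class].
#' @param X feature array `173 x 64 x N` (a single `173 x 64` matrix is
#'   promoted to a batch of one).
#' @return `N x 2` matrix of softmax probabilities, columns named by class.
#' @export
predictProb <- function(model, X) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  .check_input(X, model@config)
  p <- senet_forward_cpp(X, model@params, model@config)
  colnames(p) <- model@classes
  p
}

#' Hard class labels for a feature batch
#'
#' @param model a trained [SENetModel-class].
#' @param X feature array `173 x 64 x N`.
#' @return character vector of predicted labels (argmax of the softmax).
#' @export
predictClasses <- function(model, X) {
  p <- predictProb(model, X)
  model@classes[max.col(p, ties.method = "first")]
}

# Plain-R reference forward pass (single sample), used as the independent
# oracle for the compiled implementation in the test suite. Direct loops;
# intentionally naive.
.referenceForward <- function(x, params, config) {
  k <- config$kernel
  A <- array(x, c(config$input_h, config$input_w, 1L))
  pi <- 1L
  for (l in seq_along(config$channels)) {
    W <- params[[pi]]; b <- params[[pi + 1L]]; pi <- pi + 2L
    H <- dim(A)[1]; Wd <- dim(A)[2]; Cin <- dim(A)[3]
    sh <- config$stride_h[l]; sw <- config$stride_w[l]
    Ho <- (H + 2L - k) %/% sh + 1L
    Wo <- (Wd + 2L - k) %/% sw + 1L
    O <- array(0, c(Ho, Wo, config$channels[l]))
    for (co in seq_len(config$channels[l]))
      for (io in seq_len(Ho)) for (jo in seq_len(Wo)) {
        acc <- b[co, 1]
        for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) for (ci in seq_len(Cin)) {
          ii <- (io - 1L) * sh + di  # 0-based with pad 1: input index di-1
          jj <- (jo - 1L) * sw + dj
          if (ii >= 1L && ii <= H && jj >= 1L && jj <= Wd) {
            tap <- di + k * dj + k * k * (ci - 1L) + 1L
            acc <- acc + A[ii, jj, ci] * W[tap, co]
          }
        }
        O[io, jo, co] <- acc
      }
    O <- pmax(O, 0)
    if (config$use_se[l]) {
      fmap <- aperm(O, c(3, 1, 2))
      w <- seExcite(seSqueeze(fmap),
                    params[[pi]], params[[pi + 1L]],
                    params[[pi + 2L]], params[[pi + 3L]])
      pi <- pi + 4L
      O <- aperm(seRescale(fmap, w), c(2, 3, 1))
    }
    A <- O
  }
  g <- apply(A, 3L, mean)
  z <- as.vector(params[[pi]] %*% g + params[[pi + 1L]])
  exp(z - max(z)) / sum(exp(z - max(z)))
}
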