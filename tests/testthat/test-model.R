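test_that("squeeze is the per-channel spatial mean", {
  f <- array(3, c(2, 4, 5))
  expect_equal(seSqueeze(f), c(3, 3))
  f2 <- array(0, c(1, 2, 2)); f2[1, , ] <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(seSqueeze(f2), 2.5)
  set.seed(71)
  f3 <- array(rnorm(3 * 6 * 7), c(3, 6, 7))
  expect_equal(seSqueeze(2.5 * f3), 2.5 * seSqueeze(f3))
  # brute-force double-loop oracle
  bf <- numeric(3)
  for (c in 1:3) { s <- 0; for (i in 1:6) for (j in 1:7) s <- s + f3[c, i, j]
    bf[c] <- s / 42 }
  expect_equal(seSqueeze(f3), bf, tolerance = 1e-9)
})

test_that("excitation weights live strictly in (0,1) and pass through monotonically", {
  C <- 8; bn <- 2
  expect_equal(seExcite(rnorm(C), matrix(0, bn, C), rep(0, bn),
                        matrix(0, C, bn), rep(0, C)), rep(0.5, C))
  set.seed(72)
  for (i in 1:1000) {
    w <- seExcite(rnorm(C), matrix(rnorm(bn * C), bn), rnorm(bn),
                  matrix(rnorm(C * bn), C), rnorm(C))
    expect_true(all(w > 0 & w < 1))
  }
  # 1-channel positive pass-through: increasing z never decreases the weight
  z <- seq(-2, 2, by = 0.05)
  w <- vapply(z, function(v) seExcite(v, matrix(1, 1, 1), 0, matrix(1, 1, 1), 0),
              numeric(1))
  expect_true(all(diff(w) >= 0))
})

test_that("rescaling multiplies each channel exactly and unit weights are the identity", {
  set.seed(73)
  f <- array(rnorm(2 * 5 * 4), c(2, 5, 4))
  expect_identical(seRescale(f, c(1, 1)), f)
  expect_true(all(seRescale(f, c(0, 0)) == 0))
  out <- seRescale(f, c(0.5, 2))
  expect_equal(out[1, , ], 0.5 * f[1, , ])
  expect_equal(out[2, , ], 2 * f[2, , ])
  expect_error(seRescale(f, c(1, 2, 3)), "one weight per channel")
})

test_that("model construction is seeded and softmax outputs normalize", {
  cfg <- modelConfig("test", seed = 99)
  m1 <- buildModel(cfg, c("juvenile", "adult"))
  m2 <- buildModel(cfg, c("juvenile", "adult"))
  expect_identical(m1@params, m2@params)

  set.seed(74)
  X <- array(rnorm(173 * 64 * 4), c(173, 64, 4))
  p <- predictProb(m1, X)
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_equal(colnames(p), c("juvenile", "adult"))

  # ablation: dropping SE blocks removes exactly the SE parameter counts
  mNoSe <- buildModel(modelConfig("test", useSE = FALSE, seed = 99), c("a", "b"))
  seSizes <- sum(vapply(grep("_se_", names(m1@params)),
                        function(i) length(m1@params[[i]]), numeric(1)))
  expect_equal(countParams(m1) - countParams(mNoSe), seSizes)
  expect_gt(seSizes, 0)
})

test_that("the compiled forward pass matches the plain-R reference network", {
  set.seed(75)
  cfg <- modelConfig("test", channels = c(2L, 3L), seed = 42)
  m <- buildModel(cfg, c("a", "b"))
  X <- array(rnorm(173 * 64 * 3), c(173, 64, 3))
  p <- predictProb(m, X)
  for (i in 1:3) {
    ref <- bleatnet:::.referenceForward(X[, , i], m@params, cfg)
    expect_equal(unname(p[i, ]), ref, tolerance = 1e-12)
  }
})

test_that("compiled gradients match finite differences of the compiled loss", {
  set.seed(76)
  cfg <- modelConfig("test", channels = c(2L, 3L), seed = 5)
  m <- buildModel(cfg, c("a", "b"))
  X <- array(rnorm(173 * 64 * 4), c(173, 64, 4))
  y <- c(1L, 2L, 2L, 1L)
  al <- c(0.6, 1)
  g <- bleatnet:::senet_grad_cpp(X, y, m@params, cfg, al, 2)
  h <- 1e-5
  for (nm in names(m@params)) {
    k <- sample(length(m@params[[nm]]), 1)
    pp <- m@params
    pp[[nm]][k] <- pp[[nm]][k] + h
    lp <- bleatnet:::senet_grad_cpp(X, y, pp, cfg, al, 2)$loss
    pp[[nm]][k] <- pp[[nm]][k] - 2 * h
    lm_ <- bleatnet:::senet_grad_cpp(X, y, pp, cfg, al, 2)$loss
    expect_equal(g$grads[[nm]][k], (lp - lm_) / (2 * h), tolerance = 1e-4)
  }
})

test_that("training separates a separable toy problem and is deterministic", {
  set.seed(77)
  N <- 50
  X <- array(rnorm(173 * 64 * N), c(173, 64, N))
  y <- rep(c("lo", "hi"), length.out = N)
  X[, 1:8, y == "hi"] <- X[, 1:8, y == "hi"] + 3
  cfg <- modelConfig("test", epochs = 20L, seed = 3)
  m0 <- buildModel(cfg, c("lo", "hi"))
  m <- trainModel(m0, X, y, loss = "focal")
  expect_equal(mean(predictClasses(m, X) == y), 1)
  expect_lt(tail(m@trainingLog$loss, 1), m@trainingLog$loss[1])

  expect_identical(trainModel(m0, X, y, epochs = 0), m0)

  m2 <- trainModel(m0, X, y, loss = "focal")
  expect_identical(m@trainingLog, m2@trainingLog)
  expect_identical(m@params, m2@params)

  expect_error(trainModel(m0, X, c(y[-1], "mid")), "outside model classes")
})

test_that("prediction is batching-invariant and near-uniform at initialization", {
  cfg <- modelConfig("test", seed = 31)
  m <- buildModel(cfg, c("a", "b"))
  set.seed(78)
  X <- array(rnorm(173 * 64 * 100), c(173, 64, 100))
  pAll <- predictProb(m, X)
  p1 <- predictProb(m, X[, , 7])
  expect_equal(unname(p1[1, ]), unname(pAll[7, ]), tolerance = 1e-12)
  # symmetric-ish init: average probability near 0.5
  expect_lt(abs(mean(pAll[, 1]) - 0.5), 0.15)
  expect_error(predictProb(m, array(0, c(10, 64, 1))), "173")
})
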