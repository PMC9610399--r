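test_that("centered framing yields the documented frame counts", {
  expect_equal(nrow(frameSignal(numeric(88200) + 1, 1024, 512)), 173L)
  expect_equal(nrow(frameSignal(numeric(1024) + 1, 1024, 512)), 3L)
  x <- numeric(2048) + 1
  expect_equal(nrow(frameSignal(x, 1024, 1024)), 3L)  # hop = nFft
  expect_error(frameSignal(numeric(0), 1024, 512), "empty")
})

test_that("framing matches a brute-force start-position enumeration", {
  set.seed(41)
  for (i in 1:100) {
    L <- sample(600:40000, 1)
    hop <- sample(c(128, 256, 512), 1)
    x <- rnorm(L)
    fr <- frameSignal(x, 1024, hop)
    expect_equal(nrow(fr), 1 + L %/% hop)
    # explicit reflect-padded signal, enumerated starts
    pad <- 512
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(L - pad):(L - 1)]))
    t <- sample(seq_len(nrow(fr)), 1)
    expect_identical(fr[t, ], xp[((t - 1) * hop + 1):((t - 1) * hop + 1024)])
  }
})

test_that("Hamming window has the standard endpoints, midpoint and symmetry", {
  w <- hammingWindow(1024)
  expect_equal(w[1], 0.08)
  expect_equal(w, rev(w))
  w5 <- hammingWindow(5)
  expect_equal(w5[3], 1.0)
  expect_error(hammingWindow(1), ">= 2")
})

test_that("power spectrum localizes sinusoids and satisfies Parseval", {
  z <- matrix(0, 1, 1024)
  expect_equal(powerSpectrum(z), matrix(0, 1, 513))

  k <- 37
  x <- sin(2 * pi * k * (0:1023) / 1024)
  ps <- powerSpectrum(matrix(x, 1))
  expect_equal(which.max(ps[1, ]), k + 1L)

  set.seed(42)
  fr <- matrix(rnorm(2 * 1024), 2)
  ps <- powerSpectrum(fr)
  twoSided <- ps[, 1] + ps[, 513] + 2 * rowSums(ps[, 2:512])
  expect_equal(twoSided, 1024 * rowSums(fr^2), tolerance = 1e-6)
})

test_that("mel filterbank rows are unit-peak triangles covering the band", {
  fb <- melFilterbank(44100, 1024, 64)
  expect_equal(dim(fb), c(64L, 513L))
  expect_true(all(fb >= 0))
  centers <- attr(fb, "centers")
  # evaluated exactly at its own center, each filter equals 1
  atCenters <- melFilterbank(44100, 1024, 64, freqs = centers)
  expect_equal(diag(atCenters), rep(1, 64))
  # mel map closed form: mel(700 Hz) = 2595 log10(2)
  m <- bleatnet:::.hz_to_mel(700)
  expect_equal(m, 2595 * log10(2))
  # every interior FFT bin gets nonzero total weight
  freqs <- (0:512) * 44100 / 1024
  interior <- freqs > 0 & freqs < 22050
  expect_true(all(colSums(fb)[interior] > 0))
  # unimodal rows: once a row starts falling it never rises again
  for (i in c(1, 20, 64)) {
    d <- diff(fb[i, fb[i, ] > 0])
    if (length(d) > 1) expect_true(all(diff(sign(d)) <= 0))
  }
  expect_error(melFilterbank(44100, 1024, 64, fMin = 100, fMax = 50), "fMin")
})

test_that("log-mel energies clamp at the floor and respect log identities", {
  fb <- melFilterbank(44100, 1024, 64)
  zero <- logMel(matrix(0, 3, 513), fb, floor = 1e-10)
  expect_true(all(logmelValues(zero) == log(1e-10)))

  set.seed(43)
  pw <- matrix(abs(rnorm(2 * 513)) + 0.1, 2)
  a <- logmelValues(logMel(pw, fb))
  b <- logmelValues(logMel(2 * pw, fb))
  expect_equal(b - a, matrix(log(2), 2, 64))
  expect_true(all(is.finite(a)))
  expect_error(logMel(matrix(0, 2, 10), fb), "bins")
})

test_that("log-mel zero padding appends zero rows and nothing else", {
  fb <- melFilterbank(44100, 1024, 64)
  set.seed(44)
  sp <- logMel(matrix(abs(rnorm(100 * 513)), 100), fb)
  out <- padLogMel(sp, 173)
  expect_equal(dim(logmelValues(out)), c(173L, 64L))
  expect_identical(logmelValues(out)[1:100, ], logmelValues(sp))
  expect_true(all(logmelValues(out)[101:173, ] == 0))
  expect_equal(effectiveFrames(out), 100L)
  full <- padLogMel(sp, 100)
  expect_identical(logmelValues(full), logmelValues(sp))
  expect_error(padLogMel(out, 100), "more than")
})

test_that("the DCT is orthonormal and the MFCC of a 2-s segment is 173 x 64", {
  C <- dctMatrix(64)
  expect_equal(C %*% t(C), diag(64), tolerance = 1e-12)

  seg <- new("CallSegment", samples = sin(2 * pi * 400 * (0:88199) / 44100),
             individualId = "i", ageGroup = "adult", sex = "female",
             sourceClip = "c", segmentIndex = 0L, needsPadding = FALSE)
  sp <- segmentLogMel(seg)
  M <- mfcc(sp)
  expect_equal(dim(M), c(173L, 64L))
  # full-coefficient DCT is invertible: recover the log-mel exactly
  expect_equal(M %*% dctMatrix(64), logmelValues(sp), tolerance = 1e-9)

  # constant log-mel frame c -> first coefficient c*sqrt(64), rest 0
  cst <- new("LogMelSpectrum", values = matrix(3.5, 2, 64),
             effectiveFrames = 2L, params = list())
  Mc <- mfcc(cst)
  expect_equal(Mc[, 1], rep(3.5 * sqrt(64), 2))
  expect_equal(max(abs(Mc[, -1])), 0, tolerance = 1e-12)
  expect_error(mfcc(sp, nCoeffs = 65), "exceeds")
})

test_that("every segment length up to 2 s maps to a 173 x 64 feature matrix", {
  set.seed(45)
  for (dur in c(0.21, runif(6, 0.2, 2), 2)) {
    n <- round(dur * 44100)
    seg <- new("CallSegment", samples = rnorm(n), individualId = "i",
               ageGroup = "juvenile", sex = "male", sourceClip = "c",
               segmentIndex = 0L, needsPadding = n < 88200)
    expect_equal(dim(mfcc(segmentLogMel(seg))), c(173L, 64L))
  }
})

test_that("filterbank application treats frames independently", {
  fb <- melFilterbank(44100, 1024, 64)
  set.seed(46)
  pw <- matrix(abs(rnorm(5 * 513)), 5)
  whole <- logmelValues(logMel(pw, fb))
  perm <- c(3, 1, 5, 2, 4)
  shuffled <- logmelValues(logMel(pw[perm, ], fb))
  expect_identical(shuffled, whole[perm, ])
})
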