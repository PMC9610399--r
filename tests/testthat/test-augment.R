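mkspec <- function(nFrames = 173, ef = 120, nMels = 64, seed = 1) {
  set.seed(seed)
  v <- matrix(0, nFrames, nMels)
  v[seq_len(ef), ] <- rnorm(ef * nMels)
  new("LogMelSpectrum", values = v, effectiveFrames = as.integer(ef),
      params = list())
}

test_that("Gaussian noise has the requested moments and spares padded rows", {
  sp <- mkspec()
  expect_identical(addGaussianNoise(sp, 0), sp)

  big <- mkspec(nFrames = 1600, ef = 1600, nMels = 64, seed = 2)  # ~1e5 entries
  set.seed(51)
  out <- addGaussianNoise(big, 0.5)
  d <- logmelValues(out) - logmelValues(big)
  expect_equal(mean(d), 0, tolerance = 0.01)
  expect_equal(sd(d), 0.5, tolerance = 0.01)

  set.seed(52)
  padded <- addGaussianNoise(sp, 1)
  expect_true(all(logmelValues(padded)[121:173, ] == 0))

  set.seed(53); a <- addGaussianNoise(sp, 0.3)
  set.seed(53); b <- addGaussianNoise(sp, 0.3)
  expect_identical(logmelValues(a), logmelValues(b))
})

test_that("frequency and time masks zero exactly the drawn bands", {
  sp <- mkspec()
  set.seed(54)
  same <- freqMask(sp, nMasks = 2, maxWidth = 0)
  expect_equal(logmelValues(same), logmelValues(sp), ignore_attr = TRUE)

  for (i in 1:100) {
    out <- freqMask(sp, nMasks = 2, maxWidth = 8)
    masks <- attr(logmelValues(out), "masks")
    zeroed <- integer(0)
    for (j in seq_len(nrow(masks)))
      if (masks[j, "width"] > 0)
        zeroed <- union(zeroed, (masks[j, "start"] + 1):(masks[j, "start"] + masks[j, "width"]))
    if (length(zeroed) > 0)
      expect_true(all(logmelValues(out)[, zeroed] == 0))
    untouched <- setdiff(seq_len(64), zeroed)
    expect_identical(logmelValues(out)[, untouched],
                     logmelValues(sp)[, untouched])
  }

  for (i in 1:100) {
    out <- timeMask(sp, nMasks = 1, maxWidth = 20)
    masks <- attr(logmelValues(out), "masks")
    w <- masks[1, "width"]; f0 <- masks[1, "start"]
    # masks live strictly inside the real frames
    expect_lte(f0 + w, sp@effectiveFrames)
    if (w > 0) expect_true(all(logmelValues(out)[(f0 + 1):(f0 + w), ] == 0))
    untouched <- setdiff(seq_len(173), if (w > 0) (f0 + 1):(f0 + w) else integer(0))
    expect_identical(logmelValues(out)[untouched, ],
                     logmelValues(sp)[untouched, ])
  }

  expect_error(freqMask(sp, 1, 65), "mel axis")
})

test_that("a full-axis frequency mask blanks the whole spectrum", {
  sp <- mkspec()
  # width drawn as Uniform{0..64}; find a draw of 64 and check the contract
  set.seed(55)
  repeat {
    out <- freqMask(sp, nMasks = 1, maxWidth = 64)
    if (attr(logmelValues(out), "masks")[1, "width"] == 64L) break
  }
  expect_true(all(logmelValues(out) == 0))
})

test_that("per-class replication produces the advertised counts and keeps labels", {
  # 10 male + 70 female segments; male replicated 6x meets the female count
  fs <- toyFeatureSet(c(10, 70), c("m1", "f1"), c("adult", "adult"),
                      c("male", "female"))
  pol <- augmentationPolicy()
  set.seed(56)
  out <- balanceDataset(fs, pol, task = "sex")
  expect_equal(sum(manifest(out)$sex == "male"), 70L)
  expect_equal(sum(manifest(out)$sex == "female"), 70L)
  # augmented copies keep their parent's individual ID
  expect_true(all(manifest(out)$individual_id[manifest(out)$sex == "male"] == "m1"))

  # r == 0 for every class: unchanged
  pol0 <- augmentationPolicy(replication = c(male = 0, female = 0,
                                             juvenile = 0, adult = 0))
  same <- balanceDataset(fs, pol0, task = "sex")
  expect_equal(nrow(manifest(same)), 80L)

  # juveniles doubled -> 3x originals; adults once -> 2x
  fs2 <- toyFeatureSet(c(12, 20), c("j1", "a1"), c("juvenile", "adult"),
                       c("female", "female"))
  set.seed(57)
  out2 <- balanceDataset(fs2, augmentationPolicy(), task = "age")
  expect_equal(sum(manifest(out2)$age_group == "juvenile"), 36L)
  expect_equal(sum(manifest(out2)$age_group == "adult"), 40L)

  bad <- fs
  bad@manifest$sex[1] <- "unknown"
  expect_error(suppressWarnings(balanceDataset(bad, pol, task = "sex")),
               "replication factor")
})

test_that("augmented variants never disturb the padded region", {
  fs <- toyFeatureSet(c(4), "i1", "juvenile", "male", seed = 3)
  set.seed(58)
  out <- balanceDataset(fs, augmentationPolicy(), task = "age")
  man <- manifest(out)
  for (k in which(man$augmented)) {
    ef <- man$effective_frames[k]
    if (ef < 173)
      expect_true(all(logmelValues(out@logmel[[k]])[(ef + 1):173, ] == 0))
  }
})
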