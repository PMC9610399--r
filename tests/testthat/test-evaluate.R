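test_that("confusion counts tally the 2x2 table", {
  cc <- confusionCounts(c("+", "+", "+", "-"), c("+", "-", "+", "-"), "+")
  expect_equal(cc, c(tp = 2L, fp = 1L, fn = 0L, tn = 1L))
  allpos <- confusionCounts(rep("+", 5), rep("+", 5), "+")
  expect_equal(allpos[["fp"]], 0L)
  expect_equal(allpos[["fn"]], 0L)
  # swapping the positive class swaps (tp,tn) and (fp,fn)
  sw <- confusionCounts(c("+", "+", "+", "-"), c("+", "-", "+", "-"), "-")
  expect_equal(sw[["tp"]], cc[["tn"]])
  expect_equal(sw[["fp"]], cc[["fn"]])
  expect_error(confusionCounts("+", c("+", "-"), "+"), "length")
})

test_that("precision, recall and F1 follow their formulas with the 0/0 -> 0 convention", {
  cc <- c(tp = 9, fp = 1, fn = 3, tn = 0)
  expect_equal(precisionScore(cc), 0.9)
  expect_equal(recallScore(cc), 0.75)
  expect_equal(f1Score(cc), 2 * 0.9 * 0.75 / 1.65)
  perfect <- c(tp = 5, fp = 0, fn = 0, tn = 5)
  expect_equal(f1Score(perfect), 1)
  none <- c(tp = 0, fp = 2, fn = 3, tn = 5)
  expect_equal(f1Score(none), 0)
  expect_equal(precisionScore(c(tp = 0, fp = 0, fn = 1, tn = 0)), 0)
})

test_that("metrics agree with a brute-force element-loop tally on random labels", {
  set.seed(81)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    pred <- sample(c("a", "b"), n, replace = TRUE)
    true <- sample(c("a", "b"), n, replace = TRUE)
    cc <- confusionCounts(pred, true, "a")
    tp <- fp <- fn <- 0
    for (k in seq_len(n)) {
      if (pred[k] == "a" && true[k] == "a") tp <- tp + 1
      if (pred[k] == "a" && true[k] != "a") fp <- fp + 1
      if (pred[k] != "a" && true[k] == "a") fn <- fn + 1
    }
    P <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R <- if (tp + fn == 0) 0 else tp / (tp + fn)
    F <- if (P + R == 0) 0 else 2 * P * R / (P + R)
    expect_identical(precisionScore(cc), P)
    expect_identical(recallScore(cc), R)
    expect_identical(f1Score(cc), F)
  }
})

mkman <- function(nInd = 12, segsPerInd = 80) {
  data.frame(
    segment_id = sprintf("s%04d", seq_len(nInd * segsPerInd)),
    individual_id = rep(sprintf("i%02d", seq_len(nInd)), each = segsPerInd),
    age_group = rep(rep(c("juvenile", "adult"), length.out = nInd), each = segsPerInd),
    sex = rep(rep(c("female", "male"), length.out = nInd), each = segsPerInd),
    stringsAsFactors = FALSE)
}

test_that("individual-exclusive plans never share individuals and hit the fixed sizes", {
  man <- mkman()
  plans <- makeSplits(man, mutuallyExclusive = TRUE, nReps = 10, seed = 5)
  expect_length(plans, 10L)
  for (p in plans) {
    expect_length(intersect(p@testIndividuals, p@trainIndividuals), 0L)
    expect_length(p@testSegments, 100L)
    expect_length(p@trainSegments, 540L)
    expect_false(any(man$individual_id[p@trainSegments] %in% p@testIndividuals))
    expect_length(p@testIndividuals, 4L)
  }
})

test_that("small test pools are copied round-robin up to 100", {
  man <- mkman(nInd = 12, segsPerInd = 15)   # 4 test individuals hold 60 segs
  # train pool 8*15=120 < 540 -> size down for this check
  plans <- makeSplits(man, TRUE, nReps = 5, nTrain = 100, seed = 2)
  for (p in plans) {
    tab <- table(p@testSegments)
    expect_length(p@testSegments, 100L)
    expect_true(all(tab %in% c(ceiling(100 / 60), floor(100 / 60))))
  }
})

test_that("pooled (non-exclusive) plans split 540/100 without the individual constraint", {
  man <- mkman()
  plans <- makeSplits(man, mutuallyExclusive = FALSE, nReps = 3, seed = 9)
  for (p in plans) {
    expect_length(p@trainSegments, 540L)
    expect_length(p@testSegments, 100L)
    expect_length(intersect(p@trainSegments, p@testSegments), 0L)
  }
})

test_that("an undersized train pool raises an error naming the shortfall", {
  man <- mkman(nInd = 6, segsPerInd = 20)
  expect_error(makeSplits(man, TRUE, nReps = 1, seed = 1), "short by")
  expect_error(makeSplits(man[man$individual_id %in% c("i01", "i02"), ],
                          TRUE, nReps = 1, seed = 1), "individuals")
})

test_that("split construction is reproducible from its seed", {
  man <- mkman()
  a <- makeSplits(man, TRUE, nReps = 4, seed = 77)
  b <- makeSplits(man, TRUE, nReps = 4, seed = 77)
  for (r in 1:4) {
    expect_identical(a[[r]]@testSegments, b[[r]]@testSegments)
    expect_identical(a[[r]]@trainSegments, b[[r]]@trainSegments)
  }
})
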