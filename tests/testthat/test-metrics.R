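test_that("confusion counts agree with a brute-force per-pixel tally", {
  set.seed(21)
  # the 4x4 reference case: truth has 6 foreground, prediction covers 4 of
  # them plus 2 background pixels
  truth <- matrix(0, 4, 4); truth[c(1, 2, 3, 5, 6, 7)] <- 1
  pred <- matrix(0, 4, 4); pred[c(1, 2, 3, 5, 9, 10)] <- 1
  cc <- confusionCounts(pred, truth)
  expect_identical(c(cc@tp, cc@fn, cc@fp, cc@tn), c(4L, 2L, 2L, 8L))
  expect_identical(bruteConfusion(pred, truth),
                   c(tp = 4, fp = 2, tn = 8, fn = 2))
  # identity and complement cases
  m <- matrix(rbinom(100, 1, 0.3), 10, 10)
  ci <- confusionCounts(m, m)
  expect_identical(ci@fp + ci@fn, 0L)
  expect_identical(ci@tp, sum(m == 1))
  ccp <- confusionCounts(1 - m, m)
  expect_identical(ccp@tp + ccp@tn, 0L)
  # random masks match the brute-force oracle
  for (i in 1:5) {
    a <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    cc <- confusionCounts(a, b)
    expect_equal(c(tp = cc@tp, fp = cc@fp, tn = cc@tn, fn = cc@fn),
                 bruteConfusion(a, b))
  }
  expect_error(confusionCounts(matrix(0.5, 2, 2), matrix(1, 2, 2)),
               class = "eunetArgumentError")
})

test_that("metric formulas match hand arithmetic", {
  r <- metricReport(new("ConfusionCounts", tp = 4, fn = 2, fp = 2, tn = 8))
  expect_equal(r@accuracy, 75)
  expect_equal(r@precision, 400 / 6)
  expect_equal(r@specificity, 80)
  expect_equal(r@miou, 100 * (4 / 8 + 8 / 12) / 2)
  perfect <- metricReport(new("ConfusionCounts", tp = 30, tn = 70,
                              fp = 0, fn = 0))
  expect_equal(c(perfect@accuracy, perfect@precision, perfect@specificity,
                 perfect@miou), rep(100, 4))
  expect_length(perfect@undefined, 0L)
})

test_that("zero denominators produce explicit undefined markers", {
  r <- metricReport(new("ConfusionCounts", tp = 0, fp = 0, tn = 9, fn = 1))
  expect_true(is.na(r@precision))
  expect_identical(r@undefined, "precision")
  expect_equal(r@accuracy, 90)
  expect_equal(r@specificity, 100)
  expect_error(metricReport(new("ConfusionCounts", tp = 0, fp = 0,
                                tn = 0, fn = 0)),
               class = "eunetArgumentError")
})

test_that("foreground/background relabeling preserves accuracy and mIoU only", {
  a <- matrix(rbinom(144, 1, 0.35), 12, 12)
  b <- matrix(rbinom(144, 1, 0.4), 12, 12)
  r <- metricReport(confusionCounts(a, b))
  rFlip <- metricReport(confusionCounts(1 - a, 1 - b))
  expect_equal(rFlip@accuracy, r@accuracy)
  expect_equal(rFlip@miou, r@miou)
  # precision and specificity take the complementary-class roles
  cc <- confusionCounts(a, b)
  expect_equal(rFlip@precision, 100 * cc@tn / (cc@tn + cc@fn))
  expect_equal(rFlip@specificity, 100 * cc@tp / (cc@tp + cc@fn))
})

test_that("micro-averaged evaluation pools pixel counts", {
  ph <- generatePhantoms("cell", count = 3, size = 32, seed = 13)
  oracle <- function(im) ph[[which(vapply(ph, function(p)
    identical(p$image, im), logical(1)))]]$mask
  # a perfect oracle scores 100 on every metric
  rp <- evaluateDataset(oracle, ph)
  expect_equal(c(rp@accuracy, rp@precision, rp@specificity, rp@miou),
               rep(100, 4))
  # a fixed imperfect predictor: pooled counts equal summed per-image counts
  noisy <- function(im) {
    mk <- oracle(im)
    mk[1:8, 1:8] <- 1 - mk[1:8, 1:8]
    0.25 + 0.5 * mk
  }
  rep1 <- evaluateDataset(noisy, ph)
  counts <- Reduce(`+`, lapply(ph, function(p)
    confusionCounts(1 * (noisy(p$image) > 0.5), p$mask)))
  expect_equal(reportRow(rep1), reportRow(metricReport(counts)))
  # duplication invariance of the pooled report
  rep2 <- evaluateDataset(noisy, c(ph, ph))
  expect_equal(reportRow(rep2), reportRow(rep1))
  # macro mode averages per-image metrics instead
  repM <- evaluateDataset(noisy, ph, average = "macro")
  perImage <- vapply(ph, function(p)
    metricReport(confusionCounts(1 * (noisy(p$image) > 0.5), p$mask))@accuracy,
    numeric(1))
  expect_equal(repM@accuracy, mean(perImage))
  expect_error(evaluateDataset(noisy, list()), class = "eunetArgumentError")
})

test_that("adding a correctly predicted pixel never decreases accuracy", {
  set.seed(5)
  cc <- confusionCounts(matrix(rbinom(64, 1, 0.5), 8),
                        matrix(rbinom(64, 1, 0.5), 8))
  acc0 <- metricReport(cc)@accuracy
  ccPlus <- cc + new("ConfusionCounts", tp = 1, fp = 0, tn = 0, fn = 0)
  expect_gte(metricReport(ccPlus)@accuracy, acc0)
})
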