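publishedCm <- function() {
  readConfusionCsv(system.file("extdata", "ds2_confusion_published.csv",
                               package = "BeatEnsemble", mustWork = TRUE))
}

test_that("the shipped published confusion matrix is internally consistent", {
  cm <- publishedCm()
  expect_equal(rownames(cm), aamiClasses())
  expect_equal(colnames(cm), c("N", "S", "V"))
  expect_equal(sum(cm), 49711L)
  expect_equal(unname(rowSums(cm)), c(44258L, 1837L, 3221L, 388L, 7L))
})

test_that("sensitivity and PP reproduce the published DS2 metrics", {
  cm <- publishedCm()
  expect_equal(sensitivity(cm, "V"), 100 * 3025 / 3221)
  expect_equal(positivePredictiveValue(cm, "V"), 100 * 3025 / 3329)
  expect_equal(sensitivity(cm, "S"), 100 * 1673 / 1837)
  expect_equal(positivePredictiveValue(cm, "S"), 100 * 1673 / 3964)
  expect_equal(accuracy(cm), 100 * (41931 + 1673 + 3025) / 49711)
})

test_that("undefined metrics propagate as NA, not 0 or NaN", {
  cm <- confusionCounts(c("N", "N", "V"), c("N", "N", "V"))
  expect_true(is.na(sensitivity(cm, "S")))       # empty reference row
  expect_true(is.na(positivePredictiveValue(cm, "S")))  # empty column
  expect_true(is.na(computeAve(confusionCounts(c("N", "N"), c("N", "N")))))
  expect_error(sensitivity(cm, "X"), "unknown")
})

test_that("accuracy extremes behave", {
  ident <- confusionCounts(rep(aamiClasses()[1:3], 4L),
                           rep(aamiClasses()[1:3], 4L))
  expect_equal(accuracy(ident), 100)
  wrong <- confusionCounts(rep("N", 5), rep("S", 5))
  expect_equal(accuracy(wrong), 0)
  # reference F/Q count in the denominator and can never be correct
  mixed <- confusionCounts(c("N", "F", "Q"), c("N", "N", "N"))
  expect_equal(accuracy(mixed), 100 / 3)
})

test_that("per-recording reports pool correctly and mark undefined cells", {
  ref  <- c("N", "S", "V", "N", "N", "F", "N", "V")
  pred <- c("N", "S", "V", "N", "S", "N", "N", "V")
  recs <- c("r1", "r1", "r1", "r1", "r2", "r2", "r2", "r2")
  rep_ <- perRecordingReport(ref, pred, recs)
  expect_equal(nrow(rep_), 3L)                 # r1, r2, Total
  tot <- rep_[rep_$record == "Total", ]
  cm <- confusionCounts(ref, pred)
  expect_equal(tot$se_V, sensitivity(cm, "V"))
  expect_equal(tot$acc, accuracy(cm))
  # r2 has no reference S: Se_S undefined; PP_S defined (one false S)
  r2 <- rep_[rep_$record == "r2", ]
  expect_true(is.na(r2$se_S))
  expect_equal(r2$pp_S, 0)
  fmt <- formatReport(rep_)
  expect_equal(fmt$se_S[fmt$record == "r2"], "-")
  # every printed percentage agrees with its own matrix within 0.05
  expect_equal(as.numeric(fmt$acc[fmt$record == "Total"]),
               accuracy(cm), tolerance = 0.05)
})

test_that("stage-2 input count arithmetic", {
  expect_equal(stage2InputCount(49711, 3329), 46382)
  expect_equal(stage2InputCount(100, 0), 100)
  expect_equal(stage2InputCount(10, 10), 0)
  expect_error(stage2InputCount(5, 6), "more V-labeled")
})

test_that("pooled metrics equal metrics of summed per-recording matrices", {
  set.seed(77)
  ref  <- sample(aamiClasses(), 200, replace = TRUE, prob = c(.8, .08, .08, .03, .01))
  pred <- sample(c("N", "S", "V"), 200, replace = TRUE, prob = c(.85, .08, .07))
  recs <- sample(c("a", "b", "c"), 200, replace = TRUE)
  total <- Reduce(`+`, lapply(c("a", "b", "c"), function(r)
    confusionCounts(ref[recs == r], pred[recs == r])))
  expect_identical(total, confusionCounts(ref, pred))
})
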