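test_that("segmentBeat window arithmetic and boundary handling", {
  ramp <- 0:999
  w <- segmentBeat(ramp, 501L)           # R at value 500
  expect_length(w, 200L)
  expect_equal(w, 401:600 - 1)           # 100 before R .. 99 after
  expect_equal(w[101L], 500)             # R sample itself at position 101

  expect_error(segmentBeat(ramp, 50L), "beyond the signal")
  expect_error(segmentBeat(ramp, 950L), "beyond the signal")
  expect_error(segmentBeat(ramp, 901L), NA)  # exactly fits: 801..1000
})

test_that("normalizeBeat centers and scales with the population sd", {
  z <- normalizeBeat(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2))  # population-sd closed form

  x <- rnorm(50, mean = 3, sd = 7)
  expect_equal(normalizeBeat(normalizeBeat(x)), normalizeBeat(x),
               tolerance = 1e-12)              # idempotence
  expect_error(normalizeBeat(c(5, 5, 5)), "zero variance")
  expect_error(normalizeBeat(3), "at least 2")
})

test_that("symbol mapping is total on beats and rejects non-beat codes", {
  got <- mapSymbolToAami(c("V", "A", "N", "L", "E", "F", "/", "zz"))
  expect_equal(as.character(got), c("V", "S", "N", "N", "V", "F", "Q", "Q"))
  expect_s3_class(got, "factor")
  expect_equal(levels(got), c("N", "S", "V", "F", "Q"))
  expect_error(mapSymbolToAami("+"), "non-beat")
  expect_false(any(isBeatSymbol(c("+", "~", "|", "x"))))
  expect_true(all(isBeatSymbol(c("N", "V", "A"))))
})

test_that("RR features: intervals, ratios and scale invariance", {
  rrf <- computeRRFeatures(c(0, 1, 2, 3))
  expect_equal(rrf$rr_prev_s[-1L], c(1, 1, 1))
  expect_equal(rrf$rr_ratio[-1L], c(1, 1, 1))

  rrf <- computeRRFeatures(c(0, 1, 1.5, 2.5))
  expect_equal(rrf$rr_prev_s[-1L], c(1, 0.5, 1))
  expect_equal(rrf$rr_ratio[-1L], c(1.2, 0.6, 1.2))
  expect_true(is.na(rrf$rr_prev_s[1L]))

  t <- cumsum(runif(20, 0.5, 1.2))
  expect_equal(computeRRFeatures(t * 3)$rr_ratio,
               computeRRFeatures(t)$rr_ratio, tolerance = 1e-12)

  expect_error(computeRRFeatures(5), "at least 2")
  expect_error(computeRRFeatures(c(1, 1)), "strictly increasing")
})

test_that("extractBeats keeps 200-sample z-normalized windows and accounts for drops", {
  rec <- simulateRecording(nBeats = 60, seed = 3, recordId = "X1")
  bs <- extractBeats(rec)
  expect_s4_class(bs, "BeatSet")
  A <- beatMatrix(bs, "A")
  expect_equal(ncol(A), 200L)
  expect_equal(rowMeans(A), rep(0, nrow(A)), tolerance = 1e-9)
  expect_equal(sqrt(rowMeans(A^2)), rep(1, nrow(A)), tolerance = 1e-9)

  dc <- dropCounts(bs)
  expect_identical(dc[["annotations"]],
                   dc[["non_beat"]] + dc[["first_beat"]] + dc[["boundary"]] +
                   dc[["flat"]] + dc[["retained"]])
  expect_identical(dc[["retained"]], nBeats(bs))
  expect_identical(dc[["non_beat"]], 1L)   # the generator's "+" marker
  expect_identical(dc[["first_beat"]], 1L) # no preceding RR
  expect_true(all(beatInfo(bs)$rr_prev_s > 0))
  expect_true(all(beatInfo(bs)$rr_ratio > 0))
})

test_that("edge beats whose window exits the signal are dropped and counted", {
  rec <- makeRampRecording(rSamples = c(50L, 300L, 600L, 950L),
                           symbols = c("N", "N", "V", "N"))
  bs <- extractBeats(rec)
  dc <- dropCounts(bs)
  # beat 1 is the first beat; beat 4's window needs sample 1049
  expect_identical(dc[["boundary"]], 1L)
  expect_identical(nBeats(bs), 2L)
  expect_equal(beatInfo(bs)$r_sample, c(300L, 600L))
})

test_that("combineBeatSets concatenates aligned sets", {
  r1 <- extractBeats(simulateRecording(nBeats = 20, seed = 1, recordId = "A1"))
  r2 <- extractBeats(simulateRecording(nBeats = 25, seed = 2, recordId = "A2"))
  both <- combineBeatSets(r1, r2)
  expect_equal(nBeats(both), nBeats(r1) + nBeats(r2))
  expect_equal(unique(beatInfo(both)$record_id), c("A1", "A2"))
  expect_equal(dropCounts(both), dropCounts(r1) + dropCounts(r2))
})
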