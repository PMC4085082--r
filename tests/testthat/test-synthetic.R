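test_that("simulation is deterministic in the seed", {
  r1 <- simulateRecording(nBeats = 40, seed = 123)
  r2 <- simulateRecording(nBeats = 40, seed = 123)
  expect_identical(signalMatrix(r1), signalMatrix(r2))
  expect_identical(annotations(r1), annotations(r2))
  r3 <- simulateRecording(nBeats = 40, seed = 124)
  expect_false(identical(signalMatrix(r1), signalMatrix(r3)))
})

test_that("annotations align with rendered QRS centers", {
  rec <- simulateRecording(nBeats = 50, seed = 31, noiseSd = 0)
  ann <- annotations(rec)
  beats <- ann[isBeatSymbol(ann$symbol), ]
  sig <- signalMatrix(rec)[, "A"]
  # the QRS bump is centered on the annotated R sample: the signal there
  # must be near the (possibly jittered) QRS amplitude for non-F beats
  nonF <- beats$symbol != "F"
  expect_true(all(sig[beats$sample[nonF]] > 0.5))
  # and the local maximum lies within one sample of the fiducial
  for (s in beats$sample[nonF][1:10]) {
    win <- sig[(s - 5):(s + 5)]
    expect_lte(abs(which.max(win) - 6L), 1L)
  }
})

test_that("an all-N recording has RR ratios concentrated at 1", {
  rhythm <- defaultRhythm()
  rhythm$class_mix <- c(N = 1, S = 0, V = 0, F = 0)
  rec <- simulateRecording(nBeats = 400, rhythm = rhythm, seed = 41)
  bs <- extractBeats(rec)
  expect_true(all(beatInfo(bs)$aami_class == "N"))
  expect_equal(mean(beatInfo(bs)$rr_ratio), 1, tolerance = 0.01)
})

test_that("SVEB RR ratios fall below 0.8 for the vast majority of S beats", {
  rhythm <- defaultRhythm()
  rhythm$class_mix <- c(N = 0.7, S = 0.3, V = 0, F = 0)  # enough S to count
  rec <- simulateRecording(nBeats = 1000, rhythm = rhythm, seed = 43)
  info <- beatInfo(extractBeats(rec))
  sRatios <- info$rr_ratio[info$aami_class == "S"]
  expect_gt(length(sRatios), 200)
  expect_gte(mean(sRatios < 0.8), 0.9)
})

test_that("class prevalences converge to the configured mix", {
  rec <- simulateRecording(nBeats = 2000, seed = 47)
  info <- beatInfo(extractBeats(rec))
  mix <- defaultRhythm()$class_mix
  for (cls in names(mix)) {
    p <- mean(info$aami_class == cls)
    # binomial tolerance: 4 standard errors around the target share
    expect_lt(abs(p - mix[[cls]]),
              4 * sqrt(mix[[cls]] * (1 - mix[[cls]]) / 2000) + 2e-3)
  }
})

test_that("template invariants hold: wide V QRS, no V P wave, shared S morphology", {
  tmpl <- defaultTemplates()
  expect_gte(tmpl$V$qrs_width_s, 2 * tmpl$N$qrs_width_s)
  expect_identical(tmpl$V$p_amp, 0)
  expect_identical(tmpl$S, tmpl$N)
  expect_null(tmpl$F)   # fusion rendered as an N/V mixture
})

test_that("datasets have disjoint train/test ids and per-recording variation", {
  ds <- simulateDataset(nRecordings = 6, nBeats = 30, seed = 53)
  ids1 <- names(ds$ds1); ids2 <- names(ds$ds2)
  expect_length(ids1, 3L)
  expect_length(ids2, 3L)
  expect_length(intersect(ids1, ids2), 0L)

  # degenerate variation: identical hyper-draws still yield valid output
  ds0 <- simulateDataset(nRecordings = 2, nBeats = 20, seed = 54,
                         variation = list(base_rr_range = c(0.8, 0.8),
                                          qrs_width_sd = 0,
                                          amp_range = c(1, 1),
                                          lead_b_range = c(0.7, 0.7)))
  expect_length(ds0$ds1, 1L)
  expect_error(simulateDataset(nRecordings = 1), "at least 2")
  badMix <- defaultRhythm(); badMix$class_mix <- c(N = 0.5, S = 0.1, V = 0, F = 0)
  expect_error(simulateRecording(rhythm = badMix, seed = 1), "summing to 1")
})

test_that("written fixtures survive the reader and the preprocessing chain", {
  ds <- simulateDataset(nRecordings = 2, nBeats = 40, seed = 59)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  back <- readDataset(dir, expectedRate = 360)
  orig <- c(ds$ds1, ds$ds2)
  for (id in names(orig)) {
    expect_identical(annotations(back[[id]]), annotations(orig[[id]]))
    bsO <- extractBeats(orig[[id]])
    bsB <- extractBeats(back[[id]])
    expect_equal(beatInfo(bsB), beatInfo(bsO))
    expect_equal(beatMatrix(bsB), beatMatrix(bsO), tolerance = 1e-3)
  }
})
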