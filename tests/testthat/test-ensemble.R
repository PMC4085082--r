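test_that("members fit separable clusters perfectly and votes are conserved", {
  fix <- makeSeparableGroups(n = 40, M = 3)
  model <- trainEnsemble(fix$groups, fix$labels, C = 1, delta = 0.5)
  votes <- predictVotes(model, fix$groups)
  expect_true(all(rowSums(votes$counts) == 3L))       # vote conservation
  expect_equal(as.character(votes$winner), as.character(fix$labels))
  expect_false(any(votes$tie))
})

test_that("an M=1 ensemble equals its single member and refits are deterministic", {
  fix <- makeSeparableGroups(n = 30, M = 1, gap = 4)
  m1 <- trainEnsemble(fix$groups, fix$labels, C = 1, delta = 1.3)
  single <- predict(m1@members[[1L]], fix$groups[[1L]])
  votes <- predictVotes(m1, fix$groups)
  expect_equal(as.character(votes$winner), as.character(single))

  m2 <- trainEnsemble(fix$groups, fix$labels, C = 1, delta = 1.3)
  expect_equal(predictVotes(m2, fix$groups)$winner, votes$winner)
})

test_that("degenerate inputs are rejected", {
  fix <- makeSeparableGroups(n = 20, M = 2)
  oneClass <- factor(rep("N", 20), levels = aamiClasses())
  expect_error(trainEnsemble(fix$groups, oneClass), "two classes")
  expect_error(trainEnsemble(fix$groups, fix$labels, C = -1), "positive")
  expect_error(trainEnsemble(fix$groups, fix$labels, delta = 0), "positive")
  model <- trainEnsemble(fix$groups, fix$labels)
  expect_error(predictVotes(model, fix$groups[1L]), "feature groups")
})

test_that("the vote winner is the mode; ties resolve deterministically", {
  # exhaustive oracle over all tallies with M <= 5 votes
  classes <- aamiClasses()
  priority <- c("V", "S", "N", "F", "Q")
  grids <- expand.grid(rep(list(0:5), 5))
  grids <- grids[rowSums(grids) >= 1 & rowSums(grids) <= 5, ]
  for (i in seq_len(nrow(grids))) {
    counts <- as.integer(grids[i, ]); names(counts) <- classes
    res <- voteWinner(counts)
    top <- classes[counts == max(counts)]
    expect_true(res$winner %in% top)                 # winner is a mode
    expect_identical(res$tie, length(top) > 1L)
    if (length(top) > 1L)                            # priority tie-break
      expect_identical(res$winner, priority[priority %in% top][1L])
  }
})

test_that("margin tie-breaking is order-independent", {
  counts <- c(N = 2L, S = 2L, V = 1L, F = 0L, Q = 0L)
  margins <- c(N = 0.4, S = 1.2, V = 0.1, F = 0, Q = 0)
  res <- voteWinner(counts, margins)
  expect_identical(res$winner, "S")
  expect_true(res$tie)
  perm <- sample(names(counts))
  expect_identical(voteWinner(counts[perm], margins[perm])$winner, "S")
})

test_that("random tallies at M = 15 match a brute-force mode computation", {
  set.seed(99)
  classes <- aamiClasses()
  for (i in 1:200) {
    labs <- sample(classes, 15, replace = TRUE)
    counts <- vapply(classes, function(cl) sum(labs == cl), integer(1))
    res <- voteWinner(counts)
    expect_equal(unname(counts[res$winner]), max(table(labs)))
  }
})

test_that("detectVeb routes only V winners out of stage 2", {
  fix <- makeSeparableGroups(n = 40, M = 3)
  model <- trainEnsemble(fix$groups, fix$labels)
  det <- detectVeb(model, fix$groups)
  expect_identical(det$is_veb, det$winner == "V")
  expect_identical(sum(det$is_veb), 20L)

  empty <- lapply(fix$groups, function(G) G[0L, , drop = FALSE])
  det0 <- detectVeb(model, empty)
  expect_length(det0$is_veb, 0L)
  expect_length(det0$winner, 0L)
})

test_that("ensemble winners match the mode of member predictions on real features", {
  sp <- makeSmallSplit(nRecordings = 2, nBeats = 80, seed = 21)
  bank <- generateBank(M = 5, d = 20, m = 200, seed = 2)
  gTr <- featurize(sp$train, bank, "A")
  gTe <- featurize(sp$test, bank, "A")
  model <- trainEnsemble(gTr, beatInfo(sp$train)$aami_class)
  votes <- predictVotes(model, gTe)
  memberLabs <- sapply(seq_len(5), function(k)
    as.character(predict(model@members[[k]], gTe[[k]])))
  for (i in seq_len(nrow(memberLabs))) {
    tab <- table(memberLabs[i, ])
    expect_true(votes$counts[i, names(which.max(tab))] == max(tab))
    expect_true(votes$counts[i, as.character(votes$winner[i])] == max(tab))
  }
})
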