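# Stage 1: an ensemble of RBF-kernel SVMs, one per random-projection view,
# combined by majority vote.

#' Train the SVM ensemble
#'
#' Fits one RBF-kernel support vector machine per feature group; member k
#' sees only group k (the features produced by bank matrix k). All members
#' share the same penalty `C` and kernel parameter `delta`, used as the
#' RBF coefficient gamma in exp(-gamma * ||x - y||^2). Multi-class
#' handling is libsvm's one-vs-one scheme. Features enter unscaled: the
#' projection coefficients of z-normalized beats are already commensurate.
#'
#' @param featureGroups list of M aligned feature matrices, see
#'   [featurize()].
#' @param labels factor (or character) of reference classes, one per beat,
#'   aligned with every group; at least two classes must be present.
#' @param C penalty parameter, default 1.
#' @param delta RBF kernel parameter, default 1.3.
#' @param leadConfig lead configuration recorded in the model.
#' @param bank the generating [RandomMatrixBank-class], recorded so that
#'   prediction can verify feature provenance.
#' @return a [BeatEnsembleModel-class].
#' @export
trainEnsemble <- function(featureGroups, labels, C = 1, delta = 1.3,
                          leadConfig = "A", bank = NULL) {
  if (C <= 0 || delta <= 0)
    stop("C and delta must be positive", call. = FALSE)
  labels <- droplevels(factor(labels, levels = aamiClasses()))
  if (nlevels(labels) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  n <- length(labels)
  if (!all(vapply(featureGroups, nrow, integer(1)) == n))
    stop("feature groups are not aligned with the label vector", call. = FALSE)
  members <- lapply(featureGroups, function(G) {
    e1071::svm(x = G, y = labels, type = "C-classification",
               kernel = "radial", gamma = delta, cost = C, scale = FALSE)
  })
  bankSeed <- if (is.null(bank)) NA_integer_ else bank@seed
  bankDims <- if (is.null(bank)) rep(NA_integer_, 3L) else c(bank@M, bank@d, bank@m)
  new("BeatEnsembleModel", members = members, cost = C, delta = delta,
      leadConfig = leadConfig, bankSeed = bankSeed, bankDims = bankDims,
      classLevels = levels(labels))
}

#' Resolve one vote tally
#'
#' The winner is the class with the most votes. Ties are broken first by
#' the larger summed one-vs-one decision margin across members (when
#' margins are supplied), then by a fixed clinical priority V > S > N >
#' F > Q. Both rules are independent of member order.
#'
#' @param counts named integer vector of votes per class.
#' @param margins optional named numeric vector of summed decision margins
#'   per class.
#' @return list with `winner` (character), `tie` (logical: was the vote
#'   count maximum shared?).
#' @export
voteWinner <- function(counts, margins = NULL) {
  top <- names(counts)[counts == max(counts)]
  tie <- length(top) > 1L
  if (tie && !is.null(margins)) {
    ms <- margins[top]
    top <- top[ms == max(ms)]
  }
  if (length(top) > 1L)
    top <- .classPriority[.classPriority %in% top][1L]
  list(winner = top, tie = tie)
}

#' Collect the ensemble's votes for each test beat
#'
#' Each member classifies its own feature group; the M predicted labels
#' per beat are tallied over the AAMI classes and resolved by
#' [voteWinner()].
#'
#' @param model a [BeatEnsembleModel-class].
#' @param featureGroups list of M feature matrices generated by the same
#'   bank and lead configuration as the training features.
#' @return list with `counts` (n-by-5 integer matrix of votes per class),
#'   `winner` (factor over N,S,V,F,Q) and `tie` (logical vector).
#' @export
predictVotes <- function(model, featureGroups) {
  stopifnot(is(model, "BeatEnsembleModel"))
  M <- length(model@members)
  if (length(featureGroups) != M)
    stop("expected ", M, " feature groups, got ", length(featureGroups),
         call. = FALSE)
  n <- nrow(featureGroups[[1L]])
  classes <- aamiClasses()
  counts <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  margins <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  if (n == 0L)
    return(list(counts = counts,
                winner = factor(character(), levels = classes),
                tie = logical()))
  for (k in seq_len(M)) {
    p <- stats::predict(model@members[[k]], featureGroups[[k]],
                        decision.values = TRUE)
    ci <- match(as.character(p), classes)
    counts[cbind(seq_len(n), ci)] <- counts[cbind(seq_len(n), ci)] + 1L
    dv <- attr(p, "decision.values")
    if (!is.null(dv)) {
      for (j in seq_len(ncol(dv))) {
        pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1L]]
        margins[, pair[1L]] <- margins[, pair[1L]] + dv[, j]
        margins[, pair[2L]] <- margins[, pair[2L]] - dv[, j]
      }
    }
  }
  res <- lapply(seq_len(n), function(i) voteWinner(counts[i, ], margins[i, ]))
  list(counts = counts,
       winner = factor(vapply(res, `[[`, character(1), "winner"),
                       levels = classes),
       tie = vapply(res, `[[`, logical(1), "tie"))
}

#' Flag ventricular ectopic beats
#'
#' Applies the ensemble and keeps only the V / non-V decision for the next
#' stage; the full five-class winners are returned for diagnostics but
#' stage-1 S/F/Q labels are not final.
#'
#' @inheritParams predictVotes
#' @return list with `is_veb` (logical vector) and `winner` (factor of
#'   stage-1 winners).
#' @export
detectVeb <- function(model, featureGroups) {
  votes <- predictVotes(model, featureGroups)
  list(is_veb = votes$winner == "V", winner = votes$winner)
}
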