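# Leave-one-recording-out cross-validation, (C, delta) grid search and
# lead-configuration selection on the training records.

#' Leave-one-recording-out folds
#'
#' Partitions by record id, never by beat: each recording is the held-out
#' test set exactly once and all beats of the held-out patient are absent
#' from that fold's training set (the inter-patient guarantee).
#'
#' @param recordIds character vector of record ids (one per recording; a
#'   per-beat vector is reduced to its unique ids in first-appearance
#'   order).
#' @return list of folds, each `list(test = <id>, train = <other ids>)`.
#' @export
loroFolds <- function(recordIds) {
  ids <- as.character(recordIds)
  if (length(ids) != length(unique(ids)) && length(ids) > 0L)
    ids <- unique(ids)
  if (anyDuplicated(ids)) stop("duplicate record ids", call. = FALSE)
  if (length(ids) < 2L)
    stop("need at least 2 recordings for cross-validation", call. = FALSE)
  lapply(ids, function(id) list(test = id, train = setdiff(ids, id)))
}

#' Cross-validated stage-1 confusion matrix for one (C, delta)
#'
#' Runs the full leave-one-recording-out loop: per fold, train an M-member
#' ensemble on the training recordings' feature groups, classify the
#' held-out recording, and element-wise sum the per-fold five-class
#' confusion matrices. Metrics (and Ave) are computed from the summed
#' matrix, never averaged across folds.
#'
#' @param featureGroups list of M aligned feature matrices for all
#'   training beats, see [featurize()].
#' @param labels reference classes, one per beat.
#' @param recordIds record id per beat.
#' @param C,delta SVM parameters, see [trainEnsemble()].
#' @param leadConfig recorded in the fold models.
#' @return list with `confusion` (summed 5x5 matrix), `ave` (percent from
#'   the summed matrix) and `folds` (fold count).
#' @export
crossValidateEnsemble <- function(featureGroups, labels, recordIds,
                                  C = 1, delta = 1.3, leadConfig = "A") {
  recordIds <- as.character(recordIds)
  folds <- loroFolds(unique(recordIds))
  classes <- aamiClasses()
  total <- matrix(0L, length(classes), length(classes),
                  dimnames = list(classes, classes))
  for (fold in folds) {
    testSel  <- recordIds == fold$test
    trainSel <- !testSel
    stopifnot(!any(recordIds[trainSel] == fold$test))  # inter-patient guard
    trainGroups <- lapply(featureGroups, function(G) G[trainSel, , drop = FALSE])
    testGroups  <- lapply(featureGroups, function(G) G[testSel, , drop = FALSE])
    model <- trainEnsemble(trainGroups, labels[trainSel], C = C,
                           delta = delta, leadConfig = leadConfig)
    votes <- predictVotes(model, testGroups)
    total <- total + confusionCounts(labels[testSel], votes$winner,
                                     algClasses = classes)
  }
  list(confusion = total, ave = computeAve(total), folds = length(folds))
}

#' Grid search over (C, delta)
#'
#' Evaluates every parameter combination with
#' [crossValidateEnsemble()] and returns the one maximizing the Ave
#' criterion. Ties prefer the smaller C, then the smaller delta (the
#' simpler model). A combination whose cross-validation fails (e.g. a fold
#' left with a single training class) is kept in the table with NA Ave.
#'
#' @inheritParams crossValidateEnsemble
#' @param Cs candidate penalty values, default `c(1, 10, 100)`.
#' @param deltas candidate kernel values, default `c(0.4, 0.7, 1.0, 1.3)`.
#' @return list with `best` (list: C, delta, ave, confusion) and `table`
#'   (data.frame: delta, C, ave, failed).
#' @export
gridSearchParams <- function(featureGroups, labels, recordIds,
                             Cs = c(1, 10, 100),
                             deltas = c(0.4, 0.7, 1.0, 1.3),
                             leadConfig = "A") {
  stopifnot(length(Cs) >= 1L, length(deltas) >= 1L)
  combos <- expand.grid(C = Cs, delta = deltas, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(combos))
  results <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    res <- tryCatch(
      crossValidateEnsemble(featureGroups, labels, recordIds,
                            C = combos$C[i], delta = combos$delta[i],
                            leadConfig = leadConfig),
      error = function(e) NULL)
    results[[i]] <- res
    rows[[i]] <- data.frame(delta = combos$delta[i], C = combos$C[i],
                            ave = if (is.null(res)) NA_real_ else res$ave,
                            failed = is.null(res))
  }
  table <- do.call(rbind, rows)
  ok <- which(!is.na(table$ave))
  if (!length(ok)) stop("every parameter combination failed", call. = FALSE)
  # argmax Ave; ties -> smaller C, then smaller delta
  ord <- ok[order(-table$ave[ok], table$C[ok], table$delta[ok])]
  bestIdx <- ord[1L]
  list(best = list(C = table$C[bestIdx], delta = table$delta[bestIdx],
                   ave = table$ave[bestIdx],
                   confusion = results[[bestIdx]]$confusion),
       table = table)
}

#' Choose the lead configuration
#'
#' Picks the configuration whose best cross-validated Ave on the training
#' records is maximal; exact ties fall back to the canonical order
#' A, B, A+B.
#'
#' @param aves named numeric vector of best-Ave per configuration; names
#'   must be a subset of `leadConfigs()`.
#' @return the chosen configuration name.
#' @export
selectLeadConfig <- function(aves) {
  stopifnot(length(aves) >= 1L, all(names(aves) %in% leadConfigs()))
  canon <- leadConfigs()[leadConfigs() %in% names(aves)]
  aves <- aves[canon]
  canon[which.max(aves)]  # which.max takes the first maximum -> canonical tie rule
}
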