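# AAMI-style evaluation: confusion matrices, Se/PP/Acc, the Ave selection
# criterion, and per-recording report tables.

#' Build a reference-by-algorithm confusion matrix
#'
#' Rows are reference classes (always all of N,S,V,F,Q), columns the
#' algorithm's label set — N,S,V for the final hierarchical system, all
#' five classes for stage-1 diagnostics.
#'
#' @param reference factor/character of reference classes.
#' @param predicted factor/character of algorithm labels, same length.
#' @param algClasses column classes, default `c("N","S","V")`.
#' @return integer matrix with reference rows and algorithm columns.
#' @export
confusionCounts <- function(reference, predicted,
                            algClasses = c("N", "S", "V")) {
  stopifnot(length(reference) == length(predicted))
  reference <- factor(as.character(reference), levels = aamiClasses())
  predicted <- factor(as.character(predicted), levels = algClasses)
  if (anyNA(predicted))
    stop("predicted labels outside the algorithm class set", call. = FALSE)
  cm <- table(reference = reference, algorithm = predicted)
  matrix(as.integer(cm), nrow(cm), ncol(cm),
         dimnames = list(rownames(cm), colnames(cm)))
}

#' Read a confusion matrix from CSV
#'
#' Expects a `reference` column holding row classes and one column per
#' algorithm class, as shipped in `extdata/ds2_confusion_published.csv`.
#'
#' @param path CSV path.
#' @return integer confusion matrix.
#' @export
readConfusionCsv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  stopifnot("reference" %in% names(tab))
  cm <- as.matrix(tab[, setdiff(names(tab), "reference"), drop = FALSE])
  storage.mode(cm) <- "integer"
  rownames(cm) <- tab$reference
  cm
}

#' Per-class sensitivity
#'
#' Fraction of reference beats of `class` that the algorithm labeled as
#' that class, in percent. Undefined (NA) when the reference row is empty.
#'
#' @param cm confusion matrix from [confusionCounts()].
#' @param class class name, must be a row of `cm`.
#' @return percent, or NA when undefined.
#' @export
sensitivity <- function(cm, class) {
  if (!class %in% rownames(cm)) stop("unknown reference class ", class)
  total <- sum(cm[class, ])
  if (total == 0L) return(NA_real_)
  tp <- if (class %in% colnames(cm)) cm[class, class] else 0L
  100 * tp / total
}

#' Per-class positive predictive value
#'
#' Fraction of algorithm detections of `class` that are correct, in
#' percent. Undefined (NA) when nothing was labeled as `class`.
#'
#' @inheritParams sensitivity
#' @param class class name, must be a column of `cm`.
#' @return percent, or NA when undefined.
#' @export
positivePredictiveValue <- function(cm, class) {
  if (!class %in% colnames(cm)) stop("unknown algorithm class ", class)
  total <- sum(cm[, class])
  if (total == 0L) return(NA_real_)
  tp <- if (class %in% rownames(cm)) cm[class, class] else 0L
  100 * tp / total
}

#' Overall accuracy
#'
#' Correct detections over all evaluated beats, in percent. Reference
#' classes the algorithm can never emit (F and Q in the final three-column
#' system) still count in the denominator.
#'
#' @inheritParams sensitivity
#' @return percent.
#' @export
accuracy <- function(cm) {
  shared <- intersect(rownames(cm), colnames(cm))
  100 * sum(cm[cbind(shared, shared)]) / sum(cm)
}

#' The Ave model-selection criterion
#'
#' Mean of the sensitivity and positive predictive value of class N and of
#' VEB: `(Se_N + PP_N + Se_V + PP_V) / 4`, in percent. Computed from one
#' (summed) confusion matrix, never by averaging per-fold percentages.
#' NA when any of the four terms is undefined.
#'
#' @inheritParams sensitivity
#' @return percent, or NA.
#' @export
computeAve <- function(cm) {
  terms <- c(sensitivity(cm, "N"), positivePredictiveValue(cm, "N"),
             sensitivity(cm, "V"), positivePredictiveValue(cm, "V"))
  if (anyNA(terms)) return(NA_real_)
  mean(terms)
}

#' Ave from four already-rounded table entries
#'
#' Convenience for recomputing a printed table row: the plain mean of the
#' four percentages.
#'
#' @param seN,ppN,seV,ppV percentages.
#' @return percent.
#' @export
aveFromRates <- function(seN, ppN, seV, ppV) mean(c(seN, ppN, seV, ppV))

#' Count of beats entering the SVEB stage
#'
#' Beats not labeled VEB by stage 1 continue to the RR-ratio threshold.
#'
#' @param totalBeats total evaluated beats.
#' @param vLabeled beats the ensemble labeled V.
#' @return integer.
#' @export
stage2InputCount <- function(totalBeats, vLabeled) {
  out <- totalBeats - vLabeled
  if (out < 0) stop("more V-labeled beats than beats in total", call. = FALSE)
  out
}

# Display rounding: half-up to `digits` decimals, matching printed tables.
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  ifelse(is.na(x), NA_real_, floor(x * p + 0.5) / p)
}

#' Per-recording performance report
#'
#' One row per recording with its reference N/S/V beat counts, per-class
#' Se and PP, and accuracy over all beats of the recording (reference F
#' and Q beats count in the accuracy denominator). The `Total` row is
#' computed from the pooled confusion matrix, not by averaging rows.
#'
#' @param reference,predicted aligned class vectors.
#' @param recordIds aligned record-id vector.
#' @param algClasses algorithm label set, default `c("N","S","V")`.
#' @return data.frame; undefined metrics are NA (rendered `-` by
#'   [formatReport()]).
#' @export
perRecordingReport <- function(reference, predicted, recordIds,
                               algClasses = c("N", "S", "V")) {
  stopifnot(length(reference) == length(predicted),
            length(reference) == length(recordIds))
  oneRow <- function(id, cm) {
    data.frame(
      record = id,
      n_N = sum(cm["N", ]), n_S = sum(cm["S", ]), n_V = sum(cm["V", ]),
      se_N = sensitivity(cm, "N"), pp_N = positivePredictiveValue(cm, "N"),
      se_S = sensitivity(cm, "S"), pp_S = positivePredictiveValue(cm, "S"),
      se_V = sensitivity(cm, "V"), pp_V = positivePredictiveValue(cm, "V"),
      acc = accuracy(cm),
      stringsAsFactors = FALSE
    )
  }
  ids <- unique(as.character(recordIds))
  rows <- lapply(ids, function(id) {
    sel <- recordIds == id
    oneRow(id, confusionCounts(reference[sel], predicted[sel], algClasses))
  })
  pooled <- confusionCounts(reference, predicted, algClasses)
  out <- rbind(do.call(rbind, rows), oneRow("Total", pooled))
  rownames(out) <- NULL
  out
}

#' Render a report table for printing
#'
#' Rounds percentages half-up to one decimal and renders undefined metrics
#' as `-`.
#'
#' @param report data.frame from [perRecordingReport()].
#' @return character-matrix-backed data.frame ready for printing/writing.
#' @export
formatReport <- function(report) {
  pct <- grep("^(se|pp|acc)", names(report), value = TRUE)
  for (col in pct) {
    v <- roundHalfUp(report[[col]], 1L)
    report[[col]] <- ifelse(is.na(v), "-", sprintf("%.1f", v))
  }
  report
}
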