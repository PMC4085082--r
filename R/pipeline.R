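# The two-stage pipeline: ensemble VEB detection, then the RR-ratio SVEB
# rule on the surviving beats.

#' Train the full hierarchical classifier
#'
#' Featurizes the training beats with the bank, optionally grid-searches
#' (C, delta) by leave-one-recording-out cross-validation, trains the
#' final M-member ensemble on all training beats, and selects the stage-2
#' RR-ratio threshold on the training beats that survive stage 1.
#'
#' @param trainBeats a multi-recording [BeatSet-class] (the DS1 analogue).
#' @param bank a [RandomMatrixBank-class].
#' @param C,delta SVM parameters used when `gridSearch` is FALSE.
#' @param leadConfig `"A"`, `"B"` or `"A+B"`.
#' @param gridSearch run [gridSearchParams()] first?
#' @param Cs,deltas grid passed to [gridSearchParams()].
#' @param seTarget stage-2 sensitivity target in percent, see
#'   [selectThreshold()].
#' @param thresholdGrid stage-2 threshold grid, see [scanThresholds()].
#' @param thresholdOn `"detected"` (default): scan stage-2 thresholds on
#'   training beats the trained ensemble itself does not label V —
#'   mirroring the deployment pipeline; `"reference"`: remove reference-V
#'   beats instead.
#' @return a [HierarchicalBeatModel-class]; the grid-search table (when
#'   run) and the threshold scan are attached as attributes `"grid"` and
#'   `"scan"`.
#' @export
trainHierarchicalModel <- function(trainBeats, bank, C = 1, delta = 1.3,
                                   leadConfig = "A", gridSearch = FALSE,
                                   Cs = c(1, 10, 100),
                                   deltas = c(0.4, 0.7, 1.0, 1.3),
                                   seTarget = 80,
                                   thresholdGrid = seq(0.70, 0.90, by = 0.01),
                                   thresholdOn = c("detected", "reference")) {
  thresholdOn <- match.arg(thresholdOn)
  stopifnot(is(trainBeats, "BeatSet"), nBeats(trainBeats) > 0L)
  info <- beatInfo(trainBeats)
  groups <- featurize(trainBeats, bank, leadConfig)

  gridTab <- NULL
  if (gridSearch) {
    gs <- gridSearchParams(groups, info$aami_class, info$record_id,
                           Cs = Cs, deltas = deltas, leadConfig = leadConfig)
    C <- gs$best$C; delta <- gs$best$delta
    gridTab <- gs$table
  }

  ensemble <- trainEnsemble(groups, info$aami_class, C = C, delta = delta,
                            leadConfig = leadConfig, bank = bank)

  keep <- if (thresholdOn == "detected") {
    !detectVeb(ensemble, groups)$is_veb
  } else {
    info$aami_class != "V"
  }
  scan <- scanThresholds(info$rr_ratio[keep],
                         info$aami_class[keep] == "S",
                         grid = thresholdGrid)
  threshold <- selectThreshold(scan, seTarget = seTarget)

  model <- new("HierarchicalBeatModel", ensemble = ensemble,
               rrThreshold = threshold)
  attr(model, "grid") <- gridTab
  attr(model, "scan") <- scan
  model
}

#' Classify beats with a trained hierarchical model
#'
#' Stage 1 labels ventricular ectopic beats by ensemble majority vote;
#' stage 2 applies the RR-ratio threshold to the remaining beats. Final
#' labels are N, S or V only.
#'
#' @param model a [HierarchicalBeatModel-class].
#' @param beats a [BeatSet-class].
#' @param bank the [RandomMatrixBank-class] that generated the model's
#'   training features; its seed and shape must match the model's record.
#' @return data.frame with one row per beat: `record_id`, `reference`
#'   (AAMI class), `stage1` (five-class ensemble winner), `label` (final
#'   N/S/V), `rr_ratio`. The stage-2 input count is attached as attribute
#'   `"stage2_n"`.
#' @export
classifyBeats <- function(model, beats, bank) {
  stopifnot(is(model, "HierarchicalBeatModel"), is(beats, "BeatSet"),
            is(bank, "RandomMatrixBank"))
  ens <- model@ensemble
  if (!is.na(ens@bankSeed) &&
      (ens@bankSeed != bank@seed ||
       !identical(ens@bankDims, c(bank@M, bank@d, bank@m))))
    stop("feature bank does not match the one the model was trained with",
         call. = FALSE)
  info <- beatInfo(beats)
  if (nBeats(beats) == 0L) {
    out <- data.frame(record_id = character(), reference = character(),
                      stage1 = character(), label = character(),
                      rr_ratio = numeric())
    attr(out, "stage2_n") <- 0L
    return(out)
  }
  groups <- featurize(beats, bank, ens@leadConfig)
  stage1 <- detectVeb(ens, groups)
  labels <- factor(rep("N", nBeats(beats)), levels = c("N", "S", "V"))
  labels[stage1$is_veb] <- "V"
  nonVeb <- !stage1$is_veb
  labels[nonVeb] <- detectSveb(info$rr_ratio[nonVeb], model@rrThreshold)
  out <- data.frame(record_id = info$record_id,
                    reference = info$aami_class,
                    stage1 = stage1$winner,
                    label = labels,
                    rr_ratio = info$rr_ratio,
                    stringsAsFactors = FALSE)
  attr(out, "stage2_n") <- stage2InputCount(nBeats(beats),
                                            sum(stage1$is_veb))
  out
}

#' Save / load a trained model archive
#'
#' The archive records the fitted members, (C, delta), lead configuration
#' and the generating bank's seed and shape; reloading reproduces
#' predictions exactly on the same platform.
#'
#' @param model a [HierarchicalBeatModel-class].
#' @param path archive path (RDS).
#' @return `saveModel`: the path, invisibly. `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "HierarchicalBeatModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "HierarchicalBeatModel"))
  model
}
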