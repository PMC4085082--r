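# Stage 2: RR-interval-ratio threshold rule for supraventricular ectopic
# beats, and its threshold selection on the training records.

#' Default stage-2 RR-ratio threshold
#'
#' The deployment value selected on the reference training records: a
#' beat surviving stage 1 is called SVEB when its RR-interval ratio is
#' below 0.8.
#'
#' @export
DEFAULT_RR_THRESHOLD <- 0.8

# Ratios are rounded to 10 decimals before the strict comparison so that
# decimal grid thresholds (0.70, 0.71, ...) behave as written despite
# binary floating point.
.belowThreshold <- function(rrRatio, threshold) {
  round(rrRatio, 10L) < threshold
}

#' Label non-VEB beats as SVEB or N by the RR-ratio rule
#'
#' A beat is SVEB when its RR-interval ratio is strictly smaller than the
#' threshold; every other beat is N. The rule is only meant for beats the
#' ensemble did not label V; final system labels are N, S, V only.
#'
#' @param rrRatio numeric vector of RR-interval ratios (no NA).
#' @param threshold scalar threshold, default [DEFAULT_RR_THRESHOLD].
#' @return factor with levels N,S,V (no V is ever assigned here).
#' @examples
#' detectSveb(c(0.79, 0.80, 1.0))
#' @export
detectSveb <- function(rrRatio, threshold = DEFAULT_RR_THRESHOLD) {
  if (anyNA(rrRatio)) stop("missing RR ratio", call. = FALSE)
  factor(ifelse(.belowThreshold(rrRatio, threshold), "S", "N"),
         levels = c("N", "S", "V"))
}

#' Scan the threshold grid on training beats
#'
#' Computes SVEB sensitivity and positive predictive value of the
#' threshold rule at every grid point (default 0.70 to 0.90 in steps of
#' 0.01) from an S-vs-not-S confusion of the supplied (non-VEB) training
#' beats.
#'
#' @param rrRatio RR-interval ratios of the beats entering stage 2.
#' @param isSveb logical: reference class is S.
#' @param grid threshold grid, default `seq(0.70, 0.90, by = 0.01)`.
#' @return data.frame with columns `threshold`, `se`, `pp` (percent; NA
#'   where undefined).
#' @export
scanThresholds <- function(rrRatio, isSveb,
                           grid = seq(0.70, 0.90, by = 0.01)) {
  stopifnot(length(rrRatio) == length(isSveb))
  if (anyNA(rrRatio)) stop("missing RR ratio", call. = FALSE)
  nS <- sum(isSveb)
  res <- lapply(grid, function(th) {
    called <- .belowThreshold(rrRatio, th)
    tp <- sum(called & isSveb)
    data.frame(threshold = th,
               se = if (nS == 0L) NA_real_ else 100 * tp / nS,
               pp = if (sum(called) == 0L) NA_real_ else 100 * tp / sum(called))
  })
  do.call(rbind, res)
}

#' Select the operating threshold
#'
#' Operationalizes "sensitivity close to the target": the smallest grid
#' threshold whose training sensitivity reaches `seTarget` percent. If no
#' grid point reaches the target the grid maximum is returned with a
#' warning.
#'
#' @param scan data.frame from [scanThresholds()].
#' @param seTarget sensitivity target in percent, default 80.
#' @return the chosen threshold.
#' @export
selectThreshold <- function(scan, seTarget = 80) {
  stopifnot(nrow(scan) >= 1L)
  ok <- which(!is.na(scan$se) & scan$se >= seTarget)
  if (!length(ok)) {
    warning("no grid threshold reaches ", seTarget,
            "% sensitivity; using the grid maximum", call. = FALSE)
    return(max(scan$threshold))
  }
  min(scan$threshold[ok])
}
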