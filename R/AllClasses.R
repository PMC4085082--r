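#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' EcgRecording: an annotated two-lead ECG recording
#'
#' Container for one ECG recording: a samples-by-leads signal matrix, the
#' sampling rate, and the beat/non-beat annotation stream (R-peak sample
#' indices plus single-character type codes).
#'
#' @slot recordId character(1) record identifier.
#' @slot signal numeric matrix, one column per lead; column names are the
#'   lead ids (conventionally \code{"A"} and \code{"B"}).
#' @slot samplingRate numeric(1) samples per second.
#' @slot annotations data.frame with columns \code{sample} (integer, strictly
#'   increasing) and \code{symbol} (character).
#'
#' @seealso [readRecording()], [simulateRecording()], [extractBeats()]
#' @export
setClass("EcgRecording",
  representation(
    recordId     = "character",
    signal       = "matrix",
    samplingRate = "numeric",
    annotations  = "data.frame"
  )
)

setValidity("EcgRecording", function(object) {
  msg <- character()
  if (length(object@recordId) != 1L || is.na(object@recordId))
    msg <- c(msg, "recordId must be a single non-NA string")
  if (!is.numeric(object@signal))
    msg <- c(msg, "signal must be a numeric matrix")
  if (is.null(colnames(object@signal)))
    msg <- c(msg, "signal columns must be named by lead")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  ann <- object@annotations
  if (!all(c("sample", "symbol") %in% names(ann)))
    msg <- c(msg, "annotations needs columns 'sample' and 'symbol'")
  if (nrow(ann) > 1L && any(diff(ann$sample) <= 0))
    msg <- c(msg, "annotation samples must be strictly increasing")
  if (nrow(ann) > 0L &&
      (any(ann$sample < 1L) || any(ann$sample > nrow(object@signal))))
    msg <- c(msg, "annotation samples must lie inside the signal")
  if (length(msg)) msg else TRUE
})

#' BeatSet: segmented, normalized heartbeats with RR features
#'
#' One row per retained beat. Each lead's windows are stored as an
#' n-by-windowLen matrix of z-normalized samples; per-beat metadata
#' (record id, R sample, annotation symbol, AAMI class, preceding RR
#' interval, RR-interval ratio) live in \code{beatInfo}. \code{dropCounts}
#' keeps the beat-count accounting of the segmentation step.
#'
#' @slot leadA numeric matrix (beats x window samples), lead A windows.
#' @slot leadB numeric matrix or NULL, lead B windows (same shape as leadA).
#' @slot beatInfo data.frame with columns \code{record_id}, \code{beat_index},
#'   \code{r_sample}, \code{symbol}, \code{aami_class} (factor with levels
#'   N,S,V,F,Q), \code{rr_prev_s}, \code{rr_ratio}.
#' @slot dropCounts named integer vector: \code{annotations}, \code{non_beat},
#'   \code{first_beat}, \code{boundary}, \code{flat}, \code{retained}.
#'
#' @seealso [extractBeats()], [featurize()]
#' @export
setClass("BeatSet",
  representation(
    leadA      = "matrix",
    leadB      = "matrixOrNULL",
    beatInfo   = "data.frame",
    dropCounts = "integer"
  )
)

setValidity("BeatSet", function(object) {
  msg <- character()
  n <- nrow(object@leadA)
  need <- c("record_id", "beat_index", "r_sample", "symbol", "aami_class",
            "rr_prev_s", "rr_ratio")
  if (!all(need %in% names(object@beatInfo)))
    msg <- c(msg, paste("beatInfo needs columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@beatInfo) != n)
      msg <- c(msg, "beatInfo rows must match leadA rows")
    if (!is.factor(object@beatInfo$aami_class) ||
        !identical(levels(object@beatInfo$aami_class), aamiClasses()))
      msg <- c(msg, "aami_class must be a factor with levels N,S,V,F,Q")
    if (n > 0L && any(object@beatInfo$rr_prev_s <= 0))
      msg <- c(msg, "rr_prev_s must be positive")
  }
  if (!is.null(object@leadB) && !identical(dim(object@leadB), dim(object@leadA)))
    msg <- c(msg, "leadB must have the same shape as leadA")
  if (length(msg)) msg else TRUE
})

#' RandomMatrixBank: seeded Gaussian projection matrices
#'
#' A bank of M independent d-by-m matrices with i.i.d. standard-normal
#' entries, regenerated bit-identically from \code{seed}. Rows play the role
#' of random sensing signals; beats are represented by their least-squares
#' coefficients on each matrix's row space.
#'
#' @slot matrices list of M numeric d-by-m matrices.
#' @slot M integer(1) number of matrices (ensemble views).
#' @slot d integer(1) projection dimension (rows per matrix).
#' @slot m integer(1) beat window length (columns per matrix).
#' @slot seed integer(1) generating seed.
#'
#' @seealso [generateBank()], [projectBeats()]
#' @export
setClass("RandomMatrixBank",
  representation(
    matrices = "list",
    M        = "integer",
    d        = "integer",
    m        = "integer",
    seed     = "integer"
  )
)

setValidity("RandomMatrixBank", function(object) {
  msg <- character()
  if (object@M < 1L) msg <- c(msg, "M must be >= 1")
  if (object@d >= object@m) msg <- c(msg, "projection must reduce dimension (d < m)")
  if (length(object@matrices) != object@M)
    msg <- c(msg, "bank must hold exactly M matrices")
  ok <- vapply(object@matrices, function(A)
    identical(dim(A), c(object@d, object@m)), logical(1))
  if (!all(ok)) msg <- c(msg, "every matrix must be d x m")
  if (length(msg)) msg else TRUE
})

#' BeatEnsembleModel: a majority-vote SVM ensemble over random-projection views
#'
#' M RBF-kernel support vector machines, member k trained on the feature
#' group produced by matrix k of the bank. All members share one (C, delta)
#' setting; a test beat receives M votes and is assigned the winning class.
#'
#' @slot members list of M fitted [e1071::svm] objects.
#' @slot cost numeric(1) SVM penalty parameter (the C of the soft-margin objective).
#' @slot delta numeric(1) RBF kernel parameter, used as the coefficient
#'   gamma in exp(-gamma * ||x - y||^2).
#' @slot leadConfig character(1), one of "A", "B", "A+B".
#' @slot bankSeed integer(1), seed of the generating bank.
#' @slot bankDims integer(3): M, d, m of the generating bank.
#' @slot classLevels character, the class labels seen in training.
#'
#' @seealso [trainEnsemble()], [predictVotes()], [detectVeb()]
#' @export
setClass("BeatEnsembleModel",
  representation(
    members     = "list",
    cost        = "numeric",
    delta       = "numeric",
    leadConfig  = "character",
    bankSeed    = "integer",
    bankDims    = "integer",
    classLevels = "character"
  )
)

setValidity("BeatEnsembleModel", function(object) {
  msg <- character()
  if (length(object@members) < 1L) msg <- c(msg, "ensemble needs >= 1 member")
  if (object@cost <= 0) msg <- c(msg, "C must be positive")
  if (object@delta <= 0) msg <- c(msg, "delta must be positive")
  if (!object@leadConfig %in% leadConfigs())
    msg <- c(msg, "leadConfig must be one of A, B, A+B")
  if (length(msg)) msg else TRUE
})

#' HierarchicalBeatModel: the full two-stage classifier
#'
#' Stage 1 is a [BeatEnsembleModel] that flags ventricular ectopic beats
#' (VEB); stage 2 labels the remaining beats as supraventricular ectopic
#' (SVEB) when their RR-interval ratio falls below \code{rrThreshold}.
#' Final labels are restricted to N, S, V.
#'
#' @slot ensemble the stage-1 [BeatEnsembleModel].
#' @slot rrThreshold numeric(1), stage-2 RR-ratio threshold.
#'
#' @seealso [trainHierarchicalModel()], [classifyBeats()]
#' @export
setClass("HierarchicalBeatModel",
  representation(
    ensemble    = "BeatEnsembleModel",
    rrThreshold = "numeric"
  )
)

setValidity("HierarchicalBeatModel", function(object) {
  if (length(object@rrThreshold) != 1L || object@rrThreshold <= 0)
    "rrThreshold must be a single positive number" else TRUE
})
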