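# Beat segmentation, normalization, AAMI labels and RR features.

#' Cut a fixed-length window around an annotated R peak
#'
#' Returns `windowLen` consecutive samples covering `preSamples` points
#' before the R fiducial through `windowLen - preSamples - 1` points after
#' it. With the defaults (200 and 100) the window spans roughly 0.278 s on
#' either side of the R wave at 360 Hz, enough to contain the P wave, QRS
#' complex and T wave of one beat.
#'
#' @param signal numeric vector, one lead of an ECG recording.
#' @param rSample integer, sample index of the R fiducial (1-based).
#' @param windowLen window length in samples.
#' @param preSamples samples taken before the R fiducial.
#' @return numeric vector of length `windowLen`.
#' @examples
#' segmentBeat(seq_len(1000), 500)[1] # sample 400
#' @export
segmentBeat <- function(signal, rSample, windowLen = 200L, preSamples = 100L) {
  stopifnot(windowLen >= 2L, preSamples >= 0L, preSamples < windowLen)
  from <- rSample - preSamples
  to   <- rSample + (windowLen - preSamples - 1L)
  if (from < 1L || to > length(signal))
    stop("beat window [", from, ", ", to, "] extends beyond the signal ",
         "(1..", length(signal), ")", call. = FALSE)
  signal[from:to]
}

#' Z-normalize one beat window
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divide by n, not n-1: this is a normalization target, not an inference),
#' so every retained beat has mean 0 and sd 1 regardless of amplifier gain
#' or electrode placement.
#'
#' @param samples numeric vector of length >= 2.
#' @return numeric vector, same length, zero mean and unit population sd.
#' @examples
#' normalizeBeat(c(1, 2, 3))
#' @export
normalizeBeat <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to normalize", call. = FALSE)
  mu <- mean(samples)
  sdev <- sqrt(sum((samples - mu)^2) / n)
  if (sdev == 0)
    stop("flat beat window (zero variance) cannot be normalized", call. = FALSE)
  (samples - mu) / sdev
}

#' Map an annotation symbol to its AAMI class
#'
#' Total on beat codes: codes absent from the map fall back to Q (unknown).
#' Non-beat codes (rhythm changes, artifacts, ...) raise an error; use
#' [isBeatSymbol()] to screen them out first.
#'
#' @param symbol character vector of single-character beat codes.
#' @param map symbol table as returned by [defaultSymbolMap()].
#' @return factor with levels N,S,V,F,Q.
#' @examples
#' mapSymbolToAami(c("V", "A", "N", "z"))
#' @export
mapSymbolToAami <- function(symbol, map = defaultSymbolMap()) {
  if (any(symbol %in% .nonBeatSymbols))
    stop("non-beat annotation code(s): ",
         paste(unique(symbol[symbol %in% .nonBeatSymbols]), collapse = " "),
         call. = FALSE)
  cls <- map$aami_class[match(symbol, map$symbol)]
  cls[is.na(cls)] <- "Q"
  factor(cls, levels = aamiClasses())
}

#' Is an annotation code a beat?
#'
#' @param symbol character vector of annotation codes.
#' @return logical vector: TRUE for beat codes, FALSE for rhythm/artifact
#'   markers.
#' @export
isBeatSymbol <- function(symbol) !(symbol %in% .nonBeatSymbols)

#' Preceding RR interval and RR-interval ratio
#'
#' For beat i, `rr_prev_s[i]` is the time since the previous beat's R wave
#' and `rr_ratio[i]` divides it by the mean preceding-RR interval of the
#' whole recording. The ratio removes between-recording heart-rate
#' differences: persistently fast rhythms have short RR intervals but
#' ratios near 1, while premature beats stand out with ratios well below 1.
#' The first beat of a recording has no preceding interval and gets NA in
#' both outputs; it is dropped during segmentation.
#'
#' @param rTimesS strictly increasing numeric vector of R-wave times in
#'   seconds.
#' @return list with numeric vectors `rr_prev_s` and `rr_ratio`, aligned
#'   with `rTimesS` (first element NA).
#' @examples
#' computeRRFeatures(c(0, 1, 1.5, 2.5))
#' @export
computeRRFeatures <- function(rTimesS) {
  if (length(rTimesS) < 2L)
    stop("need at least 2 beats to define RR intervals", call. = FALSE)
  if (any(diff(rTimesS) <= 0))
    stop("R times must be strictly increasing", call. = FALSE)
  rr <- c(NA_real_, diff(rTimesS))
  list(rr_prev_s = rr,
       rr_ratio  = rr / mean(rr, na.rm = TRUE))
}

#' Segment a recording into a normalized BeatSet
#'
#' Runs the full preprocessing chain on one recording: keep beat
#' annotations only, compute RR features over the whole beat sequence, cut
#' a fixed window per beat on every lead, z-normalize each window, and drop
#' (with accounting) the first beat (no preceding RR), beats whose window
#' leaves the signal, and flat windows.
#'
#' @param recording an [EcgRecording-class].
#' @param windowLen,preSamples window geometry passed to [segmentBeat()].
#' @param map symbol table, see [defaultSymbolMap()].
#' @param leads leads to extract, subset of the recording's lead names.
#' @return a [BeatSet-class]; `dropCounts()` carries the conservation
#'   accounting (annotations = non_beat + first_beat + boundary + flat +
#'   retained).
#' @export
extractBeats <- function(recording, windowLen = 200L, preSamples = 100L,
                         map = defaultSymbolMap(),
                         leads = colnames(signalMatrix(recording))) {
  stopifnot(is(recording, "EcgRecording"))
  sig <- signalMatrix(recording)
  if (!all(leads %in% colnames(sig)))
    stop("recording lacks lead(s): ",
         paste(setdiff(leads, colnames(sig)), collapse = ", "))
  ann <- annotations(recording)
  fs  <- samplingRate(recording)

  isBeat <- isBeatSymbol(ann$symbol)
  beats  <- ann[isBeat, , drop = FALSE]
  nNonBeat <- sum(!isBeat)

  n <- nrow(beats)
  counts <- c(annotations = nrow(ann), non_beat = nNonBeat,
              first_beat = 0L, boundary = 0L, flat = 0L, retained = 0L)
  emptySet <- function(counts) {
    info <- data.frame(record_id = character(), beat_index = integer(),
                       r_sample = integer(), symbol = character(),
                       aami_class = factor(character(), levels = aamiClasses()),
                       rr_prev_s = numeric(), rr_ratio = numeric(),
                       stringsAsFactors = FALSE)
    new("BeatSet",
        leadA = matrix(numeric(), 0L, windowLen),
        leadB = if (length(leads) > 1L) matrix(numeric(), 0L, windowLen) else NULL,
        beatInfo = info, dropCounts = counts)
  }
  if (n < 2L) {
    if (n == 1L) counts["first_beat"] <- 1L
    return(emptySet(counts))
  }

  rrf <- computeRRFeatures(beats$sample / fs)
  keep <- rep(TRUE, n)
  keep[1L] <- FALSE                       # no preceding RR
  counts["first_beat"] <- 1L

  lo <- beats$sample - preSamples
  hi <- beats$sample + (windowLen - preSamples - 1L)
  boundary <- keep & (lo < 1L | hi > nrow(sig))
  counts["boundary"] <- sum(boundary)
  keep <- keep & !boundary

  idx <- which(keep)
  winList <- lapply(leads, function(ld) {
    t(vapply(idx, function(i) sig[lo[i]:hi[i], ld], numeric(windowLen)))
  })
  names(winList) <- leads

  # flat on any extracted lead disqualifies the beat
  popSd <- function(M) {
    mu <- rowMeans(M)
    sqrt(rowMeans((M - mu)^2))
  }
  flat <- Reduce(`|`, lapply(winList, function(M) popSd(M) == 0))
  counts["flat"] <- sum(flat)
  idx <- idx[!flat]
  winList <- lapply(winList, function(M) M[!flat, , drop = FALSE])
  counts["retained"] <- length(idx)

  norm <- function(M) {
    if (nrow(M) == 0L) return(M)
    t(apply(M, 1L, normalizeBeat))
  }
  winList <- lapply(winList, norm)

  info <- data.frame(
    record_id  = rep(recordId(recording), length(idx)),
    beat_index = idx,
    r_sample   = beats$sample[idx],
    symbol     = beats$symbol[idx],
    aami_class = mapSymbolToAami(beats$symbol[idx], map),
    rr_prev_s  = rrf$rr_prev_s[idx],
    rr_ratio   = rrf$rr_ratio[idx],
    stringsAsFactors = FALSE
  )
  rownames(info) <- NULL

  new("BeatSet",
      leadA = winList[[1L]],
      leadB = if (length(leads) > 1L) winList[[2L]] else NULL,
      beatInfo = info,
      dropCounts = counts)
}

#' Concatenate BeatSets from several recordings
#'
#' @param ... [BeatSet-class] objects with identical window length and lead
#'   layout.
#' @return a single [BeatSet-class]; drop counts are summed.
#' @export
combineBeatSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "BeatSet"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, is, logical(1), "BeatSet")))
  wl <- vapply(sets, function(s) ncol(s@leadA), integer(1))
  if (length(unique(wl)) != 1L) stop("window lengths differ")
  hasB <- vapply(sets, function(s) !is.null(s@leadB), logical(1))
  if (length(unique(hasB)) != 1L) stop("lead layouts differ")
  new("BeatSet",
      leadA = do.call(rbind, lapply(sets, function(s) s@leadA)),
      leadB = if (hasB[1L]) do.call(rbind, lapply(sets, function(s) s@leadB)) else NULL,
      beatInfo = do.call(rbind, lapply(sets, function(s) s@beatInfo)),
      dropCounts = Reduce(`+`, lapply(sets, function(s) s@dropCounts)))
}

#' Write a beat table to CSV
#'
#' Emits the per-beat metadata (record id, beat index, R sample, AAMI
#' class, RR features) in a stable column order; the exact file is
#' reproducible from the same recording and seed.
#'
#' @param beats a [BeatSet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeBeatTable <- function(beats, path) {
  info <- beatInfo(beats)
  cols <- c("record_id", "beat_index", "r_sample", "aami_class",
            "rr_prev_s", "rr_ratio")
  out <- info[, cols]
  out$rr_prev_s <- sprintf("%.6f", out$rr_prev_s)
  out$rr_ratio  <- sprintf("%.6f", out$rr_ratio)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
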