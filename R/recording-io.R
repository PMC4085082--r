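# Plain-text recording format: a header, a signal table and an annotation
# table per record. Mirrors the header/signal/annotation triplet of the
# MIT-BIH waveform format but stays human-readable and diff-able so
# synthetic fixtures can live in version control.
#
#   <id>.hea      key/value lines: record, fs, samples, leads
#   <id>.sig.csv  one column per lead, one row per sample
#   <id>.ann.csv  columns: sample, symbol

#' Write a recording as a plain-text triplet
#'
#' @param recording an [EcgRecording-class].
#' @param dir output directory (created if missing).
#' @param digits signal decimal places kept (storage/precision trade-off).
#' @return the header path, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(recording, dir, digits = 4L) {
  stopifnot(is(recording, "EcgRecording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- recordId(recording)
  sig <- signalMatrix(recording)
  hea <- file.path(dir, paste0(id, ".hea"))
  writeLines(c(
    paste("record", id),
    paste("fs", format(samplingRate(recording))),
    paste("samples", nrow(sig)),
    paste("leads", paste(colnames(sig), collapse = " "))
  ), hea)
  out <- as.data.frame(round(sig, digits))
  utils::write.csv(out, file.path(dir, paste0(id, ".sig.csv")),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(annotations(recording)[, c("sample", "symbol")],
                   file.path(dir, paste0(id, ".ann.csv")),
                   row.names = FALSE, quote = FALSE)
  invisible(hea)
}

#' Read a plain-text recording triplet
#'
#' @param dir directory holding the triplet.
#' @param id record id (basename of the three files).
#' @param expectedRate if non-NULL, the sampling rate the caller's config
#'   assumes; a header that disagrees raises a validation error.
#' @return an [EcgRecording-class]. Annotations outside the signal are
#'   dropped with a warning.
#' @export
readRecording <- function(dir, id, expectedRate = NULL) {
  hea <- file.path(dir, paste0(id, ".hea"))
  sigPath <- file.path(dir, paste0(id, ".sig.csv"))
  annPath <- file.path(dir, paste0(id, ".ann.csv"))
  for (p in c(hea, sigPath, annPath))
    if (!file.exists(p)) stop("missing recording file: ", p, call. = FALSE)

  fields <- strsplit(readLines(hea), " +")
  names(fields) <- vapply(fields, `[`, character(1), 1L)
  fs <- as.numeric(fields[["fs"]][2L])
  nSamples <- as.integer(fields[["samples"]][2L])
  leads <- fields[["leads"]][-1L]
  if (!is.null(expectedRate) && !isTRUE(all.equal(fs, expectedRate)))
    stop("header sampling rate ", fs, " Hz differs from expected ",
         expectedRate, " Hz", call. = FALSE)

  sig <- as.matrix(utils::read.csv(sigPath))
  if (nrow(sig) != nSamples || !identical(colnames(sig), leads))
    stop("signal file inconsistent with header for record ", id, call. = FALSE)

  ann <- utils::read.csv(annPath, colClasses = c(sample = "integer",
                                                 symbol = "character"))
  bad <- ann$sample < 1L | ann$sample > nSamples
  if (any(bad)) {
    warning(sum(bad), " annotation(s) outside the signal dropped for record ",
            id, call. = FALSE)
    ann <- ann[!bad, , drop = FALSE]
    rownames(ann) <- NULL
  }

  new("EcgRecording", recordId = fields[["record"]][2L], signal = sig,
      samplingRate = fs, annotations = ann)
}

#' Read every recording of a dataset directory
#'
#' @param dir dataset directory written by [writeRecording()] /
#'   [writeDataset()].
#' @param ids record ids to read; default: every `*.hea` in `dir`.
#' @param expectedRate see [readRecording()].
#' @return named list of [EcgRecording-class] objects.
#' @export
readDataset <- function(dir, ids = NULL, expectedRate = NULL) {
  if (is.null(ids))
    ids <- sort(sub("\\.hea$", "", basename(Sys.glob(file.path(dir, "*.hea")))))
  if (!length(ids)) stop("no recordings found in ", dir, call. = FALSE)
  recs <- lapply(ids, function(id) readRecording(dir, id, expectedRate))
  names(recs) <- ids
  recs
}
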