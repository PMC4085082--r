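# Shared constants and small helpers.

#' AAMI beat classes
#'
#' The five-class beat taxonomy of the Association for the Advancement of
#' Medical Instrumentation: N (normal and bundle-branch-block), S
#' (supraventricular ectopic), V (ventricular ectopic), F (fusion),
#' Q (unknown/paced).
#'
#' @return character(5): `c("N","S","V","F","Q")`.
#' @export
aamiClasses <- function() c("N", "S", "V", "F", "Q")

#' Supported lead configurations
#'
#' @return character(3): `c("A","B","A+B")`, the canonical order used for
#'   tie-breaking in lead selection.
#' @export
leadConfigs <- function() c("A", "B", "A+B")

# Class priority used only to resolve voting ties that decision margins
# cannot: clinically critical classes first.
.classPriority <- c("V", "S", "N", "F", "Q")

# MIT-BIH annotation codes that mark rhythm changes, artifacts or other
# non-beat events; they are rejected before segmentation, not mapped to Q.
.nonBeatSymbols <- c("+", "~", "|", "!", "[", "]", "\"", "x", "s", "T",
                     "*", "D", "=", "@")

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Beat-symbol to AAMI-class lookup table
#'
#' The standard mapping of MIT-BIH single-character beat codes onto the five
#' AAMI classes, shipped as an editable CSV under `extdata` so sites using
#' other annotation dialects can extend it.
#'
#' @param path optional path to an alternative mapping CSV with columns
#'   `symbol` and `aami_class`.
#' @return data.frame with columns `symbol`, `aami_class`.
#' @export
defaultSymbolMap <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aami_symbol_map.csv",
                        package = "BeatEnsemble", mustWork = TRUE)
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "aami_class") %in% names(map)),
            all(map$aami_class %in% aamiClasses()))
  map
}

#' Inter-patient record split of the MIT-BIH arrhythmia database
#'
#' The standard division of the 48 records into a 22-record training set
#' (DS1), a 22-record testing set (DS2) and the four paced records that the
#' AAMI recommendation excludes. Stored as a CSV config table, not in code.
#'
#' @param path optional path to an alternative split CSV with columns
#'   `record` and `set` (values `DS1`, `DS2`, `excluded`).
#' @return list with character vectors `ds1`, `ds2`, `excluded`.
#' @export
mitdbSplit <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mitdb_split.csv",
                        package = "BeatEnsemble", mustWork = TRUE)
  tab <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("record", "set") %in% names(tab)))
  split <- list(ds1      = tab$record[tab$set == "DS1"],
                ds2      = tab$record[tab$set == "DS2"],
                excluded = tab$record[tab$set == "excluded"])
  if (length(intersect(split$ds1, split$ds2)))
    stop("DS1 and DS2 must be disjoint")
  if (anyDuplicated(tab$record))
    stop("duplicate record ids in split table")
  split
}
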