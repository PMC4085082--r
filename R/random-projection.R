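# Random-projection feature extraction: beats are represented by their
# least-squares coefficients on the row space of seeded Gaussian matrices.

#' Generate a seeded bank of Gaussian random matrices
#'
#' Draws M independent d-by-m matrices with i.i.d. standard-normal entries.
#' The same seed always yields a bit-identical bank, so feature extraction
#' is reproducible across sessions and machines sharing one RNG kind.
#' Row rank is verified at generation (a Gaussian matrix is full rank
#' almost surely; a failing draw is replaced).
#'
#' @param M number of matrices (ensemble views), default 15.
#' @param d projection dimension (rows; the number of random signals),
#'   default 50.
#' @param m beat window length (columns), default 200; must exceed `d`.
#' @param seed integer seed.
#' @return a [RandomMatrixBank-class].
#' @examples
#' bank <- generateBank(M = 2, d = 4, m = 10, seed = 1)
#' @export
generateBank <- function(M = 15L, d = 50L, m = 200L, seed = 1L) {
  M <- as.integer(M); d <- as.integer(d); m <- as.integer(m)
  if (M < 1L) stop("need at least one matrix", call. = FALSE)
  if (d >= m) stop("projection must reduce dimension: d < m", call. = FALSE)
  mats <- withSeed(seed, {
    lapply(seq_len(M), function(k) {
      for (try in 1:5) {
        A <- matrix(stats::rnorm(d * m), d, m)
        if (.fullRowRank(A)) return(A)
      }
      stop("failed to draw a full-rank matrix", call. = FALSE)
    })
  })
  new("RandomMatrixBank", matrices = mats, M = M, d = d, m = m,
      seed = as.integer(seed))
}

# Row-rank check with singular-value tolerance m * eps * sigma_max.
.fullRowRank <- function(A) {
  sv <- svd(A, nu = 0, nv = 0)$d
  tol <- ncol(A) * .Machine$double.eps * sv[1L]
  sum(sv > tol) == nrow(A)
}

#' Project beats onto a random matrix
#'
#' In `pinv` mode (the default) each beat row x of `X` is mapped to the
#' least-squares coefficient vector f minimizing ||x - f A|| over the row
#' space of `A`, i.e. `F = X %*% pinv(A)` with the Moore-Penrose
#' pseudo-inverse — the sensing-matrix reading of random-projection
#' feature extraction. `transpose` mode computes the classical random
#' projection `F = X %*% t(A)`; the two coincide when the rows of `A` are
#' orthonormal.
#'
#' @param X numeric n-by-m matrix of beat windows (rows are beats).
#' @param A numeric d-by-m random matrix, full row rank.
#' @param mode `"pinv"` (least-squares coefficients) or `"transpose"`.
#' @return numeric n-by-d feature matrix.
#' @examples
#' A <- matrix(rnorm(40), 4, 10)
#' X <- matrix(rnorm(30), 3, 10)
#' F <- projectBeats(X, A)
#' @export
projectBeats <- function(X, A, mode = c("pinv", "transpose")) {
  mode <- match.arg(mode)
  X <- rbind(X)  # promote a single beat vector
  if (ncol(X) != ncol(A))
    stop("beat length ", ncol(X), " does not match matrix columns ", ncol(A),
         call. = FALSE)
  if (mode == "transpose") return(X %*% t(A))
  if (!.fullRowRank(A))
    stop("rank-deficient projection matrix", call. = FALSE)
  X %*% MASS::ginv(A)
}

#' Build the M feature groups of a BeatSet
#'
#' For every matrix in the bank, projects the configured lead(s) and
#' appends the preceding RR interval (seconds, unscaled) as the last
#' column: d+1 features for a single lead, 2d+1 for `"A+B"` (lead A
#' coefficients, then lead B, then RR). Group k of the output is produced
#' by bank matrix k, and beat i occupies row i of every group.
#'
#' @param beats a [BeatSet-class].
#' @param bank a [RandomMatrixBank-class] whose column count matches the
#'   beat window length.
#' @param leadConfig `"A"`, `"B"` or `"A+B"`.
#' @param mode projection mode, see [projectBeats()].
#' @return list of M numeric feature matrices.
#' @export
featurize <- function(beats, bank, leadConfig = c("A", "B", "A+B"),
                      mode = "pinv") {
  leadConfig <- match.arg(leadConfig)
  stopifnot(is(beats, "BeatSet"), is(bank, "RandomMatrixBank"))
  useLeads <- if (leadConfig == "A+B") c("A", "B") else leadConfig
  if ("B" %in% useLeads && is.null(beats@leadB))
    stop("lead configuration ", leadConfig,
         " requires lead B windows", call. = FALSE)
  Xs <- lapply(useLeads, function(ld) beatMatrix(beats, ld))
  rr <- beatInfo(beats)$rr_prev_s
  lapply(bankMatrices(bank), function(A) {
    parts <- lapply(Xs, projectBeats, A = A, mode = mode)
    out <- cbind(do.call(cbind, parts), rr)
    colnames(out) <- NULL
    out
  })
}
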