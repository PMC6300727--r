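#' Symmetrize a tractography connection-probability matrix
#'
#' Probabilistic tractography is directional, so the raw connection
#' probability from region i to j generally differs from j to i. The
#' connection probability of the pair is taken as the arithmetic mean of the
#' two directions; the diagonal (self-connections) is set to zero.
#'
#' @param P square non-negative numeric matrix of connection probabilities.
#' @return symmetric matrix of pairwise connection probabilities.
#' @export
symmetrize_probabilities <- function(P) {
  if (!is.matrix(P) || !is.numeric(P)) stop("`P` must be a numeric matrix", call. = FALSE)
  if (nrow(P) != ncol(P)) stop("`P` must be square", call. = FALSE)
  if (anyNA(P)) stop("`P` contains missing values", call. = FALSE)
  if (any(P < 0)) stop("`P` must be non-negative", call. = FALSE)
  S <- (P + t(P)) / 2
  diag(S) <- 0
  S
}

#' Normalise a symmetric probability matrix into structural edge weights
#'
#' Maps each positive connection probability p through
#' `w = (log p - min log p) / (max log p - min log p)`, where the minimum and
#' maximum are taken over the positive off-diagonal entries. This puts every
#' subject's structural connectome on a common `[0, 1]` weight scale
#' regardless of individual differences in overall connection probability
#' (the log min-max form is invariant to global rescaling of the
#' probabilities).
#'
#' Zero probabilities are non-edges: the log is undefined at 0, so zeros are
#' excluded from the min/max and remain weight-0 non-edges. A consequence of
#' the min-max form is that the smallest positive probability maps to weight
#' exactly 0 (its edge class is removed) and the largest to exactly 1.
#'
#' @param P_sym symmetric non-negative probability matrix (see
#'   [symmetrize_probabilities()]).
#' @param labels optional node labels.
#' @return an `"SC"` [connectome()].
#' @export
normalize_sc <- function(P_sym, labels = NULL) {
  if (!is.matrix(P_sym) || nrow(P_sym) != ncol(P_sym)) {
    stop("`P_sym` must be a square matrix", call. = FALSE)
  }
  if (max(abs(P_sym - t(P_sym))) > 1e-10) {
    stop("`P_sym` must be symmetric; call symmetrize_probabilities() first",
         call. = FALSE)
  }
  off <- upper.tri(P_sym)
  pos <- P_sym[off][P_sym[off] > 0]
  if (length(pos) < 2) stop("need at least two positive off-diagonal entries",
                            call. = FALSE)
  lo <- log(min(pos)); hi <- log(max(pos))
  if (hi - lo < .Machine$double.eps * 100) {
    stop("all positive probabilities are equal: normalisation denominator is zero",
         call. = FALSE)
  }
  W <- matrix(0, nrow(P_sym), ncol(P_sym))
  nz <- P_sym > 0
  W[nz] <- (log(P_sym[nz]) - lo) / (hi - lo)
  diag(W) <- 0
  if (is.null(labels)) labels <- colnames(P_sym)
  connectome(W, "SC", labels = labels)
}

#' Build a functional connectome from region-averaged BOLD time series
#'
#' Edge weights are the absolute Pearson correlations `|r_ij|` between the
#' time series of every region pair; the result is a symmetric, unsigned,
#' weighted functional connectivity network with zero diagonal. Folding
#' negative correlations by the absolute value treats anti-correlated region
#' pairs as functionally connected; no signed-network option is offered.
#'
#' @param ts numeric T x N matrix, rows = time points, columns = regions.
#' @return an `"FC"` [connectome()].
#' @export
build_fc <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts)) stop("`ts` must be a numeric matrix", call. = FALSE)
  if (nrow(ts) <= 3) stop("need more than 3 time points", call. = FALSE)
  if (anyNA(ts)) stop("`ts` contains missing values", call. = FALSE)
  v <- apply(ts, 2, sd)
  if (any(v == 0)) {
    bad <- colnames(ts)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance BOLD series in region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Z <- abs(cor(ts))
  diag(Z) <- 0
  connectome(Z, "FC", labels = colnames(ts))
}
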