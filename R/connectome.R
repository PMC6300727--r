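#' @useDynLib costnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rnorm runif rbinom quantile sd lm pf pt pnorm aov
#'   chisq.test t.test p.adjust shapiro.test as.formula coef resid
#' @importFrom utils write.table read.table head
NULL

#' Construct a connectome object
#'
#' A connectome is a symmetric, non-negatively weighted adjacency matrix over
#' parcellated brain regions with a zero diagonal (no self-connections) and a
#' modality tag: `"SC"` for structural (tractography-derived) networks, whose
#' weights are log-min-max normalised connection probabilities in `[0, 1]`,
#' or `"FC"` for functional networks, whose weights are absolute Pearson
#' correlations of regional BOLD signals, also in `[0, 1]`.
#'
#' @param weights square numeric matrix of edge weights.
#' @param modality `"SC"` or `"FC"`.
#' @param labels optional character vector of node labels; defaults to
#'   existing dimnames or `ROI001, ROI002, ...`.
#' @param tol numeric tolerance used when checking symmetry.
#' @return a `connectome`: the weight matrix with class and modality attached.
#' @export
connectome <- function(weights, modality = c("SC", "FC"), labels = NULL,
                       tol = 1e-10) {
  modality <- match.arg(modality)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(weights)
  if (ncol(weights) != n) stop("`weights` must be square", call. = FALSE)
  if (n < 2) stop("a connectome needs at least 2 nodes", call. = FALSE)
  if (anyNA(weights)) stop("`weights` contains missing values", call. = FALSE)
  if (any(weights < 0)) stop("`weights` must be non-negative", call. = FALSE)
  if (max(abs(weights - t(weights))) > tol) {
    stop("`weights` must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(weights)) > tol)) {
    stop("diagonal (self-connections) must be zero", call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(labels)) labels <- colnames(weights)
  if (is.null(labels)) labels <- default_node_labels(n)
  if (length(labels) != n) stop("`labels` length must match node count", call. = FALSE)
  dimnames(weights) <- list(labels, labels)
  structure(weights, class = c("connectome", "matrix", "array"),
            modality = modality)
}

#' @rdname connectome
#' @param x object to test or print.
#' @export
is_connectome <- function(x) inherits(x, "connectome")

#' @export
print.connectome <- function(x, ...) {
  w <- unclass(x)
  nz <- sum(w[upper.tri(w)] > 0)
  n <- nrow(w)
  cat(sprintf("<connectome> %s, %d nodes, %d edges (density %.3f)\n",
              attr(x, "modality"), n, nz, nz / (n * (n - 1) / 2)))
  invisible(x)
}

#' Modality of a connectome
#' @param G a `connectome`.
#' @return `"SC"` or `"FC"`.
#' @export
modality <- function(G) attr(G, "modality")

default_node_labels <- function(n) sprintf("ROI%03d", seq_len(n))

# strip class so plain matrix arithmetic applies
conn_weights <- function(G) {
  w <- unclass(G)
  attr(w, "modality") <- NULL
  w
}

#' Read / write square matrices and time series as tab-separated text
#'
#' One file dialect is used throughout: tab-separated values with a header
#' row of node labels and no row names. `read_matrix_tsv()` expects a full
#' square matrix; `read_ts_tsv()` expects a T x N time-series table.
#'
#' @param path file path.
#' @return `read_matrix_tsv()`: a numeric matrix with dimnames;
#'   `read_ts_tsv()`: a numeric matrix (rows = time points).
#' @export
read_matrix_tsv <- function(path) {
  x <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  if (nrow(x) != ncol(x)) stop("file does not contain a square matrix: ", path,
                               call. = FALSE)
  rownames(x) <- colnames(x)
  x
}

#' @rdname read_matrix_tsv
#' @param x matrix to write.
#' @export
write_matrix_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname read_matrix_tsv
#' @export
read_ts_tsv <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t", check.names = FALSE))
}

# run expr with a temporarily-seeded RNG, restoring the caller's stream
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# deterministic per-unit seed derivation from a base seed (kept below 2^31)
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(counter)) %% 2147483647)
}
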