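# Structure-function coupling: edge-wise correlation between the structural
# and functional connectome over structurally present connections.

#' Element-wise mean connectome of a cohort
#'
#' @param cohort non-empty list of [connectome()]s of equal size and one
#'   modality.
#' @return a [connectome()] of the same modality.
#' @export
group_mean_connectome <- function(cohort) {
  if (length(cohort) == 0) stop("`cohort` is empty", call. = FALSE)
  mods <- unique(vapply(cohort, modality, character(1)))
  if (length(mods) != 1) stop("cohort mixes modalities", call. = FALSE)
  dims <- unique(vapply(cohort, nrow, integer(1)))
  if (length(dims) != 1) stop("cohort mixes matrix sizes", call. = FALSE)
  M <- Reduce(`+`, lapply(cohort, conn_weights)) / length(cohort)
  connectome(M, mods, labels = colnames(cohort[[1]]))
}

#' Structure-function coupling of an SC/FC pair
#'
#' Pearson correlation between structural and functional edge weights over
#' the upper-triangle positions where the structural connectome is non-zero.
#' The mask comes from the unthresholded normalised SC; higher coupling
#' means functional connectivity more tightly constrained by the anatomical
#' backbone. Note the masked edges are not independent observations; the
#' edge count `n_edges` is reported so downstream inferences on it can be
#' audited.
#'
#' @param sc structural [connectome()] (or matrix) supplying the edge mask.
#' @param fc functional [connectome()] (or matrix) of the same dimension.
#' @return one-row tibble with columns `r` and `n_edges`.
#' @export
coupling <- function(sc, fc) {
  Ws <- as_weight_matrix(sc)
  Wf <- as_weight_matrix(fc)
  if (!all(dim(Ws) == dim(Wf))) stop("SC and FC dimensions differ", call. = FALSE)
  mask <- upper.tri(Ws) & Ws > 0
  n_edges <- sum(mask)
  if (n_edges < 3) stop("need at least 3 non-zero SC edges", call. = FALSE)
  x <- Ws[mask]; y <- Wf[mask]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance over the masked edges", call. = FALSE)
  }
  tibble::tibble(r = cor(x, y), n_edges = n_edges)
}

#' Individual-level coupling for a cohort
#'
#' One coupling value per subject, each constrained to that subject's own
#' non-zero SC edges.
#'
#' @param sc_list,fc_list parallel lists of subject connectomes.
#' @param subject_id optional subject identifiers.
#' @return tibble with `subject_id`, `r`, `n_edges`.
#' @export
individual_coupling <- function(sc_list, fc_list, subject_id = NULL) {
  if (length(sc_list) != length(fc_list)) {
    stop("SC and FC lists differ in length", call. = FALSE)
  }
  if (is.null(subject_id)) subject_id <- sprintf("S%03d", seq_along(sc_list))
  purrr::map_dfr(seq_along(sc_list), function(s) {
    dplyr::bind_cols(tibble::tibble(subject_id = subject_id[s]),
                     coupling(sc_list[[s]], fc_list[[s]]))
  })
}

#' Fisher z test comparing two correlation coefficients
#'
#' Tests equality of two independent correlations via the variance-
#' stabilising Fisher transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed p-value from the standard normal.
#'
#' @param r1,r2 correlations with `|r| < 1`.
#' @param n1,n2 the sample sizes behind each correlation (each > 3).
#' @return one-row tibble with columns `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stop("|r| must be < 1", call. = FALSE)
  if (any(c(n1, n2) <= 3)) stop("sample sizes must exceed 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}
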