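# Synthetic three-group connectome cohort generator.
#
# Emulates, at the matrix level, the inputs of a cross-sectional ageing
# cohort with no cognitive impairment (NCI), mild and moderate impairment
# groups: per-subject tractography connection-probability matrices,
# region-averaged BOLD time series, demographic covariates and seven
# cognitive-domain z-scores. Ground-truth effects (a structural long-range
# deficit, a group gradient in structure-function coupling, and
# cognition-metric couplings) are injected with known sizes so that the
# downstream pipeline can be power-checked. All distributional choices are
# stand-ins chosen to be realistic at the summary-statistic level; the
# generator makes no claim about the true generative process of imaging
# data.

#' Simulation configuration
#'
#' Defaults emulate the target study scale: 126 brain regions, group sizes
#' 97/61/56 (NCI / mild / moderate), and 125 time points (a 5-minute
#' task-free run at TR 2.3 s). The structural backbone is a ring lattice
#' with distance-decaying connection probability plus distance-independent
#' shortcuts, which keeps thresholded networks in the small-world regime;
#' edges spanning a ring distance greater than N/8 are considered
#' "long-range" and are attenuated by `sc_deficit` in the impaired groups.
#' The functional covariance of each subject blends the subject's own
#' structural connectome (weight `alpha`, the ground-truth coupling) with a
#' cohort-level structured component (weight `1 - alpha`).
#'
#' @param n_nodes number of brain regions (>= 2).
#' @param n_subjects_per_group named vector of group sizes (NCI, mild,
#'   moderate); a scalar is recycled.
#' @param n_timepoints BOLD time points per subject (> 3).
#' @param backbone list of backbone parameters: `lambda` (ring-distance
#'   decay scale of connection existence), `p_far` (shortcut probability),
#'   `w_base`, `w_slope`, `w_sd` (logistic-normal weight model), `asym_sd`
#'   (directional asymmetry), `n_factors` (rank of the structured
#'   functional component).
#' @param sc_deficit named per-group multiplier on long-range connection
#'   probabilities (1 = intact). Defaults are calibrated by simulation at
#'   the default scale so the moderate-vs-NCI deficit in composite
#'   structural global efficiency is about Cohen's d = 0.4 (the magnitude a
#'   t of about -2.5 implies at these group sizes), with mild intermediate.
#' @param coupling_alpha named per-group mean of the SC-to-functional
#'   covariance mixing weight, in `[0, 1]`; calibrated by simulation so
#'   group-level coupling sits near the 0.43 / 0.45 / 0.48 ladder.
#' @param alpha_sd between-subject SD of the mixing weight.
#' @param cognition_effects list with named vectors `e_glob` and `alpha`:
#'   linear coefficients (per SD of the true quantity) on each of the seven
#'   domain z-scores.
#' @param noise_sd residual SD of the domain z-scores.
#' @param seed integer RNG seed; the whole cohort is a pure function of
#'   (config, seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_nodes = 126,
                       n_subjects_per_group = c(NCI = 97, mild = 61, moderate = 56),
                       n_timepoints = 125,
                       backbone = list(),
                       sc_deficit = c(NCI = 1, mild = 0.988, moderate = 0.971),
                       coupling_alpha = c(NCI = 0.562, mild = 0.575, moderate = 0.590),
                       alpha_sd = 0.04,
                       cognition_effects = default_cognition_effects(),
                       noise_sd = 0.6,
                       seed = 1L) {
  groups <- c("NCI", "mild", "moderate")
  if (length(n_subjects_per_group) == 1) {
    n_subjects_per_group <- stats::setNames(rep(n_subjects_per_group, 3), groups)
  }
  if (is.null(names(n_subjects_per_group))) {
    names(n_subjects_per_group) <- groups
  }
  bb <- utils::modifyList(list(lambda = n_nodes / 10, p_far = 0.35,
                               p_far_sd = 0.02, w_base = 0.5, w_slope = 6,
                               w_sd = 0.6, asym_sd = 0.05, n_factors = 8),
                          backbone)
  cfg <- list(n_nodes = as.integer(n_nodes),
              n_subjects_per_group = n_subjects_per_group,
              n_timepoints = as.integer(n_timepoints),
              backbone = bb, sc_deficit = sc_deficit,
              coupling_alpha = coupling_alpha, alpha_sd = alpha_sd,
              cognition_effects = cognition_effects, noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  if (any(cfg$n_subjects_per_group < 2)) stop("each group needs >= 2 subjects",
                                              call. = FALSE)
  if (cfg$n_timepoints <= 3) stop("n_timepoints must be > 3", call. = FALSE)
  if (any(cfg$coupling_alpha < 0 | cfg$coupling_alpha > 1)) {
    stop("coupling_alpha must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$sc_deficit <= 0 | cfg$sc_deficit > 1)) {
    stop("sc_deficit must lie in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Default cognition-effect coefficients
#'
#' Positive loadings of true structural global efficiency on executive
#' function and visual memory (echoing the association pattern the pipeline
#' is designed to detect), and negative loadings of true coupling on visual
#' memory, executive function and visuoconstruction. Units: domain SDs per
#' SD of the true quantity; magnitudes are calibrated so the adjusted
#' association t statistics at the default cohort scale sit in the 3-4
#' range typical of such cohort studies.
#'
#' @return list with vectors `e_glob` and `alpha` over [cognitive_domains()].
#' @export
default_cognition_effects <- function() {
  d <- cognitive_domains()
  e <- stats::setNames(rep(0.06, 7), d)
  e[c("executive", "visual_memory")] <- c(0.15, 0.13)
  a <- stats::setNames(rep(-0.04, 7), d)
  a[c("visual_memory", "executive", "visuoconstruction")] <- c(-0.16, -0.10, -0.11)
  list(e_glob = e, alpha = a)
}

ring_distance <- function(n) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  pmin(d, n - d)
}

#' Long-range edge indicator
#'
#' Edges spanning a ring (node-index) distance greater than `n/8` are the
#' generator's deterministic surrogate for anatomically long-range
#' connections.
#'
#' @param n node count.
#' @return logical n x n matrix.
#' @export
long_range_mask <- function(n) ring_distance(n) > n / 8

#' Generate one subject's tractography connection-probability matrix
#'
#' Connection existence decays with ring distance (`p_far` keeps
#' distance-independent shortcuts); probabilities follow a logistic-normal
#' model decaying with distance, with a small independent directional
#' perturbation so that `P_ij != P_ji` (as in real tractography output).
#' Long-range connection probabilities are multiplied by the group's
#' `sc_deficit`.
#'
#' @param config a [sim_config()].
#' @param group `"NCI"`, `"mild"` or `"moderate"`.
#' @param seed integer seed for this subject.
#' @return n x n matrix of connection probabilities in `[0, 1]`, zero
#'   diagonal, mildly asymmetric.
#' @export
generate_sc_probabilities <- function(config, group = "NCI", seed = 1L) {
  n <- config$n_nodes
  bb <- config$backbone
  with_preserved_seed(seed, {
    d <- ring_distance(n)
    # subject-level heterogeneity in long-range connectivity richness
    p_far_s <- min(max(rnorm(1, bb$p_far, bb$p_far_sd), 0.02), 0.95)
    p_exist <- p_far_s + (1 - p_far_s) * exp(-d / bb$lambda)
    u <- matrix(0, n, n)
    u[upper.tri(u)] <- runif(n * (n - 1) / 2)
    exist <- (u < p_exist) & upper.tri(u)
    exist <- exist | t(exist)
    eps_sym <- matrix(0, n, n)
    eps_sym[upper.tri(eps_sym)] <- rnorm(n * (n - 1) / 2, sd = bb$w_sd)
    eps_sym <- eps_sym + t(eps_sym)
    eps_asym <- matrix(rnorm(n * n, sd = bb$asym_sd), n, n)
    P <- stats::plogis(bb$w_base - bb$w_slope * d / n + eps_sym + eps_asym)
    deficit <- config$sc_deficit[[group]]
    if (deficit < 1) P[long_range_mask(n)] <- P[long_range_mask(n)] * deficit
    P[!exist] <- 0
    diag(P) <- 0
    dimnames(P) <- list(default_node_labels(n), default_node_labels(n))
    P
  })
}

#' Cohort-level structured functional component
#'
#' A fixed low-rank-plus-diagonal correlation matrix shared by every
#' subject in a cohort; it supplies the `1 - alpha` share of the functional
#' covariance, so groups differ only through `alpha` and the structural
#' deficit.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return n x n correlation matrix.
#' @export
structured_component <- function(config, seed) {
  n <- config$n_nodes
  q <- config$backbone$n_factors
  with_preserved_seed(seed, {
    B <- matrix(rnorm(n * q, sd = 0.4), n, q)
    stats::cov2cor(tcrossprod(B) + diag(n))
  })
}

#' Generate one subject's BOLD time series
#'
#' Draws T x N zero-mean Gaussian series whose covariance is the blend
#' `alpha * C_sc + (1 - alpha) * structured`, where `C_sc` is the subject's
#' normalised structural connectome rescaled into a valid correlation matrix
#' (unit diagonal; eigenvalues clipped from below at 0.01, since a dense
#' weight matrix plus identity is generally indefinite). If the blend is
#' still not positive definite it is repaired by adding the smallest ridge
#' that lifts the minimum eigenvalue to 1e-8.
#'
#' @param config a [sim_config()].
#' @param subject_sc the subject's normalised structural [connectome()]
#'   (or symmetric weight matrix).
#' @param alpha mixing weight in `[0, 1]`.
#' @param structured cohort [structured_component()].
#' @param seed integer seed for this subject.
#' @return T x N matrix of BOLD signals.
#' @export
generate_bold <- function(config, subject_sc, alpha, structured, seed) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  W <- as_weight_matrix(subject_sc)
  n <- nrow(W)
  # scaled-SC correlation component: I + W is generally indefinite for dense
  # weight matrices, so project to the nearest-in-spirit valid correlation by
  # clipping eigenvalues from below before rescaling to unit diagonal
  C_sc <- W
  diag(C_sc) <- 1
  e <- eigen(C_sc, symmetric = TRUE)
  if (min(e$values) < 0.01) {
    C_sc <- stats::cov2cor(e$vectors %*% (pmax(e$values, 0.01) * t(e$vectors)))
  }
  Sigma <- alpha * C_sc + (1 - alpha) * structured
  if (anyNA(Sigma) || any(!is.finite(Sigma))) {
    stop("covariance blend is not repairable to positive-definite", call. = FALSE)
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    Sigma <- Sigma + diag(1e-8 - min(ev), n)
  }
  R <- chol(Sigma)
  with_preserved_seed(seed, {
    X <- matrix(rnorm(config$n_timepoints * n), config$n_timepoints, n) %*% R
    colnames(X) <- colnames(W)
    if (is.null(colnames(X))) colnames(X) <- default_node_labels(n)
    X
  })
}

# Table-style per-group demographic profiles (age mean/sd/range, proportion
# female, proportion right-handed) echoing the target cohort.
group_demographics <- function() {
  list(
    NCI = list(age_mean = 67.0, age_sd = 4.7, age_range = c(60, 86),
               p_female = 42 / 97, p_right = 94 / 97),
    mild = list(age_mean = 71.0, age_sd = 6.4, age_range = c(60, 84),
                p_female = 33 / 61, p_right = 61 / 61),
    moderate = list(age_mean = 74.0, age_sd = 5.3, age_range = c(62, 85),
                    p_female = 40 / 56, p_right = 54 / 56)
  )
}

#' Generate covariates and cognitive scores for a cohort
#'
#' Ages are drawn per group from truncated normal profiles echoing an
#' ageing CIND cohort (NCI mean 67, moderate mean 74); gender and
#' handedness are categorical draws with per-group proportions. Each domain
#' z-score is a linear function of the subject's true (cohort-standardised)
#' structural global efficiency and true coupling weight, per
#' `config$cognition_effects`, plus Gaussian noise — so group differences
#' in cognition arise only through the injected network effects.
#'
#' @param config a [sim_config()].
#' @param truths tibble with columns `subject_id`, `group`, `alpha_true`,
#'   `e_glob_true` (one row per subject).
#' @param seed integer seed.
#' @return tibble: identifiers, covariates and the seven domain z-scores.
#' @export
generate_covariates_and_cognition <- function(config, truths, seed) {
  dem <- group_demographics()
  n <- nrow(truths)
  eff <- config$cognition_effects
  with_preserved_seed(seed, {
    age <- numeric(n); gender <- character(n); handed <- character(n)
    for (s in seq_len(n)) {
      pr <- dem[[truths$group[s]]]
      age[s] <- pmin(pmax(rnorm(1, pr$age_mean, pr$age_sd), pr$age_range[1]),
                     pr$age_range[2])
      gender[s] <- if (runif(1) < pr$p_female) "F" else "M"
      handed[s] <- if (runif(1) < pr$p_right) "R" else "L"
    }
    zE <- as.numeric(scale(truths$e_glob_true))
    zA <- as.numeric(scale(truths$alpha_true))
    if (anyNA(zE)) zE <- rep(0, n)   # degenerate: no between-subject spread
    if (anyNA(zA)) zA <- rep(0, n)
    doms <- sapply(cognitive_domains(), function(d) {
      eff$e_glob[[d]] * zE + eff$alpha[[d]] * zA + rnorm(n, sd = config$noise_sd)
    })
    out <- tibble::tibble(subject_id = truths$subject_id,
                          group = truths$group, age = age, gender = gender,
                          handedness = handed)
    dplyr::bind_cols(out, tibble::as_tibble(doms))
  })
}

#' Simulate a full synthetic cohort
#'
#' Pure function of `(config, config$seed)`: generates, for every subject,
#' the tractography probability matrix, the normalised structural
#' connectome, the ground-truth coupling weight, the BOLD time series, and
#' finally the covariate / cognition table. The per-subject RNG streams are
#' split from the cohort seed by subject counter, so subject k's data do
#' not change when the group sizes change.
#'
#' @param config a [sim_config()].
#' @param with_bold generate BOLD series (default). Setting `FALSE` skips
#'   the functional stage (the `bold` list is `NULL`) without changing any
#'   other draw, for structural-only simulation studies.
#' @return object of class `sim_cohort`: list with `config`, `subjects`
#'   (cohort table including ground-truth columns `alpha_true`,
#'   `e_glob_true`), `sc_prob`, `sc`, `bold` (per-subject lists) and
#'   `structured` (the shared functional component).
#' @export
simulate_cohort <- function(config = sim_config(), with_bold = TRUE) {
  validate_sim_config(config)
  groups <- rep(names(config$n_subjects_per_group), config$n_subjects_per_group)
  n_sub <- length(groups)
  structured <- if (with_bold) {
    structured_component(config, derive_seed(config$seed, 1))
  } else NULL
  sc_prob <- vector("list", n_sub)
  sc <- vector("list", n_sub)
  bold <- vector("list", n_sub)
  alpha_true <- numeric(n_sub)
  e_glob_true <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    g <- groups[s]
    sc_prob[[s]] <- generate_sc_probabilities(config, g,
                                              derive_seed(config$seed, 1000 + s))
    sc[[s]] <- normalize_sc(symmetrize_probabilities(sc_prob[[s]]))
    a <- with_preserved_seed(derive_seed(config$seed, 2000 + s),
                             rnorm(1, config$coupling_alpha[[g]], config$alpha_sd))
    alpha_true[s] <- pmin(pmax(a, 0), 1)
    if (with_bold) {
      bold[[s]] <- generate_bold(config, sc[[s]], alpha_true[s], structured,
                                 derive_seed(config$seed, 3000 + s))
    }
    e_glob_true[s] <- global_efficiency(sc[[s]])
  }
  truths <- tibble::tibble(subject_id = sprintf("S%03d", seq_len(n_sub)),
                           group = groups, alpha_true = alpha_true,
                           e_glob_true = e_glob_true)
  subjects <- generate_covariates_and_cognition(config, truths,
                                                derive_seed(config$seed, 2))
  subjects$alpha_true <- alpha_true
  subjects$e_glob_true <- e_glob_true
  structure(list(config = config, subjects = subjects, sc_prob = sc_prob,
                 sc = sc, bold = if (with_bold) bold else NULL,
                 structured = structured),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects (%s), %d nodes, %d time points\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(x$config$n_subjects_per_group),
                            x$config$n_subjects_per_group), collapse = ", "),
              x$config$n_nodes, x$config$n_timepoints))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Per-subject probability matrices and BOLD series as tab-separated text
#' (full square matrix with a header row of node labels), the cohort table
#' as CSV, and the ground truth as a JSON sidecar.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$subjects$subject_id
  for (s in seq_along(ids)) {
    write_matrix_tsv(cohort$sc_prob[[s]],
                     file.path(dir, paste0(ids[s], "_sc_prob.tsv")))
    write_matrix_tsv(cohort$bold[[s]],
                     file.path(dir, paste0(ids[s], "_bold.tsv")))
  }
  utils::write.csv(cohort$subjects[, setdiff(names(cohort$subjects),
                                             c("alpha_true", "e_glob_true"))],
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  gt <- list(seed = cohort$config$seed,
             sc_deficit = as.list(cohort$config$sc_deficit),
             coupling_alpha_group = as.list(cohort$config$coupling_alpha),
             alpha_true = stats::setNames(as.list(cohort$subjects$alpha_true), ids),
             e_glob_true = stats::setNames(as.list(cohort$subjects$e_glob_true), ids))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
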