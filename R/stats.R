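# Group and cognition statistics: covariate-adjusted linear models on
# composite network measures, per-node exploratory tests, cognitive-domain
# associations with Bonferroni control, and cohort demographics tests.

#' The seven cognitive domains
#'
#' Column names used for the domain-specific z-scores throughout the
#' package: executive function, attention, language, verbal memory, visual
#' memory, visuoconstruction and visuomotor speed.
#'
#' @return character vector of length 7.
#' @export
cognitive_domains <- function() {
  c("executive", "attention", "language", "verbal_memory", "visual_memory",
    "visuoconstruction", "visuomotor_speed")
}

# assemble the model frame, dropping covariates that are constant in it
glm_frame <- function(data, y, covariates) {
  df <- data.frame(.y = y, group = factor(data$group),
                   data[covariates], check.names = FALSE)
  keep <- vapply(covariates, function(v) length(unique(df[[v]])) > 1, logical(1))
  attr(df, "covariates") <- covariates[keep]
  df
}

#' Covariate-adjusted group contrast on a per-subject measure
#'
#' Ordinary least squares of a per-subject scalar on dummy-coded group plus
#' the nuisance covariates (by default age, gender and handedness). The
#' requested pairwise contrast is read off by re-referencing the group
#' factor to `contrast[2]`, so the reported t statistic tests
#' `contrast[1] - contrast[2]` adjusted for the covariates, with all groups
#' contributing to the error term. Covariates constant across the cohort are
#' dropped (a covariate uniform within one group only is retained as usual).
#'
#' @param data data frame / tibble with a `group` column and the covariates.
#' @param y per-subject response: a numeric vector or the name of a column
#'   of `data`.
#' @param contrast character pair `c(level_tested, reference)`.
#' @param covariates nuisance covariate column names.
#' @return one-row tibble: `contrast`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `df`, `n`.
#' @export
fit_glm <- function(data, y, contrast,
                    covariates = c("age", "gender", "handedness")) {
  if (is.character(y) && length(y) == 1) y <- data[[y]]
  if (length(y) != nrow(data)) stop("`y` length must match `data`", call. = FALSE)
  if (!all(contrast %in% data$group)) {
    stop("contrast levels not present in `group`", call. = FALSE)
  }
  df <- glm_frame(data, y, covariates)
  covs <- attr(df, "covariates")
  df$group <- stats::relevel(df$group, ref = contrast[2])
  rhs <- paste(c("group", covs), collapse = " + ")
  fit <- lm(as.formula(paste(".y ~", rhs)), data = df)
  if (fit$df.residual < 2) {
    stop("too few subjects for the model size", call. = FALSE)
  }
  term <- paste0("group", contrast[1])
  cf <- summary(fit)$coefficients
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design: perfectly collinear predictors", call. = FALSE)
  }
  n_obs <- nrow(df)
  tibble::tibble(
    contrast = paste(contrast[1], "-", contrast[2]),
    estimate = cf[term, "Estimate"],
    std_error = cf[term, "Std. Error"],
    statistic = cf[term, "t value"],
    p_value = cf[term, "Pr(>|t|)"],
    df = fit$df.residual,
    n = n_obs
  )
}

#' Exploratory per-node group contrasts
#'
#' Fits one covariate-adjusted group GLM per node on the composite nodal
#' measures and flags nodes with `p < alpha` (default 0.01, uncorrected for
#' the number of nodes — exploratory, as conventional for nodal connectome
#' comparisons).
#'
#' @param nodal subject x node numeric matrix (or data frame) of composite
#'   nodal measures, rows aligned with `data`.
#' @inheritParams fit_glm
#' @param alpha uncorrected nodal significance level.
#' @return tibble, one row per node, with the GLM contrast columns plus
#'   `node` and `flagged`.
#' @export
nodal_group_tests <- function(nodal, data, contrast, alpha = 0.01,
                              covariates = c("age", "gender", "handedness")) {
  nodal <- as.matrix(nodal)
  if (nrow(nodal) != nrow(data)) {
    stop("`nodal` rows must align with `data`", call. = FALSE)
  }
  labs <- colnames(nodal)
  if (is.null(labs)) labs <- default_node_labels(ncol(nodal))
  res <- purrr::map_dfr(seq_len(ncol(nodal)), function(j) {
    fit_glm(data, nodal[, j], contrast, covariates)
  })
  res$node <- labs
  res$flagged <- res$p_value < alpha
  dplyr::relocate(res, "node")
}

#' Cognitive-domain associations with a network measure
#'
#' Regresses each of the seven cognitive-domain z-scores on the network
#' measure plus the nuisance covariates, across all subjects. Family-wise
#' error over the domain family is controlled by Bonferroni: an association
#' is significant when its raw p-value is strictly below `alpha / 7`
#' (`p_adjusted = min(1, 7 p)` is also reported).
#'
#' @param data cohort table containing the domain z-score columns.
#' @param metric per-subject network measure: numeric vector or column name.
#' @param domains domain column names (default [cognitive_domains()]).
#' @inheritParams fit_glm
#' @param alpha family-wise significance level.
#' @return tibble, one row per domain: `domain`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant`, `n`.
#' @export
domain_associations <- function(data, metric, domains = cognitive_domains(),
                                covariates = c("age", "gender", "handedness"),
                                alpha = 0.05) {
  if (is.character(metric) && length(metric) == 1) metric <- data[[metric]]
  m <- length(domains)
  purrr::map_dfr(domains, function(d) {
    df <- data.frame(.y = data[[d]], .x = metric, data[covariates],
                     check.names = FALSE)
    covs <- covariates[vapply(covariates,
                              function(v) length(unique(df[[v]])) > 1,
                              logical(1))]
    fit <- lm(as.formula(paste(".y ~ .x +", paste(covs, collapse = " + "))),
              data = df)
    if (any(is.na(coef(fit)))) {
      stop("rank-deficient design for domain ", d, call. = FALSE)
    }
    cf <- summary(fit)$coefficients
    tibble::tibble(
      domain = d,
      estimate = cf[".x", "Estimate"],
      std_error = cf[".x", "Std. Error"],
      statistic = cf[".x", "t value"],
      p_value = cf[".x", "Pr(>|t|)"],
      p_adjusted = min(1, m * cf[".x", "Pr(>|t|)"]),
      significant = cf[".x", "Pr(>|t|)"] < alpha / m,
      n = nrow(df)
    )
  })
}

# pairwise post-hoc comparisons for one continuous item
posthoc_pairwise <- function(y, g, homoscedastic) {
  levs <- levels(g)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    yi <- y[g == pr[1]]; yj <- y[g == pr[2]]
    if (homoscedastic) {
      # Bonferroni-adjusted pairwise t-tests with the pooled within-group SD
      k <- length(levs)
      ni <- tapply(y, g, length)
      vars <- tapply(y, g, stats::var)
      s2 <- sum((ni - 1) * vars) / (length(y) - k)
      se <- sqrt(s2 * (1 / length(yi) + 1 / length(yj)))
      tt <- (mean(yi) - mean(yj)) / se
      df <- length(y) - k
      p <- 2 * pt(-abs(tt), df)
      p_adj <- min(1, m * p)
      method <- "bonferroni_t"
    } else {
      # Tamhane's T2: pairwise Welch t with Sidak-type adjustment
      w <- t.test(yi, yj, var.equal = FALSE)
      tt <- unname(w$statistic); df <- unname(w$parameter); p <- w$p.value
      p_adj <- 1 - (1 - p)^m
      method <- "tamhane_t2"
    }
    tibble::tibble(test = "posthoc", contrast = paste(pr[1], "-", pr[2]),
                   statistic = tt, df = df, p_value = p,
                   p_adjusted = p_adj, method = method)
  })
}

#' Demographics and clinical characteristics tests
#'
#' Continuous items get a one-way omnibus ANOVA across groups followed by
#' all pairwise post-hoc comparisons: Bonferroni-adjusted pooled-SD t-tests
#' when Levene's test indicates homoscedasticity (p >= 0.05), otherwise
#' Tamhane's T2 (pairwise Welch t with a Sidak-type adjustment, an
#' approximation of the classical procedure). Categorical items get a
#' Pearson chi-square test without continuity correction; a warning is
#' recorded when any expected cell count is below 5.
#'
#' @param data cohort table with a `group` column.
#' @param continuous names of continuous item columns.
#' @param categorical names of categorical item columns.
#' @return tidy tibble, one row per test: `variable`, `test` (omnibus /
#'   levene / posthoc), `contrast`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `method`, `note`.
#' @export
demographics_tests <- function(data,
                               continuous = c("age", cognitive_domains()),
                               categorical = c("gender", "handedness")) {
  g <- factor(data$group)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  out <- list()
  for (v in continuous) {
    y <- data[[v]]
    if (any(tapply(y, g, length) < 2)) {
      stop("group with fewer than 2 subjects for item ", v, call. = FALSE)
    }
    lev <- car::leveneTest(y ~ g)
    lev_p <- lev[1, "Pr(>F)"]
    fit <- aov(y ~ g)
    an <- summary(fit)[[1]]
    omni <- tibble::tibble(
      variable = v, test = "omnibus", contrast = NA_character_,
      statistic = an["g", "F value"], df = an["g", "Df"],
      p_value = an["g", "Pr(>F)"], p_adjusted = NA_real_,
      method = "anova", note = NA_character_)
    levr <- tibble::tibble(
      variable = v, test = "levene", contrast = NA_character_,
      statistic = lev[1, "F value"], df = lev[1, "Df"],
      p_value = lev_p, p_adjusted = NA_real_, method = "levene",
      note = NA_character_)
    ph <- posthoc_pairwise(y, g, homoscedastic = lev_p >= 0.05)
    ph$variable <- v
    ph$note <- NA_character_
    out[[length(out) + 1]] <- dplyr::bind_rows(omni, levr, ph)
  }
  for (v in categorical) {
    tab <- table(g, factor(data[[v]]))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    note <- if (any(expected < 5)) "expected cell count < 5" else NA_character_
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    out[[length(out) + 1]] <- tibble::tibble(
      variable = v, test = "omnibus", contrast = NA_character_,
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = ct$p.value, p_adjusted = NA_real_,
      method = "pearson_chisq", note = note)
  }
  dplyr::relocate(dplyr::bind_rows(out), "variable", "test", "contrast")
}
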