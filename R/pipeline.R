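# End-to-end orchestration: simulate (or load) -> build connectomes ->
# select cost ranges -> composite metrics -> coupling -> statistics, with a
# JSON reproducibility manifest. All outputs are CSV; identical
# (config, seed) reruns produce byte-identical files.

#' Assemble and validate a pipeline run configuration
#'
#' Either `sim` (arguments for [sim_config()]) or `input_dir` (a directory
#' written by [write_cohort()]) must be supplied. The configuration is
#' validated before any computation and echoed in full into the run
#' manifest.
#'
#' @param out_dir output directory.
#' @param sim list of [sim_config()] arguments (the seed is injected from
#'   `seed`), or `NULL` when loading from disk.
#' @param input_dir directory with cohort inputs, or `NULL` when simulating.
#' @param seed integer seed governing every stochastic step of the run.
#' @param costs list of [cost_grid()] arguments.
#' @param criteria named list with optional `SC` / `FC` entries overriding
#'   [default_criteria()].
#' @param n_null_select nulls per cost during cost-range selection.
#' @param alpha_global,alpha_nodal,alpha_domains significance levels for
#'   the global contrasts, nodal tests and domain associations.
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, sim = list(), input_dir = NULL, seed = 1L,
                       costs = list(), criteria = list(), n_null_select = 20,
                       alpha_global = 0.05, alpha_nodal = 0.01,
                       alpha_domains = 0.05) {
  if (is.null(sim) && is.null(input_dir)) {
    stop("supply either `sim` or `input_dir`", call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  cfg <- list(out_dir = out_dir, sim = sim, input_dir = input_dir,
              seed = as.integer(seed), costs = costs, criteria = criteria,
              n_null_select = n_null_select, alpha_global = alpha_global,
              alpha_nodal = alpha_nodal, alpha_domains = alpha_domains)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file; `.json` is parsed as JSON, anything else as
#'   YAML.
#' @param out_dir,seed optional overrides of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (!is.null(seed)) raw$seed <- seed
  do.call(run_config, raw)
}

#' Load a cohort from a directory written by [write_cohort()]
#'
#' @param dir input directory containing `cohort.csv`,
#'   `<id>_sc_prob.tsv` and `<id>_bold.tsv` files.
#' @return list with `subjects`, `sc_prob` and `bold`.
#' @export
load_cohort <- function(dir) {
  subjects <- tibble::as_tibble(utils::read.csv(file.path(dir, "cohort.csv")))
  ids <- subjects$subject_id
  sc_prob <- lapply(ids, function(id) {
    read_matrix_tsv(file.path(dir, paste0(id, "_sc_prob.tsv")))
  })
  bold <- lapply(ids, function(id) {
    read_ts_tsv(file.path(dir, paste0(id, "_bold.tsv")))
  })
  list(subjects = subjects, sc_prob = sc_prob, bold = bold)
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(x, path, row.names = FALSE)
  nrow(x)
}

#' Run the full connectome analysis pipeline
#'
#' Executes every stage in order: cohort simulation (or loading), SC / FC
#' construction, cost-range selection per modality, cost-integrated
#' composite metrics, group- and individual-level structure-function
#' coupling, and the full statistics battery (demographics, global and
#' nodal group contrasts, coupling comparisons, cognitive-domain
#' associations). All result tables are written as CSV under
#' `config$out_dir` together with a JSON run manifest sufficient to rerun
#' the analysis bit-identically.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage progress messages.
#' @return the manifest list, invisibly; the full in-memory results are
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  rows <- list()

  # --- stage: cohort -------------------------------------------------------
  if (!is.null(config$input_dir)) {
    say("[cohort] loading from %s", config$input_dir)
    raw <- load_cohort(config$input_dir)
    subjects <- raw$subjects
    sc_prob <- raw$sc_prob
    bold <- raw$bold
  } else {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    say("[cohort] simulating %d subjects", sum(scfg$n_subjects_per_group))
    cohort <- simulate_cohort(scfg)
    subjects <- cohort$subjects
    sc_prob <- cohort$sc_prob
    bold <- cohort$bold
  }
  n_sub <- nrow(subjects)
  rows$cohort <- write_stage_csv(
    subjects[setdiff(names(subjects), c("alpha_true", "e_glob_true"))],
    config$out_dir, "cohort")

  # --- stage: build --------------------------------------------------------
  say("[build] constructing SC and FC connectomes")
  sc <- lapply(sc_prob, function(P) normalize_sc(symmetrize_probabilities(P)))
  fc <- lapply(bold, build_fc)

  # --- stage: cost ranges --------------------------------------------------
  say("[threshold] selecting cost ranges")
  crit_sc <- utils::modifyList(default_criteria("SC"), config$criteria$SC %||% list())
  crit_fc <- utils::modifyList(default_criteria("FC"), config$criteria$FC %||% list())
  grid <- do.call(cost_grid, config$costs)
  range_sc <- select_cost_range(sc, "SC", costs = grid, criteria = crit_sc,
                                n_null = config$n_null_select,
                                seed = derive_seed(config$seed, 41))
  range_fc <- select_cost_range(fc, "FC", costs = grid, criteria = crit_fc,
                                n_null = config$n_null_select,
                                seed = derive_seed(config$seed, 42))
  say("[threshold] SC %.2f-%.2f, FC %.2f-%.2f",
      min(range_sc$costs), max(range_sc$costs),
      min(range_fc$costs), max(range_fc$costs))

  # --- stage: composite metrics -------------------------------------------
  say("[metrics] composite metrics over selected ranges")
  comp <- function(conns, rng, modality) {
    glob <- vector("list", n_sub); nod <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      cs <- subject_composites(conns[[s]], rng)
      glob[[s]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = subjects$subject_id[s], modality = modality),
        cs$global)
      nod[[s]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = subjects$subject_id[s], modality = modality),
        cs$nodal)
    }
    list(global = dplyr::bind_rows(glob), nodal = dplyr::bind_rows(nod))
  }
  m_sc <- comp(sc, range_sc, "SC")
  m_fc <- comp(fc, range_fc, "FC")
  global_metrics_tbl <- dplyr::bind_rows(m_sc$global, m_fc$global)
  nodal_metrics_tbl <- dplyr::bind_rows(m_sc$nodal, m_fc$nodal)
  rows$global_metrics <- write_stage_csv(global_metrics_tbl, config$out_dir,
                                         "global_metrics")
  rows$nodal_metrics <- write_stage_csv(nodal_metrics_tbl, config$out_dir,
                                        "nodal_metrics")

  # --- stage: coupling -----------------------------------------------------
  say("[coupling] group and individual structure-function coupling")
  groups <- unique(subjects$group)
  group_coupling <- purrr::map_dfr(groups, function(g) {
    idx <- which(subjects$group == g)
    cp <- coupling(group_mean_connectome(sc[idx]), group_mean_connectome(fc[idx]))
    dplyr::bind_cols(tibble::tibble(group = g), cp)
  })
  group_coupling_tests <- purrr::map_dfr(
    utils::combn(groups, 2, simplify = FALSE), function(pr) {
      a <- group_coupling[group_coupling$group == pr[1], ]
      b <- group_coupling[group_coupling$group == pr[2], ]
      dplyr::bind_cols(tibble::tibble(contrast = paste(pr[1], "-", pr[2])),
                       fisher_z_compare(a$r, a$n_edges, b$r, b$n_edges))
    })
  indiv_coupling <- individual_coupling(sc, fc, subjects$subject_id)
  rows$group_coupling <- write_stage_csv(group_coupling, config$out_dir,
                                         "group_coupling")
  rows$group_coupling_tests <- write_stage_csv(group_coupling_tests,
                                               config$out_dir,
                                               "group_coupling_tests")
  rows$individual_coupling <- write_stage_csv(indiv_coupling, config$out_dir,
                                              "individual_coupling")

  # --- stage: statistics ---------------------------------------------------
  say("[stats] demographics, group contrasts, associations")
  demo <- demographics_tests(subjects)
  if (any(!is.na(demo$note))) note("expected cell count < 5 in a demographics table")
  rows$demographics <- write_stage_csv(demo, config$out_dir, "demographics")

  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  ordered_pair <- function(pr) {       # test the more-impaired level vs reference
    ord <- c("NCI", "mild", "moderate")
    pr[order(match(pr, ord), decreasing = TRUE)]
  }
  global_tests <- purrr::map_dfr(c("SC", "FC"), function(mod) {
    tbl <- global_metrics_tbl[global_metrics_tbl$modality == mod, ]
    tbl <- tbl[match(subjects$subject_id, tbl$subject_id), ]
    purrr::map_dfr(c("e_glob", "e_loc"), function(met) {
      purrr::map_dfr(pairs, function(pr) {
        pr <- ordered_pair(pr)
        res <- fit_glm(subjects, tbl[[met]], pr)
        dplyr::bind_cols(tibble::tibble(modality = mod, metric = met), res)
      })
    })
  })
  global_tests$significant <- global_tests$p_value < config$alpha_global
  rows$global_tests <- write_stage_csv(global_tests, config$out_dir,
                                       "global_tests")

  nodal_wide <- function(tblall, mod, met) {
    tbl <- tblall[tblall$modality == mod, c("subject_id", "node", met)]
    w <- tidyr::pivot_wider(tbl, names_from = "node",
                            values_from = tidyr::all_of(met))
    w <- w[match(subjects$subject_id, w$subject_id), ]
    as.matrix(w[, -1])
  }
  nodal_tests <- purrr::map_dfr(c("SC", "FC"), function(mod) {
    purrr::map_dfr(c("degree", "e_nodal"), function(met) {
      mat <- nodal_wide(nodal_metrics_tbl, mod, met)
      purrr::map_dfr(pairs, function(pr) {
        pr <- ordered_pair(pr)
        res <- nodal_group_tests(mat, subjects, pr, alpha = config$alpha_nodal)
        dplyr::bind_cols(tibble::tibble(modality = mod, metric = met), res)
      })
    })
  })
  rows$nodal_tests <- write_stage_csv(nodal_tests, config$out_dir, "nodal_tests")

  coupling_group_glm <- purrr::map_dfr(pairs, function(pr) {
    pr <- ordered_pair(pr)
    fit_glm(subjects,
            indiv_coupling$r[match(subjects$subject_id, indiv_coupling$subject_id)],
            pr)
  })
  rows$coupling_tests <- write_stage_csv(coupling_group_glm, config$out_dir,
                                         "coupling_tests")

  sc_glob <- m_sc$global[match(subjects$subject_id, m_sc$global$subject_id), ]
  fc_glob <- m_fc$global[match(subjects$subject_id, m_fc$global$subject_id), ]
  assoc <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(measure = "sc_e_glob"),
                     domain_associations(subjects, sc_glob$e_glob,
                                         alpha = config$alpha_domains)),
    dplyr::bind_cols(tibble::tibble(measure = "sc_e_loc"),
                     domain_associations(subjects, sc_glob$e_loc,
                                         alpha = config$alpha_domains)),
    dplyr::bind_cols(tibble::tibble(measure = "fc_e_glob"),
                     domain_associations(subjects, fc_glob$e_glob,
                                         alpha = config$alpha_domains)),
    dplyr::bind_cols(tibble::tibble(measure = "fc_e_loc"),
                     domain_associations(subjects, fc_glob$e_loc,
                                         alpha = config$alpha_domains)),
    dplyr::bind_cols(tibble::tibble(measure = "coupling"),
                     domain_associations(
                       subjects,
                       indiv_coupling$r[match(subjects$subject_id,
                                              indiv_coupling$subject_id)],
                       alpha = config$alpha_domains))
  )
  rows$domain_associations <- write_stage_csv(assoc, config$out_dir,
                                              "domain_associations")

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("costnet")),
    config = unclass(config),
    seed = config$seed,
    cost_range = list(SC = range_sc$costs, FC = range_fc$costs),
    stage_rows = rows,
    warnings = warnings_log
  )
  tmp <- file.path(config$out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, file.path(config$out_dir, "manifest.json"))
  say("[done] outputs in %s", config$out_dir)
  results <- list(subjects = subjects, sc = sc, fc = fc,
                  range_sc = range_sc, range_fc = range_fc,
                  global_metrics = global_metrics_tbl,
                  nodal_metrics = nodal_metrics_tbl,
                  group_coupling = group_coupling,
                  group_coupling_tests = group_coupling_tests,
                  individual_coupling = indiv_coupling,
                  demographics = demo, global_tests = global_tests,
                  nodal_tests = nodal_tests,
                  coupling_tests = coupling_group_glm,
                  domain_associations = assoc)
  invisible(structure(manifest, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
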