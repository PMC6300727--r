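small_cfg <- function(...) {
  sim_config(n_nodes = 30, n_subjects_per_group = 3, n_timepoints = 40,
             seed = 123, ...)
}

test_that("the configuration validates its invariants", {
  expect_error(sim_config(n_nodes = 1), "n_nodes")
  expect_error(sim_config(n_subjects_per_group = 1), "2 subjects")
  expect_error(sim_config(n_timepoints = 3), "n_timepoints")
  expect_error(sim_config(coupling_alpha = c(NCI = 1.2, mild = 0.5, moderate = 0.5)),
               "coupling_alpha")
  expect_error(sim_config(sc_deficit = c(NCI = 0, mild = 1, moderate = 1)),
               "sc_deficit")
})

test_that("every generated artefact is a pure function of (config, seed)", {
  cfg <- small_cfg()
  expect_identical(generate_sc_probabilities(cfg, "mild", 5),
                   generate_sc_probabilities(cfg, "mild", 5))
  S <- structured_component(cfg, 9)
  P <- generate_sc_probabilities(cfg, "NCI", 5)
  sc <- normalize_sc(symmetrize_probabilities(P))
  expect_identical(generate_bold(cfg, sc, 0.5, S, 11),
                   generate_bold(cfg, sc, 0.5, S, 11))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$sc_prob, c2$sc_prob)
  expect_identical(c1$bold, c2$bold)
  # and the cohort RNG does not leak into the caller's stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_cohort(small_cfg())); after <- runif(3)
  expect_identical(before, after)
})

test_that("subject draws do not depend on the size of other groups", {
  cfg_a <- sim_config(n_nodes = 30, n_subjects_per_group = c(NCI = 2, mild = 2, moderate = 2),
                      n_timepoints = 40, seed = 123)
  cfg_b <- sim_config(n_nodes = 30, n_subjects_per_group = c(NCI = 2, mild = 3, moderate = 2),
                      n_timepoints = 40, seed = 123)
  a <- simulate_cohort(cfg_a)
  b <- simulate_cohort(cfg_b)
  expect_identical(a$sc_prob[[1]], b$sc_prob[[1]])   # first NCI subject unchanged
  expect_identical(a$bold[[2]], b$bold[[2]])
})

test_that("probability matrices look like tractography output", {
  cfg <- small_cfg()
  P <- generate_sc_probabilities(cfg, "NCI", 77)
  off <- P[row(P) != col(P)]
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(diag(P), rep(0, 30), ignore_attr = TRUE)
  expect_gt(max(abs(P - t(P))), 0)                   # deliberate asymmetry
  expect_lt(max(abs(P - t(P))), 0.2)                 # ... but slight
  zero_frac <- mean(off == 0)
  expect_gt(zero_frac, 0.3)
  expect_lt(zero_frac, 0.6)
  # symmetric existence: an absent connection is absent in both directions
  expect_identical(P == 0, t(P) == 0)
})

test_that("sc_deficit only lowers long-range connectivity when below one", {
  cfg_null <- small_cfg(sc_deficit = c(NCI = 1, mild = 1, moderate = 1))
  cfg_def <- small_cfg(sc_deficit = c(NCI = 1, mild = 1, moderate = 0.7))
  lr <- long_range_mask(30)
  mean_lr <- function(cfg, grp, s) {
    P <- generate_sc_probabilities(cfg, grp, s)
    mean(P[lr])
  }
  n_rep <- 200
  base <- sapply(1:n_rep, function(i) mean_lr(cfg_null, "NCI", 4000 + i))
  same <- sapply(1:n_rep, function(i) mean_lr(cfg_null, "moderate", 8000 + i))
  hit <- sapply(1:n_rep, function(i) mean_lr(cfg_def, "moderate", 8000 + i))
  # with deficit = 1 the groups are exchangeable
  expect_gt(t.test(base, same)$p.value, 0.01)
  # with deficit < 1 long-range mass drops in expectation
  expect_lt(mean(hit), mean(base))
  expect_lt(t.test(base, hit)$p.value, 1e-6)
})

test_that("the functional covariance blend is exactly reproducible and valid", {
  cfg <- small_cfg()
  S <- structured_component(cfg, 1)
  expect_equal(diag(S), rep(1, 30), ignore_attr = TRUE)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  P <- generate_sc_probabilities(cfg, "NCI", 2)
  sc <- normalize_sc(symmetrize_probabilities(P))
  X <- generate_bold(cfg, sc, 0.6, S, 3)
  expect_equal(dim(X), c(40, 30))
  expect_error(generate_bold(cfg, sc, 1.4, S, 3), "alpha")
})

test_that("cognition is driven only by the injected network effects", {
  zero_eff <- list(e_glob = setNames(rep(0, 7), cognitive_domains()),
                   alpha = setNames(rep(0, 7), cognitive_domains()))
  cfg <- sim_config(n_nodes = 20, n_subjects_per_group = 100, n_timepoints = 40,
                    cognition_effects = zero_eff, seed = 9)
  truths <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:300),
    group = rep(c("NCI", "mild", "moderate"), each = 100),
    alpha_true = withr::with_seed(1, runif(300, 0.3, 0.7)),
    e_glob_true = withr::with_seed(2, runif(300, 0.1, 0.2)))
  tab <- generate_covariates_and_cognition(cfg, truths, 5)
  for (d in cognitive_domains()) {
    expect_lt(abs(cor(tab[[d]], truths$alpha_true)), 0.15)
    expect_lt(abs(cor(tab[[d]], truths$e_glob_true)), 0.15)
  }
  # a negative alpha coefficient is recovered with negative sign
  neg_eff <- zero_eff
  neg_eff$alpha["visual_memory"] <- -0.5
  cfg2 <- sim_config(n_nodes = 20, n_subjects_per_group = 100, n_timepoints = 40,
                     cognition_effects = neg_eff, noise_sd = 0.4, seed = 9)
  signs <- sapply(1:20, function(i) {
    tab2 <- generate_covariates_and_cognition(cfg2, truths, 100 + i)
    cor(tab2$visual_memory, truths$alpha_true)
  })
  expect_true(mean(signs < 0) >= 0.95)
})

test_that("cohort ages and demographics echo the group profiles", {
  cfg <- sim_config(n_nodes = 20, n_subjects_per_group = 200, n_timepoints = 40,
                    seed = 31)
  truths <- tibble::tibble(subject_id = sprintf("S%03d", 1:600),
                           group = rep(c("NCI", "mild", "moderate"), each = 200),
                           alpha_true = rep(0.5, 600), e_glob_true = rep(0.15, 600))
  tab <- generate_covariates_and_cognition(cfg, truths, 8)
  m <- tapply(tab$age, tab$group, mean)
  expect_lt(abs(m[["NCI"]] - 67), 1.5)
  expect_lt(abs(m[["moderate"]] - 74), 1.5)
  expect_gt(mean(tab$gender[tab$group == "moderate"] == "F"), 0.55)
  expect_true(all(tab$handedness[tab$group == "mild"] == "R"))
})

test_that("cohorts round-trip through the on-disk text formats", {
  ch <- simulate_cohort(small_cfg())
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- load_cohort(dir)
  expect_equal(back$subjects$group, ch$subjects$group)
  expect_equal(back$sc_prob[[1]], ch$sc_prob[[1]], tolerance = 1e-12)
  expect_equal(back$bold[[4]], ch$bold[[4]], tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$seed, 123)
  expect_length(gt$alpha_true, 9)
})
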