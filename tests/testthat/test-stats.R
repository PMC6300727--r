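test_that("group GLM contrast matches the closed-form OLS solution", {
  tab <- tibble::tibble(
    group = c("NCI", "NCI", "NCI", "mild", "mild", "moderate", "moderate", "moderate"),
    age = c(65, 70, 72, 68, 75, 71, 74, 80),
    gender = c("F", "M", "F", "M", "F", "F", "M", "F"),
    handedness = c("R", "R", "L", "R", "R", "R", "L", "R"))
  y <- c(1.2, 0.9, 1.1, 0.8, 0.7, 0.4, 0.5, 0.2)
  res <- fit_glm(tab, y, c("moderate", "NCI"))
  # independent normal-equations oracle
  X <- cbind(1, tab$group == "mild", tab$group == "moderate",
             tab$age, tab$gender == "M", tab$handedness == "R")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$estimate, beta[3], tolerance = 1e-10)
  expect_equal(res$n, 8)
  # intercept absorbs constant shifts of the response
  res_shift <- fit_glm(tab, y + 100, c("moderate", "NCI"))
  expect_equal(res_shift$statistic, res$statistic)
  # re-referencing flips the sign of the mirrored contrast
  res_rev <- fit_glm(tab, y, c("NCI", "moderate"))
  expect_equal(res_rev$statistic, -res$statistic)
})

test_that("a constant response yields a null contrast", {
  tab <- toy_cohort_table(10)
  res <- suppressWarnings(fit_glm(tab, rep(3.3, nrow(tab)), c("moderate", "NCI")))
  expect_equal(res$estimate, 0, tolerance = 1e-10)
})

test_that("perfectly collinear predictors are rejected", {
  tab <- toy_cohort_table(10)
  tab$handedness <- ifelse(tab$gender == "F", "R", "L")   # aliased with gender
  expect_error(fit_glm(tab, rnorm(nrow(tab)), c("moderate", "NCI")),
               "collinear")
})

test_that("nodal tests flag an injected effect and respect alignment", {
  withr::with_seed(14, {
    tab <- toy_cohort_table(25)
    nodal <- matrix(rnorm(nrow(tab) * 12), nrow(tab), 12,
                    dimnames = list(NULL, sprintf("ROI%03d", 1:12)))
    nodal[tab$group == "moderate", 5] <- nodal[tab$group == "moderate", 5] + 1.5
  })
  res <- nodal_group_tests(nodal, tab, c("moderate", "NCI"))
  expect_equal(nrow(res), 12)
  expect_true(res$flagged[res$node == "ROI005"])
  expect_lt(sum(res$flagged), 5)
  expect_error(nodal_group_tests(nodal[1:10, ], tab, c("moderate", "NCI")),
               "align")
})

test_that("domain associations control the family of seven comparisons", {
  withr::with_seed(25, {
    tab <- toy_cohort_table(40)
    metric <- rnorm(nrow(tab))
    for (d in cognitive_domains()) tab[[d]] <- rnorm(nrow(tab))
    tab$visual_memory <- -0.6 * scale(metric)[, 1] + rnorm(nrow(tab), sd = 0.5)
  })
  res <- domain_associations(tab, metric)
  expect_equal(nrow(res), 7)
  expect_equal(res$significant, res$p_value < 0.05 / 7)
  expect_equal(res$p_adjusted, pmin(1, 7 * res$p_value))
  vm <- res[res$domain == "visual_memory", ]
  expect_lt(vm$estimate, 0)
  expect_true(vm$significant)
  # Bonferroni is monotone: adjusted decisions never exceed raw ones
  expect_true(all(!res$significant | res$p_value < 0.05))
})

test_that("demographics tests reproduce hand-computed statistics", {
  # equal group means: F = 0, p = 1
  tab0 <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                         x = rep(c(1, 2, 3, 4), times = 3))
  res0 <- demographics_tests(tab0, continuous = "x", categorical = character())
  omni <- res0[res0$test == "omnibus" & res0$variable == "x", ]
  expect_equal(omni$statistic, 0, tolerance = 1e-12)
  expect_equal(omni$p_value, 1)

  # 2x2 table (10,0 / 0,10): Pearson chi-square (no correction) = 20
  tab1 <- tibble::tibble(group = rep(c("g1", "g2"), each = 10),
                         flag = rep(c("yes", "no"), each = 10),
                         x = rnorm(20))
  res1 <- demographics_tests(tab1, continuous = character(), categorical = "flag")
  expect_equal(res1$statistic, 20)
  expect_equal(res1$df, 1)
  expect_equal(res1$p_value, 7.744216e-6, tolerance = 1e-6)
  expect_true(is.na(res1$note))          # expected counts are exactly 5

  # 3x2 handedness-style table (94,3 / 61,0 / 54,2): chi-square ~= 2.077, df 2
  tab2 <- tibble::tibble(
    group = rep(c("NCI", "mild", "moderate"), times = c(97, 61, 56)),
    handed = c(rep("R", 94), rep("L", 3), rep("R", 61),
               rep("R", 54), rep("L", 2)))
  res2 <- demographics_tests(tab2, continuous = character(), categorical = "handed")
  expect_equal(res2$statistic, 2.077, tolerance = 1e-3)
  expect_equal(res2$df, 2)
})

test_that("post-hoc procedure follows the homoscedasticity diagnostic", {
  withr::with_seed(50, {
    hom <- tibble::tibble(group = rep(c("a", "b", "c"), each = 30),
                          x = rnorm(90) + rep(c(0, 0.5, 1), each = 30))
    het <- tibble::tibble(group = rep(c("a", "b", "c"), each = 30),
                          x = rnorm(90, sd = rep(c(0.2, 1, 5), each = 30)))
  })
  rh <- demographics_tests(hom, continuous = "x", categorical = character())
  expect_true(all(rh$method[rh$test == "posthoc"] == "bonferroni_t"))
  expect_equal(sum(rh$test == "posthoc"), 3)
  rt <- demographics_tests(het, continuous = "x", categorical = character())
  expect_true(all(rt$method[rt$test == "posthoc"] == "tamhane_t2"))
  # adjusted p never below raw p under either procedure
  ph <- rbind(rh[rh$test == "posthoc", ], rt[rt$test == "posthoc", ])
  expect_true(all(ph$p_adjusted >= ph$p_value - 1e-12))
  expect_error(demographics_tests(tibble::tibble(group = "a", x = 1),
                                  continuous = "x", categorical = character()),
               "2 groups")
})
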