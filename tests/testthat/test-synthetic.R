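test_that("a fixed seed yields an identical dataset; seeds change it", {
  cfg <- generator_config(n_projects = 5, project_sizes = 40)
  expect_identical(generate_outcomes(cfg, seed = 7),
                   generate_outcomes(cfg, seed = 7))
  expect_false(identical(generate_outcomes(cfg, seed = 7),
                         generate_outcomes(cfg, seed = 8)))
  expect_identical(generate_items(cfg, seed = 7), generate_items(cfg, seed = 7))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_outcomes(generator_config(n_projects = 3,
                                               project_sizes = 10), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("zero intercept SD and no effects give exchangeable projects", {
  cfg <- generator_config(n_projects = 10, project_sizes = 300,
                          project_intercept_sd = 0, covariates = NULL,
                          age_effect = 0)
  d <- generate_outcomes(cfg, seed = 3)
  expect_true(all(d$.project_intercept == 0))
  means <- tapply(d$indexed_cep, d$project_id, mean)
  # project means scatter like iid sampling error around the grand mean
  expect_lt(max(abs(means - cfg$grand_mean)),
            5 * cfg$residual_sd / sqrt(300))
})

test_that("within-project correlations converge to the configured targets", {
  cfg <- generator_config(n_projects = 1, project_sizes = 5000,
                          covariates = NULL, age_effect = 0,
                          project_intercept_sd = 0, truncate_outcomes = FALSE)
  d <- generate_outcomes(cfg, seed = 13)
  R <- cfg$outcome_correlations
  expect_equal(cor(d$indexed_cep, d$cantril), R["cep", "cantril"],
               tolerance = 0.05)
  expect_equal(cor(d$indexed_cep, d$eq5d_utility), R["cep", "eq5d"],
               tolerance = 0.05)
  expect_equal(cor(d$cantril, d$eq5d_utility), R["cantril", "eq5d"],
               tolerance = 0.08)
})

test_that("group contrasts converge to the configured true effects", {
  covs <- list(depression = list(levels = c("no", "yes"),
                                 probs = c(0.909, 0.091),
                                 effects = c(yes = -1.16)))
  cfg <- generator_config(n_projects = 1, project_sizes = 20000,
                          project_intercept_sd = 0, covariates = covs,
                          age_effect = 0)
  d <- generate_outcomes(cfg, seed = 17)
  diff <- mean(d$indexed_cep[d$depression == "yes"]) -
    mean(d$indexed_cep[d$depression == "no"])
  expect_equal(diff, -1.16, tolerance = 0.1)
})

test_that("invalid configurations are rejected", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(generator_config(outcome_correlations = R), "semi-definite")
  expect_error(generator_config(project_sizes = 2), ">= 4")
  bad <- default_covariates()
  bad$gender$probs <- c(0.5, 0.6)
  expect_error(generator_config(covariates = bad), "probability")
})

test_that("item-level mode: missingness drives scoreability", {
  cfg0 <- generator_config(n_projects = 4, project_sizes = 50,
                           missingness_rate = 0)
  d0 <- score_dataset(strip_ground_truth(generate_items(cfg0, seed = 2)))
  expect_true(all(d0$scoreable))
  cfg1 <- generator_config(n_projects = 4, project_sizes = 50,
                           missingness_rate = 1)
  d1 <- score_dataset(strip_ground_truth(generate_items(cfg1, seed = 2)))
  expect_false(any(d1$scoreable))
})

test_that("scored items track latent wellbeing (round-trip ordering)", {
  cfg <- generator_config(n_projects = 6, project_sizes = 200)
  raw <- generate_items(cfg, seed = 19)
  scored <- score_dataset(strip_ground_truth(raw))
  rho <- cor(raw$.latent_wellbeing, scored$indexed_cep, method = "spearman")
  expect_gt(rho, 0.9)
  # EQ-5D and Cantril also move with the latent trait
  expect_gt(cor(raw$.latent_wellbeing, scored$eq5d_utility), 0.5)
  expect_gt(cor(raw$.latent_wellbeing, scored$cantril), 0.3)
})

test_that("ground-truth columns are flagged by a dot prefix and strippable", {
  d <- generate_outcomes(generator_config(n_projects = 3, project_sizes = 10),
                         seed = 1)
  expect_true(all(c(".project_intercept", ".latent_wellbeing") %in% names(d)))
  expect_false(any(startsWith(names(strip_ground_truth(d)), ".")))
})

test_that("default outcome generation respects instrument bounds", {
  d <- generate_outcomes(generator_config(n_projects = 8, project_sizes = 400),
                         seed = 29)
  expect_true(all(d$indexed_cep >= 0 & d$indexed_cep <= 10))
  expect_true(all(d$cantril %in% 0:10))
  b <- eq5d_bounds()
  expect_true(all(d$eq5d_utility >= b["min"] & d$eq5d_utility <= b["max"]))
  # bounded utilities show a ceiling, like tariff-scored utilities do
  expect_gt(mean(d$eq5d_utility == b[["max"]]), 0.02)
})

test_that("drawn project sizes are skewed and respect the minimum", {
  cfg <- generator_config(n_projects = 28)
  d <- generate_outcomes(cfg, seed = 23)
  sizes <- as.numeric(table(d$project_id))
  expect_true(all(sizes >= 4))
  expect_gt(mean(sizes), stats::median(sizes))  # right-skewed
})
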