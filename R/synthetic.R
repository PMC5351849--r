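#' Default covariate specification for the synthetic cohort
#'
#' Each covariate has levels, sampling probabilities and true effects (in
#' composite-endpoint points, relative to the first level as reference).
#' Defaults are calibrated to the pooled multi-project cohort the generator
#' emulates: 61.5% women, prevalences of 5.6% (dementia), 9.1% (depression)
#' and 14.6% (dizziness with falls), and group contrasts matching the
#' unadjusted known-group estimates (e.g. depression -1.16 points).
#'
#' @return Named list of covariate specs.
#' @export
default_covariates <- function() {
  list(
    gender = list(levels = c("male", "female"), probs = c(0.385, 0.615),
                  effects = c(female = -0.39)),
    marital_status = list(
      levels = c("married_cohabiting", "partner_deceased", "other"),
      probs = c(0.467, 0.410, 0.123),
      effects = c(partner_deceased = -0.37, other = -0.22)),
    living_arrangement = list(
      levels = c("independent_alone", "independent_with_others", "dependent"),
      probs = c(0.400, 0.449, 0.151),
      effects = c(independent_with_others = 0.19, dependent = -1.01)),
    education = list(levels = c("primary", "secondary", "university"),
                     probs = c(0.300, 0.467, 0.233),
                     effects = c(secondary = 0.27, university = 0.44)),
    dementia = list(levels = c("no", "yes"), probs = c(0.944, 0.056),
                    effects = c(yes = -1.13)),
    depression = list(levels = c("no", "yes"), probs = c(0.909, 0.091),
                      effects = c(yes = -1.16)),
    dizziness_falls = list(levels = c("no", "yes"), probs = c(0.854, 0.146),
                           effects = c(yes = -1.07))
  )
}

#' Configuration of the synthetic multi-project generator
#'
#' Parameterizes a pooled cohort of older persons spread over heterogeneous
#' research projects: project-level random intercepts, a within-project
#' correlation structure among the three outcomes (composite endpoint,
#' Cantril ladder, EQ-5D utility), covariate prevalences with true group
#' effects, and item-level missingness.  Defaults emulate the pooled dataset
#' the validation targets: 28 projects totalling about 17,600 respondents,
#' mean age 79 (SD 7), outcome means/SDs 7.37 (1.23), 7.12 (1.40) and
#' 0.63 (0.29), and within-project correlations 0.43 (CEP-Cantril),
#' 0.63 (CEP-EQ-5D) and 0.34 (Cantril-EQ-5D).
#'
#' The correlation targets apply to the within-project residual vector; true
#' covariate effects enter the composite endpoint's mean only, so nonzero
#' `covariates` effects slightly attenuate the realized marginal
#' within-project correlations.  Set `covariates = NULL` for a pure
#' correlation-structure cohort.
#'
#' @param n_projects Number of projects.
#' @param project_sizes Integer vector (recycled to `n_projects`) or NULL to
#'   draw skewed sizes from a log-normal targeting `total_n` in expectation.
#' @param total_n Expected total cohort size when sizes are drawn.
#' @param project_intercept_sd SD of the project random intercept (points).
#' @param grand_mean Reference-group mean composite score at mean age.
#' @param residual_sd Residual SD of the composite endpoint (points).
#' @param outcome_means,outcome_sds Named over `cep`, `cantril`, `eq5d`
#'   (`outcome_sds` for the two non-CEP outcomes; the CEP scale comes from
#'   `residual_sd` and `project_intercept_sd`).
#' @param outcome_correlations 3x3 correlation matrix for (cep, cantril, eq5d)
#'   residuals; must be symmetric positive semi-definite with unit diagonal.
#' @param age_mean,age_sd Age distribution in years; `age_effect` points per
#'   year (age enters centered at `age_mean`).
#' @param covariates Covariate specification as in [default_covariates()],
#'   or NULL for none.
#' @param setting_probs Probabilities that a project belongs to the primary
#'   care, general population or hospital stratum.
#' @param missingness_rate Per-item probability of masking each of the 42
#'   composite-endpoint items (item-level mode only).
#' @param item_loading Latent-trait loading of each generated item in (0, 1).
#' @param truncate_outcomes If TRUE (default), outcome-level scores are
#'   bounded to their instruments: composite endpoint clamped to 0-10,
#'   Cantril rounded to an integer in 0-10, EQ-5D clamped to its tariff
#'   range.  This reproduces realistic ceiling behaviour (about 10% of
#'   EQ-5D utilities at 1.00 under the defaults) at the cost of a small
#'   (< 0.01) attenuation of the realized correlations; set FALSE for exact
#'   latent correlation structure.
#' @return A list classed `"cep_generator_config"`.
#' @export
generator_config <- function(n_projects = 28L,
                             project_sizes = NULL,
                             total_n = 17600L,
                             project_intercept_sd = 0.5,
                             grand_mean = 7.37,
                             residual_sd = 1.1,
                             outcome_means = c(cantril = 7.12, eq5d = 0.63),
                             outcome_sds = c(cantril = 1.40, eq5d = 0.29),
                             outcome_correlations = matrix(
                               c(1.00, 0.43, 0.63,
                                 0.43, 1.00, 0.34,
                                 0.63, 0.34, 1.00), 3, 3,
                               dimnames = rep(list(c("cep", "cantril", "eq5d")), 2)),
                             age_mean = 79, age_sd = 7, age_effect = 0.03,
                             covariates = default_covariates(),
                             setting_probs = c(primary_care = 0.60,
                                               general_population = 0.25,
                                               hospital = 0.15),
                             missingness_rate = 0,
                             item_loading = 0.7,
                             truncate_outcomes = TRUE) {
  R <- outcome_correlations
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("outcome_correlations must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("outcome_correlations is not positive semi-definite")
  if (!is.null(project_sizes)) {
    project_sizes <- rep_len(as.integer(project_sizes), n_projects)
    if (any(project_sizes < 4)) stop("project sizes must be >= 4")
  }
  for (cv in covariates) {
    if (any(cv$probs < 0 | cv$probs > 1) || abs(sum(cv$probs) - 1) > 1e-8)
      stop("covariate probs must be a probability vector")
    if (!all(names(cv$effects) %in% cv$levels[-1]))
      stop("covariate effects must be named by non-reference levels")
  }
  cfg <- list(n_projects = as.integer(n_projects),
              project_sizes = project_sizes, total_n = total_n,
              project_intercept_sd = project_intercept_sd,
              grand_mean = grand_mean, residual_sd = residual_sd,
              outcome_means = outcome_means, outcome_sds = outcome_sds,
              outcome_correlations = R,
              age_mean = age_mean, age_sd = age_sd, age_effect = age_effect,
              covariates = covariates, setting_probs = setting_probs,
              missingness_rate = missingness_rate,
              item_loading = item_loading,
              truncate_outcomes = truncate_outcomes)
  class(cfg) <- "cep_generator_config"
  cfg
}

# run code with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# project sizes, settings, covariates, age and the respondent-level linear
# predictor shared by both generation modes
draw_cohort_frame <- function(cfg) {
  sizes <- cfg$project_sizes
  if (is.null(sizes)) {
    # log-normal sizes: a few large projects, many small ones
    sdlog <- 1
    meanlog <- log(cfg$total_n / cfg$n_projects) - sdlog^2 / 2
    sizes <- pmax(4L, as.integer(round(stats::rlnorm(cfg$n_projects,
                                                     meanlog, sdlog))))
  }
  settings <- sample(names(cfg$setting_probs), cfg$n_projects,
                     replace = TRUE, prob = cfg$setting_probs)
  u <- stats::rnorm(cfg$n_projects, 0, cfg$project_intercept_sd)
  n <- sum(sizes)
  d <- data.frame(project_id = factor(rep(sprintf("P%02d", seq_along(sizes)),
                                          sizes)),
                  setting = rep(settings, sizes))
  d$.project_intercept <- rep(u, sizes)
  d$age <- round(stats::rnorm(n, cfg$age_mean, cfg$age_sd))
  eta <- cfg$age_effect * (d$age - cfg$age_mean)
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    lv <- sample(cv$levels, n, replace = TRUE, prob = cv$probs)
    d[[nm]] <- factor(lv, levels = cv$levels)
    eff <- c(stats::setNames(0, cv$levels[1]), cv$effects)
    eta <- eta + eff[lv]
  }
  d$.fixed_effects <- as.numeric(eta)
  d
}

# correlated standard-normal residual triplet (cep, cantril, eq5d)
draw_residuals <- function(n, R) {
  z <- matrix(stats::rnorm(3 * n), n, 3)
  z %*% chol(R)
}

#' Generate a synthetic multi-project cohort with ready-scored outcomes
#'
#' Outcome-level mode: each respondent gets a composite-endpoint score built
#' as grand mean + project intercept + covariate effects + residual, plus
#' Cantril and EQ-5D outcomes whose residuals share the configured
#' within-project correlation structure with the composite's residual.
#' Hidden ground-truth columns are prefixed with "." and are dropped by
#' [strip_ground_truth()] before the table is used as pipeline input.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; a fixed seed yields a byte-identical dataset.
#' @return data.frame with `project_id`, `setting`, covariates, `indexed_cep`,
#'   `cantril`, `eq5d_utility` and ground-truth columns `.project_intercept`,
#'   `.latent_wellbeing`.
#' @export
generate_outcomes <- function(cfg = generator_config(), seed = 1L) {
  with_seed(seed, {
    d <- draw_cohort_frame(cfg)
    n <- nrow(d)
    e <- draw_residuals(n, cfg$outcome_correlations)
    mu_cep <- cfg$grand_mean + d$.project_intercept + d$.fixed_effects
    d$indexed_cep <- mu_cep + cfg$residual_sd * e[, 1]
    d$cantril <- cfg$outcome_means[["cantril"]] +
      cfg$outcome_sds[["cantril"]] * e[, 2]
    d$eq5d_utility <- cfg$outcome_means[["eq5d"]] +
      cfg$outcome_sds[["eq5d"]] * e[, 3]
    if (isTRUE(cfg$truncate_outcomes)) {
      b <- eq5d_bounds()
      d$indexed_cep <- pmin(10, pmax(0, d$indexed_cep))
      d$cantril <- pmin(10, pmax(0, round(d$cantril)))
      d$eq5d_utility <- pmin(b[["max"]], pmax(b[["min"]], d$eq5d_utility))
    }
    d$.latent_wellbeing <- mu_cep
    d
  })
}

# marginal level probabilities (best state first) used to discretize items
item_level_probs <- function(component) {
  switch(component,
    morbidities = c(0.80, 0.20),
    functional_limitations = c(0.75, 0.25),
    emotional_wellbeing = c(0.35, 0.25, 0.15, 0.10, 0.08, 0.07),
    pain = c(0.55, 0.30, 0.15),
    cognition = c(0.60, 0.28, 0.12),
    social_functioning = c(0.45, 0.25, 0.15, 0.09, 0.06),
    self_perceived_health = c(0.15, 0.35, 0.30, 0.15, 0.05),
    self_perceived_qol = c(0.15, 0.38, 0.30, 0.12, 0.05)
  )
}

# discretize a standard-normal severity variable into oriented levels 0..K-1
discretize_severity <- function(sev, probs) {
  cuts <- stats::qnorm(cumsum(probs)[-length(probs)])
  findInterval(sev, cuts)
}

#' Generate a synthetic cohort at the item level
#'
#' Item-level mode: draws the 42 raw composite-endpoint items, the five
#' EQ-5D dimensions and a Cantril score consistent with each respondent's
#' latent wellbeing through a one-factor graded-threshold model, then masks
#' composite-endpoint items completely at random at `cfg$missingness_rate`.
#' Scoring the generated items reproduces the intended wellbeing ordering.
#'
#' @inheritParams generate_outcomes
#' @param scheme Coding scheme defining the raw item codings to emit.
#' @return data.frame with `project_id`, `setting`, covariates, the raw item
#'   columns of `scheme`, EQ-5D dimensions, `cantril`, and ground-truth
#'   columns `.project_intercept`, `.latent_wellbeing`.
#' @export
generate_items <- function(cfg = generator_config(), seed = 1L,
                           scheme = default_coding_scheme()) {
  with_seed(seed, {
    d <- draw_cohort_frame(cfg)
    n <- nrow(d)
    latent <- d$.project_intercept + d$.fixed_effects +
      cfg$residual_sd * stats::rnorm(n)
    # standardized severity: higher = worse
    z <- -(latent - mean(latent)) / stats::sd(latent)
    lam <- cfg$item_loading
    for (i in seq_len(nrow(scheme))) {
      probs <- item_level_probs(scheme$component[i])
      sev <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
      oriented <- discretize_severity(sev, probs)
      raw <- if (scheme$reverse[i]) scheme$max_level[i] - oriented
             else oriented + scheme$min_level[i]
      if (cfg$missingness_rate > 0)
        raw[stats::runif(n) < cfg$missingness_rate] <- NA
      d[[scheme$item[i]]] <- raw
    }
    eq_probs <- list(mobility = c(0.55, 0.35, 0.10),
                     self_care = c(0.75, 0.18, 0.07),
                     daily_activities = c(0.55, 0.33, 0.12),
                     pain_discomfort = c(0.45, 0.42, 0.13),
                     anxiety_depression = c(0.65, 0.28, 0.07))
    for (dim in eq5d_dimensions()) {
      sev <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
      d[[dim]] <- discretize_severity(sev, eq_probs[[dim]]) + 1L
    }
    cant <- cfg$outcome_means[["cantril"]] +
      cfg$outcome_sds[["cantril"]] * (0.5 * (-z) + sqrt(0.75) * stats::rnorm(n))
    d$cantril <- pmin(10L, pmax(0L, as.integer(round(cant))))
    d$.latent_wellbeing <- latent
    d
  })
}

#' Drop hidden ground-truth columns from a synthetic dataset
#'
#' @param data A data.frame from [generate_outcomes()] or [generate_items()].
#' @return The data without columns whose names start with ".".
#' @export
strip_ground_truth <- function(data) {
  data[!startsWith(names(data), ".")]
}
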