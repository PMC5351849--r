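#' Fit a random-intercept model contrasting known groups
#'
#' Linear mixed model (REML) of an outcome on one group factor, with a random
#' intercept per project to account for clustering of respondents within
#' research projects, optionally adjusted for age (centered at the sample
#' mean, so the intercept is the reference-group mean at average age) and
#' gender.  Falls back to a plain linear model with a warning when the mixed
#' fit is singular or only one project is present.
#'
#' @param data data.frame with the outcome, factor, `project_id` and, if
#'   requested, `age` and `gender`.
#' @param factor_name Column name of the group factor; its first level is the
#'   reference.
#' @param outcome Outcome column (default `"indexed_cep"`).
#' @param adjust Character vector of adjusters among `"age"` and `"gender"`,
#'   or NULL for the unadjusted model.
#' @param conf_level Confidence level of the Wald intervals.
#' @return A list classed `"known_group_fit"` with `reference_level`,
#'   `reference_mean` (and its CI), `effects` (data.frame: `level`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p_value`), `factor_name`,
#'   `adjusted`, `singular`, `n`, `n_projects`.
#' @export
fit_group_model <- function(data, factor_name, outcome = "indexed_cep",
                            adjust = NULL, conf_level = 0.95) {
  stopifnot(factor_name %in% names(data), outcome %in% names(data),
            "project_id" %in% names(data))
  if (!is.null(adjust) && !all(adjust %in% c("age", "gender")))
    stop("adjusters must be among 'age' and 'gender'")
  keep <- stats::complete.cases(data[c(outcome, factor_name, "project_id",
                                       adjust)])
  d <- data[keep, , drop = FALSE]
  d$.y <- d[[outcome]]
  d$.g <- droplevels(as.factor(d[[factor_name]]))
  if (nlevels(d$.g) < 2) stop("group factor needs at least 2 observed levels")
  rhs <- ".g"
  if ("age" %in% adjust) {
    d$.age_c <- d$age - mean(d$age)
    rhs <- paste(rhs, "+ .age_c")
  }
  if ("gender" %in% adjust) rhs <- paste(rhs, "+ gender")
  n_projects <- length(unique(d$project_id))
  singular <- FALSE
  if (n_projects >= 2) {
    fit <- lme4::lmer(stats::as.formula(paste(".y ~", rhs, "+ (1 | project_id)")),
                      data = d, REML = TRUE)
    singular <- lme4::isSingular(fit)
    if (singular) warning("singular random-intercept fit; ",
                          "falling back to a plain linear model")
  } else {
    singular <- TRUE
    warning("only one project; falling back to a plain linear model")
  }
  if (singular) fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  b <- if (singular) stats::coef(fit) else lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  idx <- grep("^\\.g", names(b))
  levels_ <- sub("^\\.g", "", names(b)[idx])
  eff <- data.frame(level = levels_,
                    estimate = as.numeric(b[idx]),
                    se = se[idx],
                    ci_low = as.numeric(b[idx]) - crit * se[idx],
                    ci_high = as.numeric(b[idx]) + crit * se[idx],
                    p_value = 2 * stats::pnorm(-abs(as.numeric(b[idx]) / se[idx])),
                    row.names = NULL)
  out <- list(reference_level = levels(d$.g)[1],
              reference_mean = as.numeric(b[1]),
              reference_ci = as.numeric(b[1]) + c(-1, 1) * crit * se[1],
              effects = eff, factor_name = factor_name,
              adjusted = if (is.null(adjust)) character(0) else adjust,
              singular = singular, n = nrow(d), n_projects = n_projects)
  class(out) <- "known_group_fit"
  out
}

#' Group mean implied by a fixed-effect contrast
#'
#' The modelled mean of a non-reference group: reference mean plus its
#' contrast estimate (e.g. a male reference mean of 7.56 and a female
#' contrast of -0.39 give a female mean of 7.17).
#'
#' @param reference_mean Reference-group mean in points.
#' @param estimate Fixed-effect contrast(s) in points.
#' @return reference_mean + estimate.
#' @export
group_mean <- function(reference_mean, estimate) {
  reference_mean + estimate
}

#' Change-in-estimate comparison of unadjusted and adjusted fits
#'
#' Percent change of each group contrast after covariate adjustment,
#' |unadjusted - adjusted| / |unadjusted| x 100, flagged when it exceeds the
#' acceptability threshold (15% by default).  A zero unadjusted estimate
#' yields an undefined (NA) percent change, flagged for review.
#'
#' @param unadjusted,adjusted `known_group_fit` objects for the same factor.
#' @param threshold Percent-change threshold.
#' @return A list classed `"known_group_result"` with the two fits and a
#'   `comparison` data.frame (`level`, `unadjusted`, `adjusted`, `pct_change`,
#'   `exceeds_threshold`).
#' @export
compare_adjusted <- function(unadjusted, adjusted, threshold = 15) {
  if (!identical(unadjusted$effects$level, adjusted$effects$level))
    stop("factor levels differ between the unadjusted and adjusted fits")
  u <- unadjusted$effects$estimate
  a <- adjusted$effects$estimate
  pct <- ifelse(u == 0, NA_real_, abs(u - a) / abs(u) * 100)
  # small numeric tolerance so a change of exactly 15% is acceptable
  flag <- is.na(pct) | pct > threshold + 1e-8
  out <- list(unadjusted = unadjusted, adjusted = adjusted,
              threshold = threshold,
              comparison = data.frame(level = unadjusted$effects$level,
                                      unadjusted = u, adjusted = a,
                                      pct_change = pct,
                                      exceeds_threshold = flag))
  class(out) <- "known_group_result"
  out
}

#' Known-group validity table over several characteristics
#'
#' One unadjusted and one age/gender-adjusted random-intercept model per
#' characteristic (never one joint model), with the change-in-estimate flag.
#'
#' @param data Scored respondent table.
#' @param factors Characteristics to contrast.
#' @param outcome Outcome column.
#' @param adjust Adjusters for the adjusted models.
#' @param threshold Percent-change threshold.
#' @return data.frame with one row per factor level: reference mean,
#'   unadjusted and adjusted estimates with CIs, `pct_change` and flag.
#' @export
known_group_validity <- function(data,
                                 factors = c("marital_status",
                                             "living_arrangement", "education",
                                             "dementia", "depression",
                                             "dizziness_falls"),
                                 outcome = "indexed_cep",
                                 adjust = c("age", "gender"),
                                 threshold = 15) {
  rows <- lapply(factors, function(f) {
    un <- fit_group_model(data, f, outcome = outcome, adjust = NULL)
    ad <- fit_group_model(data, f, outcome = outcome, adjust = adjust)
    cmp <- compare_adjusted(un, ad, threshold = threshold)$comparison
    data.frame(characteristic = f,
               reference_level = un$reference_level,
               reference_mean = un$reference_mean,
               level = un$effects$level,
               estimate = un$effects$estimate,
               ci_low = un$effects$ci_low,
               ci_high = un$effects$ci_high,
               group_mean = group_mean(un$reference_mean, un$effects$estimate),
               adj_estimate = ad$effects$estimate,
               adj_ci_low = ad$effects$ci_low,
               adj_ci_high = ad$effects$ci_high,
               pct_change = cmp$pct_change,
               exceeds_threshold = cmp$exceeds_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
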