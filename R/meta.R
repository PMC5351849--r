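#' Per-project Pearson correlations
#'
#' Complete-pair Pearson correlation between two outcomes within each project.
#' Projects with fewer than `min_n` complete pairs or zero variance in either
#' outcome are excluded with a warning (Fisher-z pooling needs n > 3 and a
#' defined r).
#'
#' @param data data.frame with a `project_id` column and the two outcomes.
#' @param x,y Column names of the outcome pair.
#' @param min_n Minimum complete-pair count per project (default 4).
#' @return data.frame with `project_id`, `r`, `n`, one row per retained
#'   project.
#' @export
project_correlations <- function(data, x, y, min_n = 4L) {
  stopifnot("project_id" %in% names(data), x %in% names(data),
            y %in% names(data))
  res <- lapply(split(data, data$project_id, drop = TRUE), function(d) {
    ok <- stats::complete.cases(d[[x]], d[[y]])
    n <- sum(ok)
    if (n < min_n)
      return(list(r = NA_real_, n = n, why = "too few complete pairs"))
    if (stats::sd(d[[x]][ok]) == 0 || stats::sd(d[[y]][ok]) == 0)
      return(list(r = NA_real_, n = n, why = "zero variance"))
    list(r = stats::cor(d[[x]][ok], d[[y]][ok]), n = n, why = NA_character_)
  })
  out <- data.frame(project_id = names(res),
                    r = vapply(res, `[[`, numeric(1), "r"),
                    n = vapply(res, `[[`, numeric(1), "n"),
                    row.names = NULL)
  drop <- !is.na(vapply(res, `[[`, character(1), "why"))
  if (any(drop))
    warning(sprintf("excluded %d project(s) from %s-%s correlations: %s",
                    sum(drop), x, y,
                    paste(out$project_id[drop], collapse = ", ")))
  out <- out[!drop, , drop = FALSE]
  if (nrow(out) == 0) stop("no eligible projects for correlation pooling")
  rownames(out) <- NULL
  out
}

#' Random-effects pooling of correlations (Fisher z, DerSimonian-Laird)
#'
#' Each correlation is Fisher-z transformed with sampling variance
#' 1/(n - 3); between-project variance tau^2 is estimated by the
#' DerSimonian-Laird moment method; the pooled z uses inverse-variance
#' weights 1/(1/(n - 3) + tau^2), and the pooled estimate and its 95%
#' confidence interval are back-transformed to the correlation scale.
#'
#' @param correlations data.frame with columns `r` and `n`, e.g. from
#'   [project_correlations()].
#' @param conf_level Confidence level for the pooled interval.
#' @return A list classed `"pooled_correlation"` with `r_pooled`, `ci_low`,
#'   `ci_high`, `tau2` (on the z scale), `k`, `q` and `total_n`.
#' @export
pool_random_effects <- function(correlations, conf_level = 0.95) {
  r <- correlations$r
  n <- correlations$n
  if (length(r) < 1) stop("at least one project correlation is required")
  if (any(is.na(r)) || any(abs(r) > 1)) stop("correlations must be in [-1, 1]")
  if (any(n <= 3)) stop("Fisher-z variance 1/(n-3) requires n > 3")
  z <- atanh(r)
  v <- 1 / (n - 3)
  w <- 1 / v
  z_fixed <- sum(w * z) / sum(w)
  q <- sum(w * (z - z_fixed)^2)
  k <- length(z)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  w_star <- 1 / (v + tau2)
  z_pooled <- sum(w_star * z) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(r_pooled = tanh(z_pooled),
              ci_low = tanh(z_pooled - crit * se),
              ci_high = tanh(z_pooled + crit * se),
              tau2 = tau2, k = k, q = q, total_n = sum(n))
  class(out) <- "pooled_correlation"
  out
}

#' @export
print.pooled_correlation <- function(x, ...) {
  cat(sprintf("Pooled r = %.3f [%.3f; %.3f] (%s), k = %d projects, tau^2 = %.4f\n",
              x$r_pooled, x$ci_low, x$ci_high,
              classify_strength(x$r_pooled), x$k, x$tau2))
  invisible(x)
}

#' Classify correlation strength
#'
#' Magnitudes below 0.3 are weak, between 0.3 and 0.5 (boundaries included)
#' moderate, and above 0.5 strong.
#'
#' @param r Correlation(s) in [-1, 1].
#' @param weak_below,strong_above Band thresholds.
#' @return Character vector: "weak", "moderate" or "strong".
#' @export
classify_strength <- function(r, weak_below = 0.3, strong_above = 0.5) {
  if (!(0 < weak_below && weak_below < strong_above && strong_above < 1))
    stop("thresholds must satisfy 0 < weak_below < strong_above < 1")
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  a <- abs(r)
  ifelse(a < weak_below, "weak", ifelse(a <= strong_above, "moderate", "strong"))
}

#' Convergent-validity table for several outcome pairs
#'
#' Per-project correlations pooled by [pool_random_effects()] for each
#' requested pair, optionally within strata.
#'
#' @param data Scored respondent table with `project_id`.
#' @param pairs List of 2-element character vectors of outcome columns.
#' @param by Optional stratification column (e.g. `"setting"`); the complete
#'   sample is always reported as stratum `"complete"`.
#' @param min_n Per-project minimum complete-pair count.
#' @return data.frame with one row per stratum x pair: `stratum`, `outcome_x`,
#'   `outcome_y`, `r`, `ci_low`, `ci_high`, `tau2`, `k`, `n`, `strength`.
#' @export
convergent_validity <- function(data,
                                pairs = list(c("indexed_cep", "eq5d_utility"),
                                             c("indexed_cep", "cantril"),
                                             c("cantril", "eq5d_utility")),
                                by = NULL, min_n = 4L) {
  strata <- list(complete = data)
  if (!is.null(by)) strata <- c(strata, split(data, data[[by]], drop = TRUE))
  rows <- list()
  for (s in names(strata)) {
    for (p in pairs) {
      pc <- project_correlations(strata[[s]], p[1], p[2], min_n = min_n)
      pl <- pool_random_effects(pc)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, outcome_x = p[1], outcome_y = p[2],
        r = pl$r_pooled, ci_low = pl$ci_low, ci_high = pl$ci_high,
        tau2 = pl$tau2, k = pl$k, n = pl$total_n,
        strength = classify_strength(pl$r_pooled))
    }
  }
  do.call(rbind, rows)
}
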