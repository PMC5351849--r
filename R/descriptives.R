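#' Distribution and floor/ceiling summary of an outcome
#'
#' Counts respondents at the theoretical minimum and maximum of the
#' instrument (not the observed extremes), as percentages of the non-missing
#' sample, and flags a floor or ceiling effect when the percentage exceeds
#' the acceptability threshold (15% by default).  Scores are compared with
#' the bounds after rounding to `digits` decimals, matching the reporting
#' precision of tariff-based utilities.
#'
#' @param scores Numeric vector of scores (NA = missing).
#' @param theoretical_min,theoretical_max Instrument bounds (composite
#'   endpoint and Cantril ladder 0-10; Dutch EQ-5D -0.33 to 1.00).
#' @param threshold Percentage above which a floor/ceiling effect is flagged.
#' @param digits Rounding applied before comparing with the bounds.
#' @return A one-row data.frame: `n`, `n_complete`, `mean`, `sd`,
#'   `observed_min`, `observed_max`, `floor_n`, `floor_pct`, `ceiling_n`,
#'   `ceiling_pct`, `floor_flag`, `ceiling_flag`.
#' @export
summarize_outcome <- function(scores, theoretical_min, theoretical_max,
                              threshold = 15, digits = 2) {
  if (length(scores) == 0) stop("empty score vector")
  x <- scores[!is.na(scores)]
  if (length(x) == 0) stop("no non-missing scores")
  xr <- round(x, digits)
  lo <- round(theoretical_min, digits)
  hi <- round(theoretical_max, digits)
  if (any(xr < lo) || any(xr > hi))
    stop("scores outside the theoretical bounds")
  floor_n <- sum(xr == lo)
  ceiling_n <- sum(xr == hi)
  floor_pct <- 100 * floor_n / length(x)
  ceiling_pct <- 100 * ceiling_n / length(x)
  data.frame(n = length(scores), n_complete = length(x),
             mean = mean(x), sd = stats::sd(x),
             observed_min = min(x), observed_max = max(x),
             floor_n = floor_n, floor_pct = floor_pct,
             ceiling_n = ceiling_n, ceiling_pct = ceiling_pct,
             floor_flag = floor_pct > threshold,
             ceiling_flag = ceiling_pct > threshold)
}

#' Outcome summaries per stratum
#'
#' Feasibility/floor/ceiling table for the three outcomes, for the complete
#' sample and optionally within strata.
#'
#' @param data Scored respondent table.
#' @param outcomes Named list mapping outcome column to
#'   `c(theoretical_min, theoretical_max)`.
#' @param by Optional stratification column (e.g. `"setting"`).
#' @param threshold Floor/ceiling percentage threshold.
#' @return data.frame with one row per stratum x outcome.
#' @export
describe_outcomes <- function(data,
                              outcomes = list(
                                indexed_cep = c(0, 10),
                                cantril = c(0, 10),
                                eq5d_utility = unname(eq5d_bounds())),
                              by = NULL, threshold = 15) {
  strata <- list(complete = data)
  if (!is.null(by)) strata <- c(strata, split(data, data[[by]], drop = TRUE))
  rows <- list()
  for (s in names(strata)) {
    for (oc in names(outcomes)) {
      b <- outcomes[[oc]]
      sm <- summarize_outcome(strata[[s]][[oc]], b[1], b[2],
                              threshold = threshold)
      rows[[length(rows) + 1L]] <- cbind(data.frame(stratum = s, outcome = oc),
                                         sm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
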