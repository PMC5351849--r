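#' Dutch EQ-5D-3L value set
#'
#' Decrement constants of the Dutch time-trade-off tariff: a constant for any
#' departure from full health, per-dimension decrements for moderate (level 2)
#' and extreme (level 3) problems, and an extra "N3" decrement when any
#' dimension is at level 3.  Full health (11111) maps to 1.00 and the worst
#' state (33333) to -0.329 (reported as -0.33 at two decimals).
#'
#' @return A list classed `"eq5d_tariff"`.
#' @export
dutch_tariff <- function() {
  t <- list(
    constant = 0.071,
    level2 = c(mobility = 0.036, self_care = 0.082, daily_activities = 0.032,
               pain_discomfort = 0.086, anxiety_depression = 0.124),
    level3 = c(mobility = 0.161, self_care = 0.152, daily_activities = 0.057,
               pain_discomfort = 0.329, anxiety_depression = 0.325),
    n3 = 0.234
  )
  class(t) <- "eq5d_tariff"
  t
}

#' Dimension column names of the EQ-5D
#' @return Character vector of length 5.
#' @export
eq5d_dimensions <- function() {
  c("mobility", "self_care", "daily_activities",
    "pain_discomfort", "anxiety_depression")
}

#' EQ-5D utility under a national tariff
#'
#' Combines the five 3-level dimensions (1 = no problems, 2 = moderate,
#' 3 = extreme) into a utility.  Any missing dimension yields NA (no partial
#' scoring).  Full precision is retained; round to two decimals only for
#' reporting.
#'
#' @param resp data.frame with the five dimension columns (see
#'   [eq5d_dimensions()]), or a numeric vector of length 5 for one respondent.
#' @param tariff Value set; default [dutch_tariff()].
#' @return Numeric utility vector.
#' @export
eq5d_utility <- function(resp, tariff = dutch_tariff()) {
  dims <- eq5d_dimensions()
  if (is.numeric(resp) && is.null(dim(resp))) {
    if (length(resp) != 5) stop("a single EQ-5D state needs 5 levels")
    resp <- as.data.frame(as.list(stats::setNames(resp, dims)))
  }
  missing_cols <- setdiff(dims, names(resp))
  if (length(missing_cols))
    stop("missing EQ-5D column(s): ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(resp[dims])
  if (any(!is.na(m) & !(m %in% 1:3)))
    stop("EQ-5D levels must be 1, 2 or 3")
  u <- rep(NA_real_, nrow(m))
  complete <- rowSums(is.na(m)) == 0
  if (any(complete)) {
    mc <- m[complete, , drop = FALSE]
    dec <- rowSums((mc == 2) * rep(tariff$level2, each = nrow(mc))) +
           rowSums((mc == 3) * rep(tariff$level3, each = nrow(mc)))
    any_problem <- rowSums(mc > 1) > 0
    any_l3 <- rowSums(mc == 3) > 0
    u[complete] <- 1 - any_problem * tariff$constant - dec - any_l3 * tariff$n3
  }
  u
}

#' Theoretical bounds of an EQ-5D tariff
#' @param tariff Value set.
#' @param digits Reporting precision (the published tariff prints 2 decimals).
#' @return Named vector `c(min = ..., max = ...)` at reporting precision.
#' @export
eq5d_bounds <- function(tariff = dutch_tariff(), digits = 2) {
  worst <- eq5d_utility(rep(3, 5), tariff)
  c(min = round(worst, digits), max = 1.00)
}
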