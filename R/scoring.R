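#' Pro-rating policy for partially missing components
#'
#' Maximum number of missing items tolerated in each multi-item component
#' before the respondent is declared not scoreable.  Defaults follow the
#' published rule of fewer than 5 missing morbidity and functional-limitation
#' items and fewer than 2 missing emotional-wellbeing items.
#'
#' @param max_missing_morbidities,max_missing_functional,max_missing_emotional
#'   integer thresholds (missing counts strictly above them fail).
#' @return A list classed `"cep_prorating_policy"`.
#' @export
prorating_policy <- function(max_missing_morbidities = 4L,
                             max_missing_functional = 4L,
                             max_missing_emotional = 1L) {
  p <- list(morbidities = as.integer(max_missing_morbidities),
            functional_limitations = as.integer(max_missing_functional),
            emotional_wellbeing = as.integer(max_missing_emotional))
  if (any(unlist(p) < 0L)) stop("thresholds must be non-negative")
  if (p$morbidities >= 17L || p$functional_limitations >= 15L ||
      p$emotional_wellbeing >= 5L)
    stop("each threshold must be smaller than the component's item count")
  class(p) <- "cep_prorating_policy"
  p
}

#' Preference weights and derived index anchors
#'
#' The published preference-weight formula: raw score = 9.00 (intercept) minus
#' a weighted sum of the eight components.  `raw_min` and `raw_range` are
#' derived from the component maxima of the active coding scheme (never
#' hard-coded), so alternative codings remain internally consistent.
#'
#' @param scheme Coding scheme supplying the component maxima.
#' @param intercept Intercept of the raw-score formula, in points.
#' @param weights Named vector of the eight component weights (points per
#'   component unit, all positive; they enter the formula with a minus sign).
#' @return A list classed `"cep_weights"` with `intercept`, `weights`,
#'   `component_max`, `raw_min`, `raw_max`, `raw_range`.
#' @export
topics_weights <- function(scheme = default_coding_scheme(),
                           intercept = 9.00,
                           weights = c(morbidities = 0.18,
                                       functional_limitations = 0.12,
                                       emotional_wellbeing = 0.03,
                                       pain = 0.03,
                                       cognition = 0.14,
                                       social_functioning = 0.01,
                                       self_perceived_health = 0.17,
                                       self_perceived_qol = 0.02)) {
  comps <- cep_components()
  if (!setequal(names(weights), comps))
    stop("weights must be named by the eight components")
  weights <- weights[comps]
  if (any(weights <= 0)) stop("all preference weights must be positive")
  cm <- component_maxima(scheme)
  w <- list(intercept = intercept, weights = weights, component_max = cm,
            raw_max = intercept,
            raw_min = intercept - sum(weights * cm),
            raw_range = sum(weights * cm))
  if (w$raw_range <= 0) stop("raw score range must be positive")
  class(w) <- "cep_weights"
  w
}

#' Pro-rate a partially answered component
#'
#' Estimates a multi-item component from its answered items as
#' `answered_sum / n_answered * n_items`; e.g. 12 of 15 functional-limitation
#' items answered with sum 6 gives (6/12) x 15 = 7.5.
#'
#' @param answered_sum Sum of the answered (oriented) items.
#' @param n_answered Number of answered items (must be >= 1).
#' @param n_items Total items in the component.
#' @return Pro-rated component score in points.
#' @export
prorate_component <- function(answered_sum, n_answered, n_items) {
  if (any(n_answered < 1)) stop("component with no answered items cannot be pro-rated")
  if (any(n_answered > n_items)) stop("n_answered exceeds n_items")
  if (any(answered_sum < 0)) stop("answered_sum must be non-negative")
  answered_sum / n_answered * n_items
}

#' Aggregate oriented items into the eight component scores
#'
#' Sums the three multi-item components (pro-rating within the policy's
#' missing-item thresholds) and copies the five single-item components.  A
#' respondent exceeding any threshold, or missing any single-item component,
#' is not scoreable and gets NA components.
#'
#' @param oriented data.frame of oriented items from [reverse_code()].
#' @param policy A [prorating_policy()].
#' @param scheme The coding scheme used for orientation.
#' @return data.frame with one column per component, logical `scoreable`, and
#'   logical `prorated_<component>` flags for the three multi-item components.
#' @export
aggregate_components <- function(oriented,
                                 policy = prorating_policy(),
                                 scheme = default_coding_scheme()) {
  comps <- cep_components()
  multi <- names(unclass(policy))
  out <- as.data.frame(matrix(NA_real_, nrow(oriented), length(comps),
                              dimnames = list(NULL, comps)))
  scoreable <- rep(TRUE, nrow(oriented))
  flags <- list()
  for (comp in comps) {
    cols <- scheme$item[scheme$component == comp]
    m <- as.matrix(oriented[cols])
    if (comp %in% multi) {
      n_items <- length(cols)
      n_miss <- rowSums(is.na(m))
      ok <- n_miss <= policy[[comp]]
      scoreable <- scoreable & ok
      s <- rowSums(m, na.rm = TRUE)
      n_ans <- n_items - n_miss
      val <- ifelse(n_ans > 0, s / pmax(n_ans, 1) * n_items, NA_real_)
      val[!ok] <- NA_real_
      out[[comp]] <- val
      flags[[paste0("prorated_", comp)]] <- ok & n_miss > 0
    } else {
      v <- m[, 1]
      scoreable <- scoreable & !is.na(v)
      out[[comp]] <- v
    }
  }
  out[!scoreable, ] <- NA_real_
  out$scoreable <- scoreable
  for (nm in names(flags)) out[[nm]] <- flags[[nm]] & scoreable
  out
}

#' Raw composite-endpoint score
#'
#' Intercept minus the preference-weighted component sum.
#'
#' @param components data.frame (or named list) with the eight component
#'   columns, e.g. from [aggregate_components()].
#' @param w Preference weights from [topics_weights()].
#' @return Numeric vector of raw scores in points (NA where not scoreable).
#' @export
raw_cep <- function(components, w = topics_weights()) {
  m <- sapply(cep_components(), function(k) components[[k]])
  m <- matrix(m, ncol = length(cep_components()))
  w$intercept - as.numeric(m %*% w$weights)
}

#' Index a raw score onto the 0-10 scale
#'
#' Affine map `(raw - raw_min) / raw_range * 10`; 0 is the worst and 10 the
#' best attainable state under the active coding scheme.
#'
#' @param raw Numeric vector of raw scores.
#' @param w Preference weights from [topics_weights()].
#' @return Indexed scores on 0-10.
#' @export
index_cep <- function(raw, w = topics_weights()) {
  bad <- !is.na(raw) & (raw < w$raw_min - 1e-9 | raw > w$raw_max + 1e-9)
  if (any(bad))
    stop(sprintf("raw score %g outside [%g, %g]: coding scheme and weights disagree",
                 raw[which(bad)[1]], w$raw_min, w$raw_max))
  (raw - w$raw_min) / w$raw_range * 10
}

#' Score the composite endpoint from raw item responses
#'
#' Runs the four scoring steps — reverse coding, component aggregation with
#' pro-rating, preference weighting, and the 0-10 index transformation — for
#' each row of an item table.
#'
#' @param items data.frame of raw item responses (one respondent per row)
#'   covering the scheme's item columns.
#' @param scheme Coding scheme; default [default_coding_scheme()].
#' @param policy Pro-rating policy; default [prorating_policy()].
#' @param w Preference weights; default [topics_weights()] on `scheme`.
#' @return data.frame with the eight component scores, pro-rating flags,
#'   `raw_cep`, `indexed_cep` and logical `scoreable`.
#' @export
score_cep <- function(items,
                      scheme = default_coding_scheme(),
                      policy = prorating_policy(),
                      w = topics_weights(scheme)) {
  oriented <- reverse_code(items, scheme)
  comp <- aggregate_components(oriented, policy, scheme)
  comp$raw_cep <- raw_cep(comp, w)
  comp$indexed_cep <- index_cep(comp$raw_cep, w)
  comp
}

#' Validate a Cantril ladder score
#'
#' Life-satisfaction rating on the 0 (completely unsatisfied) to 10
#' (completely satisfied) self-anchoring ladder.  Missing values pass
#' through; out-of-range values raise an error.
#'
#' @param value Numeric vector.
#' @return The validated values.
#' @export
cantril_validate <- function(value) {
  bad <- !is.na(value) & (value < 0 | value > 10 | value != round(value))
  if (any(bad))
    stop(sprintf("Cantril ladder score %s outside integer range 0-10",
                 format(value[which(bad)[1]])))
  value
}
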