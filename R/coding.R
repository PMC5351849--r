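#' Component names of the composite endpoint
#'
#' The eight health/wellbeing domains combined by the composite endpoint, in
#' the order of the preference-weight formula.
#'
#' @return Character vector of length 8.
#' @export
cep_components <- function() {
  c("morbidities", "functional_limitations", "emotional_wellbeing",
    "pain", "cognition", "social_functioning",
    "self_perceived_health", "self_perceived_qol")
}

#' Default item coding scheme
#'
#' One row per item: its level range, the component it belongs to, and whether
#' it is reverse coded.  Orientation maps every item onto a 0-based scale with
#' 0 = best state, so component maxima are 17 (morbidities), 15 (functional
#' limitations), 25 (emotional wellbeing), 2 (pain), 2 (cognition) and 4 for
#' each of the remaining single-item domains.
#'
#' Item conventions: the 17 morbidity indicators and 15 Katz-derived
#' functional-limitation items are 0/1 with 1 = condition present / limited;
#' the five RAND-36 mental-health items are scored 1-6 on "how much of the
#' time", with the two positively phrased items (calm/peaceful, happy) coded
#' so that level 1 is best and the three negatively phrased ones reverse
#' coded; pain and cognition are the 3-level EQ-5D(+C) dimensions; social
#' functioning is the 5-level RAND-36 interference item (level 5 = never, so
#' reverse coded); self-perceived health and quality of life run 1 =
#' excellent to 5 = poor.
#'
#' The per-item level ranges and reverse directions are a versioned default
#' configuration and can be overridden via [coding_scheme()].
#'
#' @return A data.frame with columns `item`, `component`, `min_level`,
#'   `max_level`, `reverse`.
#' @export
default_coding_scheme <- function() {
  morb <- sprintf("morb_%02d", 1:17)
  func <- sprintf("func_%02d", 1:15)
  emot <- sprintf("emot_%02d", 1:5)
  scheme <- rbind(
    data.frame(item = morb, component = "morbidities",
               min_level = 0, max_level = 1, reverse = FALSE),
    data.frame(item = func, component = "functional_limitations",
               min_level = 0, max_level = 1, reverse = FALSE),
    data.frame(item = emot, component = "emotional_wellbeing",
               min_level = 1, max_level = 6,
               # nervous, down-in-dumps, downhearted phrased negatively
               reverse = c(TRUE, TRUE, FALSE, TRUE, FALSE)),
    data.frame(item = "pain", component = "pain",
               min_level = 1, max_level = 3, reverse = FALSE),
    data.frame(item = "cognition", component = "cognition",
               min_level = 1, max_level = 3, reverse = FALSE),
    data.frame(item = "social_functioning", component = "social_functioning",
               min_level = 1, max_level = 5, reverse = TRUE),
    data.frame(item = "self_perceived_health",
               component = "self_perceived_health",
               min_level = 1, max_level = 5, reverse = FALSE),
    data.frame(item = "self_perceived_qol", component = "self_perceived_qol",
               min_level = 1, max_level = 5, reverse = FALSE)
  )
  rownames(scheme) <- scheme$item
  coding_scheme(scheme)
}

#' Validate (or override) a coding scheme
#'
#' @param scheme data.frame with columns `item`, `component`, `min_level`,
#'   `max_level`, `reverse`.
#' @return The validated scheme, classed `"cep_coding_scheme"`.
#' @export
coding_scheme <- function(scheme) {
  req <- c("item", "component", "min_level", "max_level", "reverse")
  if (!all(req %in% names(scheme)))
    stop("coding scheme must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(scheme$item))
    stop("duplicated item names in coding scheme")
  if (any(scheme$max_level <= scheme$min_level))
    stop("degenerate item level range (max_level must exceed min_level)")
  bad <- setdiff(scheme$component, cep_components())
  if (length(bad))
    stop("unknown component(s): ", paste(bad, collapse = ", "))
  rownames(scheme) <- scheme$item
  class(scheme) <- c("cep_coding_scheme", "data.frame")
  scheme
}

#' Post-orientation maximum of each component
#'
#' @param scheme A coding scheme.
#' @return Named numeric vector over [cep_components()].
#' @export
component_maxima <- function(scheme) {
  spans <- scheme$max_level - scheme$min_level
  mx <- tapply(spans, factor(scheme$component, levels = cep_components()), sum)
  stats::setNames(as.numeric(mx), cep_components())
}

#' Reverse-coding map
#'
#' Reflects levels within `[min_level, max_level]`; an involution on the
#' item's level set.  Missing values pass through.
#'
#' @param x numeric vector of levels.
#' @param min_level,max_level the item's level range.
#' @return Reflected levels.
#' @export
reverse_map <- function(x, min_level, max_level) {
  min_level + max_level - x
}

#' Orient item responses so that 0 is the best state
#'
#' Applies the reverse-coding map to items flagged `reverse` in the scheme and
#' shifts every item to a 0-based scale.  Missingness is preserved.
#'
#' @param items data.frame of raw item responses; columns must cover the
#'   scheme's items.
#' @param scheme A coding scheme (default [default_coding_scheme()]).
#' @return data.frame of oriented item values (0 = best), same rows.
#' @export
reverse_code <- function(items, scheme = default_coding_scheme()) {
  missing_cols <- setdiff(scheme$item, names(items))
  if (length(missing_cols))
    stop("missing item column(s): ", paste(missing_cols, collapse = ", "))
  out <- items[scheme$item]
  for (i in seq_len(nrow(scheme))) {
    nm <- scheme$item[i]
    v <- out[[nm]]
    ok <- is.na(v) | (v >= scheme$min_level[i] & v <= scheme$max_level[i])
    if (!all(ok)) {
      row <- which(!ok)[1]
      stop(sprintf("item '%s', row %d: level %s outside [%g, %g]",
                   nm, row, format(v[row]),
                   scheme$min_level[i], scheme$max_level[i]))
    }
    if (scheme$reverse[i])
      v <- reverse_map(v, scheme$min_level[i], scheme$max_level[i])
    out[[nm]] <- v - scheme$min_level[i]
  }
  out
}
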