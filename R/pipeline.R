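#' Read a respondent-level CSV
#'
#' UTF-8, header row, comma separated, "." decimal, empty cell = missing.
#' A `project_id` column is required.
#'
#' @param path CSV path.
#' @return data.frame with `project_id` as a factor.
#' @export
read_respondents <- function(path) {
  d <- utils::read.csv(path, na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (!"project_id" %in% names(d))
    stop("input is missing the required 'project_id' column")
  d$project_id <- factor(d$project_id)
  d
}

#' Score a respondent table
#'
#' Appends the composite-endpoint scores (raw, indexed, scoreable flag),
#' the EQ-5D utility and the validated Cantril score to an item-level
#' respondent table.
#'
#' @param data data.frame with the scheme's item columns, the EQ-5D dimension
#'   columns and a `cantril` column.
#' @param scheme,policy,w Scoring configuration (see [score_cep()]).
#' @param tariff EQ-5D value set.
#' @return `data` with appended `raw_cep`, `indexed_cep`, `scoreable`,
#'   `eq5d_utility` and validated `cantril` columns.
#' @export
score_dataset <- function(data,
                          scheme = default_coding_scheme(),
                          policy = prorating_policy(),
                          w = topics_weights(scheme),
                          tariff = dutch_tariff()) {
  sc <- score_cep(data, scheme, policy, w)
  data$raw_cep <- sc$raw_cep
  data$indexed_cep <- sc$indexed_cep
  data$scoreable <- sc$scoreable
  if (all(eq5d_dimensions() %in% names(data)))
    data$eq5d_utility <- eq5d_utility(data, tariff)
  if ("cantril" %in% names(data))
    data$cantril <- cantril_validate(data$cantril)
  data
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys (all optional): `prorating_policy`
#' (`max_missing_morbidities`, `max_missing_functional`,
#' `max_missing_emotional`), `weights` (`intercept` and the eight component
#' weights), `floor_ceiling_threshold`, `pct_change_threshold`, and
#' `generator` (arguments of [generator_config()] other than the correlation
#' matrix and covariate specs).
#'
#' @param path YAML file.
#' @return Named list of overrides merged over the package defaults.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- list(policy = prorating_policy(), weights = topics_weights(),
              floor_ceiling_threshold = 15, pct_change_threshold = 15,
              generator = generator_config())
  if (!is.null(raw$prorating_policy))
    cfg$policy <- do.call(prorating_policy, raw$prorating_policy)
  if (!is.null(raw$weights)) {
    int <- raw$weights$intercept %||% 9.00
    ww <- raw$weights[setdiff(names(raw$weights), "intercept")]
    defaults <- topics_weights()$weights
    defaults[names(ww)] <- unlist(ww)
    cfg$weights <- topics_weights(intercept = int, weights = defaults)
  }
  if (!is.null(raw$floor_ceiling_threshold))
    cfg$floor_ceiling_threshold <- raw$floor_ceiling_threshold
  if (!is.null(raw$pct_change_threshold))
    cfg$pct_change_threshold <- raw$pct_change_threshold
  if (!is.null(raw$generator))
    cfg$generator <- do.call(generator_config, raw$generator)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full scoring and validation pipeline
#'
#' Orchestrates score -> describe -> convergent validity -> known groups and
#' writes one CSV per stage plus a run log.  Input is either a respondent CSV
#' (`input`) or a synthetic cohort drawn from `generator` at `seed`; the run
#' is deterministic given input and seed.
#'
#' @param input Path to a respondent CSV, or NULL to generate synthetically.
#' @param outdir Output directory (created if absent).
#' @param mode `"items"` (raw items, scored by the package) or `"outcomes"`
#'   (ready-scored `indexed_cep`, `cantril`, `eq5d_utility` columns).
#' @param generator [generator_config()] used when `input` is NULL.
#' @param seed Seed for synthetic generation.
#' @param by Stratification column for the report tables, or NULL.
#' @param factors Known-group characteristics present in the data.
#' @param scheme,policy,w,tariff Scoring configuration.
#' @param floor_ceiling_threshold,pct_change_threshold Report thresholds.
#' @return Invisibly, a list with `scored`, `descriptives`, `convergent`,
#'   `known_groups` and `log` (named character vector).
#' @export
run_pipeline <- function(input = NULL, outdir,
                         mode = c("items", "outcomes"),
                         generator = generator_config(), seed = 1L,
                         by = "setting",
                         factors = c("marital_status", "living_arrangement",
                                     "education", "dementia", "depression",
                                     "dizziness_falls"),
                         scheme = default_coding_scheme(),
                         policy = prorating_policy(),
                         w = topics_weights(scheme),
                         tariff = dutch_tariff(),
                         floor_ceiling_threshold = 15,
                         pct_change_threshold = 15) {
  mode <- match.arg(mode)
  if (is.null(input)) {
    data <- if (mode == "items") generate_items(generator, seed, scheme)
            else generate_outcomes(generator, seed)
    data <- strip_ground_truth(data)
  } else {
    data <- read_respondents(input)
  }
  n_input <- nrow(data)
  if (mode == "items") {
    data <- score_dataset(data, scheme, policy, w, tariff)
  } else {
    need <- c("indexed_cep", "cantril", "eq5d_utility")
    miss <- setdiff(need, names(data))
    if (length(miss))
      stop("stage 'score': outcome mode requires column(s): ",
           paste(miss, collapse = ", "))
    data$scoreable <- !is.na(data$indexed_cep)
  }
  if (!is.null(by) && !by %in% names(data))
    stop("stage 'validate': stratification column '", by, "' not found")
  scored <- data[data$scoreable, , drop = FALSE]
  n_excluded <- n_input - nrow(scored)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  desc <- stage("describe",
                describe_outcomes(scored, by = by,
                                  threshold = floor_ceiling_threshold))
  conv <- stage("converge", convergent_validity(scored, by = by))
  kg <- stage("knowngroups",
              known_group_validity(scored,
                                   factors = intersect(factors, names(scored)),
                                   threshold = pct_change_threshold))

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_out <- function(obj, file) {
    utils::write.csv(obj, file.path(outdir, file), row.names = FALSE)
  }
  write_out(data, "scored.csv")
  write_out(desc, "table1_descriptives.csv")
  write_out(conv, "table2_convergent.csv")
  write_out(kg, "table3_knowngroups.csv")
  log <- c(package_version = as.character(utils::packageVersion("topicscep")),
           r_version = paste(R.version$major, R.version$minor, sep = "."),
           seed = as.character(seed),
           input = if (is.null(input)) "synthetic" else input,
           mode = mode,
           n_input = as.character(n_input),
           n_scoreable = as.character(nrow(scored)),
           n_excluded_not_scoreable = as.character(n_excluded),
           pct_complete = sprintf("%.1f", 100 * nrow(scored) / n_input))
  writeLines(paste(names(log), log, sep = ": "), file.path(outdir, "run_log.txt"))
  invisible(list(scored = data, descriptives = desc, convergent = conv,
                 known_groups = kg, log = log))
}
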