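# Fixture builders: respondent records at chosen states of the item lattice.

# a one-row item table with every item at its best (or worst) raw level
make_record <- function(state = c("best", "worst"),
                        scheme = default_coding_scheme()) {
  state <- match.arg(state)
  raw <- if (state == "best") {
    ifelse(scheme$reverse, scheme$max_level, scheme$min_level)
  } else {
    ifelse(scheme$reverse, scheme$min_level, scheme$max_level)
  }
  as.data.frame(as.list(stats::setNames(raw, scheme$item)))
}

# a one-row item table with uniformly random levels (optionally with NAs)
random_record <- function(scheme = default_coding_scheme(), na_prob = 0) {
  raw <- mapply(function(lo, hi) sample(lo:hi, 1),
                scheme$min_level, scheme$max_level)
  if (na_prob > 0) raw[runif(length(raw)) < na_prob] <- NA
  as.data.frame(as.list(stats::setNames(raw, scheme$item)))
}

# raw level whose oriented value is `oriented` for scheme row i
raw_for_oriented <- function(scheme, item, oriented) {
  i <- match(item, scheme$item)
  if (scheme$reverse[i]) scheme$max_level[i] - oriented
  else oriented + scheme$min_level[i]
}
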