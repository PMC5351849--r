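test_that("orientation maps every best-state item to 0 and worst to its span", {
  sch <- default_coding_scheme()
  best <- reverse_code(make_record("best"), sch)
  expect_true(all(unlist(best) == 0))
  worst <- reverse_code(make_record("worst"), sch)
  expect_equal(unname(unlist(worst)),
               unname(sch$max_level - sch$min_level))
})

test_that("the reverse-coding map is an involution on each item's level set", {
  sch <- default_coding_scheme()
  for (i in seq_len(nrow(sch))) {
    lv <- sch$min_level[i]:sch$max_level[i]
    expect_equal(reverse_map(reverse_map(lv, sch$min_level[i], sch$max_level[i]),
                             sch$min_level[i], sch$max_level[i]), lv)
  }
})

test_that("5-level social-functioning item at its worst level orients to 4", {
  rec <- make_record("best")
  rec$social_functioning <- 1  # reverse-coded item: level 1 = worst
  expect_equal(reverse_code(rec)$social_functioning, 4)
})

test_that("out-of-range levels raise a validation error naming the item", {
  rec <- make_record("best")
  rec$pain <- 4
  expect_error(reverse_code(rec), "pain")
  rec2 <- make_record("best")
  rec2$morb_03 <- 2
  expect_error(reverse_code(rec2), "morb_03")
})

test_that("missingness passes through orientation untouched", {
  rec <- make_record("best")
  rec$emot_02 <- NA
  expect_true(is.na(reverse_code(rec)$emot_02))
})

test_that("pro-rating follows answered_sum / n_answered * n_items", {
  expect_identical(prorate_component(6, 12, 15), 7.5)
  expect_identical(prorate_component(3, 4, 16), 12)
  # complete component is the plain sum
  for (s in c(0, 2, 9)) expect_identical(prorate_component(s, 15, 15), s)
  # scale equivariance
  expect_equal(prorate_component(8, 10, 15), 2 * prorate_component(4, 10, 15))
  expect_error(prorate_component(0, 0, 15), "pro-rat")
  expect_error(prorate_component(5, 16, 15), "exceeds")
})

test_that("component aggregation pro-rates within policy and fails beyond it", {
  sch <- default_coding_scheme()
  rec <- make_record("best")
  oriented <- reverse_code(rec, sch)
  agg <- aggregate_components(oriented)
  expect_true(agg$scoreable)
  expect_equal(unlist(agg[cep_components()]), setNames(rep(0, 8), cep_components()))

  # worked example: 12 functional items answered summing to 6, 3 missing
  rec2 <- make_record("best")
  func <- grep("^func_", sch$item, value = TRUE)
  rec2[func[1:6]] <- 1   # six limitations present
  rec2[func[13:15]] <- NA
  agg2 <- aggregate_components(reverse_code(rec2, sch))
  expect_equal(agg2$functional_limitations, 7.5)
  expect_true(agg2$prorated_functional_limitations)
  expect_true(agg2$scoreable)

  # 5 missing morbidities breaches the "fewer than 5" rule
  rec3 <- make_record("best")
  rec3[sprintf("morb_%02d", 1:5)] <- NA
  agg3 <- aggregate_components(reverse_code(rec3, sch))
  expect_false(agg3$scoreable)
  expect_true(is.na(agg3$morbidities))

  # 4 missing is still scoreable
  rec4 <- make_record("best")
  rec4[sprintf("morb_%02d", 1:4)] <- NA
  expect_true(aggregate_components(reverse_code(rec4, sch))$scoreable)

  # a missing single-item component is never scoreable
  rec5 <- make_record("best")
  rec5$self_perceived_health <- NA
  expect_false(aggregate_components(reverse_code(rec5, sch))$scoreable)

  # 2 missing emotional-wellbeing items breach their threshold of < 2
  rec6 <- make_record("best")
  rec6[c("emot_01", "emot_02")] <- NA
  expect_false(aggregate_components(reverse_code(rec6, sch))$scoreable)
})

test_that("raw score applies the printed preference-weight formula", {
  w <- topics_weights()
  zero <- as.data.frame(as.list(setNames(rep(0, 8), cep_components())))
  expect_identical(raw_cep(zero, w), 9.00)
  # independent hand evaluation of the linear formula
  comp <- as.data.frame(as.list(setNames(c(2, 1, 5, 1, 0, 1, 2, 1),
                                         cep_components())))
  expect_equal(raw_cep(comp, w), 7.97)
  # all components at the scheme maxima reach raw_min
  mx <- as.data.frame(as.list(w$component_max))
  expect_equal(raw_cep(mx, w), w$raw_min)
  expect_equal(w$raw_min, 2.25)
  expect_equal(w$raw_range, 6.75)
})

test_that("index transformation is the affine map onto 0-10", {
  w <- topics_weights()
  expect_equal(index_cep(w$raw_max, w), 10)
  expect_equal(index_cep(w$raw_min, w), 0)
  expect_equal(index_cep((w$raw_min + w$raw_max) / 2, w), 5)
  expect_error(index_cep(w$raw_max + 0.5, w), "outside")
})

test_that("end-to-end scoring hits both anchors and the pro-rating example", {
  best <- score_cep(make_record("best"))
  expect_equal(best$indexed_cep, 10)
  worst <- score_cep(make_record("worst"))
  expect_equal(worst$indexed_cep, 0)
  # pro-rating worked example with all else best: raw 9 - 0.12 * 7.5 = 8.10
  rec <- make_record("best")
  func <- sprintf("func_%02d", 1:15)
  rec[func[1:6]] <- 1
  rec[func[13:15]] <- NA
  s <- score_cep(rec)
  expect_equal(s$raw_cep, 8.10)
  expect_equal(s$indexed_cep, (8.10 - 2.25) / 6.75 * 10)
})

test_that("indexed scores stay in [0, 10] over random item lattices", {
  set.seed(101)
  recs <- do.call(rbind, replicate(200, random_record(), simplify = FALSE))
  s <- score_cep(recs)
  expect_true(all(s$indexed_cep >= 0 & s$indexed_cep <= 10))
  expect_true(all(s$scoreable))
})

test_that("worsening any single component strictly decreases the score", {
  w <- topics_weights()
  base <- as.data.frame(as.list(setNames(rep(0, 8), cep_components())))
  for (comp in cep_components()) {
    for (val in c(1, w$component_max[[comp]])) {
      worse <- base
      worse[[comp]] <- val
      expect_lt(raw_cep(worse, w), raw_cep(base, w))
      expect_lt(index_cep(raw_cep(worse, w), w), index_cep(raw_cep(base, w), w))
    }
  }
})

test_that("Cantril validation passes integers 0-10 and rejects the rest", {
  expect_identical(cantril_validate(c(7, 0, 10, NA)), c(7, 0, 10, NA))
  expect_error(cantril_validate(11), "0-10")
  expect_error(cantril_validate(-1), "0-10")
  expect_error(cantril_validate(6.5), "0-10")
})

test_that("alternative coding schemes propagate to the index anchors", {
  # halve the emotional-wellbeing item range: component max 10 instead of 25
  sch <- default_coding_scheme()
  sch$max_level[grepl("^emot_", sch$item)] <- 3
  sch <- coding_scheme(sch)
  w <- topics_weights(sch)
  expect_equal(w$raw_range, 6.75 - 0.03 * 15)
  expect_equal(unname(component_maxima(sch)["emotional_wellbeing"]), 10)
})
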