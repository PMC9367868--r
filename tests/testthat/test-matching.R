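# Matching TTI labels to product shelf-life.

test_that("activation-energy compatibility uses the +/- 20 kJ/mol window", {
  expect_true(ea_compatible(113100, 97100))   # 16.0 kJ/mol apart
  expect_true(ea_compatible(133900, 148000))  # 14.1 kJ/mol apart
  expect_false(ea_compatible(113100, 148000)) # 34.9 kJ/mol apart
  expect_error(ea_compatible(-1, 1e5), class = "ttishelf_error_domain")
})

toy_curve <- function(days, temps = c(2, 6, 10)) {
  tibble::tibble(temperature_C = temps, shelf_life_d = days)
}

as_tti_curve <- function(curve) {
  tibble::tibble(temperature_C = curve$temperature_C,
                 response_d = curve$shelf_life_d)
}

test_that("match score handles identical, proportional and mixed curves", {
  shelf <- toy_curve(c(12, 8, 4))
  identical_match <- match_score(shelf, as_tti_curve(shelf))
  expect_equal(identical_match$max_abs_relative_deviation, 0)
  expect_true(identical_match$conservative_at_abuse)

  shrunk <- as_tti_curve(toy_curve(0.9 * c(12, 8, 4)))
  prop <- match_score(shelf, shrunk)
  expect_equal(prop$max_abs_relative_deviation, 0.1, tolerance = 1e-12)
  expect_true(prop$conservative_at_abuse)

  # 30% overshoot only below the abuse threshold: conservative but poorly
  # matched
  mixed <- tibble::tibble(temperature_C = c(2, 6, 10),
                          response_d = c(12 * 1.3, 8, 4))
  mix <- match_score(shelf, mixed, abuse_threshold_c = 6)
  expect_equal(mix$max_abs_relative_deviation, 0.3, tolerance = 1e-12)
  expect_true(mix$conservative_at_abuse)
  # the same overshoot above the threshold is flagged
  late <- tibble::tibble(temperature_C = c(2, 6, 10),
                         response_d = c(12, 8, 4 * 1.3))
  expect_false(match_score(shelf, late, 6)$conservative_at_abuse)

  other_grid <- tibble::tibble(temperature_C = c(0, 5, 10),
                               response_d = c(12, 8, 4))
  expect_error(match_score(shelf, other_grid),
               class = "ttishelf_error_format")
})

test_that("relative deviations are scale invariant", {
  shelf <- toy_curve(c(15, 9, 5))
  tti <- tibble::tibble(temperature_C = c(2, 6, 10),
                        response_d = c(14, 10, 4))
  m1 <- match_score(shelf, tti)
  shelf2 <- shelf; shelf2$shelf_life_d <- shelf2$shelf_life_d * 3.7
  tti2 <- tti; tti2$response_d <- tti2$response_d * 3.7
  m2 <- match_score(shelf2, tti2)
  expect_equal(m1$max_abs_relative_deviation, m2$max_abs_relative_deviation,
               tolerance = 1e-12)
})

test_that("selection ranks by deviation, filters by Ea and is order invariant", {
  spec <- shelf_life_spec(5, 7, kref = 0.4, Ea = 1e5, lambda_ref = 2)
  good <- tti_global_model("M", Ea = 1e5, k1ref = 40, k2ref = 8,
                           alpha = 0.8, beta = 0.8)
  off <- tti_global_model("M", Ea = 1.1e5, k1ref = 400, k2ref = 80,
                          alpha = 0.8, beta = 0.8)
  incompatible <- tti_global_model("LP", Ea = 1.5e5, k1ref = 40, k2ref = 8,
                                   alpha = 0.8, beta = 0.8)
  cand <- tibble::tibble(model = list(good, off, incompatible),
                         conc = c(10, 10, 10),
                         label = c("good", "off", "incompat"))
  ranked <- select_tti(spec, cand)
  expect_equal(ranked$label[which(ranked$rank == 1)], "good")
  expect_true(is.na(ranked$rank[ranked$label == "incompat"]))
  # order invariance
  ranked_rev <- select_tti(spec, cand[3:1, ])
  expect_equal(ranked$label, ranked_rev$label)
  # single compatible candidate ranks first
  solo <- select_tti(spec, cand[1, ])
  expect_equal(solo$rank, 1L)
  # no compatible candidate: empty ranking with a diagnostic
  expect_warning(none <- select_tti(spec, cand[3, ]),
                 class = "ttishelf_warning_no_compatible_tti")
  expect_true(all(is.na(none$rank)))
})

test_that("reference labels selected for seabream match the study outcome", {
  models <- reference_tti_models()
  # MAP-PAD product pairs with the M-type chemistry; M-25U must rank top 2
  spec_pad <- seabream_shelf_life_spec("MAP_PAD")
  cand_m <- tibble::tibble(model = rep(models["M"], 8),
                           conc = c(5, 10, 15, 20, 25, 50, 75, 100))
  ranked_m <- select_tti(spec_pad, cand_m)
  expect_true(all(ranked_m$ea_compatible))
  expect_lte(ranked_m$rank[ranked_m$label == "M-25U"], 2L)
  # MAP product pairs with the LP-type; LP-150U must rank top 2
  spec_map <- seabream_shelf_life_spec("MAP")
  cand_lp <- tibble::tibble(model = rep(models["LP"], 4),
                            conc = c(100, 150, 300, 500))
  ranked_lp <- select_tti(spec_map, cand_lp)
  expect_lte(ranked_lp$rank[ranked_lp$label == "LP-150U"], 2L)
  # cross-chemistry Ea screen: M-type is not admissible for the MAP product
  mixed <- select_tti(spec_pad, tibble::tibble(
    model = list(models$M, models$LP), conc = c(25, 150)))
  expect_false(mixed$ea_compatible[mixed$label == "LP-150U"])
})
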