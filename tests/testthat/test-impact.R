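test_that("linked components take their parent's coverage pair", {
  cat41 <- default_catalog()
  ids <- cat41$interventions$intervention_id
  base <- setNames(rep(0.3, length(ids)), ids)
  targ <- base
  base["facility_delivery"] <- 0.5
  targ["facility_delivery"] <- 0.7
  sc <- make_test_scenario(ids, unname(base), unname(targ))
  ec <- effective_coverage(sc, cat41)
  row <- ec[ec$intervention_id == "neonatal_resuscitation", ]
  expect_equal(c(row$c0, row$c1), c(0.5, 0.7))
  # direct interventions keep their own pair; parents are not in the output
  expect_equal(ec$c0[ec$intervention_id == "ors"], 0.3)
  expect_false("skilled_birth_attendant" %in% ec$intervention_id)
  expect_equal(nrow(ec), 38)
})

test_that("contraception scale-up shrinks the birth cohort by the stated formula", {
  cat1 <- make_test_catalog(
    tibble::tibble(intervention_id = "cpr", is_cpr = TRUE),
    tibble::tibble(intervention_id = character(), age_band = character(),
                   cause = character(), effectiveness = numeric(),
                   affected_fraction = numeric())
  )
  prof <- make_test_profile(live_births = 1e6)
  sc <- make_test_scenario("cpr", 0.20, 0.30, cpr_scaled = TRUE)
  expect_equal(births_under_scenario(prof, sc, cat1),
               1e6 * (1 - 0.27) / (1 - 0.18))   # 890243.9...
  # no scale-up (or equal prevalence): births unchanged
  sc0 <- make_test_scenario("cpr", 0.20, 0.20)
  expect_equal(births_under_scenario(prof, sc0, cat1), 1e6)
  # degenerate: all fecund exposure removed
  cat_hot <- cat1
  cat_hot$cpr_effectiveness <- 1
  sc_bad <- make_test_scenario("cpr", 0.2, 1)
  expect_error(births_under_scenario(prof, sc_bad, cat_hot), "degenerate")
})

test_that("residual fraction is the product over affecting interventions", {
  cat2 <- make_test_catalog(
    tibble::tibble(intervention_id = c("a", "b", "cpr"),
                   is_cpr = c(FALSE, FALSE, TRUE)),
    tibble::tibble(intervention_id = c("a", "b"),
                   age_band = "postneonatal", cause = "diarrhea",
                   effectiveness = c(0.5, 0.25),
                   affected_fraction = c(1, 0.8))
  )
  expect_equal(residual_fraction("pneumonia", "postneonatal",
                                 c(a = 0.4), cat2), 1)   # empty product
  expect_equal(residual_fraction("diarrhea", "postneonatal",
                                 c(a = 0.4), cat2), 0.8)
  # two interventions with E*AF*C of 0.2 and 0.1 leave 0.8 * 0.9
  expect_equal(residual_fraction("diarrhea", "postneonatal",
                                 c(a = 0.4, b = 0.5), cat2), 0.8 * 0.9)
})

test_that("single-intervention impact matches the closed form", {
  # D0 = 10000, E = 0.6, AF = 1, coverage 0.2 -> 0.7
  cat1 <- make_test_catalog(
    tibble::tibble(intervention_id = c("x", "cpr"), is_cpr = c(FALSE, TRUE)),
    tibble::tibble(intervention_id = "x", age_band = "postneonatal",
                   cause = "only", effectiveness = 0.6, affected_fraction = 1)
  )
  prof <- make_test_profile(live_births = 1e5, nmr = 0, post_nmr = 100,
                            pfrac = c(only = 1))
  sc <- make_test_scenario(c("x", "cpr"), c(0.2, 0.3), c(0.7, 0.3))
  imp <- run_impact(prof, sc, cat1)
  expect_equal(sum(imp$deaths$scenario), 10000 * (1 - 0.42) / (1 - 0.12),
               tolerance = 1e-12)
  expect_equal(imp$lives_saved_total, 10000 * (1 - 0.58 / 0.88),
               tolerance = 1e-9)
  att <- imp$lives_saved_by_intervention
  expect_equal(att$lives_saved[att$intervention_id == "x"],
               imp$lives_saved_total, tolerance = 1e-9)
})

test_that("a null scenario changes nothing", {
  set.seed(42)
  inst <- rand_instance(k = 3)
  sc <- inst$scenario
  sc$target <- sc$baseline
  imp <- run_impact(inst$profile, sc, inst$catalog)
  expect_equal(imp$lives_saved_total, 0, tolerance = 1e-9)
  expect_equal(imp$u5mr_change, 0, tolerance = 1e-12)
  expect_equal(imp$nmr_change, 0, tolerance = 1e-12)
  expect_true(all(imp$lives_saved_by_intervention$lives_saved == 0))
})

test_that("under-five accounting: bands sum to the total", {
  set.seed(99)
  inst <- rand_instance(k = 3, scale_cpr = TRUE)
  imp <- run_impact(inst$profile, inst$scenario, inst$catalog)
  expect_equal(sum(imp$lives_saved_by_age$lives_saved), imp$lives_saved_total,
               tolerance = 1e-9)
  expect_equal(imp$lives_saved_total,
               sum(imp$deaths$baseline) - sum(imp$deaths$scenario),
               tolerance = 1e-9)
  expect_true(all(imp$deaths$scenario <= imp$deaths$baseline + 1e-12))
})

test_that("zero-effect interventions never receive attribution", {
  cat2 <- make_test_catalog(
    tibble::tibble(intervention_id = c("real", "dud", "cpr"),
                   is_cpr = c(FALSE, FALSE, TRUE)),
    tibble::tibble(intervention_id = c("real", "dud"),
                   age_band = "postneonatal", cause = "only",
                   effectiveness = c(0.5, 0), affected_fraction = c(0.8, 0.9))
  )
  prof <- make_test_profile(nmr = 0, post_nmr = 50, pfrac = c(only = 1))
  sc <- make_test_scenario(c("real", "dud", "cpr"),
                           c(0.2, 0.2, 0.3), c(0.6, 0.9, 0.3))
  imp <- run_impact(prof, sc, cat2)
  att <- setNames(imp$lives_saved_by_intervention$lives_saved,
                  imp$lives_saved_by_intervention$intervention_id)
  expect_equal(att[["dud"]], 0)
  expect_gt(att[["real"]], 0)
  expect_equal(sum(att), imp$lives_saved_total, tolerance = 1e-9)
})
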