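test_that("raw ratio is top-quintile over national, unfloored, NA-safe", {
  expect_equal(compute_raw_ratio(0.40, 0.50), 1.25)
  expect_equal(compute_raw_ratio(0.40, 0.38), 0.95)   # pro-poor stays sub-1
  expect_true(is.na(compute_raw_ratio(NA, 0.5)))
  expect_true(is.na(compute_raw_ratio(0.4, NA)))
  expect_message(r <- compute_raw_ratio(0, 0.5), "undefined")
  expect_true(is.na(r))
})

make_cov <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(country_id = "A", intervention_id = r$id,
                   national = r$nat %||% NA_real_,
                   q1 = NA_real_, q2 = NA_real_, q3 = NA_real_, q4 = NA_real_,
                   q5 = r$q5 %||% NA_real_)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("proxy/backup resolution follows the delivery graph one level deep", {
  cat41 <- default_catalog()
  cov <- make_cov(list(id = "dpt_vaccine", nat = 0.50, q5 = 0.55),
                  list(id = "hib_vaccine"),                     # missing survey
                  list(id = "ors", nat = 0.40, q5 = 0.466),
                  list(id = "itn", nat = 0.60, q5 = 0.57))
  r <- resolve_ratios(cov, cat41)
  g <- function(id, col) r[[col]][r$intervention_id == id]
  # direct intervention missing from the survey falls back to its backup
  expect_equal(g("hib_vaccine", "applied_ratio"), 1.1)
  expect_equal(g("hib_vaccine", "provenance"), "backup(dpt_vaccine)")
  # proxied interventions always borrow their source's resolved ratio
  expect_equal(g("zinc_diarrhea", "applied_ratio"), 1.165)
  expect_equal(g("zinc_diarrhea", "provenance"), "proxy(ors)")
  expect_equal(g("hepb_vaccine", "applied_ratio"), 1.1)
  # pro-poor ratio floors to 1 in applied form, stays raw in raw form
  expect_equal(g("itn", "raw_ratio"), 0.95)
  expect_equal(g("itn", "applied_ratio"), 1)
  # nothing measured and no backup -> unavailable with missing applied ratio
  expect_equal(g("improved_water_source", "provenance"), "unavailable")
  expect_true(is.na(g("improved_water_source", "applied_ratio")))
  expect_true(all(r$applied_ratio >= 1, na.rm = TRUE))
})

test_that("linked components inherit their parent contact point's ratio", {
  cat41 <- default_catalog()
  cov <- make_cov(list(id = "facility_delivery", nat = 0.50, q5 = 0.70),
                  list(id = "antenatal_care", nat = 0.60, q5 = 0.72))
  r <- resolve_ratios(cov, cat41)
  expect_equal(r$applied_ratio[r$intervention_id == "neonatal_resuscitation"], 1.4)
  expect_equal(r$provenance[r$intervention_id == "neonatal_resuscitation"],
               "proxy(facility_delivery)")
  expect_equal(r$applied_ratio[r$intervention_id == "tetanus_toxoid"], 1.2)
})

test_that("top-quintile missing while national present resolves via backup", {
  cat41 <- default_catalog()
  cov <- make_cov(list(id = "ors", nat = 0.40),             # q5 absent
                  list(id = "oral_antibiotics", nat = 0.30, q5 = 0.36))
  r <- resolve_ratios(cov, cat41)
  expect_equal(r$provenance[r$intervention_id == "ors"],
               "backup(oral_antibiotics)")
  expect_equal(r$applied_ratio[r$intervention_id == "ors"], 1.2)
})

test_that("scenario targets apply floored ratios with a cap at full coverage", {
  wx <- make_worked_example()
  sc <- build_scenario(wx$profile, wx$coverage, wx$catalog, "full")
  g <- function(id) sc$target[sc$intervention_id == id]
  expect_equal(g("ors"), 0.4 * 1.25)
  expect_equal(g("zinc"), 0.2 * 1.25)
  expect_equal(g("itn"), 0.6)                 # floored ratio leaves it put
  expect_true(all(sc$target >= sc$baseline))
  # cap: very high baseline times ratio > 1 stops at 1
  cov2 <- wx$coverage
  cov2$national[cov2$intervention_id == "ors"] <- 0.95
  cov2$q5[cov2$intervention_id == "ors"] <- 0.99   # ratio ~1.042
  sc2 <- suppressWarnings(build_scenario(wx$profile, cov2, wx$catalog, "full"))
  expect_equal(sc2$target[sc2$intervention_id == "ors"], pmin(0.95 * (0.99 / 0.95), 1))
  expect_lte(max(sc2$target), 1)
})

test_that("the fertility gate controls contraception scale-up", {
  wx <- make_worked_example()
  low <- wx$profile                      # tfr = 2.0, below the 2.33 gate
  sc_low <- build_scenario(low, wx$coverage, wx$catalog, "full")
  expect_false(attr(sc_low, "cpr_scaled"))
  expect_equal(sc_low$target[sc_low$intervention_id == "cpr"],
               sc_low$baseline[sc_low$intervention_id == "cpr"])
  high <- low
  high$tfr <- 3.0
  sc_high <- build_scenario(high, wx$coverage, wx$catalog, "full")
  expect_true(attr(sc_high, "cpr_scaled"))
  expect_equal(sc_high$target[sc_high$intervention_id == "cpr"], 0.4)
})

test_that("limited scope is nested in full scope; single mode moves one item", {
  sim <- simulate_equity_data(n_countries = 4, seed = 7)
  cat41 <- default_catalog()
  for (r in seq_len(4)) {
    p <- sim$profiles[r, ]
    full <- suppressMessages(build_scenario(p, sim$coverage, cat41, "full"))
    lim <- suppressMessages(build_scenario(p, sim$coverage, cat41, "limited"))
    moved_full <- full$intervention_id[full$target > full$baseline]
    moved_lim <- lim$intervention_id[lim$target > lim$baseline]
    expect_true(all(moved_lim %in% moved_full))
    proxied <- cat41$interventions$intervention_id[
      cat41$interventions$channel == "proxied"]
    expect_length(intersect(moved_lim, proxied), 0)
  }
  p <- sim$profiles[1, ]
  single <- suppressMessages(
    build_scenario(p, sim$coverage, cat41, "single", intervention = "ors"))
  moved <- single$intervention_id[single$target > single$baseline]
  expect_equal(moved, "ors")
})

test_that("identical inputs give identical scenarios and ratio tables", {
  sim <- simulate_equity_data(n_countries = 2, seed = 11)
  cat41 <- default_catalog()
  r1 <- resolve_ratios(sim$coverage, cat41)
  r2 <- resolve_ratios(sim$coverage, cat41)
  expect_identical(r1, r2)
  s1 <- suppressMessages(build_scenario(sim$profiles[1, ], sim$coverage, cat41, "full"))
  s2 <- suppressMessages(build_scenario(sim$profiles[1, ], sim$coverage, cat41, "full"))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("equal quintiles mean unit ratios and a do-nothing scenario", {
  sim <- simulate_equity_data(n_countries = 3, seed = 3, gradient_scale = 0,
                              missingness_prob = 0)
  r <- resolve_ratios(sim$coverage, default_catalog())
  expect_true(all(abs(r$raw_ratio - 1) < 1e-12, na.rm = TRUE))
  sc <- build_scenario(sim$profiles[1, ], sim$coverage, default_catalog(), "full")
  expect_equal(sc$target, sc$baseline)
})
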