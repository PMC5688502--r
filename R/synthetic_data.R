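#' Simulate wealth-quintile coverage surveys and country profiles
#'
#' Seeded generator emulating the statistical structure of household-survey
#' inputs: for each country and intervention an intercept is drawn
#' uniformly on the logit of `base_coverage_range` and a wealth gradient
#' `beta` from a half-normal with scale `gradient_scale`; quintile
#' coverage is `plogis(alpha + beta * (q - 3))`, nondecreasing in wealth
#' for positive gradients, and national coverage is the unweighted mean of
#' the five quintiles (quintiles are population fifths). Interventions
#' listed in `sign_overrides` with a negative sign get a pro-poor
#' (decreasing) gradient — by default bednet ownership, the one indicator
#' that tends to average an inequality ratio below 1. With probability
#' `missingness_prob` an intervention's five quintile columns are blanked,
#' mimicking a survey that lacks the indicator (national baselines stay,
#' as a preloaded-data analogue), which exercises backup resolution.
#'
#' Mortality rates, fertility and survey year are uniform in their ranges;
#' cause-of-death fractions are Dirichlet with concentration
#' `cause_concentration` over the fixed cause lists. Identical seeds give
#' identical output.
#'
#' @param n_countries Number of countries (default 98, a survey-compendium
#'   scale analysis).
#' @param seed Integer RNG seed.
#' @param gradient_scale Half-normal scale of the wealth gradient on the
#'   logit scale; 0 gives perfectly equal quintiles.
#' @param base_coverage_range National-coverage anchor range (proportions).
#' @param missingness_prob Per-intervention probability that quintile
#'   columns are missing.
#' @param nmr_range,postnmr_range Mortality-rate ranges per 1000 live births.
#' @param tfr_range Total-fertility range (children per woman).
#' @param births_range Annual live-birth range.
#' @param survey_year_range Survey-year range.
#' @param cause_concentration Dirichlet concentration for cause fractions.
#' @param catalog Catalog whose interventions get coverage rows.
#' @param sign_overrides Named numeric vector of gradient signs per
#'   intervention id (+1 pro-rich, -1 pro-poor).
#' @return List with `profiles` (country-profile tibble) and `coverage`
#'   (coverage tibble).
#' @export
#' @examples
#' sim <- simulate_equity_data(n_countries = 3, seed = 1)
#' nrow(sim$profiles)
simulate_equity_data <- function(n_countries = 98,
                                 seed = 1,
                                 gradient_scale = 0.4,
                                 base_coverage_range = c(0.2, 0.8),
                                 missingness_prob = 0.1,
                                 nmr_range = c(15, 45),
                                 postnmr_range = c(10, 60),
                                 tfr_range = c(1.8, 6.5),
                                 births_range = c(5e4, 3e6),
                                 survey_year_range = c(1998, 2014),
                                 cause_concentration = 5,
                                 catalog = default_catalog(),
                                 sign_overrides = c(itn = -1)) {
  stopifnot(n_countries >= 1, gradient_scale >= 0,
            missingness_prob >= 0, missingness_prob < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  ids <- catalog$interventions$intervention_id
  sign <- setNames(rep(1, length(ids)), ids)
  over <- intersect(names(sign_overrides), ids)
  sign[over] <- sign(sign_overrides[over])

  ncz <- neonatal_causes()
  pcz <- postneonatal_causes()
  rdirichlet1 <- function(k, conc) {
    g <- rgamma(k, shape = conc)
    g / sum(g)
  }

  profiles <- purrr::map_dfr(seq_len(n_countries), function(j) {
    nf <- rdirichlet1(length(ncz), cause_concentration)
    pf <- rdirichlet1(length(pcz), cause_concentration)
    row <- tibble::tibble(
      country_id = sprintf("SYN%03d", j),
      survey_year = floor(runif(1, survey_year_range[1], survey_year_range[2] + 1)),
      live_births = round(exp(runif(1, log(births_range[1]), log(births_range[2])))),
      nmr = runif(1, nmr_range[1], nmr_range[2]),
      post_nmr = runif(1, postnmr_range[1], postnmr_range[2]),
      tfr = runif(1, tfr_range[1], tfr_range[2])
    )
    row[paste0("ncause_", ncz)] <- as.list(nf)
    row[paste0("pcause_", pcz)] <- as.list(pf)
    row
  })

  coverage <- purrr::map_dfr(profiles$country_id, function(cid) {
    alpha <- runif(length(ids), qlogis(base_coverage_range[1]),
                   qlogis(base_coverage_range[2]))
    beta <- unname(abs(rnorm(length(ids), 0, gradient_scale)) * sign)
    if (gradient_scale == 0) beta <- rep(0, length(ids))
    q <- vapply(1:5, function(k) plogis(alpha + beta * (k - 3)), numeric(length(ids)))
    nat <- rowMeans(q)
    blank <- runif(length(ids)) < missingness_prob
    q[blank, ] <- NA_real_
    tibble::tibble(country_id = cid, intervention_id = ids, national = nat,
                   q1 = q[, 1], q2 = q[, 2], q3 = q[, 3], q4 = q[, 4],
                   q5 = q[, 5])
  })
  list(profiles = profiles, coverage = validate_coverage_table(coverage))
}

#' Hand-checkable worked example
#'
#' A tiny fixed fixture used across tests and documentation: one country
#' (all deaths post-neonatal, split 60/40 between diarrhea and malaria)
#' and a four-intervention catalog — oral rehydration solution (measured),
#' zinc (proxied by ORS), bednets (measured, pro-poor so its ratio floors
#' to 1) and an inert contraceptive-prevalence entry below the fertility
#' gate. Its expected ratio, scenario and lives-saved numbers were derived
#' by hand and ship alongside the fixture files.
#'
#' @return List with `profile`, `coverage`, `catalog`, and `expected`
#'   (the hand-derived numbers, from `expected.json`).
#' @export
make_worked_example <- function() {
  dir <- system.file("extdata", "worked_example", package = "equilist",
                     mustWork = TRUE)
  list(
    profile = read_country_profiles(file.path(dir, "countries.csv")),
    coverage = read_coverage_table(file.path(dir, "coverage.csv")),
    catalog = read_catalog(file.path(dir, "catalog.json")),
    expected = jsonlite::fromJSON(file.path(dir, "expected.json"))
  )
}
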