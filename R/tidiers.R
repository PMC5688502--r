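#' Tidy an impact result into a per-cell death table
#'
#' @param x An `impact_result`.
#' @param ... Unused.
#' @return Tibble with `age_band`, `cause`, `baseline`, `scenario` and
#'   `lives_saved` (the cell difference).
#' @export
tidy.impact_result <- function(x, ...) {
  out <- x$deaths
  out$lives_saved <- out$baseline - out$scenario
  dplyr::bind_cols(tibble::tibble(country_id = x$country_id), out)
}

#' One-row summary of an impact result
#'
#' @inheritParams tidy.impact_result
#' @return One-row tibble: births, total deaths under both scenarios,
#'   lives saved, and mortality-rate changes.
#' @export
glance.impact_result <- function(x, ...) {
  tibble::tibble(
    country_id = x$country_id,
    mode = x$mode,
    births_baseline = x$births_baseline,
    births_scenario = x$births_scenario,
    deaths_baseline = sum(x$deaths$baseline),
    deaths_scenario = sum(x$deaths$scenario),
    lives_saved = x$lives_saved_total,
    u5mr_change = x$u5mr_change,
    nmr_change = x$nmr_change,
    cpr_scaled = x$cpr_scaled
  )
}

#' Tidy an aggregate result into a per-country table
#'
#' @param x An `equity_aggregate`.
#' @param ... Unused.
#' @export
tidy.equity_aggregate <- function(x, ...) {
  x$per_country
}

#' One-row summary of an aggregate result
#'
#' @inheritParams tidy.equity_aggregate
#' @export
glance.equity_aggregate <- function(x, ...) {
  by_age <- setNames(x$by_age$pct_averted, x$by_age$age_band)
  tibble::tibble(
    mode = x$mode,
    n_countries = x$n_countries,
    deaths_baseline_u5 = x$deaths_baseline_u5,
    deaths_scenario_u5 = x$deaths_scenario_u5,
    pct_averted_u5 = x$pct_averted_u5,
    pct_averted_neonatal = by_age[["neonatal"]] %||% NA_real_,
    pct_averted_postneonatal = by_age[["postneonatal"]] %||% NA_real_
  )
}
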