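#' Multi-country equity analysis
#'
#' Builds the scale-up scenario (national coverage raised to the
#' top-wealth-quintile level) for every country, runs the impact model,
#' and aggregates deaths and lives saved across countries. `mode = "full"`
#' scales all catalog interventions, including proxied ones; `"limited"`
#' restricts scale-up to directly measured interventions and their linked
#' components, giving a conservative lower bound.
#'
#' @param profiles Country-profile tibble (one row per country).
#' @param coverage Coverage tibble covering those countries.
#' @param catalog An `intervention_catalog`; defaults to [default_catalog()].
#' @param mode `"full"` or `"limited"`.
#' @param min_survey_year Optional filter: drop countries whose survey
#'   predates this year.
#' @return An object of class `equity_aggregate` with aggregate deaths and
#'   percent averted by age band, lives saved per intervention (summed
#'   over countries), a per-country table of rate changes and lives saved,
#'   and the ids of skipped countries (no coverage rows).
#' @export
run_equity_analysis <- function(profiles, coverage,
                                catalog = default_catalog(),
                                mode = c("full", "limited"),
                                min_survey_year = NULL) {
  mode <- match.arg(mode)
  profiles <- tibble::as_tibble(profiles)
  if (!is.null(min_survey_year)) {
    profiles <- dplyr::filter(profiles, .data$survey_year >= min_survey_year)
  }
  if (nrow(profiles) == 0) abort("no countries left to analyse")
  have_cov <- profiles$country_id %in% unique(coverage$country_id)
  skipped <- profiles$country_id[!have_cov]
  if (length(skipped) > 0) {
    warn(paste0("skipping countries without coverage tables: ",
                paste(skipped, collapse = ", ")))
  }
  profiles <- profiles[have_cov, , drop = FALSE]
  if (nrow(profiles) == 0) abort("no countries left to analyse")

  results <- purrr::map(seq_len(nrow(profiles)), function(r) {
    p <- profiles[r, ]
    sc <- build_scenario(p, coverage, catalog, mode = mode)
    run_impact(p, sc, catalog)
  })

  by_age <- purrr::map_dfr(results, function(x) {
    dplyr::summarise(dplyr::group_by(x$deaths, .data$age_band),
                     baseline = sum(.data$baseline),
                     scenario = sum(.data$scenario), .groups = "drop")
  })
  by_age <- dplyr::summarise(dplyr::group_by(by_age, .data$age_band),
                             deaths_baseline = sum(.data$baseline),
                             deaths_scenario = sum(.data$scenario),
                             .groups = "drop")
  by_age$pct_averted <- 100 * (by_age$deaths_baseline - by_age$deaths_scenario) /
    by_age$deaths_baseline
  u5_base <- sum(by_age$deaths_baseline)
  u5_scen <- sum(by_age$deaths_scenario)

  by_int <- purrr::map_dfr(results, "lives_saved_by_intervention")
  by_int <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(by_int, .data$intervention_id),
                     lives_saved = sum(.data$lives_saved), .groups = "drop"),
    dplyr::desc(.data$lives_saved), .data$intervention_id
  )

  per_country <- purrr::map_dfr(results, function(x) {
    tibble::tibble(country_id = x$country_id,
                   lives_saved = x$lives_saved_total,
                   u5mr_change = x$u5mr_change,
                   nmr_change = x$nmr_change)
  })

  structure(
    list(
      mode = mode,
      n_countries = nrow(profiles),
      by_age = by_age,
      deaths_baseline_u5 = u5_base,
      deaths_scenario_u5 = u5_scen,
      pct_averted_u5 = 100 * (u5_base - u5_scen) / u5_base,
      lives_saved_by_intervention = by_int,
      per_country = per_country,
      skipped = skipped
    ),
    class = "equity_aggregate"
  )
}

#' Rank interventions by aggregate lives saved
#'
#' @param result An `equity_aggregate`.
#' @param top_k Number of rows to keep; larger than the catalog means the
#'   full table.
#' @return Tibble (`intervention_id`, `lives_saved`) sorted descending,
#'   ties broken by id.
#' @export
intervention_league_table <- function(result, top_k = Inf) {
  tab <- result$lives_saved_by_intervention
  tab <- dplyr::arrange(tab, dplyr::desc(.data$lives_saved),
                        .data$intervention_id)
  head(tab, n = min(top_k, nrow(tab)))
}

#' @export
print.equity_aggregate <- function(x, ...) {
  cat("<equity_aggregate>", x$mode, "analysis,", x$n_countries, "countries\n")
  cat(sprintf("  under-5 deaths: %.0f baseline -> %.0f scenario (%.1f%% averted)\n",
              x$deaths_baseline_u5, x$deaths_scenario_u5, x$pct_averted_u5))
  for (r in seq_len(nrow(x$by_age))) {
    cat(sprintf("  %-13s %.0f -> %.0f (%.1f%% averted)\n",
                x$by_age$age_band[r], x$by_age$deaths_baseline[r],
                x$by_age$deaths_scenario[r], x$by_age$pct_averted[r]))
  }
  if (length(x$skipped) > 0) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
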