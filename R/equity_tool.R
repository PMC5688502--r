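#' Rank interventions for one country by solo scale-up impact
#'
#' The "first glance" equity view: each rankable intervention is scaled up
#' alone from the national average to the top-wealth-quintile level, the
#' impact model is run, and interventions are ranked by lives saved.
#' Because each row is a solo scenario, rows ignore cross-intervention
#' interactions and their sum is not the joint full-scenario total.
#'
#' Rankable items are the directly measured and proxied interventions plus
#' the coverage-only contact points (antenatal care, facility delivery,
#' skilled birth attendant), which are ranked as bundles moving all their
#' linked components at once; linked components are not ranked separately
#' since the engine always drives them from their parent's coverage.
#'
#' Filters follow the checkbox semantics of the interactive tool: they
#' restrict which rows are shown (`group`: catalog intervention group;
#' `cause`: interventions affecting that cause, bundles included via their
#' children) and which column orders them (`by`), but never change a
#' row's values.
#'
#' @inheritParams build_scenario
#' @param by Ranking column: `"total"`, `"neonatal"` or `"child"`
#'   (post-neonatal).
#' @param group Optional intervention-group filter.
#' @param cause Optional cause filter.
#' @return An object of class `equity_ranking`: a tibble with
#'   `intervention_id`, `lives_saved_neonatal`, `lives_saved_child`,
#'   `lives_saved_total`, sorted descending by the ranking column with
#'   ties broken by id; zero rows are retained at the bottom. If no
#'   inequality ratio is available at all the ranking is empty and carries
#'   a `status` attribute saying so.
#' @export
rank_interventions <- function(profile, coverage, catalog = default_catalog(),
                               by = c("total", "neonatal", "child"),
                               group = NULL, cause = NULL) {
  by <- match.arg(by)
  stopifnot(nrow(profile) == 1)
  ints <- catalog$interventions
  cov <- dplyr::filter(tibble::as_tibble(coverage),
                       .data$country_id == profile$country_id)
  ratios <- resolve_ratios(cov, catalog)
  if (all(is.na(ratios$applied_ratio))) {
    out <- tibble::tibble(intervention_id = character(),
                          lives_saved_neonatal = numeric(),
                          lives_saved_child = numeric(),
                          lives_saved_total = numeric())
    return(structure(out, status = "no inequality ratios available",
                     by = by, class = c("equity_ranking", class(out))))
  }
  rankable <- ints$intervention_id[ints$channel %in% c("direct", "proxied")]
  rows <- purrr::map_dfr(rankable, function(id) {
    sc <- build_scenario(profile, cov, catalog, mode = "single",
                         intervention = id)
    imp <- run_impact(profile, sc, catalog)
    saved <- setNames(imp$lives_saved_by_age$lives_saved,
                      imp$lives_saved_by_age$age_band)
    tibble::tibble(
      intervention_id = id,
      lives_saved_neonatal = saved[["neonatal"]] %||% 0,
      lives_saved_child = saved[["postneonatal"]] %||% 0,
      lives_saved_total = imp$lives_saved_total
    )
  })
  if (!is.null(group)) {
    keep <- ints$intervention_id[!is.na(ints$group) & ints$group %in% group]
    rows <- rows[rows$intervention_id %in% keep, , drop = FALSE]
  }
  if (!is.null(cause)) {
    eff <- catalog$effects[catalog$effects$cause %in% cause, , drop = FALSE]
    hit <- unique(eff$intervention_id)
    # a bundle qualifies when any of its linked children hits the cause
    parents <- unique(ints$parent_id[ints$channel == "linked" &
                                       ints$intervention_id %in% hit])
    rows <- rows[rows$intervention_id %in% c(hit, parents), , drop = FALSE]
  }
  key <- switch(by, total = rows$lives_saved_total,
                neonatal = rows$lives_saved_neonatal,
                child = rows$lives_saved_child)
  rows <- rows[order(-key, rows$intervention_id), , drop = FALSE]
  structure(rows, status = "ok", by = by,
            country_id = profile$country_id,
            class = c("equity_ranking", class(rows)))
}

#' @export
print.equity_ranking <- function(x, n = 10, ...) {
  cat("<equity_ranking>", attr(x, "country_id") %||% "",
      sprintf("(ranked by %s lives saved)\n", attr(x, "by") %||% "total"))
  if (nrow(x) == 0) {
    cat("  ", attr(x, "status"), "\n")
    return(invisible(x))
  }
  NextMethod()
  invisible(x)
}
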