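#' Raw inequality ratio: top-quintile over national coverage
#'
#' The inequality ratio for an intervention is the coverage in the richest
#' wealth quintile divided by the national coverage. Values above 1 mean
#' pro-rich coverage. This raw ratio is reported unfloored (pro-poor
#' interventions such as bednets can average below 1); the *applied* ratio
#' used to build scale-up scenarios is floored at 1 by [resolve_ratios()].
#'
#' @param national Numeric vector of national coverage proportions.
#' @param q5 Numeric vector of top-quintile coverage proportions.
#' @return `q5 / national` where both are present and `national > 0`,
#'   otherwise `NA` (a zero national coverage leaves the ratio undefined).
#' @export
#' @examples
#' compute_raw_ratio(c(0.4, 0.4, NA), c(0.5, 0.38, 0.7))
compute_raw_ratio <- function(national, q5) {
  out <- rep(NA_real_, length(national))
  ok <- !is.na(national) & !is.na(q5) & national > 0
  if (any(!is.na(national) & national == 0 & !is.na(q5) & q5 > 0)) {
    inform("raw ratio undefined where national coverage is 0; returning NA")
  }
  out[ok] <- q5[ok] / national[ok]
  out
}

#' Resolve inequality ratios through the proxy/backup graph
#'
#' For each catalog intervention and each country in `coverage`:
#' directly measured interventions take their own raw ratio when the
#' survey has both national and top-quintile values, falling back to their
#' single backup source's own ratio (`provenance = "backup(<id>)"`), else
#' unavailable. Proxied interventions always take their proxy source's
#' resolved ratio (`provenance = "proxy(<id>)"`), including the source's
#' backup fallback. Linked components take their parent contact point's
#' resolved ratio, reported as `proxy(<parent>)` (in the impact engine the
#' parent's coverage drives them directly). The applied ratio is the raw
#' resolved ratio floored at 1 — the scale-up scenario never lowers
#' coverage — with flooring performed after resolution.
#'
#' @param coverage A coverage tibble (may hold several countries).
#' @param catalog An `intervention_catalog`.
#' @return Tibble with `country_id`, `intervention_id`, `raw_ratio`,
#'   `applied_ratio`, `provenance`.
#' @export
resolve_ratios <- function(coverage, catalog) {
  validate_catalog(catalog)
  cov <- tibble::as_tibble(coverage)
  ints <- catalog$interventions
  purrr::map_dfr(split(cov, cov$country_id), function(cc) {
    own_raw <- setNames(
      compute_raw_ratio(
        cc$national[match(ints$intervention_id, cc$intervention_id)],
        cc$q5[match(ints$intervention_id, cc$intervention_id)]
      ),
      ints$intervention_id
    )
    # one-level resolution for a direct intervention: own, else backup's own
    resolve_direct <- function(id) {
      if (!is.na(own_raw[[id]])) {
        return(list(raw = own_raw[[id]], prov = "direct"))
      }
      bk <- ints$backup_id[ints$intervention_id == id]
      if (!is.na(bk) && !is.na(own_raw[[bk]])) {
        return(list(raw = own_raw[[bk]], prov = paste0("backup(", bk, ")")))
      }
      list(raw = NA_real_, prov = "unavailable")
    }
    rows <- purrr::pmap_dfr(
      list(ints$intervention_id, ints$channel, ints$parent_id, ints$source_id),
      function(id, channel, parent, source) {
        res <- switch(
          channel,
          direct = resolve_direct(id),
          proxied = {
            r <- resolve_direct(source)
            if (is.na(r$raw)) list(raw = NA_real_, prov = "unavailable")
            else list(raw = r$raw, prov = paste0("proxy(", source, ")"))
          },
          linked = {
            r <- resolve_direct(parent)
            if (is.na(r$raw)) list(raw = NA_real_, prov = "unavailable")
            else list(raw = r$raw, prov = paste0("proxy(", parent, ")"))
          }
        )
        tibble::tibble(intervention_id = id, raw_ratio = res$raw,
                       applied_ratio = ifelse(is.na(res$raw), NA_real_,
                                              pmax(res$raw, 1)),
                       provenance = res$prov)
      }
    )
    dplyr::bind_cols(tibble::tibble(country_id = cc$country_id[1]), rows)
  })
}

#' Build a baseline/target coverage scenario for one country
#'
#' Baseline coverage is the surveyed national rate; the target raises each
#' in-scope intervention to its top-wealth-quintile level,
#' `min(baseline * applied_ratio, 1)` (the cap keeps coverage a valid
#' proportion when a stale ratio meets a newer national rate). Scope by
#' mode: `"full"` scales every catalog item; `"limited"` scales only
#' directly measured items and their linked components (proxied items stay
#' at baseline); `"single"` scales only `intervention` — a coverage-only
#' parent moves its linked children implicitly through the engine.
#' Interventions whose ratio is unavailable, or whose national baseline is
#' missing, stay at baseline (missing baselines enter the vectors as 0).
#'
#' Contraceptive prevalence is scaled only when the country's fertility
#' exceeds the catalog's replacement-rate gate (default 2.33 children per
#' woman); otherwise its target stays at baseline and the scenario is
#' flagged `cpr_scaled = FALSE`.
#'
#' @param profile One-row country-profile tibble.
#' @param coverage Coverage tibble for (at least) that country.
#' @param catalog An `intervention_catalog`.
#' @param mode `"full"`, `"limited"` or `"single"`.
#' @param intervention Intervention id, required when `mode = "single"`.
#' @return A tibble (`country_id`, `intervention_id`, `baseline`, `target`)
#'   with class `equity_scenario` and attributes `mode`, `cpr_scaled`,
#'   `single_id`.
#' @export
build_scenario <- function(profile, coverage, catalog,
                           mode = c("full", "limited", "single"),
                           intervention = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(profile) == 1)
  cid <- profile$country_id
  cov <- dplyr::filter(tibble::as_tibble(coverage), .data$country_id == cid)
  if (nrow(cov) == 0) abort(paste0("no coverage rows for country ", cid))
  ratios <- resolve_ratios(cov, catalog)
  ints <- catalog$interventions
  if (mode == "single") {
    if (is.null(intervention) || !intervention %in% ints$intervention_id) {
      abort("mode='single' needs an `intervention` present in the catalog")
    }
  }
  baseline <- cov$national[match(ints$intervention_id, cov$intervention_id)]
  missing_base <- is.na(baseline)
  if (any(missing_base)) {
    inform(paste0("kept at baseline 0 (no national coverage): ",
                  paste(ints$intervention_id[missing_base], collapse = ", ")))
  }
  baseline[missing_base] <- 0
  applied <- ratios$applied_ratio[match(ints$intervention_id,
                                        ratios$intervention_id)]
  in_scope <- switch(mode,
    full = rep(TRUE, nrow(ints)),
    limited = ints$channel %in% c("direct", "linked"),
    single = ints$intervention_id == intervention
  )
  no_ratio <- in_scope & is.na(applied)
  if (any(no_ratio & baseline > 0)) {
    inform(paste0("no inequality ratio available, kept at baseline: ",
                  paste(ints$intervention_id[no_ratio & baseline > 0],
                        collapse = ", ")))
  }
  target <- baseline
  scale_it <- in_scope & !is.na(applied)
  target[scale_it] <- pmin(baseline[scale_it] * applied[scale_it], 1)

  # fertility gate: contraception only scales above replacement fertility
  cpr_id <- ints$intervention_id[ints$is_cpr]
  cpr_scaled <- FALSE
  k <- which(ints$intervention_id == cpr_id)
  if (target[k] > baseline[k]) {
    if (isTRUE(profile$tfr > catalog$fertility_gate)) {
      cpr_scaled <- TRUE
    } else {
      target[k] <- baseline[k]
    }
  }
  structure(
    tibble::tibble(country_id = cid, intervention_id = ints$intervention_id,
                   baseline = baseline, target = target),
    mode = mode, cpr_scaled = cpr_scaled,
    single_id = if (mode == "single") intervention else NA_character_,
    class = c("equity_scenario", class(tibble::tibble()))
  )
}

#' Write a resolved ratio table to CSV
#'
#' @param ratios Output of [resolve_ratios()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratios <- function(ratios, path) {
  readr::write_csv(ratios, path, na = "")
  invisible(path)
}
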