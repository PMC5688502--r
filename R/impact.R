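#' Effective coverage pairs under a scenario
#'
#' Maps scenario coverage onto the interventions the engine actually
#' applies effects to. Directly measured and proxied interventions use
#' their own (baseline, target) pair. Linked components (antenatal-care
#' and childbirth packages) use their parent contact point's pair: survey
#' coverage of the contact drives the component. Coverage-only parents are
#' dropped from the output — they carry no direct effect of their own.
#'
#' @param scenario An `equity_scenario` from [build_scenario()].
#' @param catalog An `intervention_catalog`.
#' @return Tibble `intervention_id`, `c0` (baseline), `c1` (target) for
#'   every non-parent catalog intervention. A linked component whose
#'   parent is absent from the scenario is kept at (0, 0) with a warning.
#' @export
effective_coverage <- function(scenario, catalog) {
  ints <- catalog$interventions
  base <- setNames(scenario$baseline, scenario$intervention_id)
  targ <- setNames(scenario$target, scenario$intervention_id)
  use_id <- ifelse(ints$channel == "linked", ints$parent_id,
                   ints$intervention_id)
  c0 <- unname(base[use_id])
  c1 <- unname(targ[use_id])
  miss <- is.na(c0) | is.na(c1)
  if (any(miss)) {
    warn(paste0("coverage absent from scenario, kept at (0, 0): ",
                paste(unique(use_id[miss]), collapse = ", ")))
    c0[miss] <- 0
    c1[miss] <- 0
  }
  tibble::tibble(intervention_id = ints$intervention_id, c0 = c0, c1 = c1)[
    !ints$is_parent, , drop = FALSE]
}

#' Birth cohort under a scenario (contraception pathway)
#'
#' Scaling contraceptive prevalence shrinks the birth cohort: with
#' prevalence moving from `u0` to `u1` and use-effectiveness `e`, the
#' scenario cohort is `live_births * (1 - u1*e) / (1 - u0*e)` — the ratio
#' of unprotected fecund exposure after versus before scale-up. With
#' contraception unscaled (`u1 = u0`) births are unchanged.
#'
#' @inheritParams effective_coverage
#' @param profile One-row country-profile tibble.
#' @return Scenario-year live births, clamped to `(0, live_births]`.
#' @export
births_under_scenario <- function(profile, scenario, catalog) {
  stopifnot(nrow(profile) == 1)
  ec <- effective_coverage(scenario, catalog)
  cpr_id <- catalog$interventions$intervention_id[catalog$interventions$is_cpr]
  row <- ec[ec$intervention_id == cpr_id, ]
  if (nrow(row) != 1) abort("contraceptive prevalence missing from scenario")
  e <- catalog$cpr_effectiveness
  if (row$c1 * e >= 1) {
    abort("degenerate contraception scale-up: u1 * effectiveness >= 1")
  }
  out <- profile$live_births * (1 - row$c1 * e) / (1 - row$c0 * e)
  min(max(out, .Machine$double.xmin), profile$live_births)
}

#' Residual fraction of cause-specific mortality at given coverages
#'
#' The engine's combination rule: interventions acting on the same cause
#' combine multiplicatively, each removing a share `E * AF * C` of the
#' deaths left by the others. The residual fraction for a (cause, age
#' band) cell is the product over affecting interventions of
#' `1 - E_i * AF_i * C_i`; an empty product is 1. This rule is what makes
#' simultaneous scale-up free of double-counting: scenario deaths are
#' baseline deaths times `R(target) / R(baseline)`.
#'
#' @param cause Cause id.
#' @param age_band `"neonatal"` or `"postneonatal"`.
#' @param coverages Named numeric vector, intervention id -> coverage
#'   proportion; interventions absent from the vector count as coverage 0.
#' @param catalog An `intervention_catalog`.
#' @return The residual proportion in (0, 1].
#' @export
#' @examples
#' # a single intervention with E = 0.5, AF = 1 at 40% coverage leaves 80%
residual_fraction <- function(cause, age_band, coverages, catalog) {
  eff <- catalog$effects
  rows <- eff[eff$cause == cause & eff$age_band == age_band, , drop = FALSE]
  if (nrow(rows) == 0) return(1)
  cv <- coverages[rows$intervention_id]
  cv[is.na(cv)] <- 0
  prod(1 - rows$effectiveness * rows$affected_fraction * unname(cv))
}

#' Run the deterministic mortality impact model for one scenario
#'
#' Baseline deaths per (age band, cause) cell are
#' `live_births * rate / 1000 * cause_fraction`, with the neonatal and
#' post-neonatal mortality rates applied to their bands. Scenario deaths
#' rescale each cell by the birth-cohort ratio (contraception pathway) and
#' by the ratio of residual fractions at target versus baseline coverage
#' — baseline deaths already embody baseline coverage, so only the
#' *change* in the residual acts.
#'
#' Lives saved are attributed per intervention without double-counting:
#' the birth-cohort component of each cell goes to contraceptive
#' prevalence, and the remaining cell savings are split across affecting
#' interventions in proportion to their solo log-impact
#' `w_i = log((1 - E_i*AF_i*c0_i) / (1 - E_i*AF_i*c1_i))`, an
#' order-independent rule that sums exactly to the cell total.
#'
#' @inheritParams births_under_scenario
#' @return An object of class `impact_result`: deaths by cell under both
#'   scenarios, births, total / per-age / per-intervention lives saved,
#'   and under-five and neonatal mortality-rate changes (scenario minus
#'   baseline, per 1000 live births; negative means a decline).
#' @export
run_impact <- function(profile, scenario, catalog) {
  stopifnot(nrow(profile) == 1)
  ints <- catalog$interventions
  ec <- effective_coverage(scenario, catalog)
  b0 <- profile$live_births
  b1 <- births_under_scenario(profile, scenario, catalog)
  b <- b1 / b0

  fr <- cause_fractions(profile)
  rate <- ifelse(fr$age_band == "neonatal", profile$nmr, profile$post_nmr)
  d0 <- b0 * rate / 1000 * fr$fraction
  cell_key <- paste(fr$age_band, fr$cause, sep = ".")

  eff <- catalog$effects
  k <- match(eff$intervention_id, ec$intervention_id)
  ea <- eff$effectiveness * eff$affected_fraction
  c0 <- ec$c0[k]
  c1 <- ec$c1[k]
  f0 <- 1 - ea * c0
  f1 <- 1 - ea * c1
  if (any(f0 <= 1e-12) || any(f1 <= 1e-12)) {
    abort("degenerate catalog: effectiveness x affected_fraction x coverage reaches 1")
  }
  ekey <- paste(eff$age_band, eff$cause, sep = ".")
  logR0 <- setNames(rep(0, length(cell_key)), cell_key)
  logR1 <- logR0
  s0 <- tapply(log(f0), ekey, sum)
  s1 <- tapply(log(f1), ekey, sum)
  hit <- intersect(names(s0), cell_key)
  logR0[hit] <- s0[hit]
  logR1[hit] <- s1[hit]
  ratioR <- exp(unname(logR1 - logR0))   # R(c1)/R(c0) per cell, <= 1
  d1 <- d0 * b * ratioR

  # attribution: fertility slice to CPR, the rest by solo log-impact weights
  cpr_id <- ints$intervention_id[ints$is_cpr]
  saved_by_int <- setNames(rep(0, nrow(ec)), ec$intervention_id)
  saved_by_int[cpr_id] <- sum(d0) * (1 - b)
  w <- log(f0) - log(f1)                  # >= 0 when targets >= baselines
  W <- tapply(w, ekey, sum)
  rest <- setNames(d0 * b * (1 - ratioR), cell_key)
  for (key in names(W)) {
    if (!key %in% cell_key || W[[key]] <= 0) next
    sel <- ekey == key
    share <- w[sel] / W[[key]] * rest[[key]]
    saved_by_int[eff$intervention_id[sel]] <-
      saved_by_int[eff$intervention_id[sel]] + share
  }

  saved_by_age <- tapply(d0 - d1, fr$age_band, sum)
  deaths <- tibble::tibble(age_band = fr$age_band, cause = fr$cause,
                           baseline = d0, scenario = d1)
  neo <- fr$age_band == "neonatal"
  structure(
    list(
      country_id = profile$country_id,
      mode = attr(scenario, "mode") %||% NA_character_,
      cpr_scaled = isTRUE(attr(scenario, "cpr_scaled")),
      deaths = deaths,
      births_baseline = b0,
      births_scenario = b1,
      lives_saved_total = sum(d0) - sum(d1),
      lives_saved_by_age = tibble::tibble(
        age_band = names(saved_by_age),
        lives_saved = as.numeric(saved_by_age)
      ),
      lives_saved_by_intervention = tibble::tibble(
        intervention_id = names(saved_by_int),
        lives_saved = as.numeric(saved_by_int)
      ),
      u5mr_change = 1000 * sum(d1) / b1 - 1000 * sum(d0) / b0,
      nmr_change = 1000 * sum(d1[neo]) / b1 - 1000 * sum(d0[neo]) / b0
    ),
    class = "impact_result"
  )
}

#' @export
print.impact_result <- function(x, ...) {
  cat("<impact_result>", x$country_id,
      sprintf("(mode: %s)\n", x$mode))
  cat(sprintf("  deaths baseline %.1f -> scenario %.1f; lives saved %.1f\n",
              sum(x$deaths$baseline), sum(x$deaths$scenario),
              x$lives_saved_total))
  cat(sprintf("  U5MR change %+.2f, NMR change %+.2f per 1000 live births\n",
              x$u5mr_change, x$nmr_change))
  invisible(x)
}
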