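# Shared fixture builders and the independent brute-force oracle.

make_test_catalog <- function(interventions, effects,
                              cpr_effectiveness = 0.9, fertility_gate = 2.33) {
  defaults <- tibble::tibble(
    parent_id = NA_character_, source_id = NA_character_,
    backup_id = NA_character_, is_parent = FALSE, is_cpr = FALSE,
    group = NA_character_
  )
  ints <- tibble::as_tibble(interventions)
  for (col in names(defaults)) {
    if (!col %in% names(ints)) ints[[col]] <- defaults[[col]]
  }
  if (!"name" %in% names(ints)) ints$name <- ints$intervention_id
  if (!"channel" %in% names(ints)) ints$channel <- "direct"
  structure(
    list(interventions = ints, effects = tibble::as_tibble(effects),
         cpr_effectiveness = cpr_effectiveness, fertility_gate = fertility_gate),
    class = "intervention_catalog"
  )
}

make_test_profile <- function(country_id = "T1", live_births = 1e5,
                              nmr = 25, post_nmr = 35, tfr = 4,
                              nfrac = c(other = 1), pfrac = c(other = 1),
                              survey_year = 2012) {
  row <- tibble::tibble(country_id = country_id, survey_year = survey_year,
                        live_births = live_births, nmr = nmr,
                        post_nmr = post_nmr, tfr = tfr)
  row[paste0("ncause_", names(nfrac))] <- as.list(unname(nfrac))
  row[paste0("pcause_", names(pfrac))] <- as.list(unname(pfrac))
  row
}

make_test_scenario <- function(ids, baseline, target, country_id = "T1",
                               mode = "full", cpr_scaled = FALSE) {
  structure(
    tibble::tibble(country_id = country_id, intervention_id = ids,
                   baseline = baseline, target = target),
    mode = mode, cpr_scaled = cpr_scaled,
    class = c("equity_scenario", class(tibble::tibble()))
  )
}

# Random small model instance: k direct interventions (plus an inert or
# scaled CPR) acting on up to two causes per age band.
rand_instance <- function(k = 3, scale_cpr = FALSE) {
  ids <- paste0("int", seq_len(k))
  causes <- expand.grid(age_band = c("neonatal", "postneonatal"),
                        cause = c("c1", "c2"), stringsAsFactors = FALSE)
  eff <- do.call(rbind, lapply(ids, function(id) {
    pick <- causes[sample(nrow(causes), sample(1:2, 1)), ]
    data.frame(intervention_id = id, age_band = pick$age_band,
               cause = pick$cause,
               effectiveness = runif(nrow(pick), 0.1, 0.9),
               affected_fraction = runif(nrow(pick), 0.1, 0.9))
  }))
  cat <- make_test_catalog(
    tibble::tibble(intervention_id = c(ids, "cpr"),
                   is_cpr = c(rep(FALSE, k), TRUE)),
    tibble::as_tibble(eff)
  )
  prof <- make_test_profile(
    nmr = runif(1, 5, 50), post_nmr = runif(1, 5, 60), tfr = runif(1, 2.5, 6),
    nfrac = c(c1 = 0.5, c2 = 0.5), pfrac = c(c1 = 0.4, c2 = 0.6)
  )
  c0 <- runif(k, 0, 0.8)
  c1 <- pmin(c0 * runif(k, 1, 1.6), 1)
  u0 <- runif(1, 0.05, 0.4)
  u1 <- if (scale_cpr) min(u0 * runif(1, 1, 1.4), 0.9) else u0
  sc <- make_test_scenario(c(ids, "cpr"), c(c0, u0), c(c1, u1),
                           cpr_scaled = scale_cpr)
  list(profile = prof, catalog = cat, scenario = sc)
}

# Independent oracle: plain-loop evaluation of the multiplicative model.
# Deliberately written with explicit loops and no shared code with the
# package internals.
oracle_impact <- function(profile, catalog, scenario) {
  eff <- as.data.frame(catalog$effects)
  sc <- as.data.frame(scenario)
  cov0 <- setNames(sc$baseline, sc$intervention_id)
  cov1 <- setNames(sc$target, sc$intervention_id)
  cpr <- catalog$interventions$intervention_id[catalog$interventions$is_cpr]
  e <- catalog$cpr_effectiveness
  b0 <- profile$live_births
  b1 <- b0 * (1 - cov1[[cpr]] * e) / (1 - cov0[[cpr]] * e)
  total0 <- 0
  total1 <- 0
  cells <- list()
  for (band in c("neonatal", "postneonatal")) {
    rate <- if (band == "neonatal") profile$nmr else profile$post_nmr
    pre <- if (band == "neonatal") "ncause_" else "pcause_"
    for (col in grep(paste0("^", pre), names(profile), value = TRUE)) {
      cause <- sub(pre, "", col)
      d0 <- b0 * rate / 1000 * profile[[col]]
      r0 <- 1
      r1 <- 1
      for (r in seq_len(nrow(eff))) {
        if (eff$age_band[r] == band && eff$cause[r] == cause) {
          id <- eff$intervention_id[r]
          ea <- eff$effectiveness[r] * eff$affected_fraction[r]
          r0 <- r0 * (1 - ea * cov0[[id]])
          r1 <- r1 * (1 - ea * cov1[[id]])
        }
      }
      d1 <- d0 * (b1 / b0) * r1 / r0
      total0 <- total0 + d0
      total1 <- total1 + d1
      cells[[paste(band, cause, sep = ".")]] <- c(baseline = d0, scenario = d1)
    }
  }
  list(births_scenario = b1, deaths_baseline = total0,
       deaths_scenario = total1, lives_saved = total0 - total1,
       cells = cells)
}
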