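#' Cause-of-death lists used by the impact model
#'
#' The deterministic impact model partitions under-five deaths into a
#' neonatal band (first month of life) and a post-neonatal band (1-59
#' months), each with a fixed cause list. Country profiles carry one
#' fraction column per cause (`ncause_<id>` / `pcause_<id>`), and the
#' intervention catalog attaches effectiveness and affected fractions to
#' (cause, age band) pairs. Users supplying their own catalog may extend
#' these lists, as long as profile columns and catalog effects agree.
#'
#' @return Character vector of cause identifiers.
#' @export
#' @examples
#' neonatal_causes()
neonatal_causes <- function() {
  c("prematurity", "intrapartum", "sepsis_pneumonia", "congenital",
    "tetanus", "other")
}

#' @rdname neonatal_causes
#' @export
postneonatal_causes <- function() {
  c("pneumonia", "diarrhea", "malaria", "measles", "injury", "other")
}

new_catalog <- function(interventions, effects, cpr_effectiveness, fertility_gate) {
  structure(
    list(
      interventions = tibble::as_tibble(interventions),
      effects = tibble::as_tibble(effects),
      cpr_effectiveness = cpr_effectiveness,
      fertility_gate = fertility_gate
    ),
    class = "intervention_catalog"
  )
}

#' Validate an intervention catalog
#'
#' Checks the structural invariants the downstream modules rely on:
#' channels are one of direct/linked/proxied; every linked parent, proxy
#' source and backup source exists and is itself a directly measured
#' (`channel = "direct"`) intervention, so the delivery graph is one level
#' deep and acyclic; exactly one intervention is flagged as contraceptive
#' prevalence; effectiveness and affected fractions lie in \[0, 1\] with
#' their product bounded away from 1 (a product of 1 would delete a cause
#' entirely and divide by zero in the residual).
#'
#' @param catalog An `intervention_catalog`.
#' @return The catalog, invisibly, if valid; otherwise an error.
#' @export
validate_catalog <- function(catalog) {
  ints <- catalog$interventions
  eff <- catalog$effects
  needed <- c("intervention_id", "name", "channel", "parent_id", "source_id",
              "backup_id", "is_parent", "is_cpr", "group")
  missing_cols <- setdiff(needed, names(ints))
  if (length(missing_cols) > 0) {
    abort(paste0("catalog interventions missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(ints$intervention_id)) {
    abort("duplicate intervention_id in catalog")
  }
  if (!all(ints$channel %in% c("direct", "linked", "proxied"))) {
    abort("channel must be one of direct, linked, proxied")
  }
  ids <- ints$intervention_id
  direct_ids <- ids[ints$channel == "direct"]
  check_ref <- function(ref, label) {
    ref <- ref[!is.na(ref)]
    bad <- setdiff(ref, direct_ids)
    if (length(bad) > 0) {
      abort(paste0(label, " must reference channel=direct interventions: ",
                   paste(bad, collapse = ", ")))
    }
  }
  check_ref(ints$parent_id[ints$channel == "linked"], "linked parent_id")
  check_ref(ints$source_id[ints$channel == "proxied"], "proxied source_id")
  check_ref(ints$backup_id, "backup_id")
  if (any(ints$channel == "linked" & is.na(ints$parent_id))) {
    abort("linked interventions need a parent_id")
  }
  if (any(ints$channel == "proxied" & is.na(ints$source_id))) {
    abort("proxied interventions need a source_id")
  }
  if (sum(ints$is_cpr) != 1) {
    abort("exactly one intervention must have is_cpr = TRUE")
  }
  if (any(ints$is_parent & ints$channel != "direct")) {
    abort("coverage-only parents must be channel=direct")
  }
  if (nrow(eff) > 0) {
    if (!all(eff$intervention_id %in% ids)) {
      abort("effects reference unknown intervention_id")
    }
    if (any(eff$intervention_id %in% ids[ints$is_parent])) {
      abort("coverage-only parents cannot carry direct effects")
    }
    if (!all(eff$age_band %in% c("neonatal", "postneonatal"))) {
      abort("effect age_band must be neonatal or postneonatal")
    }
    ok <- eff$effectiveness >= 0 & eff$effectiveness <= 1 &
      eff$affected_fraction >= 0 & eff$affected_fraction <= 1
    if (!all(ok)) abort("effectiveness and affected_fraction must lie in [0, 1]")
    if (any(eff$effectiveness * eff$affected_fraction >= 1 - 1e-12)) {
      abort("effectiveness x affected_fraction must stay below 1")
    }
  }
  if (!(catalog$fertility_gate > 0)) abort("fertility_gate must be positive")
  if (!(catalog$cpr_effectiveness > 0 && catalog$cpr_effectiveness <= 1)) {
    abort("cpr_effectiveness must lie in (0, 1]")
  }
  invisible(catalog)
}

#' Read an intervention catalog from JSON or YAML
#'
#' The file carries the intervention list (id, name, delivery channel with
#' its parent/source/backup links, coverage-only parent and contraceptive
#' prevalence flags, display group) and the effect matrix (effectiveness
#' and affected fraction per cause and age band), plus the contraception
#' use-effectiveness and the fertility gate in children per woman.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` catalog file.
#' @return A validated `intervention_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("catalog file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    rlang::check_installed("yaml")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  ints <- tibble::as_tibble(raw$interventions)
  for (col in c("parent_id", "source_id", "backup_id")) {
    if (!col %in% names(ints)) ints[[col]] <- NA_character_
    ints[[col]] <- as.character(ints[[col]])
    ints[[col]][ints[[col]] %in% c("", "NA")] <- NA_character_
  }
  if (!"group" %in% names(ints)) ints$group <- NA_character_
  ints$is_parent <- isTRUE_vec(ints$is_parent)
  ints$is_cpr <- isTRUE_vec(ints$is_cpr)
  eff <- tibble::as_tibble(raw$effects)
  cat <- new_catalog(ints, eff,
                     cpr_effectiveness = raw$cpr_effectiveness %||% 0.9,
                     fertility_gate = raw$fertility_gate %||% 2.33)
  validate_catalog(cat)
  cat
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

#' Write an intervention catalog to JSON
#'
#' @param catalog An `intervention_catalog`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(
    list(
      cpr_effectiveness = catalog$cpr_effectiveness,
      fertility_gate = catalog$fertility_gate,
      interventions = catalog$interventions,
      effects = catalog$effects
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

the_catalog_cache <- new.env(parent = emptyenv())

#' The default 41-entry intervention catalog
#'
#' Returns the catalog of maternal, newborn and child health interventions
#' used by the equity analysis: 18 directly survey-measured indicators,
#' antenatal-care and childbirth components linked to their measured
#' contact points (antenatal care, facility delivery), and proxied
#' interventions that borrow the inequality ratio of a co-delivered
#' measured indicator, with single-level backup sources for surveys that
#' lack a given indicator. Three entries (antenatal care, skilled birth
#' attendant, facility delivery) are coverage-only parents: they carry no
#' direct mortality effect and exist to drive their linked components, so
#' 38 interventions are actually scaled in a full analysis.
#'
#' Effectiveness and affected-fraction values are package defaults with
#' plausible magnitudes chosen for realistic model behaviour; they are not
#' authoritative estimates, and users should supply their own catalog via
#' [read_catalog()] for substantive country work.
#'
#' @return An `intervention_catalog`.
#' @export
#' @examples
#' cat38 <- default_catalog()
#' sum(!cat38$interventions$is_parent)
default_catalog <- function() {
  if (is.null(the_catalog_cache$default)) {
    path <- system.file("extdata", "default_catalog.json", package = "equilist",
                        mustWork = TRUE)
    the_catalog_cache$default <- read_catalog(path)
  }
  the_catalog_cache$default
}

#' @export
print.intervention_catalog <- function(x, ...) {
  n <- nrow(x$interventions)
  cat("<intervention_catalog>\n")
  cat("  interventions:", n,
      sprintf("(%d direct, %d linked, %d proxied; %d coverage-only parents)\n",
              sum(x$interventions$channel == "direct"),
              sum(x$interventions$channel == "linked"),
              sum(x$interventions$channel == "proxied"),
              sum(x$interventions$is_parent)))
  cat("  effect entries:", nrow(x$effects), "\n")
  cat("  cpr_effectiveness:", x$cpr_effectiveness,
      " fertility_gate:", x$fertility_gate, "children/woman\n")
  invisible(x)
}
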