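#' Read country profiles from CSV or JSON
#'
#' A country profile holds the demography and baseline epidemiology the
#' impact model needs: annual live births, neonatal and post-neonatal
#' mortality rates (per 1000 live births), total fertility rate, survey
#' year, and cause-of-death fractions per age band in `ncause_<cause>` /
#' `pcause_<cause>` columns (see [neonatal_causes()]).
#'
#' Rows violating the profile invariants (positive births and fertility,
#' non-negative rates, cause fractions in \[0, 1\] summing to 1) are
#' dropped with an itemized warning; a missing required column is an
#' error naming the column.
#'
#' @param path Path to a file.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A tibble of validated country profiles, one row per country.
#' @export
read_country_profiles <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  df <- if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_country_profiles(df)
}

required_profile_cols <- c("country_id", "survey_year", "live_births",
                           "nmr", "post_nmr", "tfr")

#' Validate a country-profile tibble
#'
#' @param profiles A data frame shaped like the `countries.csv` schema.
#' @return The validated tibble, with invalid rows dropped (warning).
#' @export
validate_country_profiles <- function(profiles) {
  df <- tibble::as_tibble(profiles)
  missing_cols <- setdiff(required_profile_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("country profiles missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ncols <- grep("^ncause_", names(df), value = TRUE)
  pcols <- grep("^pcause_", names(df), value = TRUE)
  if (length(ncols) == 0 || length(pcols) == 0) {
    abort("country profiles need ncause_* and pcause_* fraction columns")
  }
  problems <- purrr::map(seq_len(nrow(df)), function(r) {
    row <- df[r, ]
    msgs <- character()
    if (!isTRUE(row$live_births > 0)) msgs <- c(msgs, "live_births must be > 0")
    if (!isTRUE(row$nmr >= 0)) msgs <- c(msgs, "nmr must be >= 0")
    if (!isTRUE(row$post_nmr >= 0)) msgs <- c(msgs, "post_nmr must be >= 0")
    if (!isTRUE(row$tfr > 0)) msgs <- c(msgs, "tfr must be > 0")
    for (set in list(c("neonatal", "ncause_"), c("post-neonatal", "pcause_"))) {
      cols <- grep(paste0("^", set[2]), names(df), value = TRUE)
      fr <- as.numeric(row[, cols])
      if (anyNA(fr) || any(fr < 0 | fr > 1)) {
        msgs <- c(msgs, paste0(set[1], " cause fractions must lie in [0, 1]"))
      } else if (abs(sum(fr) - 1) > 1e-9) {
        msgs <- c(msgs, sprintf("%s cause fractions sum to %.6g, not 1",
                                set[1], sum(fr)))
      }
    }
    msgs
  })
  bad <- lengths(problems) > 0
  if (any(bad)) {
    detail <- purrr::map2_chr(df$country_id[bad], problems[bad],
                              ~ paste0(.x, ": ", paste(.y, collapse = "; ")))
    warn(paste0("dropping ", sum(bad), " invalid profile row(s):\n  ",
                paste(detail, collapse = "\n  ")))
  }
  df[!bad, , drop = FALSE]
}

#' Write country profiles to CSV or JSON
#'
#' @inheritParams read_country_profiles
#' @param profiles A country-profile tibble.
#' @return `path`, invisibly.
#' @export
write_country_profiles <- function(profiles, path,
                                   format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (format == "json") {
    jsonlite::write_json(profiles, path, auto_unbox = FALSE, digits = NA,
                         na = "null", dataframe = "columns")
  } else {
    readr::write_csv(profiles, path, na = "")
  }
  invisible(path)
}

#' Read a wealth-quintile coverage table
#'
#' Long-form table with one row per (country, intervention): columns
#' `country_id`, `intervention_id`, `national`, `q1`..`q5`. Coverage is
#' stored as proportions in \[0, 1\]; set `percent = TRUE` for files on
#' the 0-100 scale. Empty cells stay `NA`: missingness is a first-class
#' state (it drives proxy/backup resolution) and is never imputed as 0.
#'
#' Any present value outside \[0, 1\] is an error. A national value
#' outside the quintile range by more than 0.05 draws a plausibility
#' warning, not an error (national coverage is usually close to the
#' population-weighted quintile mean).
#'
#' @param path Path to a CSV file.
#' @param percent If `TRUE`, divide all coverage columns by 100 on read.
#' @param catalog Optional `intervention_catalog`; entries whose
#'   `intervention_id` is unknown to it draw a warning but are kept (the
#'   catalog in use decides usability downstream).
#' @return A tibble with class `coverage_table`.
#' @export
read_coverage_table <- function(path, percent = FALSE, catalog = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          country_id = readr::col_character(),
                          intervention_id = readr::col_character(),
                          .default = readr::col_double()
                        ))
  df <- validate_coverage_table(df, percent = percent)
  if (!is.null(catalog)) {
    unknown <- setdiff(df$intervention_id, catalog$interventions$intervention_id)
    if (length(unknown) > 0) {
      warn(paste0("coverage entries for interventions unknown to the catalog ",
                  "(kept): ", paste(unknown, collapse = ", ")))
    }
  }
  df
}

coverage_value_cols <- c("national", paste0("q", 1:5))

#' Validate a coverage tibble
#'
#' @inheritParams read_coverage_table
#' @param coverage A data frame shaped like the `coverage.csv` schema.
#' @return The validated tibble.
#' @export
validate_coverage_table <- function(coverage, percent = FALSE) {
  df <- tibble::as_tibble(coverage)
  missing_cols <- setdiff(c("country_id", "intervention_id", coverage_value_cols),
                          names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("coverage table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (percent) {
    df[coverage_value_cols] <- lapply(df[coverage_value_cols], function(x) x / 100)
  }
  vals <- as.matrix(df[coverage_value_cols])
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ex <- bad[1, ]
    abort(sprintf(
      "coverage values must lie in [0, 1]: %s/%s column %s is %g (%d offending value(s))",
      df$country_id[ex[1]], df$intervention_id[ex[1]],
      coverage_value_cols[ex[2]], vals[ex[1], ex[2]], nrow(bad)))
  }
  q <- as.matrix(df[paste0("q", 1:5)])
  have_all <- stats::complete.cases(q) & !is.na(df$national)
  if (any(have_all)) {
    lo <- apply(q[have_all, , drop = FALSE], 1, min)
    hi <- apply(q[have_all, , drop = FALSE], 1, max)
    nat <- df$national[have_all]
    off <- nat < lo - 0.05 | nat > hi + 0.05
    if (any(off)) {
      ids <- paste(df$country_id[have_all][off], df$intervention_id[have_all][off],
                   sep = "/")
      warn(paste0("national coverage outside quintile range (+/- 0.05) for: ",
                  paste(ids, collapse = ", ")))
    }
  }
  class(df) <- unique(c("coverage_table", class(df)))
  df
}

#' Write a coverage table to CSV
#'
#' Missing values are written as empty cells so round-trips preserve
#' missingness.
#'
#' @param coverage A coverage tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(coverage, path) {
  readr::write_csv(tibble::as_tibble(coverage), path, na = "")
  invisible(path)
}

#' Pivot one profile row into a long (age band, cause, fraction) table
#'
#' @param profile A one-row country-profile tibble.
#' @return Tibble with columns `age_band`, `cause`, `fraction`.
#' @export
cause_fractions <- function(profile) {
  stopifnot(nrow(profile) == 1)
  ncols <- grep("^ncause_", names(profile), value = TRUE)
  pcols <- grep("^pcause_", names(profile), value = TRUE)
  tibble::tibble(
    age_band = rep(c("neonatal", "postneonatal"), c(length(ncols), length(pcols))),
    cause = c(sub("^ncause_", "", ncols), sub("^pcause_", "", pcols)),
    fraction = c(as.numeric(profile[, ncols]), as.numeric(profile[, pcols]))
  )
}
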