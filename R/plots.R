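#' Plot per-country mortality-rate changes
#'
#' Bar chart of the change in under-five (or neonatal) mortality rate per
#' country under the scale-up scenario, the per-country companion to the
#' aggregate percentages.
#'
#' @param object An `equity_aggregate`.
#' @param rate `"u5mr"` or `"nmr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.equity_aggregate <- function(object, rate = c("u5mr", "nmr"), ...) {
  rate <- match.arg(rate)
  col <- paste0(rate, "_change")
  df <- object$per_country
  df$country_id <- stats::reorder(df$country_id, df[[col]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$country_id, y = .data[[col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = sprintf("%s change (per 1000 live births)", toupper(rate)),
      title = sprintf("Scale-up to top wealth quintile: %s analysis", object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a single-country intervention ranking
#'
#' Stacked bars of neonatal and child (post-neonatal) lives saved per
#' intervention, largest impact first.
#'
#' @param object An `equity_ranking`.
#' @param top_k How many interventions to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.equity_ranking <- function(object, top_k = 15, ...) {
  df <- utils::head(tibble::as_tibble(object), top_k)
  long <- tidyr::pivot_longer(
    df[, c("intervention_id", "lives_saved_neonatal", "lives_saved_child")],
    -"intervention_id", names_to = "age_band", values_to = "lives_saved",
    names_prefix = "lives_saved_"
  )
  long$intervention_id <- factor(long$intervention_id,
                                 levels = rev(df$intervention_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$intervention_id,
                                     y = .data$lives_saved,
                                     fill = .data$age_band)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Lives saved (solo scale-up)",
                  fill = "Age band",
                  title = attr(object, "country_id") %||% NULL) +
    ggplot2::theme_minimal()
}
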