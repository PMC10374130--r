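#' Plot per-rater assertion tallies
#'
#' Grouped bar chart of the [tally_by_rater()] table (the `Total` row is
#' dropped).
#'
#' @param tallies Output of [tally_by_rater()] or a tibble of the same
#'   shape.
#' @return A ggplot object.
#' @export
plot_rater_tallies <- function(tallies) {
  long <- tallies |>
    filter(.data$rater != "Total") |>
    select("rater", dplyr::all_of(collapsed_relations())) |>
    tidyr::pivot_longer(-"rater", names_to = "relation", values_to = "n") |>
    mutate(relation = factor(.data$relation, levels = collapsed_relations()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rater, y = .data$n, fill = .data$relation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Rater", y = "Assertions", fill = "Relation") +
    ggplot2::theme_minimal()
}

#' @rdname agreement
#' @param object An `agreement_report`.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  d <- tibble(
    outcome = factor(c("concordant", "discordant"), c("concordant", "discordant")),
    n = c(
      object$pairs_compared - object$pairs_discordant,
      object$pairs_discordant
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "(source, target) pairs",
      title = sprintf("Inter-observer agreement: %.1f%%", 100 * object$agreement_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname consolidate
#' @param object A `consolidation` object.
#' @method autoplot consolidation
#' @export
autoplot.consolidation <- function(object, ...) {
  d <- object$counts |>
    mutate(relation = factor(.data$relation, levels = collapsed_relations()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$relation, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Consolidated (source, target) relations") +
    ggplot2::theme_minimal()
}
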