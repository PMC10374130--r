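#' Inter-observer agreement on a multi-rater mapset
#'
#' Pair-level strict concordance: every (source, target) pair asserted by at
#' least two raters is *compared*; it is *concordant* when all those raters
#' asserted the same collapsed relation, *discordant* otherwise. The
#' agreement fraction is `1 - discordant / compared`. Pairs asserted by a
#' single rater are excluded from the denominator — raters may legitimately
#' map a source to different targets. This is a reconstruction of the usual
#' informal "percent agreement" on mapping exercises, not a chance-corrected
#' statistic.
#'
#' @param m A collapsed [mapset()].
#' @param exclude_auto Drop the `"auto"` rater before comparing
#'   (default `TRUE`): software output is not an observer.
#' @return An object of class `agreement_report`: list with
#'   `pairs_compared`, `pairs_discordant`, `agreement_fraction`, and a
#'   `discrepancies` tibble (`source_code`, `target_code`, `raters`,
#'   `relations` list-columns). With fewer than two raters the report is
#'   empty with fraction 1 and a warning.
#' @export
agreement <- function(m, exclude_auto = TRUE) {
  require_collapsed(m, "agreement()")
  a <- as_tibble(m)
  if (exclude_auto) a <- a[a$rater != "auto", , drop = FALSE]
  empty <- tibble(
    source_code = character(), target_code = character(),
    raters = list(), relations = list()
  )
  if (dplyr::n_distinct(a$rater) < 2) {
    warn("Fewer than two raters; agreement is undefined and reported as 1.")
    return(new_agreement_report(0L, 0L, 1, empty))
  }
  pairs <- a |>
    group_by(.data$source_code, .data$target_code) |>
    summarise(
      raters = list(sort(unique(.data$rater))),
      relations = list(.data$relation[order(.data$rater)]),
      n_raters = dplyr::n_distinct(.data$rater),
      n_relations = dplyr::n_distinct(.data$relation),
      .groups = "drop"
    ) |>
    filter(.data$n_raters >= 2)
  discord <- pairs[pairs$n_relations > 1, c("source_code", "target_code", "raters", "relations")]
  new_agreement_report(
    pairs_compared = nrow(pairs),
    pairs_discordant = nrow(discord),
    agreement_fraction = if (nrow(pairs) == 0) 1 else 1 - nrow(discord) / nrow(pairs),
    discrepancies = if (nrow(discord) == 0) empty else as_tibble(discord)
  )
}

new_agreement_report <- function(pairs_compared, pairs_discordant,
                                 agreement_fraction, discrepancies) {
  structure(
    list(
      pairs_compared = as.integer(pairs_compared),
      pairs_discordant = as.integer(pairs_discordant),
      agreement_fraction = agreement_fraction,
      discrepancies = discrepancies
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %d pairs compared, %d discordant, agreement %.1f%%\n",
    x$pairs_compared, x$pairs_discordant, 100 * x$agreement_fraction
  ))
  invisible(x)
}

#' @rdname agreement
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  x$discrepancies |>
    mutate(assessment = purrr::map2(.data$raters, .data$relations, function(r, rel) {
      tibble(rater = r, relation = rel)
    })) |>
    select("source_code", "target_code", "assessment") |>
    tidyr::unnest("assessment")
}

#' @rdname agreement
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    pairs_compared = x$pairs_compared,
    pairs_discordant = x$pairs_discordant,
    agreement_fraction = x$agreement_fraction
  )
}

#' Expected discordance under the independent-confusion rater model
#'
#' Closed form companion to [simulate_raters()]: each of `n_raters` raters
#' asserts a true map with probability `1 - omission` and, when asserting,
#' keeps the true collapsed relation with probability `1 - confusion` or
#' replaces it by one of the two other relations uniformly. A pair enters
#' the agreement denominator when at least two raters assert it; it is
#' concordant when all asserting raters chose the same relation. The
#' expected discordant fraction among compared pairs is
#' \deqn{\sum_{k\ge2} w_k (1 - S_k) / \sum_{k\ge2} w_k}
#' with binomial weights \eqn{w_k} for the number of asserting raters and
#' \eqn{S_k = (1-c)^k + 2 (c/2)^k}.
#'
#' @param confusion Relation-confusion probability in `[0, 1)`.
#' @param n_raters Number of raters (>= 2).
#' @param omission Per-rater omission probability in `[0, 1)`.
#' @return Expected discordant fraction (scalar in `[0, 1]`).
#' @export
expected_discordance <- function(confusion, n_raters = 3, omission = 0) {
  stopifnot(n_raters >= 2, confusion >= 0, confusion < 1, omission >= 0, omission < 1)
  k <- 2:n_raters
  w <- stats::dbinom(k, n_raters, 1 - omission)
  s_k <- (1 - confusion)^k + 2 * (confusion / 2)^k
  sum(w * (1 - s_k)) / sum(w)
}

#' Flag hierarchy-redundant directional assertions
#'
#' A `narrower_than` assertion onto target T is redundant when the same
#' source also asserts `narrower_than` onto some T' with T an ancestor of
#' T' — being inside a region of the brain already implies being inside the
#' brain. Symmetrically, `broader_than` onto T is redundant when the same
#' source asserts `broader_than` onto an ancestor T' of T. Equivalences are
#' never flagged. Ancestry is strict (T != T'); exact duplicates are handled
#' by mapset deduplication, not here.
#'
#' @param m A collapsed [mapset()].
#' @param target_h The target [classification()]; every target code in `m`
#'   must resolve in it.
#' @return A tibble of flagged (source, relation, target) triples with a
#'   `witness_code` column naming the assertion that implies each flag (the
#'   lexicographically smallest witness when several exist). Independent of
#'   assertion order.
#' @export
find_redundant <- function(m, target_h) {
  require_collapsed(m, "find_redundant()")
  a <- distinct(as_tibble(m), .data$source_code, .data$relation, .data$target_code)
  a <- a[a$relation %in% c("narrower_than", "broader_than"), , drop = FALSE]
  empty <- tibble(
    source_code = character(), relation = character(),
    target_code = character(), witness_code = character()
  )
  if (nrow(a) == 0) {
    return(empty)
  }
  missing_codes <- setdiff(unique(a$target_code), target_h$code)
  if (length(missing_codes) > 0) {
    abort(sprintf(
      "Target code(s) not in '%s': %s",
      clf_name(target_h), paste(missing_codes, collapse = ", ")
    ))
  }
  anc <- hierarchy_closure(target_h, unique(a$target_code), "ancestors")
  flags <- vector("list", 0)
  for (grp in split(a, paste(a$source_code, a$relation, sep = "\r"))) {
    if (nrow(grp) < 2) next
    targets <- grp$target_code
    for (i in seq_along(targets)) {
      t_i <- targets[i]
      others <- targets[-i]
      witnesses <- if (grp$relation[1] == "narrower_than") {
        # t_i redundant if it is an ancestor of some other asserted target
        others[vapply(others, function(o) t_i %in% anc[[o]], logical(1))]
      } else {
        # broader_than: t_i redundant if some other asserted target is its ancestor
        others[others %in% anc[[t_i]]]
      }
      if (length(witnesses) > 0) {
        flags[[length(flags) + 1]] <- tibble(
          source_code = grp$source_code[1], relation = grp$relation[1],
          target_code = t_i, witness_code = min(witnesses)
        )
      }
    }
  }
  if (length(flags) == 0) {
    return(empty)
  }
  arrange(bind_rows(flags), .data$source_code, .data$relation, .data$target_code)
}
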