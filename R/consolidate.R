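#' Consolidate multi-rater assertions into one agreed relation set
#'
#' Mechanizes the review step that turns raw auto + rater assertions into a
#' single published crosswalk:
#'
#' 1. **Support filter** — a distinct (source, target, relation) triple is
#'    retained only when supported by at least `min_support` raters; auto
#'    equivalences always qualify (lexical identity needs no vote). Dropped
#'    triples go to the review report instead of being silently deleted.
#' 2. **Redundancy filter** — triples flagged by [find_redundant()] against
#'    the target hierarchy are removed (with their witness recorded).
#' 3. **Priority selection per source** — an agreed equivalence wins over
#'    everything; otherwise narrower_than (the source is more specific)
#'    wins over broader_than. With `exclusive = TRUE` (default) the losing
#'    relations are discarded into the review report; with `FALSE` they are
#'    kept as a `secondary` table.
#' 4. All targets within the winning relation class are retained, so one
#'    source may map to several targets.
#'
#' @param m A collapsed [mapset()] containing auto and/or manual assertions.
#' @param target_h The target [classification()].
#' @param min_support Minimum number of distinct supporting raters
#'   (default 2, i.e. a majority of three raters).
#' @param exclusive Discard lower-priority relations for a source that has a
#'   selected relation (default `TRUE`).
#' @return An object of class `consolidation`: list with
#'   * `maps` — tibble `source_code`, `relation`, `target_code`, `raters`
#'     (list), `support`, `auto` (any auto support);
#'   * `counts` — tibble `relation`, `n` of retained (source, target) pairs;
#'   * `secondary` — retained lower-priority triples when
#'     `exclusive = FALSE`, else empty;
#'   * `review` — every excluded triple with a `reason`
#'     (`below_min_support`, `redundant` + `witness_code`,
#'     `superseded_by_equivalent_to`, `superseded_by_narrower_than`).
#' @export
consolidate <- function(m, target_h, min_support = 2, exclusive = TRUE) {
  if (min_support < 1) abort("`min_support` must be >= 1.")
  require_collapsed(m, "consolidate()")
  a <- as_tibble(m)
  triples <- a |>
    group_by(.data$source_code, .data$relation, .data$target_code) |>
    summarise(
      raters = list(sort(unique(.data$rater))),
      .groups = "drop"
    ) |>
    mutate(
      support = lengths(.data$raters),
      auto = purrr::map_lgl(.data$raters, ~ "auto" %in% .x)
    )

  review <- list()
  note_review <- function(t, reason, witness = NA_character_) {
    if (nrow(t) == 0) {
      return()
    }
    t$reason <- reason
    if (!"witness_code" %in% names(t)) t$witness_code <- witness
    review[[length(review) + 1]] <<- t
  }

  # (1) support threshold; auto equivalences always qualify
  qualifies <- triples$support >= min_support |
    (triples$auto & triples$relation == "equivalent_to")
  note_review(triples[!qualifies, , drop = FALSE], "below_min_support")
  kept <- triples[qualifies, , drop = FALSE]

  # (2) hierarchy redundancy
  if (nrow(kept) > 0) {
    red <- find_redundant(
      as_mapset_like(
        tibble(
          source_code = kept$source_code, relation = kept$relation,
          target_code = kept$target_code, rater = "consolidated"
        ),
        m
      ),
      target_h
    )
    if (nrow(red) > 0) {
      key <- paste(kept$source_code, kept$relation, kept$target_code, sep = "\r")
      rkey <- paste(red$source_code, red$relation, red$target_code, sep = "\r")
      flagged <- kept[key %in% rkey, , drop = FALSE]
      flagged$witness_code <- red$witness_code[match(
        paste(flagged$source_code, flagged$relation, flagged$target_code, sep = "\r"),
        rkey
      )]
      note_review(flagged, "redundant")
      kept <- kept[!key %in% rkey, , drop = FALSE]
    }
  }

  # (3) priority selection per source
  priority <- c(equivalent_to = 1L, narrower_than = 2L, broader_than = 3L)
  kept$priority <- priority[kept$relation]
  best <- if (nrow(kept) == 0) {
    mutate(kept, selected = logical(0))
  } else {
    kept |>
      group_by(.data$source_code) |>
      mutate(selected = .data$priority == min(.data$priority)) |>
      ungroup()
  }
  losers <- best[!best$selected, , drop = FALSE]
  winner_of <- best |>
    filter(.data$selected) |>
    distinct(.data$source_code, winner = .data$relation)
  maps <- best |>
    filter(.data$selected) |>
    select("source_code", "relation", "target_code", "raters", "support", "auto") |>
    arrange(.data$source_code, .data$target_code)
  secondary <- tibble(
    source_code = character(), relation = character(), target_code = character(),
    raters = list(), support = integer(), auto = logical()
  )
  if (nrow(losers) > 0) {
    losers <- left_join(losers, winner_of, by = "source_code")
    if (exclusive) {
      superseded <- losers |>
        select("source_code", "relation", "target_code", "raters",
          "support", "auto", "winner")
      for (w in unique(superseded$winner)) {
        note_review(
          superseded[superseded$winner == w, names(superseded) != "winner"],
          paste0("superseded_by_", w)
        )
      }
    } else {
      secondary <- losers |>
        select("source_code", "relation", "target_code", "raters", "support", "auto") |>
        arrange(.data$source_code, .data$target_code)
    }
  }

  counts <- tibble(relation = collapsed_relations()) |>
    left_join(count(bind_rows(maps, secondary), .data$relation), by = "relation") |>
    mutate(n = as.integer(tidyr::replace_na(.data$n, 0L)))

  review_tbl <- if (length(review) == 0) {
    tibble(
      source_code = character(), relation = character(),
      target_code = character(), raters = list(), support = integer(),
      auto = logical(), reason = character(), witness_code = character()
    )
  } else {
    bind_rows(review) |>
      select(dplyr::any_of(c(
        "source_code", "relation", "target_code", "raters",
        "support", "auto", "reason", "witness_code"
      ))) |>
      arrange(.data$source_code, .data$relation, .data$target_code)
  }
  if (!"witness_code" %in% names(review_tbl)) review_tbl$witness_code <- NA_character_

  structure(
    list(
      maps = maps, counts = counts, secondary = secondary, review = review_tbl,
      params = list(min_support = min_support, exclusive = exclusive)
    ),
    class = "consolidation"
  )
}

#' @export
print.consolidation <- function(x, ...) {
  cts <- stats::setNames(x$counts$n, x$counts$relation)
  cat(sprintf(
    "<consolidation> %d maps (%d equivalent_to, %d broader_than, %d narrower_than), %d under review\n",
    sum(cts), cts[["equivalent_to"]], cts[["broader_than"]],
    cts[["narrower_than"]], nrow(x$review)
  ))
  invisible(x)
}

#' @rdname consolidate
#' @param x A `consolidation` object.
#' @param ... Unused.
#' @method tidy consolidation
#' @export
tidy.consolidation <- function(x, ...) {
  bind_rows(x$maps, x$secondary)
}

#' @rdname consolidate
#' @method glance consolidation
#' @export
glance.consolidation <- function(x, ...) {
  cts <- stats::setNames(x$counts$n, x$counts$relation)
  tibble(
    equivalent_to = cts[["equivalent_to"]],
    broader_than = cts[["broader_than"]],
    narrower_than = cts[["narrower_than"]],
    total = sum(cts),
    n_review = nrow(x$review),
    min_support = x$params$min_support,
    exclusive = x$params$exclusive
  )
}
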