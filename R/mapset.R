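#' Typed mapping relations
#'
#' Raw assertions use `identical_to` (same title and concept) and
#' `synonym_of` (different title, same concept) alongside the directional
#' `broader_than` / `narrower_than`, which are source-relative:
#' `broader_than` means the SOURCE concept is broader than the target.
#' For analysis the two equivalence flavours are collapsed into
#' `equivalent_to` (see [collapse_equivalents()]).
#'
#' @return Character vectors of relation names.
#' @export
relation_types <- function() {
  c("identical_to", "synonym_of", "equivalent_to", "broader_than", "narrower_than")
}

#' @rdname relation_types
#' @export
collapsed_relations <- function() {
  c("equivalent_to", "broader_than", "narrower_than")
}

mapset_cols <- c(
  "source_code", "source_label", "relation", "target_code",
  "target_label", "rater", "provenance", "note"
)

#' A set of typed mapping assertions
#'
#' A `mapset` is a tibble of assertions — one row per (source entity, target
#' entity, relation, rater) — bound to the names of its source and target
#' classifications. It is the common currency of the pipeline: the auto
#' matcher emits one, raters' files read into one, and agreement, redundancy
#' and consolidation all consume one.
#'
#' @param assertions Data frame with columns `source_code`, `relation`,
#'   `target_code`, `rater` and optionally `source_label`, `target_label`,
#'   `provenance` (`"auto"` or `"manual"`, inferred from `rater` when
#'   missing) and `note`.
#' @param source_ref,target_ref Names of the source and target
#'   classifications the codes refer to.
#' @return A tibble of class `mapset` with the eight canonical columns.
#'   Duplicate (source, target, relation, rater) tuples are an error.
#' @export
mapset <- function(assertions = NULL, source_ref = "source", target_ref = "target") {
  if (is.null(assertions) || nrow(as.data.frame(assertions)) == 0) {
    a <- tibble(
      source_code = character(), source_label = character(),
      relation = character(), target_code = character(),
      target_label = character(), rater = character(),
      provenance = character(), note = character()
    )
  } else {
    a <- as_tibble(assertions)
    need <- c("source_code", "relation", "target_code", "rater")
    miss <- setdiff(need, names(a))
    if (length(miss) > 0) {
      abort(sprintf("Assertions lack column(s): %s", paste(miss, collapse = ", ")))
    }
    if (!"source_label" %in% names(a)) a$source_label <- NA_character_
    if (!"target_label" %in% names(a)) a$target_label <- NA_character_
    if (!"provenance" %in% names(a)) {
      a$provenance <- ifelse(a$rater == "auto", "auto", "manual")
    }
    if (!"note" %in% names(a)) a$note <- NA_character_
    bad <- setdiff(unique(a$relation), relation_types())
    if (length(bad) > 0) {
      abort(sprintf("Unknown relation type(s): %s", paste(bad, collapse = ", ")))
    }
    key <- paste(a$source_code, a$target_code, a$relation, a$rater, sep = "\r")
    if (anyDuplicated(key)) {
      abort("Duplicate (source, target, relation, rater) assertion(s).")
    }
    a <- a[, mapset_cols]
  }
  structure(a,
    class = c("mapset", class(a)),
    source_ref = source_ref, target_ref = target_ref
  )
}

#' @export
print.mapset <- function(x, ...) {
  cat(sprintf(
    "<mapset> %s -> %s: %d assertions, %d raters\n",
    attr(x, "source_ref") %||% "?", attr(x, "target_ref") %||% "?",
    nrow(x), dplyr::n_distinct(x$rater)
  ))
  NextMethod()
}

# Rebuild a mapset around a plain tibble, keeping refs from a template.
as_mapset_like <- function(a, template) {
  mapset(a,
    source_ref = attr(template, "source_ref") %||% "source",
    target_ref = attr(template, "target_ref") %||% "target"
  )
}

#' Read and write assertion TSV files
#'
#' The on-disk interchange format for assertions (one per line) with header
#' `source_code source_label relation target_code target_label rater
#' provenance note`, tab-separated — the modern replacement for ad-hoc CSV
#' exports of mapping tools.
#'
#' @param path File path.
#' @param source_ref,target_ref Hierarchy names recorded on the mapset.
#' @return `read_mapset()` a [mapset()]; `write_mapset()` `path` invisibly.
#' @export
read_mapset <- function(path, source_ref = "source", target_ref = "target") {
  a <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  mapset(a, source_ref = source_ref, target_ref = target_ref)
}

#' @rdname read_mapset
#' @param m A [mapset()].
#' @export
write_mapset <- function(m, path) {
  body <- as_tibble(m)[, mapset_cols]
  lines <- c(
    paste(mapset_cols, collapse = "\t"),
    apply(body, 1, function(r) paste(ifelse(is.na(r), "", r), collapse = "\t"))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Collapse the two equivalence flavours into one
#'
#' `identical_to` and `synonym_of` record how an equivalence was found, not
#' different semantics; for analysis they are rewritten to a single
#' `equivalent_to` category. Duplicates created by the rewrite (a rater who
#' asserted both flavours for the same pair) are dropped; directional
#' relations pass through untouched. Idempotent.
#'
#' @param m A [mapset()].
#' @return The collapsed [mapset()].
#' @export
collapse_equivalents <- function(m) {
  a <- as_tibble(m)
  a$relation[a$relation %in% c("identical_to", "synonym_of")] <- "equivalent_to"
  a <- distinct(a, .data$source_code, .data$target_code, .data$relation,
    .data$rater,
    .keep_all = TRUE
  )
  as_mapset_like(a, m)
}

is_collapsed <- function(m) {
  !any(m$relation %in% c("identical_to", "synonym_of"))
}

require_collapsed <- function(m, what) {
  if (!is_collapsed(m)) {
    abort(sprintf(
      "%s expects a collapsed mapset; run collapse_equivalents() first.", what
    ))
  }
}

#' Tally assertions by rater and relation
#'
#' The per-rater breakdown table of a mapping exercise: one row per rater
#' with counts of equivalent_to / broader_than / narrower_than assertions,
#' a row total, and a final `Total` row. Every assertion is counted exactly
#' once, so the grand total equals the number of assertions.
#'
#' @param m A collapsed [mapset()].
#' @return A tibble `rater`, `equivalent_to`, `broader_than`,
#'   `narrower_than`, `total`.
#' @export
tally_by_rater <- function(m) {
  require_collapsed(m, "tally_by_rater()")
  a <- as_tibble(m)
  base <- tidyr::expand_grid(
    rater = sort(unique(a$rater)),
    relation = collapsed_relations()
  )
  tal <- a |>
    count(.data$rater, .data$relation) |>
    dplyr::right_join(base, by = c("rater", "relation")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "relation", values_from = "n") |>
    arrange(.data$rater)
  for (col in collapsed_relations()) {
    if (is.null(tal[[col]])) tal[[col]] <- 0L
  }
  tal <- tal[, c("rater", collapsed_relations())]
  tal$total <- tal$equivalent_to + tal$broader_than + tal$narrower_than
  totals <- tibble(
    rater = "Total",
    equivalent_to = sum(tal$equivalent_to),
    broader_than = sum(tal$broader_than),
    narrower_than = sum(tal$narrower_than),
    total = sum(tal$total)
  )
  bind_rows(tal, totals)
}
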