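#' Normalize a concept title for lexical comparison
#'
#' Lowercases, replaces punctuation (commas, parentheses, hyphens, etc.) by
#' spaces, collapses internal whitespace, and trims. All title comparison in
#' the matcher happens on this normal form; codes are never normalized.
#' The function is idempotent and vectorized.
#'
#' @param s Character vector of titles.
#' @return Character vector of normalized titles.
#' @examples
#' normalize_title("  Brain ") # "brain"
#' normalize_title("Structure of brain, other specified")
#' @export
normalize_title <- function(s) {
  s <- stringr::str_to_lower(s)
  s <- stringr::str_replace_all(s, "[[:punct:]]+", " ")
  stringr::str_squish(s)
}

#' Declared synonym pairs between two classifications
#'
#' An explicit, auditable table of title pairs considered "obvious synonyms"
#' beyond the built-in "Structure of X" rule. Pairs are stored on the
#' normalized form, unordered, and never relate a title to itself.
#'
#' @param pairs A data frame with columns `title_a`, `title_b`, or `NULL`
#'   for an empty table.
#' @return A tibble of class `synonym_table` with normalized, deduplicated
#'   columns `title_a`, `title_b` (sorted within each pair).
#' @examples
#' synonym_table(data.frame(title_a = "Lens of eyeball", title_b = "Crystalline lens"))
#' @export
synonym_table <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0) {
    out <- tibble(title_a = character(), title_b = character())
  } else {
    pairs <- as_tibble(pairs)
    if (!all(c("title_a", "title_b") %in% names(pairs))) {
      abort("A synonym table needs columns `title_a` and `title_b`.")
    }
    a <- normalize_title(pairs$title_a)
    b <- normalize_title(pairs$title_b)
    keep <- a != b
    out <- distinct(tibble(
      title_a = pmin(a[keep], b[keep]),
      title_b = pmax(a[keep], b[keep])
    ))
  }
  structure(out, class = c("synonym_table", class(out)))
}

#' @rdname synonym_table
#' @param path A 2-column TSV with header `title_a<TAB>title_b`.
#' @export
read_synonym_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  synonym_table(tab)
}

# All normalized titles declared synonymous with `s` (itself excluded).
synonym_partners <- function(syn, s) {
  c(syn$title_b[syn$title_a == s], syn$title_a[syn$title_b == s])
}

# Lookup from normalized label (title or synonym) to entity codes.
label_index <- function(h, include_synonyms = TRUE) {
  labs <- lapply(seq_len(nrow(h)), function(i) {
    l <- h$title[i]
    if (include_synonyms) l <- c(l, h$synonyms[[i]])
    unique(normalize_title(l))
  })
  tibble(
    label = unlist(labs) %||% character(),
    code = rep(h$code, lengths(labs))
  ) |> distinct()
}

#' Auto-detect straightforward lexical mappings between two classifications
#'
#' Reproduces the software-assisted stage of an expert mapping exercise: for
#' every non-residual source entity it proposes at most one assertion under
#' the rater id `"auto"`:
#'
#' * `identical_to` when exactly one target entity has a title or synonym
#'   whose normal form equals the source title;
#' * otherwise `synonym_of` when the source title has the form
#'   "Structure(s) of X" and exactly one target *title* matches X — e.g.
#'   "Structure of brain" maps as synonym_of "Brain";
#' * otherwise `synonym_of` when the synonym table links the source title to
#'   exactly one target title.
#'
#' Sources with no candidate, or with ambiguous candidates (duplicated target
#' titles), get no auto assertion and appear in the unmatched report
#' (`attr(result, "unmatched")`, also via [unmatched_report()]). Residual
#' sources are never mapped.
#'
#' @param source,target [classification()]s; residual flags on `source`
#'   should already be set (see [flag_residuals()]).
#' @param syn A [synonym_table()]; defaults to empty.
#' @return A [mapset()] of auto assertions with an `unmatched` attribute
#'   (tibble with columns `source_code`, `title`, `reason`, `n_candidates`).
#' @export
auto_match <- function(source, target, syn = synonym_table()) {
  validate_classification(source)
  validate_classification(target)
  idx_all <- label_index(target, include_synonyms = TRUE)
  idx_title <- label_index(target, include_synonyms = FALSE)
  title_of <- stats::setNames(target$title, target$code)

  src <- source[!source$residual, , drop = FALSE]
  rows <- vector("list", nrow(src))
  un <- vector("list", nrow(src))
  for (i in seq_len(nrow(src))) {
    q <- normalize_title(src$title[i])
    hit <- unique(idx_all$code[idx_all$label == q])
    relation <- "identical_to"
    if (length(hit) == 0) {
      relation <- "synonym_of"
      m <- stringr::str_match(q, "^structures? of (.+)$")[, 2]
      if (!is.na(m)) hit <- unique(idx_title$code[idx_title$label == m])
      if (length(hit) == 0) {
        partners <- synonym_partners(syn, q)
        hit <- unique(idx_title$code[idx_title$label %in% partners])
      }
    }
    if (length(hit) == 1) {
      rows[[i]] <- tibble(
        source_code = src$code[i], source_label = src$title[i],
        relation = relation, target_code = hit,
        target_label = unname(title_of[hit]),
        rater = "auto", provenance = "auto", note = NA_character_
      )
    } else {
      un[[i]] <- tibble(
        source_code = src$code[i], title = src$title[i],
        reason = if (length(hit) == 0) "no_candidate" else "ambiguous",
        n_candidates = length(hit)
      )
    }
  }
  ms <- mapset(bind_rows(rows),
    source_ref = clf_name(source), target_ref = clf_name(target)
  )
  attr(ms, "unmatched") <- bind_rows(un)
  ms
}

#' @rdname auto_match
#' @param m A mapset returned by `auto_match()`.
#' @export
unmatched_report <- function(m) {
  attr(m, "unmatched") %||%
    tibble(
      source_code = character(), title = character(),
      reason = character(), n_candidates = integer()
    )
}

#' Ranked candidate search over a target classification
#'
#' A lightweight stand-in for an interactive coding tool: scores every target
#' entity against a free-text query and returns the top `k`. The score is
#' `0.75 * J + 0.25 * C` where `J` is the token-set Jaccard overlap between
#' the normalized query and the entity's normalized title or synonym
#' (whichever scores best) and `C` is 1 when either phrase contains the
#' other whole, else 0. The score is exactly 1 only for exact normalized
#' equality (near-misses are capped just below 1). Ties break by code.
#'
#' @param query Search string; an empty/blank query returns no rows.
#' @param target A [classification()].
#' @param k Maximum number of results (>= 1).
#' @return A tibble `code`, `title`, `score`, sorted by descending score
#'   then code; at most `k` rows, zero-score entities dropped.
#' @examples
#' h <- classification(data.frame(code = c("L1", "B1"),
#'                                title = c("Crystalline lens", "Brain")))
#' search_candidates("lens", h, k = 5)
#' @export
search_candidates <- function(query, target, k = 10) {
  stopifnot(k >= 1)
  q <- normalize_title(query)
  if (identical(q, "") || is.na(q)) {
    return(tibble(code = character(), title = character(), score = numeric()))
  }
  scores <- vapply(seq_len(nrow(target)), function(i) {
    labs <- unique(normalize_title(c(target$title[i], target$synonyms[[i]])))
    max(vapply(labs, function(l) lexical_score(q, l), numeric(1)))
  }, numeric(1))
  out <- tibble(code = target$code, title = target$title, score = scores)
  out <- out[out$score > 0, , drop = FALSE]
  out <- out[order(-out$score, out$code, method = "radix"), , drop = FALSE]
  head(out, k)
}

# Score one query against one normalized label.
lexical_score <- function(q, label, jaccard_weight = 0.75, phrase_bonus = 0.25) {
  if (identical(q, label)) {
    return(1)
  }
  qt <- unique(strsplit(q, " ", fixed = TRUE)[[1]])
  lt <- unique(strsplit(label, " ", fixed = TRUE)[[1]])
  j <- length(intersect(qt, lt)) / length(union(qt, lt))
  contains <- grepl(q, label, fixed = TRUE) || grepl(label, q, fixed = TRUE)
  min(jaccard_weight * j + phrase_bonus * contains, 1 - 1e-6)
}
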