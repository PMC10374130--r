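relation_to_predicate <- c(
  equivalent_to = "skos:exactMatch",
  narrower_than = "skos:broadMatch", # the OBJECT is the broader concept
  broader_than = "skos:narrowMatch" # the OBJECT is the narrower concept
)

sssom_cols <- c(
  "subject_id", "subject_label", "predicate_id", "object_id",
  "object_label", "mapping_justification", "author_id", "comment"
)

#' Write a consolidated mapping set as SSSOM TSV
#'
#' SSSOM (Simple Standard for Sharing Ontological Mappings) is a TSV format
#' with a commented YAML-style metadata header and SKOS match predicates.
#' The relation-to-predicate convention deserves care because the SKOS
#' predicates are *object*-relative while the mapping relations here are
#' *source*-relative: a source `narrower_than` its target maps to
#' `skos:broadMatch` (the object is the broader concept), and a source
#' `broader_than` its target maps to `skos:narrowMatch`. Equivalences become
#' `skos:exactMatch`. Rows carry `semapv:LexicalMatching` when auto-supported
#' and `semapv:ManualMappingCuration` otherwise, and are sorted by
#' `subject_id` then `object_id`, making output byte-stable.
#'
#' @param maps A `consolidation` object from [consolidate()], or a tibble
#'   with columns `source_code`, `relation`, `target_code` and optionally
#'   `raters` (list) and `auto`.
#' @param source_h,target_h The [classification()]s the codes resolve in
#'   (labels are taken from them).
#' @param metadata Named list/vector for the header; must include
#'   `mapping_set_id` and `license`.
#' @param path File to write; when `NULL` the document is returned as one
#'   string.
#' @param subject_prefix,object_prefix CURIE prefixes for subject and object
#'   ids (defaults: the classification names).
#' @param curie_map Named character vector prefix -> base URI for the
#'   header's curie_map block.
#' @return `path` invisibly, or the document text.
#' @export
write_sssom <- function(maps, source_h, target_h, metadata, path = NULL,
                        subject_prefix = clf_name(source_h),
                        object_prefix = clf_name(target_h),
                        curie_map = NULL) {
  if (inherits(maps, "consolidation")) maps <- tidy(maps)
  maps <- as_tibble(maps)
  for (key in c("mapping_set_id", "license")) {
    if (is.null(metadata[[key]])) {
      abort(sprintf("SSSOM metadata must include '%s'.", key))
    }
  }
  bad_rel <- setdiff(unique(maps$relation), names(relation_to_predicate))
  if (length(bad_rel) > 0) {
    abort(sprintf("Cannot serialize relation(s): %s", paste(bad_rel, collapse = ", ")))
  }
  bad_s <- setdiff(unique(maps$source_code), source_h$code)
  bad_t <- setdiff(unique(maps$target_code), target_h$code)
  if (length(bad_s) + length(bad_t) > 0) {
    abort(sprintf(
      "Unresolvable code(s): %s",
      paste(c(bad_s, bad_t), collapse = ", ")
    ))
  }
  if (is.null(curie_map)) {
    curie_map <- stats::setNames(
      paste0("https://example.org/", c(subject_prefix, object_prefix), "/"),
      c(subject_prefix, object_prefix)
    )
  }
  s_title <- stats::setNames(source_h$title, source_h$code)
  t_title <- stats::setNames(target_h$title, target_h$code)
  raters <- if ("raters" %in% names(maps)) maps$raters else rep(list(character()), nrow(maps))
  auto <- if ("auto" %in% names(maps)) {
    maps$auto
  } else {
    purrr::map_lgl(raters, ~ "auto" %in% .x)
  }
  body <- tibble(
    subject_id = paste0(subject_prefix, ":", maps$source_code),
    subject_label = unname(s_title[maps$source_code]),
    predicate_id = unname(relation_to_predicate[maps$relation]),
    object_id = paste0(object_prefix, ":", maps$target_code),
    object_label = unname(t_title[maps$target_code]),
    mapping_justification = ifelse(auto,
      "semapv:LexicalMatching", "semapv:ManualMappingCuration"
    ),
    author_id = purrr::map_chr(raters, paste, collapse = "|"),
    comment = ""
  )
  body <- body[order(body$subject_id, body$object_id, method = "radix"), , drop = FALSE]

  header <- c(
    "# curie_map:",
    sprintf("#   %s: \"%s\"", names(curie_map), unname(curie_map)),
    sprintf(
      "# %s: %s",
      sort(names(metadata)),
      vapply(sort(names(metadata)), function(k) as.character(metadata[[k]]), character(1))
    )
  )
  lines <- c(
    header,
    paste(sssom_cols, collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) {
    return(txt)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "", useBytes = TRUE)
  invisible(path)
}

#' Read an SSSOM TSV mapping set
#'
#' Inverse of [write_sssom()] up to row order, restricted to the same
#' dialect: `skos:exactMatch` / `skos:broadMatch` / `skos:narrowMatch`
#' predicates only; any other predicate is a validation error naming the
#' offending row.
#'
#' @param document Path to an SSSOM TSV file, or its text.
#' @return A list with `maps` (tibble `source_code`, `relation`,
#'   `target_code`, `raters`, `support`, `auto`, plus labels) and `metadata`
#'   (named list, with `curie_map` nested).
#' @export
read_sssom <- function(document) {
  lines <- if (length(document) == 1 && grepl("\n", document, fixed = TRUE)) {
    strsplit(document, "\n", fixed = TRUE)[[1]]
  } else if (length(document) == 1 && file.exists(document)) {
    readLines(document)
  } else {
    as.character(document)
  }
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  body_lines <- lines[!is_meta & nzchar(lines)]

  metadata <- list()
  curie_map <- character()
  in_curie <- FALSE
  for (ln in meta_lines) {
    if (grepl("^# curie_map:", ln)) {
      in_curie <- TRUE
    } else if (in_curie && grepl("^#   ", ln)) {
      kv <- stringr::str_match(ln, "^#\\s+([^:]+):\\s*\"?([^\"]*)\"?\\s*$")
      curie_map[kv[2]] <- kv[3]
    } else {
      in_curie <- FALSE
      kv <- stringr::str_match(ln, "^#\\s*([^:]+):\\s*(.*)$")
      if (!is.na(kv[2])) metadata[[stringr::str_trim(kv[2])]] <- stringr::str_trim(kv[3])
    }
  }
  if (length(curie_map) > 0) metadata$curie_map <- as.list(curie_map)

  empty <- tibble(
    source_code = character(), source_label = character(),
    relation = character(), target_code = character(),
    target_label = character(), raters = list(), support = integer(),
    auto = logical()
  )
  if (length(body_lines) == 0) {
    return(list(maps = empty, metadata = metadata))
  }
  header <- strsplit(body_lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("subject_id", "predicate_id", "object_id") %in% header)) {
    abort("SSSOM body lacks subject_id/predicate_id/object_id columns.")
  }
  cells <- lapply(body_lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  get <- function(row, col) {
    i <- match(col, header)
    if (is.na(i) || i > length(row)) "" else row[i]
  }
  predicate_to_relation <- stats::setNames(
    names(relation_to_predicate), relation_to_predicate
  )
  maps <- purrr::imap(cells, function(row, i) {
    pred <- get(row, "predicate_id")
    if (!pred %in% names(predicate_to_relation)) {
      abort(sprintf("Row %d: predicate '%s' is outside the dialect.", i, pred))
    }
    authors <- strsplit(get(row, "author_id"), "|", fixed = TRUE)[[1]]
    tibble(
      source_code = sub("^[^:]+:", "", get(row, "subject_id")),
      source_label = get(row, "subject_label"),
      relation = unname(predicate_to_relation[pred]),
      target_code = sub("^[^:]+:", "", get(row, "object_id")),
      target_label = get(row, "object_label"),
      raters = list(authors),
      support = length(authors),
      auto = "auto" %in% authors
    )
  }) |> bind_rows()
  list(maps = maps, metadata = metadata)
}
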