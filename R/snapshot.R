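#' Read and write hierarchy snapshots in the Foundation JSON dialect
#'
#' The ICD-11 Foundation is served entity-by-entity over a web API; for
#' offline, reproducible work this package consumes a snapshot instead: a
#' JSON array of records `{"id": str, "title": str, "synonyms": [str],
#' "parents": [str]}`. `parse_foundation_snapshot()` reads such a document
#' into a [classification()]; `write_foundation_snapshot()` is its inverse,
#' and parse -> write -> parse is the identity on entities and parent links.
#'
#' @param document Path to a snapshot file, or a single JSON string.
#' @param name,version Classification name and version label.
#' @return A [classification()]. Duplicate ids and parent cycles are
#'   integrity errors (a cycle is spelled out in the message).
#' @examples
#' js <- '[{"id":"B","title":"Brain","synonyms":[],"parents":[]},
#'         {"id":"C","title":"Cerebellum","synonyms":[],"parents":["B"]}]'
#' parse_foundation_snapshot(js, name = "icd11")
#' @export
parse_foundation_snapshot <- function(document, name = "foundation", version = "") {
  recs <- tryCatch(
    jsonlite::fromJSON(document, simplifyVector = FALSE),
    error = function(e) abort(sprintf("Snapshot parse error: %s", conditionMessage(e)))
  )
  if (length(recs) == 0) {
    return(classification(
      tibble(code = character(), title = character()),
      name = name, version = version
    ))
  }
  ids <- vapply(recs, function(r) as.character(r$id %||% NA_character_), character(1))
  if (anyNA(ids)) abort("Snapshot record without an 'id' field.")
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Duplicate id(s) in snapshot: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  ent <- tibble(
    code = ids,
    title = vapply(recs, function(r) as.character(r$title %||% ""), character(1)),
    synonyms = lapply(recs, function(r) as.character(unlist(r$synonyms))),
    parents = lapply(recs, function(r) as.character(unlist(r$parents)))
  )
  classification(ent, name = name, version = version)
}

#' @rdname parse_foundation_snapshot
#' @param h A [classification()].
#' @param path File to write; when `NULL` the JSON is returned as a string.
#' @export
write_foundation_snapshot <- function(h, path = NULL) {
  validate_classification(h)
  recs <- lapply(seq_len(nrow(h)), function(i) {
    list(
      id = jsonlite::unbox(h$code[i]),
      title = jsonlite::unbox(h$title[i]),
      synonyms = as.character(h$synonyms[[i]]),
      parents = as.character(h$parents[[i]])
    )
  })
  txt <- jsonlite::toJSON(recs, pretty = TRUE)
  if (is.null(path)) {
    return(as.character(txt))
  }
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}
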