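#' Build a classification hierarchy from an entity table
#'
#' A `classification` is a tibble of coded entities carrying the hierarchy
#' as list-columns, so it pipes through dplyr like any other table while the
#' classification's name and version travel along as attributes. Both WHO-FIC
#' style classifications handled here (an ICF-like linearization and an
#' ICD-11-Foundation-like polyhierarchy) fit this model: entities may have
#' several parents, the parent graph must be acyclic, and codes are opaque,
#' case-sensitive identifiers.
#'
#' @param entities A data frame with columns `code` (character), `title`
#'   (character), and optionally `synonyms` (list of character vectors),
#'   `parents` (list of character vectors of parent codes) and `residual`
#'   (logical). Missing optional columns are filled with empty defaults.
#' @param name Short name of the classification (e.g. `"icf"`).
#' @param version Free-text version label (e.g. `"2017"`).
#' @param validate Check structural invariants (default `TRUE`).
#'
#' @return A tibble of class `classification` with columns
#'   `code`, `title`, `synonyms`, `parents`, `residual`.
#' @examples
#' classification(
#'   data.frame(code = c("s110", "s1100"), title = c("Structure of brain", "Cortical lobes")),
#'   name = "icf"
#' )
#' @export
classification <- function(entities, name = "classification", version = "",
                           validate = TRUE) {
  ent <- as_tibble(entities)
  if (!all(c("code", "title") %in% names(ent))) {
    abort("`entities` needs at least `code` and `title` columns.")
  }
  n <- nrow(ent)
  if (!"synonyms" %in% names(ent)) ent$synonyms <- rep(list(character()), n)
  if (!"parents" %in% names(ent)) ent$parents <- rep(list(character()), n)
  if (!"residual" %in% names(ent)) ent$residual <- rep(FALSE, n)
  ent$code <- as.character(ent$code)
  ent$title <- as.character(ent$title)
  ent$synonyms <- lapply(ent$synonyms, function(x) as.character(x))
  # duplicate parent links are legal input but carry no information
  ent$parents <- lapply(ent$parents, function(x) unique(as.character(x)))
  ent <- ent[, c("code", "title", "synonyms", "parents", "residual")]
  out <- structure(ent,
    class = c("classification", class(ent)),
    clf_name = name, clf_version = version
  )
  if (validate) validate_classification(out)
  out
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf(
    "<classification> %s %s: %d entities, %d roots, %d residual\n",
    attr(x, "clf_name"), attr(x, "clf_version"), nrow(x),
    length(root_codes(x)), sum(x$residual)
  ))
  NextMethod()
}

#' Name, version and roots of a classification
#'
#' @param h A [classification()].
#' @return `clf_name()` and `clf_version()` return strings; `root_codes()`
#'   the codes of entities without parents.
#' @export
clf_name <- function(h) attr(h, "clf_name") %||% "classification"

#' @rdname clf_name
#' @export
clf_version <- function(h) attr(h, "clf_version") %||% ""

#' @rdname clf_name
#' @export
root_codes <- function(h) h$code[lengths(h$parents) == 0L]

#' Validate the structural invariants of a classification
#'
#' Checks that codes are non-empty and unique, that no entity is its own
#' parent, that every parent code resolves, that the parent graph is acyclic
#' (a cycle is reported), and that residual entities have a parent.
#'
#' @param h A [classification()].
#' @return `h`, invisibly; errors describe the first violated invariant.
#' @export
validate_classification <- function(h) {
  if (nrow(h) == 0) {
    return(invisible(h))
  }
  if (any(is.na(h$code) | h$code == "")) {
    abort("Every entity must have a non-empty code.")
  }
  dup <- h$code[duplicated(h$code)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate entity code(s): %s", paste(unique(dup), collapse = ", ")))
  }
  self <- h$code[mapply(function(c, p) c %in% p, h$code, h$parents)]
  if (length(self) > 0) {
    abort(sprintf("Entity is its own parent: %s", paste(self, collapse = ", ")))
  }
  all_parents <- unique(unlist(h$parents))
  dangling <- setdiff(all_parents, h$code)
  if (length(dangling) > 0) {
    abort(sprintf(
      "Parent code(s) do not resolve to any entity: %s",
      paste(dangling, collapse = ", ")
    ))
  }
  cyc <- find_parent_cycle(h)
  if (!is.null(cyc)) {
    abort(sprintf("Parent graph is cyclic: %s", paste(cyc, collapse = " -> ")))
  }
  bad_res <- h$code[h$residual & lengths(h$parents) == 0L]
  if (length(bad_res) > 0) {
    abort(sprintf(
      "Residual entities must have a parent: %s",
      paste(bad_res, collapse = ", ")
    ))
  }
  invisible(h)
}

# Edge list child -> parent as a two-column tibble.
hierarchy_edges <- function(h) {
  np <- lengths(h$parents)
  tibble(
    child = rep(h$code, np),
    parent = unlist(h$parents) %||% character()
  )
}

# igraph over child -> parent edges; isolated entities kept as vertices.
hierarchy_graph <- function(h) {
  e <- hierarchy_edges(h)
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = h["code"])
}

# One cycle in the parent graph (codes in order), or NULL if acyclic.
find_parent_cycle <- function(h) {
  g <- hierarchy_graph(h)
  if (igraph::is_dag(g)) {
    return(NULL)
  }
  parents <- stats::setNames(h$parents, h$code)
  state <- stats::setNames(rep(0L, nrow(h)), h$code) # 0 new, 1 open, 2 done
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) {
      return()
    }
    state[v] <<- 1L
    path <<- c(path, v)
    for (p in parents[[v]]) {
      if (!is.null(found)) break
      if (state[p] == 1L) {
        i <- match(p, path)
        found <<- c(path[i:length(path)], p)
      } else if (state[p] == 0L) {
        visit(p)
      }
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in h$code) {
    if (state[v] == 0L) visit(v)
    if (!is.null(found)) break
  }
  found
}

#' Ancestor and descendant queries on a classification
#'
#' Transitive closure over the parent links: `direction = "ancestors"`
#' returns every entity reachable by following parent links from `code`,
#' `"descendants"` every entity from which `code` is so reachable. The
#' entity itself is excluded. Polyhierarchies are supported; each code is
#' reported once.
#'
#' @param h A [classification()].
#' @param code An entity code present in `h`.
#' @param direction `"ancestors"` or `"descendants"`.
#' @return A character vector of codes (possibly empty), sorted.
#' @examples
#' h <- classification(data.frame(
#'   code = c("A", "B", "C"), title = c("A", "B", "C"),
#'   parents = I(list(character(), "A", "B"))
#' ))
#' hierarchy_query(h, "C", "ancestors") # "A" "B"
#' @export
hierarchy_query <- function(h, code, direction = c("ancestors", "descendants")) {
  direction <- match.arg(direction)
  if (!code %in% h$code) {
    abort(sprintf("Unknown code '%s' in classification '%s'.", code, clf_name(h)))
  }
  g <- hierarchy_graph(h)
  mode <- if (direction == "ancestors") "out" else "in"
  reach <- names(igraph::subcomponent(g, code, mode = mode))
  sort(setdiff(reach, code))
}

# Closure for many codes at once: named list code -> character vector.
hierarchy_closure <- function(h, codes, direction = "ancestors") {
  g <- hierarchy_graph(h)
  mode <- if (direction == "ancestors") "out" else "in"
  out <- lapply(codes, function(cd) {
    sort(setdiff(names(igraph::subcomponent(g, cd, mode = mode)), cd))
  })
  stats::setNames(out, codes)
}

#' Flag residual categories by title pattern
#'
#' Residual categories ("other specified", "unspecified", "not otherwise
#' specified") are semantically equivalent to their parent and are excluded
#' from mapping. Flagging is by case-insensitive fixed substring match on the
#' title; the pattern list is configurable because classifications differ in
#' how residuals are labelled.
#'
#' @param h A [classification()].
#' @param patterns Character vector of title substrings (case-insensitive)
#'   that mark a residual category.
#' @return `h` with `residual` set to `TRUE` exactly on matching titles.
#'   Idempotent; only the `residual` column is touched.
#' @examples
#' h <- classification(data.frame(
#'   code = c("s110", "s198"),
#'   title = c("Structure of brain", "Structure of brain, other specified"),
#'   parents = I(list(character(), "s110"))
#' ))
#' flag_residuals(h)$residual
#' @export
flag_residuals <- function(h, patterns = residual_patterns()) {
  stopifnot(length(patterns) > 0)
  lowered <- stringr::str_to_lower(h$title)
  hit <- rep(FALSE, nrow(h))
  for (p in stringr::str_to_lower(patterns)) {
    hit <- hit | stringr::str_detect(lowered, stringr::fixed(p))
  }
  h$residual <- hit
  validate_classification(h)
  h
}

#' @rdname flag_residuals
#' @export
residual_patterns <- function() {
  c("other specified", "unspecified", "not otherwise specified")
}
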