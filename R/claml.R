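#' Read a classification from ClaML XML
#'
#' ClaML (Classification Markup Language) is the XML exchange standard for
#' statistical classifications; ICF 2017 is distributed in it. Only the
#' elements needed for mapping are interpreted: `Class` (attribute `code`),
#' `SuperClass` (attribute `code`, one per parent), and `Rubric` labels —
#' `kind="preferred"` becomes the title, `kind="inclusion"` rubrics become
#' synonyms. Any other element is ignored with a notice.
#'
#' @param document Path to a ClaML file, or a single string of ClaML XML.
#' @param name,version Classification name and version label; when `NULL`,
#'   taken from the ClaML `<Title>` element if present.
#' @param quiet Suppress the notice about ignored element kinds.
#' @return A [classification()].
#' @examples
#' doc <- paste0(
#'   "<ClaML><Class code='s110'>",
#'   "<Rubric kind='preferred'><Label>Structure of brain</Label></Rubric></Class>",
#'   "<Class code='s1100'><SuperClass code='s110'/>",
#'   "<Rubric kind='preferred'><Label>Cortical lobes</Label></Rubric></Class></ClaML>"
#' )
#' parse_claml(doc, name = "icf", version = "2017")
#' @export
parse_claml <- function(document, name = NULL, version = NULL, quiet = FALSE) {
  xml <- tryCatch(
    xml2::read_xml(document),
    error = function(e) {
      abort(sprintf("ClaML parse error: %s", conditionMessage(e)))
    }
  )
  title_node <- xml2::xml_find_first(xml, ".//Title")
  if (is.null(name)) {
    name <- if (!inherits(title_node, "xml_missing")) {
      xml2::xml_attr(title_node, "name") %||% "claml"
    } else {
      "claml"
    }
    if (is.na(name)) name <- "claml"
  }
  if (is.null(version)) {
    version <- if (!inherits(title_node, "xml_missing")) {
      xml2::xml_attr(title_node, "version")
    } else {
      NA_character_
    }
    if (is.na(version)) version <- ""
  }

  classes <- xml2::xml_find_all(xml, ".//Class")
  codes <- xml2::xml_attr(classes, "code")
  if (anyNA(codes)) abort("ClaML Class element without a code attribute.")

  parse_class <- function(cl) {
    pref <- xml2::xml_find_first(cl, "./Rubric[@kind='preferred']/Label")
    title <- if (inherits(pref, "xml_missing")) {
      xml2::xml_attr(cl, "code")
    } else {
      xml2::xml_text(pref)
    }
    syn <- xml2::xml_text(
      xml2::xml_find_all(cl, "./Rubric[@kind='inclusion']/Label")
    )
    parents <- xml2::xml_attr(xml2::xml_find_all(cl, "./SuperClass"), "code")
    list(title = stringr::str_squish(title), synonyms = syn, parents = parents)
  }
  parsed <- lapply(classes, parse_class)

  if (!quiet) {
    kinds <- unique(xml2::xml_attr(xml2::xml_find_all(xml, ".//Rubric"), "kind"))
    ignored <- setdiff(kinds, c("preferred", "inclusion"))
    if (length(ignored) > 0) {
      inform(sprintf(
        "Ignoring Rubric kind(s) not used for mapping: %s",
        paste(ignored, collapse = ", ")
      ))
    }
  }

  ent <- tibble(
    code = codes,
    title = vapply(parsed, `[[`, character(1), "title"),
    synonyms = lapply(parsed, `[[`, "synonyms"),
    parents = lapply(parsed, `[[`, "parents")
  )
  dangling <- setdiff(unique(unlist(ent$parents)), ent$code)
  if (length(dangling) > 0) {
    abort(sprintf(
      "SuperClass reference(s) to absent code(s): %s",
      paste(dangling, collapse = ", ")
    ))
  }
  classification(ent, name = name, version = version)
}

#' Write a classification as minimal ClaML XML
#'
#' Emits only the dialect [parse_claml()] reads back: `Class`, `SuperClass`,
#' and preferred/inclusion `Rubric` labels. Used mainly to export synthetic
#' fixtures in the same format as the real source classification.
#'
#' @param h A [classification()].
#' @param path File to write; when `NULL` the XML is returned as a string.
#' @return `path` (invisibly) or the XML text.
#' @export
write_claml <- function(h, path = NULL) {
  validate_classification(h)
  doc <- xml2::xml_new_root("ClaML", version = "2.0.0")
  ttl <- xml2::xml_add_child(doc, "Title",
    name = clf_name(h), version = clf_version(h)
  )
  xml2::xml_text(ttl) <- clf_name(h)
  for (i in seq_len(nrow(h))) {
    cl <- xml2::xml_add_child(doc, "Class", code = h$code[i])
    for (p in h$parents[[i]]) xml2::xml_add_child(cl, "SuperClass", code = p)
    rb <- xml2::xml_add_child(cl, "Rubric", kind = "preferred")
    lb <- xml2::xml_add_child(rb, "Label")
    xml2::xml_text(lb) <- h$title[i]
    for (s in h$synonyms[[i]]) {
      rb <- xml2::xml_add_child(cl, "Rubric", kind = "inclusion")
      lb <- xml2::xml_add_child(rb, "Label")
      xml2::xml_text(lb) <- s
    }
  }
  txt <- as.character(doc)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}
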