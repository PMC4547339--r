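# JSON pathway dialect: the project's canonical serialization.
# Top-level keys "entities", "pathways", "reactions"; all object keys and all
# id arrays sorted, so write output is byte-stable and read/write invert.

#' Serialize a pathway model to the JSON dialect
#'
#' Output is canonical: object keys in alphabetical order, records sorted by
#' id, id arrays sorted, two-space indentation. Two structurally equal
#' models serialize to byte-identical documents.
#'
#' @param model A `pathway_model`.
#' @param path Optional file path; when given the document is also written
#'   there (UTF-8).
#' @return The JSON document as a character scalar (invisibly when `path`
#'   is supplied).
#' @export
write_pathway_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  ent <- lapply(model$entities[order(names(model$entities))], function(e) {
    list(components = as.list(e$components), id = e$id, kind = e$kind,
         name = e$name)
  })
  pw <- lapply(model$pathways[order(names(model$pathways))], function(p) {
    list(color = p$color_index, entities = as.list(p$entity_ids), id = p$id,
         name = p$name, parent = p$parent_id, reactions = as.list(p$reaction_ids))
  })
  rx <- lapply(model$reactions[order(names(model$reactions))], function(r) {
    list(id = r$id, inputs = as.list(r$inputs), outputs = as.list(r$outputs),
         pathways = as.list(r$pathway_ids))
  })
  doc <- list(entities = unname(ent), pathways = unname(pw),
              reactions = unname(rx))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, na = "null", null = "null",
                          pretty = 2)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

json_field <- function(rec, field, where, required = TRUE, default = NULL) {
  if (is.null(rec[[field]])) {
    if (required) {
      stop("pathway JSON validation error: missing field '", field,
           "' in ", where, call. = FALSE)
    }
    return(default)
  }
  rec[[field]]
}

#' Read a pathway model from the JSON dialect
#'
#' @param text JSON document as a character scalar, or a file path.
#' @return A validated `pathway_model`.
#' @export
read_pathway_json <- function(text) {
  if (length(text) == 1L && !grepl("[{\\[]", text) && file.exists(text)) {
    text <- paste(readLines(text, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
  }
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  for (key in c("entities", "pathways", "reactions")) {
    if (is.null(doc[[key]])) {
      stop("pathway JSON validation error: missing top-level key '", key, "'",
           call. = FALSE)
    }
  }
  ents <- lapply(doc$entities, function(e) {
    kind <- json_field(e, "kind", "entity")
    if (!kind %in% c("protein", "complex")) {
      stop("pathway JSON validation error: bad value for field 'kind' (",
           kind, ")", call. = FALSE)
    }
    entity(id = json_field(e, "id", "entity"),
           name = json_field(e, "name", "entity"),
           kind = kind,
           components = unlist(json_field(e, "components", "entity",
                                          required = FALSE,
                                          default = list())) %||% character(0))
  })
  pws <- lapply(doc$pathways, function(p) {
    parent <- p$parent
    pathway(id = json_field(p, "id", "pathway"),
            name = json_field(p, "name", "pathway"),
            parent_id = if (is.null(parent)) NA_character_ else parent,
            entity_ids = unlist(p$entities) %||% character(0),
            reaction_ids = unlist(p$reactions) %||% character(0),
            color_index = if (is.null(p$color)) NA_integer_ else as.integer(p$color))
  })
  rxs <- lapply(doc$reactions, function(r) {
    reaction(id = json_field(r, "id", "reaction"),
             inputs = unlist(json_field(r, "inputs", "reaction")),
             outputs = unlist(json_field(r, "outputs", "reaction")),
             pathway_ids = unlist(json_field(r, "pathways", "reaction")))
  })
  pathway_model(entities = ents, reactions = rxs, pathways = pws)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Structural equality of two pathway models
#'
#' Compares entities, reactions and pathways field by field, ignoring list
#' order (records are keyed by id) but respecting complex component order.
#'
#' @param a,b `pathway_model` objects.
#' @return `TRUE` or `FALSE`.
#' @export
models_equal <- function(a, b) {
  strip <- function(m) {
    list(
      entities = lapply(m$entities[order(names(m$entities))], function(e)
        list(e$id, e$name, e$kind, e$components)),
      reactions = lapply(m$reactions[order(names(m$reactions))], function(r)
        list(r$id, r$inputs, r$outputs, r$pathway_ids)),
      pathways = lapply(m$pathways[order(names(m$pathways))], function(p)
        list(p$id, p$name, p$parent_id, p$entity_ids, p$reaction_ids)))
  }
  identical(strip(a), strip(b))
}
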