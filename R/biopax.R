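# BioPAX Level-3 import (subset) and fixture export.
#
# Supported classes: Pathway, BiochemicalReaction, Protein, Complex.
# Other physical entities (SmallMolecule, Rna, Dna, PhysicalEntity) are
# imported as protein-kind nodes with their BioPAX class kept as metadata,
# so real exports remain loadable. Everything else is skipped and reported.

BP_NS <- "http://www.biopax.org/release/biopax-level3.owl#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

PHYSICAL_AS_PROTEIN <- c("SmallMolecule", "Rna", "Dna", "PhysicalEntity",
                         "RnaRegion", "DnaRegion")

# Fragment after '#' (or last '/') of an RDF id/about/resource value.
rdf_fragment <- function(x) {
  x <- sub("^.*#", "", x)
  sub("^.*/", "", x)
}

bp_node_id <- function(node) {
  id <- xml2::xml_attr(node, "ID")
  if (is.na(id)) id <- xml2::xml_attr(node, "about")
  if (is.na(id)) return(NA_character_)
  rdf_fragment(id)
}

bp_refs <- function(node, property, ns) {
  kids <- xml2::xml_find_all(node, paste0("./bp:", property), ns)
  res <- xml2::xml_attr(kids, "resource")
  vapply(res[!is.na(res)], rdf_fragment, "", USE.NAMES = FALSE)
}

bp_name <- function(node, id, ns) {
  for (prop in c("displayName", "name", "standardName")) {
    v <- xml2::xml_find_first(node, paste0("./bp:", prop), ns)
    if (!inherits(v, "xml_missing")) {
      txt <- xml2::xml_text(v)
      if (nzchar(txt)) return(txt)
    }
  }
  id
}

#' Read a BioPAX Level-3 document (subset)
#'
#' Maps `Pathway` (with `pathwayComponent` links to reactions and
#' sub-pathways), `BiochemicalReaction` (`left` = inputs, `right` =
#' outputs), `Protein` and `Complex` (with nested `component` links) into a
#' pathway model. Unknown classes are skipped, never fatal; problems are
#' collected in a parse report. Pathway entity sets are derived from the
#' participants of each pathway's own reactions.
#'
#' @param source File path or XML string.
#' @return A list with `model` (a `pathway_model`) and `report` (class
#'   `biopax_report`: per-class `counts`, `skipped` records with reasons,
#'   and `unresolved` reference ids).
#' @export
read_biopax <- function(source) {
  doc <- xml2::read_xml(source)
  ns <- c(bp = BP_NS, rdf = RDF_NS)
  all_bp <- xml2::xml_find_all(doc, "//bp:*", ns)
  classes <- xml2::xml_name(all_bp)
  skipped <- list()
  unresolved <- character(0)

  ent_nodes <- all_bp[classes %in% c("Protein", "Complex", PHYSICAL_AS_PROTEIN)]
  entities <- list()
  for (nd in ent_nodes) {
    id <- bp_node_id(nd)
    cls <- xml2::xml_name(nd)
    if (is.na(id)) {
      skipped[[length(skipped) + 1L]] <- list(class = cls,
                                              reason = "entity without rdf:ID/about")
      next
    }
    if (id %in% names(entities)) next  # same resource referenced twice
    kind <- if (cls == "Complex") "complex" else "protein"
    comps <- if (kind == "complex") bp_refs(nd, "component", ns) else character(0)
    meta <- if (!cls %in% c("Protein", "Complex")) list(biopax_class = cls) else list()
    entities[[id]] <- entity(id, name = bp_name(nd, id, ns), kind = kind,
                             components = comps, meta = meta)
  }

  rxn_nodes <- all_bp[classes == "BiochemicalReaction"]
  raw_rxns <- list()
  for (nd in rxn_nodes) {
    id <- bp_node_id(nd)
    if (is.na(id) || id %in% names(raw_rxns)) next
    raw_rxns[[id]] <- list(id = id,
                           inputs = bp_refs(nd, "left", ns),
                           outputs = bp_refs(nd, "right", ns))
  }

  pw_nodes <- all_bp[classes == "Pathway"]
  raw_pws <- list()
  for (nd in pw_nodes) {
    id <- bp_node_id(nd)
    if (is.na(id) || id %in% names(raw_pws)) next
    raw_pws[[id]] <- list(id = id, name = bp_name(nd, id, ns),
                          components = bp_refs(nd, "pathwayComponent", ns))
  }

  known <- c("Pathway", "BiochemicalReaction", "Protein", "Complex",
             PHYSICAL_AS_PROTEIN,
             "displayName", "name", "standardName", "component", "left",
             "right", "pathwayComponent", "organism", "comment", "xref")
  for (cls in setdiff(unique(classes), known)) {
    skipped[[length(skipped) + 1L]] <- list(class = cls,
                                            reason = "unsupported BioPAX class")
  }

  # Resolve references: drop dangling participants/components, recording them.
  for (id in names(entities)) {
    comps <- entities[[id]]$components
    bad <- setdiff(comps, names(entities))
    if (length(bad)) {
      unresolved <- c(unresolved, bad)
      entities[[id]]$components <- comps[comps %in% names(entities)]
    }
  }
  for (id in names(raw_rxns)) {
    r <- raw_rxns[[id]]
    bad <- setdiff(c(r$inputs, r$outputs), names(entities))
    if (length(bad)) unresolved <- c(unresolved, bad)
    raw_rxns[[id]]$inputs <- intersect(r$inputs, names(entities))
    raw_rxns[[id]]$outputs <- intersect(r$outputs, names(entities))
  }

  # Pathway ownership: which pathways reference each reaction / sub-pathway.
  owners <- list()
  parent_of <- list()
  for (pid in names(raw_pws)) {
    for (ref in raw_pws[[pid]]$components) {
      if (ref %in% names(raw_rxns)) {
        owners[[ref]] <- c(owners[[ref]], pid)
      } else if (ref %in% names(raw_pws)) {
        if (is.null(parent_of[[ref]])) parent_of[[ref]] <- pid
      } else {
        unresolved <- c(unresolved, ref)
      }
    }
  }

  reactions <- list()
  for (id in names(raw_rxns)) {
    r <- raw_rxns[[id]]
    own <- owners[[id]]
    if (length(r$inputs) == 0L || length(r$outputs) == 0L) {
      skipped[[length(skipped) + 1L]] <- list(
        class = "BiochemicalReaction",
        reason = paste0("reaction ", id, " lacks resolvable left/right participants"))
      next
    }
    if (is.null(own)) {
      skipped[[length(skipped) + 1L]] <- list(
        class = "BiochemicalReaction",
        reason = paste0("reaction ", id, " not referenced by any pathway"))
      next
    }
    reactions[[id]] <- reaction(id, r$inputs, r$outputs, own)
  }

  pathways <- list()
  for (pid in names(raw_pws)) {
    rids <- intersect(raw_pws[[pid]]$components, names(reactions))
    eids <- sort(unique(unlist(lapply(reactions[rids], function(r)
      c(r$inputs, r$outputs)))))
    pathways[[pid]] <- pathway(
      id = pid, name = raw_pws[[pid]]$name,
      parent_id = parent_of[[pid]] %||% NA_character_,
      entity_ids = eids %||% character(0), reaction_ids = rids)
  }

  model <- pathway_model(entities = unname(entities),
                         reactions = unname(reactions),
                         pathways = unname(pathways))
  report <- structure(
    list(counts = c(pathways = length(pathways),
                    proteins = sum(vapply(entities, function(e)
                      e$kind == "protein", logical(1))),
                    complexes = sum(vapply(entities, function(e)
                      e$kind == "complex", logical(1))),
                    reactions = length(reactions)),
         skipped = skipped,
         unresolved = sort(unique(unresolved))),
    class = "biopax_report")
  list(model = model, report = report)
}

#' @export
print.biopax_report <- function(x, ...) {
  cat("<biopax_report> parsed:",
      paste(names(x$counts), x$counts, collapse = ", "), "\n")
  if (length(x$skipped)) {
    cat("skipped:\n")
    for (s in x$skipped) cat("  -", s$class, ":", s$reason, "\n")
  }
  if (length(x$unresolved)) {
    cat("unresolved references:", paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a model as a BioPAX Level-3 fixture document
#'
#' Serializes the supported subset: entities become `Protein`/`Complex`
#' elements (with `component` links), reactions `BiochemicalReaction`
#' (`left`/`right`), pathways `Pathway` with `pathwayComponent` links to
#' their reactions and sub-pathways. Pathway entity membership is not a
#' BioPAX construct; on re-import it is recovered from reaction
#' participation (see [biopax_subset()]). Output is deterministic.
#'
#' @param model A `pathway_model` whose ids are XML-name safe.
#' @param path Optional output file path.
#' @return The OWL/XML document as a character scalar.
#' @export
write_fixture_biopax <- function(model, path = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"", RDF_NS, "\"",
           " xmlns:bp=\"", BP_NS, "\"",
           " xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
           " xml:base=\"http://pathlanes.invalid/fixture#\">"),
    "  <owl:Ontology rdf:about=\"\">",
    paste0("    <owl:imports rdf:resource=\"", sub("#$", "", BP_NS), "#\"/>"),
    "  </owl:Ontology>")
  for (eid in sort(names(model$entities))) {
    e <- model$entities[[eid]]
    cls <- if (e$kind == "complex") "Complex" else "Protein"
    lines <- c(lines, paste0("  <bp:", cls, " rdf:ID=\"", xml_escape(eid), "\">"),
               paste0("    <bp:displayName>", xml_escape(e$name),
                      "</bp:displayName>"))
    for (cid in e$components) {
      lines <- c(lines, paste0("    <bp:component rdf:resource=\"#",
                               xml_escape(cid), "\"/>"))
    }
    lines <- c(lines, paste0("  </bp:", cls, ">"))
  }
  for (rid in sort(names(model$reactions))) {
    r <- model$reactions[[rid]]
    lines <- c(lines, paste0("  <bp:BiochemicalReaction rdf:ID=\"",
                             xml_escape(rid), "\">"))
    for (i in r$inputs) {
      lines <- c(lines, paste0("    <bp:left rdf:resource=\"#",
                               xml_escape(i), "\"/>"))
    }
    for (o in r$outputs) {
      lines <- c(lines, paste0("    <bp:right rdf:resource=\"#",
                               xml_escape(o), "\"/>"))
    }
    lines <- c(lines, "  </bp:BiochemicalReaction>")
  }
  for (pid in sort(names(model$pathways))) {
    p <- model$pathways[[pid]]
    lines <- c(lines, paste0("  <bp:Pathway rdf:ID=\"", xml_escape(pid), "\">"),
               paste0("    <bp:displayName>", xml_escape(p$name),
                      "</bp:displayName>"))
    kids <- sort(p$reaction_ids)
    subs <- sort(names(model$pathways)[vapply(model$pathways, function(q)
      identical(q$parent_id, pid), logical(1))])
    for (ref in c(kids, subs)) {
      lines <- c(lines, paste0("    <bp:pathwayComponent rdf:resource=\"#",
                               xml_escape(ref), "\"/>"))
    }
    lines <- c(lines, "  </bp:Pathway>")
  }
  lines <- c(lines, "</rdf:RDF>")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Restrict a model to the BioPAX-expressible subset
#'
#' Recomputes every pathway's entity set from the participants of its own
#' reactions and drops entity metadata, yielding the part of the model that
#' a BioPAX write/read round trip preserves.
#'
#' @param model A `pathway_model`.
#' @return A `pathway_model`.
#' @export
biopax_subset <- function(model) {
  pws <- lapply(model$pathways, function(p) {
    eids <- sort(unique(unlist(lapply(model$reactions[p$reaction_ids],
                                      function(r) c(r$inputs, r$outputs)))))
    pathway(p$id, p$name, p$parent_id, eids %||% character(0),
            p$reaction_ids, p$color_index)
  })
  ents <- lapply(model$entities, function(e) {
    entity(e$id, e$name, e$kind, e$components)
  })
  pathway_model(entities = unname(ents),
                reactions = unname(model$reactions),
                pathways = unname(pws))
}
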