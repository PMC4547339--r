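# Interaction semantics as pure functions over (graph, view state).
# A view state fully determines what is drawn; interactions return either
# element sets or deltas to be applied with apply_delta(), never mutating
# their inputs, so sessions are scriptable and replayable.

edge_key <- function(e) paste(e$source, e$target, e$pathway_id, sep = "\r")

empty_edge_set <- function() {
  data.frame(source = character(0), target = character(0),
             pathway_id = character(0), stringsAsFactors = FALSE)
}

#' Create a view state
#'
#' @param visible_pathways Ids of pathways currently visible (the rest of
#'   the field of interest is hidden).
#' @param keywords Ordered character vector of active search keywords; an
#'   empty vector disables keyword filtering.
#' @param revealed_nodes Entity ids revealed so far.
#' @param revealed_edges Data frame (`source`, `target`, `pathway_id`) of
#'   revealed relationship edges; endpoints must be revealed nodes.
#' @param enlarged_complexes Ids of complexes shown with their inner
#'   structure.
#' @param hover_target Optional entity id under the pointer.
#' @return A list of class `view_state`.
#' @export
view_state <- function(visible_pathways = character(0),
                       keywords = character(0),
                       revealed_nodes = character(0),
                       revealed_edges = empty_edge_set(),
                       enlarged_complexes = character(0),
                       hover_target = NULL) {
  revealed_edges <- as.data.frame(revealed_edges, stringsAsFactors = FALSE)
  if (nrow(revealed_edges) > 0L) {
    miss <- setdiff(unique(c(revealed_edges$source, revealed_edges$target)),
                    revealed_nodes)
    if (length(miss)) {
      stop("view_state: revealed edge endpoints not revealed as nodes: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(visible_pathways = sort(unique(as.character(visible_pathways))),
         keywords = as.character(keywords),
         revealed_nodes = sort(unique(as.character(revealed_nodes))),
         revealed_edges = revealed_edges[!duplicated(edge_key(revealed_edges)), ,
                                         drop = FALSE],
         enlarged_complexes = sort(unique(as.character(enlarged_complexes))),
         hover_target = hover_target),
    class = "view_state")
}

#' Reveal everything in a graph
#'
#' Convenience: a view state with all pathways visible and every node and
#' edge revealed.
#'
#' @param graph A `pathway_graph`.
#' @param ... Passed on to [view_state()] (e.g. `keywords`).
#' @return A `view_state`.
#' @export
full_view <- function(graph, ...) {
  view_state(visible_pathways = names(graph$pathways),
             revealed_nodes = names(graph$entities),
             revealed_edges = graph$edges[, c("source", "target", "pathway_id")],
             ...)
}

# Pathway that a drawn element with membership `pid` takes under the
# aggregation rule: itself when visible, else its nearest visible ancestor.
effective_pathway <- function(graph, pid, visible) {
  if (pid %in% visible) return(pid)
  for (anc in pathway_ancestors(graph$pathways, pid)) {
    if (anc %in% visible) return(anc)
  }
  NA_character_
}

#' Keyword match for an entity
#'
#' Case-insensitive substring match: a protein matches when any keyword
#' occurs in its name; a complex matches when its own name matches or any
#' transitively contained protein matches. An empty keyword list matches
#' everything (no filtering).
#'
#' @param ent Entity object or id.
#' @param keywords Character vector of keywords.
#' @param model The containing model/graph.
#' @return Logical scalar.
#' @export
match_keywords <- function(ent, keywords, model) {
  if (length(keywords) == 0L) return(TRUE)
  ent <- resolve_entity(model, ent)
  name_hits <- function(nm) any(vapply(keywords, function(k)
    grepl(tolower(k), tolower(nm), fixed = TRUE), logical(1)))
  if (name_hits(ent$name)) return(TRUE)
  if (ent$kind == "complex") {
    for (cid in ent$components) {
      ch <- model$entities[[cid]]
      hit <- if (ch$kind == "protein") name_hits(ch$name)
             else match_keywords(ch, keywords, model)
      if (hit) return(TRUE)
    }
  }
  FALSE
}

#' Visible elements of a view
#'
#' A node is visible when it is revealed, belongs to at least one visible
#' pathway (membership aggregates up from sub-pathways), and passes the
#' keyword filter. An edge is visible when it is revealed, its pathway (or
#' an ancestor) is visible, and both endpoints are visible.
#'
#' @param graph A `pathway_graph`.
#' @param view A `view_state`.
#' @return List with `nodes` (sorted ids) and `edges` (data frame
#'   `source`, `target`, `pathway_id`).
#' @export
visible_elements <- function(graph, view) {
  vis <- view$visible_pathways
  nodes <- Filter(function(id) {
    length(intersect(memberships(graph, id), vis)) > 0L &&
      match_keywords(id, view$keywords, graph)
  }, intersect(view$revealed_nodes, names(graph$entities)))
  nodes <- sort(unlist(nodes) %||% character(0))
  e <- view$revealed_edges
  if (nrow(e) > 0L) {
    keep <- vapply(seq_len(nrow(e)), function(i) {
      !is.na(effective_pathway(graph, e$pathway_id[i], vis)) &&
        e$source[i] %in% nodes && e$target[i] %in% nodes
    }, logical(1))
    e <- e[keep, , drop = FALSE]
    rownames(e) <- NULL
  }
  list(nodes = nodes, edges = e)
}

assert_known_node <- function(graph, id) {
  if (!id %in% names(graph$entities)) {
    stop("unknown entity id: ", id, call. = FALSE)
  }
}

# Edges of the full graph whose pathway is visible under aggregation.
visible_pathway_edges <- function(graph, view) {
  e <- graph$edges
  if (nrow(e) == 0L) return(empty_edge_set())
  keep <- vapply(e$pathway_id, function(p)
    !is.na(effective_pathway(graph, p, view$visible_pathways)), logical(1))
  e[keep, c("source", "target", "pathway_id"), drop = FALSE]
}

delta <- function(nodes, edges, view) {
  edges <- edges[!edge_key(edges) %in% edge_key(view$revealed_edges), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(setdiff(unique(nodes), view$revealed_nodes)),
       edges = edges)
}

#' One downstream expansion step
#'
#' All reaction relationships in visible pathways that start from the given
#' node, together with their target nodes, returned as a delta of elements
#' not yet revealed.
#'
#' @param graph A `pathway_graph`.
#' @param node_id Entity id (must be known).
#' @param view A `view_state`.
#' @return List with `nodes` and `edges` to add; apply with
#'   [apply_delta()].
#' @export
downstream_step <- function(graph, node_id, view) {
  assert_known_node(graph, node_id)
  e <- visible_pathway_edges(graph, view)
  e <- e[e$source == node_id, , drop = FALSE]
  delta(e$target, e, view)
}

#' One upstream expansion step
#'
#' Mirror of [downstream_step()]: all visible-pathway relationships ending
#' at the node, plus their source nodes.
#'
#' @inheritParams downstream_step
#' @return List with `nodes` and `edges` to add.
#' @export
upstream_step <- function(graph, node_id, view) {
  assert_known_node(graph, node_id)
  e <- visible_pathway_edges(graph, view)
  e <- e[e$target == node_id, , drop = FALSE]
  delta(e$source, e, view)
}

#' Apply an expansion delta to a view state
#'
#' @param view A `view_state`.
#' @param d A delta from [downstream_step()], [upstream_step()] or
#'   [intermediate_subgraph()].
#' @return The updated `view_state`.
#' @export
apply_delta <- function(view, d) {
  view_state(visible_pathways = view$visible_pathways,
             keywords = view$keywords,
             revealed_nodes = c(view$revealed_nodes, d$nodes,
                                d$edges$source, d$edges$target),
             revealed_edges = rbind(view$revealed_edges,
                                    d$edges[, c("source", "target", "pathway_id")]),
             enlarged_complexes = view$enlarged_complexes,
             hover_target = view$hover_target)
}

#' Hidden-step markers
#'
#' For every visible node, reports whether it still has unrevealed
#' visible-pathway in-edges (hidden upstream step; drawn as an upward
#' triangle) or out-edges (hidden downstream step; downward triangle).
#'
#' @param graph A `pathway_graph`.
#' @param view A `view_state`.
#' @return Data frame with columns `node`, `has_hidden_upstream`,
#'   `has_hidden_downstream`.
#' @export
hidden_step_markers <- function(graph, view) {
  vis <- visible_elements(graph, view)
  all_e <- visible_pathway_edges(graph, view)
  unseen <- all_e[!edge_key(all_e) %in% edge_key(view$revealed_edges), ,
                  drop = FALSE]
  data.frame(
    node = vis$nodes,
    has_hidden_upstream = vis$nodes %in% unseen$target,
    has_hidden_downstream = vis$nodes %in% unseen$source,
    stringsAsFactors = FALSE)
}

reachable <- function(edges, start, forward = TRUE) {
  seen <- start
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- if (forward) edges$target[edges$source %in% frontier]
           else edges$source[edges$target %in% frontier]
    frontier <- setdiff(unique(nxt), seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' All intermediate steps between two nodes
#'
#' Computes the nodes lying on a directed route from `source_id` to
#' `target_id` through visible-pathway relationships — the nodes reachable
#' from the source from which the target is still reachable — plus every
#' visible edge between them. On acyclic graphs this is exactly the union
#' of all directed simple paths between the two nodes. Returned as a delta
#' of not-yet-revealed elements; no route yields an empty delta.
#'
#' @param graph A `pathway_graph`.
#' @param source_id,target_id Entity ids (must be known).
#' @param view A `view_state`.
#' @return List with `nodes` and `edges` to add.
#' @export
intermediate_subgraph <- function(graph, source_id, target_id, view) {
  assert_known_node(graph, source_id)
  assert_known_node(graph, target_id)
  e <- visible_pathway_edges(graph, view)
  fwd <- reachable(e, source_id, forward = TRUE)
  bwd <- reachable(e, target_id, forward = FALSE)
  nodes <- intersect(fwd, bwd)
  if (length(nodes) < 2L && source_id != target_id) {
    return(delta(character(0), empty_edge_set(), view))
  }
  keep <- e$source %in% nodes & e$target %in% nodes
  delta(nodes, e[keep, , drop = FALSE], view)
}

#' Hover highlighting context
#'
#' Highlights every visible element sharing at least one visible pathway
#' with the hovered element; all other visible elements are temporarily
#' desaturated. Labels are emitted only for the highlighted nodes.
#'
#' @param graph A `pathway_graph`.
#' @param element_id A visible entity id.
#' @param view A `view_state`.
#' @return List with `highlighted` (list of `nodes`, `edges`),
#'   `desaturated` (idem) and `labeled` (node ids).
#' @export
highlight_context <- function(graph, element_id, view) {
  assert_known_node(graph, element_id)
  vis <- visible_elements(graph, view)
  ctx_pw <- intersect(memberships(graph, element_id), view$visible_pathways)
  hi_nodes <- Filter(function(id)
    length(intersect(memberships(graph, id), ctx_pw)) > 0L, vis$nodes)
  hi_nodes <- sort(unlist(hi_nodes) %||% character(0))
  e <- vis$edges
  ehi <- if (nrow(e) > 0L) vapply(e$pathway_id, function(p)
    effective_pathway(graph, p, view$visible_pathways) %in% ctx_pw,
    logical(1)) else logical(0)
  list(
    highlighted = list(nodes = hi_nodes,
                       edges = e[ehi, , drop = FALSE]),
    desaturated = list(nodes = setdiff(vis$nodes, hi_nodes),
                       edges = e[!ehi, , drop = FALSE]),
    labeled = hi_nodes)
}

#' Serialize a view state to canonical JSON
#'
#' @param view A `view_state`.
#' @param path Optional output file path.
#' @return JSON text.
#' @export
write_view_json <- function(view, path = NULL) {
  e <- view$revealed_edges
  ord <- order(e$source, e$target, e$pathway_id)
  doc <- list(
    enlarged_complexes = as.list(view$enlarged_complexes),
    hover_target = view$hover_target %||% NA,
    keywords = as.list(view$keywords),
    revealed_edges = lapply(ord, function(i)
      list(pathway = e$pathway_id[i], source = e$source[i],
           target = e$target[i])),
    revealed_nodes = as.list(view$revealed_nodes),
    visible_pathways = as.list(view$visible_pathways))
  txt <- paste0(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                              na = "null", pretty = 2)), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Read a view state from JSON
#'
#' @param text JSON text or file path.
#' @return A `view_state`.
#' @export
read_view_json <- function(text) {
  if (length(text) == 1L && !grepl("[{\\[]", text) && file.exists(text)) {
    text <- paste(readLines(text, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
  }
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  edges <- if (length(doc$revealed_edges)) {
    data.frame(
      source = vapply(doc$revealed_edges, `[[`, "", "source"),
      target = vapply(doc$revealed_edges, `[[`, "", "target"),
      pathway_id = vapply(doc$revealed_edges, `[[`, "", "pathway"),
      stringsAsFactors = FALSE)
  } else empty_edge_set()
  hov <- doc$hover_target
  view_state(
    visible_pathways = unlist(doc$visible_pathways) %||% character(0),
    keywords = unlist(doc$keywords) %||% character(0),
    revealed_nodes = unlist(doc$revealed_nodes) %||% character(0),
    revealed_edges = edges,
    enlarged_complexes = unlist(doc$enlarged_complexes) %||% character(0),
    hover_target = if (is.null(hov) || (length(hov) == 1L && is.na(hov))) NULL else hov)
}
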