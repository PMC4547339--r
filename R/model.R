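# Domain model: entities (proteins / nested complexes), hypergraph reactions,
# pathways with optional sub-pathway nesting, and the merged relationship graph.

#' Create a biological entity
#'
#' An entity is either a protein or a protein complex. Complexes carry an
#' ordered vector of component entity ids; proteins have no components.
#'
#' @param id Unique opaque identifier (character scalar).
#' @param name Display name; defaults to `id`.
#' @param kind Either `"protein"` or `"complex"`.
#' @param components Character vector of component entity ids (complexes
#'   only; order is meaningful and preserved).
#' @param meta Optional named list of free-form metadata (e.g. the BioPAX
#'   class an imported node came from).
#' @return A list of class `pw_entity`.
#' @export
entity <- function(id, name = id, kind = c("protein", "complex"),
                   components = character(0), meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  components <- as.character(components)
  if (kind == "protein" && length(components) > 0L) {
    stop("entity '", id, "': proteins cannot have components", call. = FALSE)
  }
  structure(
    list(id = id, name = as.character(name)[1L], kind = kind,
         components = components, meta = meta),
    class = "pw_entity"
  )
}

#' Create a reaction
#'
#' A biochemical reaction is a hyperedge: non-empty sets of input and output
#' entity ids, owned by one or more pathways.
#'
#' @param id Unique identifier.
#' @param inputs,outputs Character vectors of entity ids; both non-empty.
#' @param pathway_ids Character vector of owning pathway ids; non-empty.
#' @return A list of class `pw_reaction`.
#' @export
reaction <- function(id, inputs, outputs, pathway_ids) {
  stopifnot(is.character(id), length(id) == 1L)
  inputs <- sort(unique(as.character(inputs)))
  outputs <- sort(unique(as.character(outputs)))
  pathway_ids <- sort(unique(as.character(pathway_ids)))
  if (length(inputs) == 0L || length(outputs) == 0L) {
    stop("invalid reaction '", id, "': inputs and outputs must be non-empty",
         call. = FALSE)
  }
  if (length(pathway_ids) == 0L) {
    stop("invalid reaction '", id, "': must belong to at least one pathway",
         call. = FALSE)
  }
  structure(
    list(id = id, inputs = inputs, outputs = outputs,
         pathway_ids = pathway_ids),
    class = "pw_reaction"
  )
}

#' Create a pathway
#'
#' @param id Unique identifier.
#' @param name Display name.
#' @param parent_id Optional id of the parent pathway (`NA` for top level).
#' @param entity_ids Character vector of member entity ids.
#' @param reaction_ids Character vector of owned reaction ids.
#' @param color_index Small integer used to order/assign set colors; assigned
#'   automatically by [pathway_model()] when `NA`.
#' @return A list of class `pw_pathway`.
#' @export
pathway <- function(id, name = id, parent_id = NA_character_,
                    entity_ids = character(0), reaction_ids = character(0),
                    color_index = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(
    list(id = id, name = as.character(name)[1L],
         parent_id = as.character(parent_id)[1L],
         entity_ids = sort(unique(as.character(entity_ids))),
         reaction_ids = sort(unique(as.character(reaction_ids))),
         color_index = as.integer(color_index)[1L]),
    class = "pw_pathway"
  )
}

#' Assemble a pathway model
#'
#' Collects entities, reactions and pathways into one validated container.
#' Missing `color_index` values are assigned deterministically: top-level
#' pathways first, then sub-pathways, each group in ascending id order.
#'
#' @param entities List of [entity()] objects.
#' @param reactions List of [reaction()] objects.
#' @param pathways List of [pathway()] objects.
#' @param validate Run [validate_model()] (default `TRUE`).
#' @return A list of class `pathway_model` with named-list fields
#'   `entities`, `reactions`, `pathways` keyed by id.
#' @export
pathway_model <- function(entities = list(), reactions = list(),
                          pathways = list(), validate = TRUE) {
  name_by_id <- function(xs) stats::setNames(xs, vapply(xs, `[[`, "", "id"))
  m <- structure(
    list(entities = name_by_id(entities),
         reactions = name_by_id(reactions),
         pathways = name_by_id(pathways)),
    class = "pathway_model"
  )
  m$pathways <- assign_color_indices(m$pathways)
  if (validate) validate_model(m)
  m
}

# Deterministic color assignment: keep explicit indices, fill the rest with
# the smallest unused positive integers, top-level pathways before subs.
assign_color_indices <- function(pathways) {
  if (length(pathways) == 0L) return(pathways)
  used <- vapply(pathways, function(p) p$color_index, integer(1))
  taken <- used[!is.na(used)]
  top <- vapply(pathways, function(p) is.na(p$parent_id), logical(1))
  order_ids <- c(sort(names(pathways)[top]), sort(names(pathways)[!top]))
  nxt <- 1L
  for (pid in order_ids) {
    if (is.na(pathways[[pid]]$color_index)) {
      while (nxt %in% taken) nxt <- nxt + 1L
      pathways[[pid]]$color_index <- nxt
      taken <- c(taken, nxt)
    }
  }
  pathways
}

#' Validate a pathway model
#'
#' Checks reference resolution (reaction participants, pathway members,
#' complex components, pathway parents), the protein/complex component rule,
#' acyclicity of complex containment, and acyclicity of the pathway parent
#' forest. Errors list every offending id.
#'
#' @param model A `pathway_model`.
#' @return `model`, invisibly, on success.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  ent_ids <- names(model$entities)
  pw_ids <- names(model$pathways)
  bad <- character(0)
  for (e in model$entities) {
    miss <- setdiff(e$components, ent_ids)
    if (length(miss)) bad <- c(bad, paste0("entity ", e$id, " -> ", miss))
  }
  for (r in model$reactions) {
    miss <- setdiff(c(r$inputs, r$outputs), ent_ids)
    if (length(miss)) bad <- c(bad, paste0("reaction ", r$id, " -> ", miss))
    misspw <- setdiff(r$pathway_ids, pw_ids)
    if (length(misspw)) bad <- c(bad, paste0("reaction ", r$id, " -> ", misspw))
  }
  for (p in model$pathways) {
    miss <- setdiff(p$entity_ids, ent_ids)
    if (length(miss)) bad <- c(bad, paste0("pathway ", p$id, " -> ", miss))
    missr <- setdiff(p$reaction_ids, names(model$reactions))
    if (length(missr)) bad <- c(bad, paste0("pathway ", p$id, " -> ", missr))
    if (!is.na(p$parent_id) && !p$parent_id %in% pw_ids) {
      bad <- c(bad, paste0("pathway ", p$id, " -> ", p$parent_id))
    }
  }
  if (length(bad)) {
    stop("unresolved references: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  cyc <- containment_cycle(model$entities)
  if (!is.null(cyc)) {
    stop("complex containment cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  pcyc <- parent_cycle(model$pathways)
  if (!is.null(pcyc)) {
    stop("pathway parent cycle: ", paste(pcyc, collapse = " -> "),
         call. = FALSE)
  }
  invisible(model)
}

# DFS three-color cycle detection over the component relation.
containment_cycle <- function(entities) {
  state <- stats::setNames(rep(0L, length(entities)), names(entities))
  path <- character(0)
  found <- NULL
  visit <- function(id) {
    if (!is.null(found)) return()
    if (state[[id]] == 1L) {
      found <<- c(path[which(path == id)[1L]:length(path)], id)
      return()
    }
    if (state[[id]] == 2L) return()
    state[[id]] <<- 1L
    path <<- c(path, id)
    for (c in entities[[id]]$components) visit(c)
    path <<- path[-length(path)]
    state[[id]] <<- 2L
  }
  for (id in names(entities)) visit(id)
  found
}

parent_cycle <- function(pathways) {
  for (pid in names(pathways)) {
    seen <- character(0)
    cur <- pid
    while (!is.na(cur)) {
      if (cur %in% seen) return(c(seen, cur))
      seen <- c(seen, cur)
      cur <- if (cur %in% names(pathways)) pathways[[cur]]$parent_id else NA_character_
    }
  }
  NULL
}

#' Convert a reaction to directed relationship edges
#'
#' A reaction relationship exists from A to B in pathway P when P has at
#' least one reaction with A among its inputs and B among its outputs.
#' Every input is paired with every output; self pairs (the same entity on
#' both sides) are dropped, since a self loop has no meaningful tip geometry.
#'
#' @param rxn A [reaction()] object.
#' @param pathway_id The owning pathway id the edges are attributed to.
#' @return A data frame with columns `source`, `target`, `pathway_id` and a
#'   list column `reactions` recording the originating reaction id.
#' @export
build_relationships <- function(rxn, pathway_id) {
  if (!inherits(rxn, "pw_reaction")) {
    stop("invalid reaction: not a pw_reaction object", call. = FALSE)
  }
  if (length(rxn$inputs) == 0L || length(rxn$outputs) == 0L) {
    stop("invalid reaction '", rxn$id, "': empty inputs or outputs",
         call. = FALSE)
  }
  grid <- expand.grid(source = rxn$inputs, target = rxn$outputs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  grid <- grid[order(grid$source, grid$target), , drop = FALSE]
  rownames(grid) <- NULL
  grid$pathway_id <- rep(as.character(pathway_id), nrow(grid))
  grid$reactions <- rep(list(rxn$id), nrow(grid))
  grid
}

empty_edges <- function() {
  data.frame(source = character(0), target = character(0),
             pathway_id = character(0), reactions = I(list()),
             stringsAsFactors = FALSE)
}

#' Build the merged multi-pathway relationship graph
#'
#' Merges all pathways into a single directed graph without duplicating
#' nodes: entities sharing an identifier map to one node. Edges are the
#' union of [build_relationships()] over every (reaction, owning pathway)
#' pair, deduplicated per (source, target, pathway) triple; the originating
#' reaction ids of a collapsed edge are retained in the `reactions` column.
#'
#' @param model A validated `pathway_model`.
#' @return A list of class `pathway_graph` with fields `entities`,
#'   `pathways` (named lists) and `edges` (data frame as in
#'   [build_relationships()], sorted by source, target, pathway).
#' @export
build_graph <- function(model) {
  validate_model(model)
  parts <- list(empty_edges())
  for (r in model$reactions) {
    for (pid in r$pathway_ids) {
      parts[[length(parts) + 1L]] <- build_relationships(r, pid)
    }
  }
  edges <- do.call(rbind, parts)
  if (nrow(edges) > 0L) {
    key <- paste(edges$source, edges$target, edges$pathway_id, sep = "\r")
    rx <- split(unlist(edges$reactions, use.names = FALSE), rep(key, lengths(edges$reactions)))
    edges <- edges[!duplicated(key), c("source", "target", "pathway_id")]
    kept <- paste(edges$source, edges$target, edges$pathway_id, sep = "\r")
    edges$reactions <- I(lapply(rx[kept], function(x) sort(unique(x))))
    edges <- edges[order(edges$source, edges$target, edges$pathway_id), ]
    rownames(edges) <- NULL
  }
  structure(
    list(entities = model$entities, pathways = model$pathways, edges = edges),
    class = "pathway_graph"
  )
}

# All ancestors of a pathway (walking parent links), excluding itself.
pathway_ancestors <- function(pathways, pid) {
  out <- character(0)
  cur <- pathways[[pid]]$parent_id
  while (!is.na(cur) && cur %in% names(pathways) && !(cur %in% out)) {
    out <- c(out, cur)
    cur <- pathways[[cur]]$parent_id
  }
  out
}

#' Pathway memberships of an entity
#'
#' Returns every pathway whose entity set contains the entity, directly or
#' through one of its sub-pathways: membership in a sub-pathway propagates
#' to all ancestor pathways, so collapsing a sub-pathway in a view
#' reassigns its elements to the visible ancestor.
#'
#' @param graph A `pathway_graph` (or `pathway_model`).
#' @param entity_id Entity identifier.
#' @return Sorted character vector of pathway ids.
#' @export
memberships <- function(graph, entity_id) {
  if (!entity_id %in% names(graph$entities)) {
    stop("unknown entity id: ", entity_id, call. = FALSE)
  }
  direct <- names(graph$pathways)[vapply(
    graph$pathways, function(p) entity_id %in% p$entity_ids, logical(1))]
  anc <- unlist(lapply(direct, function(p) pathway_ancestors(graph$pathways, p)))
  sort(unique(c(direct, anc)))
}

#' Group parallel edges into side-by-side lanes
#'
#' Edges are grouped by unordered node pair. Within a pair, each pathway
#' contributes one lane; a pathway with edges in both directions collapses
#' to a single lane with `direction = "both"` (drawn with a sharp tip at
#' both extremities). Lanes are ordered by pathway `color_index`, then
#' pathway id, so renders are stable.
#'
#' @param graph A `pathway_graph`.
#' @return A list of groups; each group has `a`, `b` (the pair in ascending
#'   id order) and `lanes`, a data frame with columns `pathway_id` and
#'   `direction` (`"forward"` = a to b, `"backward"` = b to a, `"both"`).
#' @export
edge_groups <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) return(list())
  a <- pmin(e$source, e$target)
  b <- pmax(e$source, e$target)
  fwd <- e$source == a
  pairkey <- paste(a, b, sep = "\r")
  groups <- list()
  for (k in unique(pairkey[order(a, b)])) {
    idx <- which(pairkey == k)
    lanes <- list()
    for (pid in unique(e$pathway_id[idx])) {
      pidx <- idx[e$pathway_id[idx] == pid]
      has_f <- any(fwd[pidx]); has_b <- any(!fwd[pidx])
      dir <- if (has_f && has_b) "both" else if (has_f) "forward" else "backward"
      lanes[[length(lanes) + 1L]] <- list(pathway_id = pid, direction = dir)
    }
    ord <- order(
      vapply(lanes, function(l) graph$pathways[[l$pathway_id]]$color_index, integer(1)),
      vapply(lanes, `[[`, "", "pathway_id"))
    lanes <- lanes[ord]
    groups[[length(groups) + 1L]] <- list(
      a = a[idx[1L]], b = b[idx[1L]],
      lanes = data.frame(
        pathway_id = vapply(lanes, `[[`, "", "pathway_id"),
        direction = vapply(lanes, `[[`, "", "direction"),
        stringsAsFactors = FALSE))
  }
  groups
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway_model> ", length(x$pathways), " pathways, ",
      length(x$entities), " entities, ", length(x$reactions),
      " reactions\n", sep = "")
  invisible(x)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", length(x$entities), " nodes, ", nrow(x$edges),
      " edges over ", length(x$pathways), " pathways\n", sep = "")
  invisible(x)
}
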