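# Hierarchical inspection of protein complexes: the rectangle-packed
# symbolic overview (squares = complexes, dots = proteins, no labels) and
# the pruned tree for a selected element (chain from the root to the
# selected element's parent, plus that parent's children, labelled).

resolve_entity <- function(model, x) {
  if (inherits(x, "pw_entity")) return(x)
  if (!x %in% names(model$entities)) {
    stop("unknown entity id: ", x, call. = FALSE)
  }
  model$entities[[x]]
}

# Geometry constants (abstract units): proteins are unit cells with a
# centred dot; complexes wrap their children in a padded shelf grid.
PACK_PAD <- 0.25
PACK_GAP <- 0.25
PACK_DOT_R <- 0.35

pack_size <- function(model, id) {
  e <- model$entities[[id]]
  if (e$kind == "protein" || length(e$components) == 0L) {
    return(c(w = 1, h = 1))
  }
  sizes <- lapply(e$components, function(c) pack_size(model, c))
  n <- length(sizes)
  ncol <- ceiling(sqrt(n))
  rows <- split(sizes, (seq_len(n) - 1L) %/% ncol)
  row_w <- vapply(rows, function(r)
    sum(vapply(r, `[[`, 0, "w")) + PACK_GAP * (length(r) - 1L), 0)
  row_h <- vapply(rows, function(r) max(vapply(r, `[[`, 0, "h")), 0)
  c(w = max(row_w) + 2 * PACK_PAD,
    h = sum(row_h) + PACK_GAP * (length(rows) - 1L) + 2 * PACK_PAD)
}

#' Pack a complex into a symbolic overview
#'
#' Computes rectangle-packed geometry for every transitive component of a
#' complex: complexes are rectangles, proteins are dots, nesting is strict
#' geometric containment. The layout is a deterministic per-level shelf
#' grid (components in model order, rows of ceiling(sqrt(n)) cells), chosen
#' for byte-stable output. No labels are produced; labels belong to the
#' pruned tree.
#'
#' @param root A complex entity (or its id).
#' @param model The containing `pathway_model` (or `pathway_graph`).
#' @return A list of class `packed_overview`: `width`, `height`, and
#'   `items`, a data frame with columns `entity_id`, `kind`, `depth`,
#'   `parent`, `x`, `y`, `w`, `h` (dots: `x`,`y` is the centre, `w` = `h` =
#'   dot diameter). The root rectangle is the first item, at depth 0.
#' @export
pack_overview <- function(root, model) {
  root <- resolve_entity(model, root)
  if (root$kind != "complex") {
    stop("pack_overview root must be a complex, got protein '", root$id, "'",
         call. = FALSE)
  }
  items <- list()
  place <- function(id, x, y, depth, parent) {
    e <- model$entities[[id]]
    sz <- pack_size(model, id)
    if (e$kind == "protein") {
      items[[length(items) + 1L]] <<- list(
        entity_id = id, kind = "protein", depth = depth, parent = parent,
        x = x + sz[["w"]] / 2, y = y + sz[["h"]] / 2,
        w = 2 * PACK_DOT_R, h = 2 * PACK_DOT_R)
      return(sz)
    }
    items[[length(items) + 1L]] <<- list(
      entity_id = id, kind = "complex", depth = depth, parent = parent,
      x = x, y = y, w = sz[["w"]], h = sz[["h"]])
    n <- length(e$components)
    if (n > 0L) {
      ncol <- ceiling(sqrt(n))
      cy <- y + PACK_PAD
      i <- 1L
      while (i <= n) {
        row <- e$components[i:min(n, i + ncol - 1L)]
        row_h <- max(vapply(row, function(c) pack_size(model, c)[["h"]], 0))
        cx <- x + PACK_PAD
        for (c in row) {
          csz <- place(c, cx, cy, depth + 1L, id)
          cx <- cx + csz[["w"]] + PACK_GAP
        }
        cy <- cy + row_h + PACK_GAP
        i <- i + ncol
      }
    }
    sz
  }
  sz <- place(root$id, 0, 0, 0L, NA_character_)
  items <- do.call(rbind, lapply(items, function(it)
    data.frame(it, stringsAsFactors = FALSE)))
  rownames(items) <- NULL
  structure(list(width = sz[["w"]], height = sz[["h"]], items = items),
            class = "packed_overview")
}

# All root-to-target containment paths, in lexicographic order of the id
# sequence; DFS over children sorted by id yields them smallest first.
containment_paths <- function(model, root_id, target_id, first_only = TRUE) {
  paths <- list()
  walk <- function(id, prefix) {
    if (first_only && length(paths) > 0L) return()
    prefix <- c(prefix, id)
    if (id == target_id && length(prefix) > 1L) {
      paths[[length(paths) + 1L]] <<- prefix
      return()
    }
    for (c in sort(model$entities[[id]]$components)) walk(c, prefix)
  }
  if (root_id == target_id) return(list(root_id))
  walk(root_id, character(0))
  paths
}

#' Pruned tree for a selected element of a complex
#'
#' Returns the direct chain from the complex root down to the parent of the
#' selected element, together with all of that parent's components; this is
#' the labelled detail view coordinated with the symbolic overview. When an
#' element is reachable through several containment paths, the
#' lexicographically first path is reported. Selecting the root itself
#' yields the degenerate view (empty chain, the root as sole child), so
#' hover sweeps over the overview are total.
#'
#' @param root Complex entity (or id).
#' @param selected_id Id of the selected transitive component.
#' @param model The containing model.
#' @return A list of class `pruned_tree`: `chain` (ids, root first),
#'   `children` (ids in model order), `selected`.
#' @export
prune_tree <- function(root, selected_id, model) {
  root <- resolve_entity(model, root)
  if (selected_id == root$id) {
    return(structure(list(chain = character(0), children = root$id,
                          selected = root$id), class = "pruned_tree"))
  }
  paths <- containment_paths(model, root$id, selected_id)
  if (length(paths) == 0L) {
    stop("element '", selected_id, "' is not contained in complex '",
         root$id, "'", call. = FALSE)
  }
  path <- paths[[1L]]
  parent <- path[length(path) - 1L]
  structure(
    list(chain = path[-length(path)],
         children = model$entities[[parent]]$components,
         selected = selected_id),
    class = "pruned_tree")
}

#' Locate a component in several enlarged complexes
#'
#' For each enlarged complex that transitively contains the component,
#' reports one witness containment path (the lexicographically first),
#' supporting cross-complex highlighting of shared sub-structures.
#'
#' @param enlarged_roots List/vector of complex entities or ids.
#' @param component_id Id of the component to locate.
#' @param model The containing model.
#' @return A list of records `list(root = id, path = ids)`; empty when the
#'   component occurs nowhere.
#' @export
occurrences <- function(enlarged_roots, component_id, model) {
  out <- list()
  for (r in enlarged_roots) {
    rid <- if (inherits(r, "pw_entity")) r$id else r
    paths <- containment_paths(model, rid, component_id)
    if (length(paths) > 0L && length(paths[[1L]]) > 1L) {
      out[[length(out) + 1L]] <- list(root = rid, path = paths[[1L]])
    }
  }
  out
}
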