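# Layered top-to-bottom layout. A Sugiyama-style skeleton guarantees the
# downward topological flow the visual design calls for; a seeded force
# relaxation then organizes nodes within their layers. Cycles are broken
# with the greedy Eades-Lin-Smyth linear-arrangement heuristic, so the few
# unavoidable upward (feedback) edges are identified deterministically.

#' Layout parameters
#'
#' @param layer_gap Vertical distance between layers (abstract units).
#' @param min_separation Minimum horizontal distance between nodes sharing
#'   a layer.
#' @param lane_spacing Lateral distance between side-by-side edge lanes.
#' @param barycenter_sweeps Number of down+up barycenter ordering sweeps.
#' @param force_iterations Iterations of within-layer force relaxation.
#' @param force_step Step size of the relaxation (0..1).
#' @param jitter Amplitude of the seeded tie-breaking jitter.
#' @return A list of class `layout_params`.
#' @export
layout_params <- function(layer_gap = 80, min_separation = 40,
                          lane_spacing = 6, barycenter_sweeps = 4,
                          force_iterations = 30, force_step = 0.3,
                          jitter = 0.01) {
  structure(list(layer_gap = layer_gap, min_separation = min_separation,
                 lane_spacing = lane_spacing,
                 barycenter_sweeps = as.integer(barycenter_sweeps),
                 force_iterations = as.integer(force_iterations),
                 force_step = force_step, jitter = jitter),
            class = "layout_params")
}

# Distinct directed node pairs of the relationship graph (pathway collapsed).
directed_pairs <- function(graph, nodes = NULL) {
  e <- graph$edges
  if (!is.null(nodes)) {
    e <- e[e$source %in% nodes & e$target %in% nodes, , drop = FALSE]
  }
  unique(e[, c("source", "target")])
}

# Greedy linear arrangement (Eades, Lin & Smyth): peel sinks to the back,
# sources to the front, otherwise the node maximizing outdeg - indeg; ties
# broken by ascending id. Edges pointing backward in the arrangement form
# the feedback set; the heuristic guarantees at most |E|/2 of them.
greedy_arrangement <- function(nodes, pairs) {
  s1 <- character(0)
  s2 <- character(0)
  active <- sort(nodes)
  pr <- pairs[pairs$source != pairs$target, , drop = FALSE]
  while (length(active) > 0L) {
    sub <- pr[pr$source %in% active & pr$target %in% active, , drop = FALSE]
    outd <- table(factor(sub$source, levels = active))
    ind <- table(factor(sub$target, levels = active))
    sinks <- active[outd == 0L]
    if (length(sinks) > 0L) {
      v <- sinks[1L]
      s2 <- c(v, s2)
    } else {
      sources <- active[ind == 0L]
      if (length(sources) > 0L) {
        v <- sources[1L]
      } else {
        delta <- as.integer(outd) - as.integer(ind)
        v <- active[which.max(delta)]
      }
      s1 <- c(s1, v)
    }
    active <- setdiff(active, v)
  }
  c(s1, s2)
}

#' Assign top-to-bottom layers
#'
#' On acyclic graphs every edge runs from a lower to a higher layer and the
#' feedback set is empty. On cyclic graphs a heuristically minimal feedback
#' edge set is reversed for layering purposes; those edges will be drawn
#' pointing upward. Layers come from longest-path layering on the acyclic
#' remainder, so the layout flows from sources at the top to sinks at the
#' bottom.
#'
#' @param graph A `pathway_graph`.
#' @param nodes Optional subset of node ids to lay out (default: all).
#' @return A list of class `layer_assignment`: `layers` (named integer
#'   vector, 0 = top) and `feedback_edges` (data frame `source`, `target`
#'   in original orientation).
#' @export
assign_layers <- function(graph, nodes = NULL) {
  all_nodes <- sort(if (is.null(nodes)) names(graph$entities) else nodes)
  pairs <- directed_pairs(graph, all_nodes)
  ord <- greedy_arrangement(all_nodes, pairs)
  pos <- stats::setNames(seq_along(ord), ord)
  back <- pairs[pos[pairs$source] > pos[pairs$target], , drop = FALSE]
  back <- back[order(back$source, back$target), , drop = FALSE]
  rownames(back) <- NULL
  # reverse feedback edges, then longest-path layering over the DAG
  dag <- pairs
  is_back <- pos[pairs$source] > pos[pairs$target]
  dag[is_back, c("source", "target")] <- pairs[is_back, c("target", "source")]
  dag <- unique(dag)
  layers <- stats::setNames(rep(0L, length(all_nodes)), all_nodes)
  for (v in ord) {
    preds <- dag$source[dag$target == v]
    if (length(preds) > 0L) layers[[v]] <- max(layers[preds]) + 1L
  }
  structure(list(layers = layers, feedback_edges = back),
            class = "layer_assignment")
}

# Positions from per-layer left-to-right orderings.
positions_from_orders <- function(orders, params) {
  pos <- list()
  for (l in seq_along(orders)) {
    ids <- orders[[l]]
    n <- length(ids)
    if (n == 0L) next
    x <- (seq_len(n) - (n + 1) / 2) * params$min_separation
    for (i in seq_len(n)) {
      pos[[ids[i]]] <- c(x = x[i], y = (l - 1) * params$layer_gap)
    }
  }
  df <- data.frame(node = names(pos),
                   x = vapply(pos, `[[`, 0, "x"),
                   y = vapply(pos, `[[`, 0, "y"),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(df$node), , drop = FALSE]
}

order_crossings <- function(orders, pairs, layers, params) {
  crossing_count(structure(list(positions = positions_from_orders(orders, params)),
                           class = "layout_result"),
                 pairs = pairs)
}

#' Refine horizontal positions within layers
#'
#' Vertical position is fixed by the layer. Horizontal order is refined by
#' barycenter sweeps (kept only when they do not increase the straight-line
#' crossing count), followed by a seeded within-layer force relaxation
#' pulling nodes toward the mean of their neighbours, and a final
#' overlap-removal pass enforcing the minimum separation.
#'
#' @param assignment A [assign_layers()] result.
#' @param graph The `pathway_graph`.
#' @param params [layout_params()].
#' @param seed Integer seed for the jitter in the force phase.
#' @return A list of class `layout_result`: `positions` (data frame `node`,
#'   `x`, `y`; y grows downward), `layers`, `feedback_edges`, `params`.
#' @export
refine_positions <- function(assignment, graph, params = layout_params(),
                             seed = 1L) {
  layers <- assignment$layers
  nodes <- names(layers)
  pairs <- directed_pairs(graph, nodes)
  n_layers <- if (length(layers)) max(layers) + 1L else 0L
  orders <- lapply(seq_len(n_layers) - 1L, function(l) sort(nodes[layers == l]))

  neigh <- function(v) unique(c(pairs$target[pairs$source == v],
                                pairs$source[pairs$target == v]))
  base_cross <- order_crossings(orders, pairs, layers, params)

  refined <- orders
  for (s in seq_len(params$barycenter_sweeps)) {
    for (dir in c("down", "up")) {
      rng <- if (dir == "down") seq_len(n_layers) else rev(seq_len(n_layers))
      for (l in rng) {
        ids <- refined[[l]]
        if (length(ids) < 2L) next
        xs <- positions_from_orders(refined, params)
        xv <- stats::setNames(xs$x, xs$node)
        key <- vapply(ids, function(v) {
          nb <- neigh(v)
          nb <- if (dir == "down") nb[layers[nb] < layers[v]] else nb[layers[nb] > layers[v]]
          if (length(nb) == 0L) xv[[v]] else mean(xv[nb])
        }, 0)
        refined[[l]] <- ids[order(key, ids)]
      }
    }
  }
  ref_cross <- order_crossings(refined, pairs, layers, params)
  if (ref_cross <= base_cross) orders <- refined

  df <- positions_from_orders(orders, params)
  xv <- stats::setNames(df$x, df$node)
  withr::with_seed(as.integer(seed), {
    for (it in seq_len(params$force_iterations)) {
      for (v in df$node) {
        nb <- neigh(v)
        if (length(nb) > 0L) {
          xv[[v]] <- xv[[v]] + params$force_step * (mean(xv[nb]) - xv[[v]]) +
            stats::runif(1, -params$jitter, params$jitter)
        }
      }
    }
  })
  # overlap removal: per layer, keep order by x (ties by id), enforce gaps
  for (l in seq_len(n_layers) - 1L) {
    ids <- nodes[layers == l]
    if (length(ids) < 2L) next
    ids <- ids[order(xv[ids], ids)]
    for (i in 2:length(ids)) {
      lo <- xv[[ids[i - 1L]]] + params$min_separation
      if (xv[[ids[i]]] < lo) xv[[ids[i]]] <- lo
    }
    xv[ids] <- xv[ids] - mean(xv[ids])
  }
  df$x <- round(unname(xv[df$node]), 4)
  df$y <- round(layers[df$node] * params$layer_gap, 4)
  structure(list(positions = df, layers = layers,
                 feedback_edges = assignment$feedback_edges, params = params),
            class = "layout_result")
}

seg_orient <- function(ax, ay, bx, by, cx, cy) {
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
}

segments_cross <- function(p, q) {
  d1 <- seg_orient(p[1], p[2], p[3], p[4], q[1], q[2])
  d2 <- seg_orient(p[1], p[2], p[3], p[4], q[3], q[4])
  d3 <- seg_orient(q[1], q[2], q[3], q[4], p[1], p[2])
  d4 <- seg_orient(q[1], q[2], q[3], q[4], p[3], p[4])
  d1 * d2 < 0 && d3 * d4 < 0
}

#' Count straight-line edge crossings
#'
#' Counts intersecting pairs among the centerline segments of the drawn
#' node pairs, excluding pairs that share an endpoint.
#'
#' @param result A `layout_result` (only `positions` is used).
#' @param graph The `pathway_graph`; alternatively pass `pairs` directly.
#' @param pairs Optional data frame of directed pairs (`source`, `target`).
#' @return Integer crossing count.
#' @export
crossing_count <- function(result, graph = NULL, pairs = NULL) {
  if (is.null(pairs)) pairs <- directed_pairs(graph)
  a <- pmin(pairs$source, pairs$target)
  b <- pmax(pairs$source, pairs$target)
  segs <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  segs <- segs[order(segs$a, segs$b), , drop = FALSE]
  pos <- result$positions
  px <- stats::setNames(pos$x, pos$node)
  py <- stats::setNames(pos$y, pos$node)
  m <- nrow(segs)
  if (m < 2L) return(0L)
  count <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      ends_i <- c(segs$a[i], segs$b[i])
      ends_j <- c(segs$a[j], segs$b[j])
      if (length(intersect(ends_i, ends_j)) > 0L) next
      p <- c(px[[segs$a[i]]], py[[segs$a[i]]], px[[segs$b[i]]], py[[segs$b[i]]])
      q <- c(px[[segs$a[j]]], py[[segs$a[j]]], px[[segs$b[j]]], py[[segs$b[j]]])
      if (segments_cross(p, q)) count <- count + 1L
    }
  }
  count
}

#' Side-by-side lane geometry for edge groups
#'
#' For each unordered node pair, its lanes are offset symmetrically about
#' the centerline, spaced `lane_spacing` apart, in the stable lane order of
#' [edge_groups()]. Tips sit at the target end of forward lanes, the source
#' end of backward lanes, and both ends of both-direction lanes.
#'
#' @param result A `layout_result`.
#' @param groups [edge_groups()] output.
#' @param params [layout_params()] (for `lane_spacing`).
#' @return Data frame with one row per lane: pair ids `a`, `b`,
#'   `pathway_id`, `direction`, `offset`, segment coordinates `x1`, `y1`,
#'   `x2`, `y2` (1 = a end), and logical `tip_at_a`, `tip_at_b`.
#' @export
edge_geometry <- function(result, groups, params = layout_params()) {
  pos <- result$positions
  px <- stats::setNames(pos$x, pos$node)
  py <- stats::setNames(pos$y, pos$node)
  rows <- list()
  for (g in groups) {
    ax <- px[[g$a]]; ay <- py[[g$a]]
    bx <- px[[g$b]]; by <- py[[g$b]]
    dx <- bx - ax; dy <- by - ay
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) { ux <- 0; uy <- 0 } else { ux <- -dy / len; uy <- dx / len }
    k <- nrow(g$lanes)
    for (i in seq_len(k)) {
      off <- (i - (k + 1) / 2) * params$lane_spacing
      dir <- g$lanes$direction[i]
      rows[[length(rows) + 1L]] <- data.frame(
        a = g$a, b = g$b, pathway_id = g$lanes$pathway_id[i],
        direction = dir, offset = off,
        x1 = round(ax + ux * off, 4), y1 = round(ay + uy * off, 4),
        x2 = round(bx + ux * off, 4), y2 = round(by + uy * off, 4),
        tip_at_a = dir %in% c("backward", "both"),
        tip_at_b = dir %in% c("forward", "both"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      pathway_id = character(0), direction = character(0),
                      offset = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0),
                      tip_at_a = logical(0), tip_at_b = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compute a complete layout for a graph
#'
#' Convenience pipeline: [assign_layers()], [refine_positions()], and
#' [edge_geometry()] over [edge_groups()].
#'
#' @inheritParams refine_positions
#' @param nodes Optional node subset.
#' @return A `layout_result` with an additional `lanes` data frame.
#' @export
compute_layout <- function(graph, params = layout_params(), seed = 1L,
                           nodes = NULL) {
  la <- assign_layers(graph, nodes)
  res <- refine_positions(la, graph, params, seed)
  groups <- edge_groups(graph)
  if (!is.null(nodes)) {
    groups <- Filter(function(g) g$a %in% nodes && g$b %in% nodes, groups)
  }
  res$lanes <- edge_geometry(res, groups, params)
  res
}

#' Serialize a layout result to JSON
#'
#' @param result A `layout_result`.
#' @return Canonical JSON text (positions, layers, feedback edges, lanes).
#' @export
layout_to_json <- function(result) {
  doc <- list(
    feedback_edges = unname(apply(result$feedback_edges, 1L, function(r)
      list(source = r[["source"]], target = r[["target"]]), simplify = FALSE)),
    layers = as.list(result$layers[order(names(result$layers))]),
    lanes = if (is.null(result$lanes)) list() else
      lapply(seq_len(nrow(result$lanes)), function(i) as.list(result$lanes[i, ])),
    positions = lapply(seq_len(nrow(result$positions)), function(i)
      as.list(result$positions[i, ])))
  paste0(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                       pretty = 2)), "\n")
}
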