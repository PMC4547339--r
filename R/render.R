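# Static SVG renderer for any view state: circles for proteins, squares
# for complexes, one concentric colored border ring per visible pathway
# membership, side-by-side sharp-tipped lanes per pathway, hover
# desaturation and dynamic labels, hidden-step triangles, enlarged
# complexes drawn as packed overviews with neighbours pushed away, and a
# legend graying out hidden pathway names.

#' Rendering style configuration
#'
#' @param palette Ordered pathway colors; recycled (with a warning) when
#'   more pathways are visible than colors available.
#' @param desaturated Color applied to non-highlighted elements during
#'   hover.
#' @param node_radius Protein circle radius; complexes use a square of the
#'   same half-side.
#' @param ring_width Width of each membership border ring.
#' @param tip_length,tip_width Size of the sharp lane tips.
#' @param hierarchy_fill Two intensities of one hue for nested complexes in
#'   the symbolic overview (outer, inner).
#' @param selected_gray Fill of the selected element in hierarchy views.
#' @param marker_size Side of the hidden-step triangles.
#' @param label_font_size Label font size (px).
#' @param always_label Label every visible node instead of only the hover
#'   context.
#' @return A list of class `style_config`.
#' @export
style_config <- function(palette = c("#1b9e77", "#d95f02", "#7570b3",
                                     "#e7298a", "#66a61e", "#e6ab02",
                                     "#a6761d", "#666666"),
                         desaturated = "#cccccc",
                         node_radius = 10, ring_width = 3,
                         tip_length = 8, tip_width = 5,
                         hierarchy_fill = c("#9ecae1", "#deebf7"),
                         selected_gray = "#888888",
                         marker_size = 6, label_font_size = 10,
                         always_label = FALSE) {
  structure(list(palette = palette, desaturated = desaturated,
                 node_radius = node_radius, ring_width = ring_width,
                 tip_length = tip_length, tip_width = tip_width,
                 hierarchy_fill = hierarchy_fill,
                 selected_gray = selected_gray, marker_size = marker_size,
                 label_font_size = label_font_size,
                 always_label = isTRUE(always_label)),
            class = "style_config")
}

fmt <- function(x) sprintf("%.2f", x)

pathway_color <- function(graph, pid, style) {
  ci <- graph$pathways[[pid]]$color_index
  if (ci > length(style$palette)) {
    warning("palette exhausted: recycling colors for pathway '", pid, "'",
            call. = FALSE)
  }
  style$palette[(ci - 1L) %% length(style$palette) + 1L]
}

svg_text <- function(x, y, label, size, extra = "") {
  paste0("<text class=\"label\" x=\"", fmt(x), "\" y=\"", fmt(y),
         "\" font-size=\"", size, "\"", extra, ">", xml_escape(label),
         "</text>")
}

tip_polygon <- function(x, y, dx, dy, style, color, lane_id) {
  # triangle pointing along (dx, dy), apex at (x, y)
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) { dx <- 0; dy <- 1; len <- 1 }
  ux <- dx / len; uy <- dy / len
  px <- -uy; py <- ux
  bx <- x - ux * style$tip_length
  by <- y - uy * style$tip_length
  paste0("<polygon class=\"tip\" data-lane=\"", lane_id, "\" points=\"",
         fmt(x), ",", fmt(y), " ",
         fmt(bx + px * style$tip_width / 2), ",", fmt(by + py * style$tip_width / 2), " ",
         fmt(bx - px * style$tip_width / 2), ",", fmt(by - py * style$tip_width / 2),
         "\" fill=\"", color, "\"/>")
}

# Push other nodes radially out of an enlarged complex's bounding box.
displace_for_enlarged <- function(pos, center_id, half_extent, min_sep) {
  cx <- pos$x[pos$node == center_id]
  cy <- pos$y[pos$node == center_id]
  clearance <- half_extent + min_sep
  for (i in seq_len(nrow(pos))) {
    if (pos$node[i] == center_id) next
    dx <- pos$x[i] - cx; dy <- pos$y[i] - cy
    d <- sqrt(dx^2 + dy^2)
    if (d >= clearance) next
    if (d == 0) { dx <- 1; dy <- 0; d <- 1 }
    pos$x[i] <- cx + dx / d * clearance
    pos$y[i] <- cy + dy / d * clearance
  }
  pos
}

#' Render a view state to SVG
#'
#' Implements the full visual encoding: protein circles / complex squares,
#' one concentric border ring per visible pathway membership (innermost =
#' lowest color index), side-by-side pathway-colored lanes with sharp tips
#' (both ends for two-way lanes), hover highlighting with desaturation and
#' context labels, hidden-step triangles, packed overviews for enlarged
#' complexes (neighbouring nodes pushed away), and a pathway legend with
#' hidden names in gray. Output is deterministic.
#'
#' @param graph A `pathway_graph`.
#' @param layout A `layout_result` covering all visible nodes.
#' @param view A `view_state`.
#' @param style A [style_config()].
#' @param model Optional `pathway_model` for complex structure (defaults
#'   to the graph, which carries the same entities).
#' @return SVG document as a character scalar.
#' @export
render_svg <- function(graph, layout, view, style = style_config(),
                       model = graph) {
  vis <- visible_elements(graph, view)
  missing_pos <- setdiff(vis$nodes, layout$positions$node)
  if (length(missing_pos)) {
    stop("layout does not cover visible nodes: ",
         paste(missing_pos, collapse = ", "), call. = FALSE)
  }
  params <- layout$params %||% layout_params()
  pos <- layout$positions[layout$positions$node %in% vis$nodes, , drop = FALSE]

  enlarged <- intersect(view$enlarged_complexes, vis$nodes)
  for (cid in enlarged) {
    if (graph$entities[[cid]]$kind != "complex") {
      stop("enlarged element '", cid, "' is not a complex", call. = FALSE)
    }
  }
  overviews <- lapply(enlarged, function(cid) pack_overview(cid, model))
  names(overviews) <- enlarged
  ov_scale <- style$node_radius  # abstract pack unit -> px
  for (cid in enlarged) {
    half <- max(overviews[[cid]]$width, overviews[[cid]]$height) * ov_scale / 2
    pos <- displace_for_enlarged(pos, cid, half, params$min_separation)
  }

  # hover context
  hover <- view$hover_target
  if (!is.null(hover) && !hover %in% vis$nodes) hover <- NULL
  ctx <- if (!is.null(hover)) highlight_context(graph, hover, view) else NULL

  # lanes from the visible edges, pathway collapsed to its visible ancestor
  e <- vis$edges
  if (nrow(e) > 0L) {
    e$pathway_id <- vapply(e$pathway_id, function(p)
      effective_pathway(graph, p, view$visible_pathways), "")
    e <- e[!duplicated(edge_key(e)), , drop = FALSE]
  }
  tmp_graph <- structure(list(entities = graph$entities,
                              pathways = graph$pathways, edges = e),
                         class = "pathway_graph")
  groups <- edge_groups(tmp_graph)
  lanes <- edge_geometry(structure(list(positions = pos),
                                   class = "layout_result"),
                         groups, params)

  markers <- hidden_step_markers(graph, view)
  px <- stats::setNames(pos$x, pos$node)
  py <- stats::setNames(pos$y, pos$node)

  margin <- 60
  legend_w <- 160
  xr <- range(c(pos$x, 0))
  yr <- range(c(pos$y, 0))
  ox <- legend_w + margin - xr[1]
  oy <- margin - yr[1]
  width <- legend_w + 2 * margin + (xr[2] - xr[1])
  height <- 2 * margin + max(yr[2] - yr[1],
                             20 * length(graph$pathways) + 20)

  out <- c(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\"",
                  " width=\"", fmt(width), "\" height=\"", fmt(height),
                  "\" viewBox=\"0 0 ", fmt(width), " ", fmt(height), "\">"))

  # legend: every pathway in the field of interest, hidden ones in gray
  out <- c(out, "<g class=\"legend\">")
  ord <- order(vapply(graph$pathways, `[[`, 0L, "color_index"),
               names(graph$pathways))
  ly <- 20
  for (p in graph$pathways[ord]) {
    visible <- p$id %in% view$visible_pathways
    col <- if (visible) pathway_color(graph, p$id, style) else "#999999"
    out <- c(out, paste0("<text class=\"legend-entry\" data-pathway=\"",
                         xml_escape(p$id), "\" x=\"10\" y=\"", fmt(ly),
                         "\" fill=\"", col, "\" font-size=\"",
                         style$label_font_size, "\">",
                         xml_escape(p$name), "</text>"))
    ly <- ly + 20
  }
  out <- c(out, "</g>")

  # lanes carry effective (visible) pathway ids; a lane is highlighted iff
  # its pathway is one of the hovered element's visible pathways
  ctx_pw <- if (!is.null(hover)) {
    intersect(memberships(graph, hover), view$visible_pathways)
  } else character(0)
  desat_edge <- function(i) {
    !is.null(ctx) && !(lanes$pathway_id[i] %in% ctx_pw)
  }

  out <- c(out, "<g class=\"edges\">")
  if (nrow(lanes) > 0L) {
    for (i in seq_len(nrow(lanes))) {
      col <- pathway_color(graph, lanes$pathway_id[i], style)
      if (!is.null(ctx) && desat_edge(i)) col <- style$desaturated
      lane_id <- paste(lanes$a[i], lanes$b[i], lanes$pathway_id[i], sep = "|")
      x1 <- ox + lanes$x1[i]; y1 <- oy + lanes$y1[i]
      x2 <- ox + lanes$x2[i]; y2 <- oy + lanes$y2[i]
      out <- c(out, paste0("<path class=\"lane\" data-lane=\"",
                           xml_escape(lane_id), "\" d=\"M ", fmt(x1), " ",
                           fmt(y1), " L ", fmt(x2), " ", fmt(y2),
                           "\" stroke=\"", col, "\" stroke-width=\"2\"",
                           " fill=\"none\"/>"))
      if (lanes$tip_at_b[i]) {
        out <- c(out, tip_polygon(x2, y2, x2 - x1, y2 - y1, style, col,
                                  xml_escape(lane_id)))
      }
      if (lanes$tip_at_a[i]) {
        out <- c(out, tip_polygon(x1, y1, x1 - x2, y1 - y2, style, col,
                                  xml_escape(lane_id)))
      }
    }
  }
  out <- c(out, "</g>")

  out <- c(out, "<g class=\"nodes\">")
  labeled <- if (style$always_label) vis$nodes
             else if (!is.null(ctx)) ctx$labeled else character(0)
  for (id in vis$nodes) {
    x <- ox + px[[id]]; y <- oy + py[[id]]
    ent <- graph$entities[[id]]
    mem <- intersect(memberships(graph, id), view$visible_pathways)
    mem <- mem[order(vapply(mem, function(p)
      graph$pathways[[p]]$color_index, integer(1)), mem)]
    desat <- !is.null(ctx) && !(id %in% ctx$highlighted$nodes)
    r <- style$node_radius
    if (id %in% enlarged) {
      ov <- overviews[[id]]
      sc <- ov_scale
      x0 <- x - ov$width * sc / 2
      y0 <- y - ov$height * sc / 2
      out <- c(out, paste0("<g class=\"enlarged\" data-node=\"",
                           xml_escape(id), "\">"))
      for (j in seq_len(nrow(ov$items))) {
        it <- ov$items[j, ]
        if (it$kind == "complex") {
          fill <- style$hierarchy_fill[(it$depth %% 2L) + 1L]
          out <- c(out, paste0("<rect class=\"overview-complex\" data-node=\"",
                               xml_escape(id), "\" data-entity=\"",
                               xml_escape(it$entity_id), "\" x=\"",
                               fmt(x0 + it$x * sc), "\" y=\"",
                               fmt(y0 + it$y * sc), "\" width=\"",
                               fmt(it$w * sc), "\" height=\"", fmt(it$h * sc),
                               "\" fill=\"", fill,
                               "\" stroke=\"#555555\"/>"))
        } else {
          out <- c(out, paste0("<circle class=\"overview-protein\" data-node=\"",
                               xml_escape(id), "\" data-entity=\"",
                               xml_escape(it$entity_id), "\" cx=\"",
                               fmt(x0 + it$x * sc), "\" cy=\"",
                               fmt(y0 + it$y * sc), "\" r=\"",
                               fmt(it$w * sc / 2),
                               "\" fill=\"#ffffff\" stroke=\"#555555\"/>"))
        }
      }
      out <- c(out, "</g>")
    } else {
      fill <- if (desat) style$desaturated else "#ffffff"
      if (ent$kind == "protein") {
        out <- c(out, paste0("<circle class=\"node-glyph\" data-node=\"",
                             xml_escape(id), "\" cx=\"", fmt(x), "\" cy=\"",
                             fmt(y), "\" r=\"", fmt(r), "\" fill=\"", fill,
                             "\" stroke=\"#333333\"/>"))
      } else {
        out <- c(out, paste0("<rect class=\"node-glyph\" data-node=\"",
                             xml_escape(id), "\" x=\"", fmt(x - r),
                             "\" y=\"", fmt(y - r), "\" width=\"", fmt(2 * r),
                             "\" height=\"", fmt(2 * r), "\" fill=\"", fill,
                             "\" stroke=\"#333333\"/>"))
      }
    }
    # membership border rings, innermost = lowest color index
    for (k in seq_along(mem)) {
      col <- if (desat) style$desaturated
             else pathway_color(graph, mem[k], style)
      rr <- r + (k - 0.5) * style$ring_width
      if (ent$kind == "protein" || id %in% enlarged) {
        out <- c(out, paste0("<circle class=\"ring\" data-node=\"",
                             xml_escape(id), "\" data-pathway=\"",
                             xml_escape(mem[k]), "\" cx=\"", fmt(x),
                             "\" cy=\"", fmt(y), "\" r=\"", fmt(rr),
                             "\" fill=\"none\" stroke=\"", col,
                             "\" stroke-width=\"", style$ring_width, "\"/>"))
      } else {
        out <- c(out, paste0("<rect class=\"ring\" data-node=\"",
                             xml_escape(id), "\" data-pathway=\"",
                             xml_escape(mem[k]), "\" x=\"", fmt(x - rr),
                             "\" y=\"", fmt(y - rr), "\" width=\"",
                             fmt(2 * rr), "\" height=\"", fmt(2 * rr),
                             "\" fill=\"none\" stroke=\"", col,
                             "\" stroke-width=\"", style$ring_width, "\"/>"))
      }
    }
    # hidden-step triangles
    mk <- markers[markers$node == id, , drop = FALSE]
    ring_r <- r + length(mem) * style$ring_width
    ms <- style$marker_size
    if (nrow(mk) == 1L && mk$has_hidden_upstream) {
      ty <- y - ring_r - 2
      out <- c(out, paste0("<polygon class=\"marker-up\" data-node=\"",
                           xml_escape(id), "\" points=\"",
                           fmt(x), ",", fmt(ty - ms), " ",
                           fmt(x - ms / 2), ",", fmt(ty), " ",
                           fmt(x + ms / 2), ",", fmt(ty),
                           "\" fill=\"#333333\"/>"))
    }
    if (nrow(mk) == 1L && mk$has_hidden_downstream) {
      ty <- y + ring_r + 2
      out <- c(out, paste0("<polygon class=\"marker-down\" data-node=\"",
                           xml_escape(id), "\" points=\"",
                           fmt(x), ",", fmt(ty + ms), " ",
                           fmt(x - ms / 2), ",", fmt(ty), " ",
                           fmt(x + ms / 2), ",", fmt(ty),
                           "\" fill=\"#333333\"/>"))
    }
    if (id %in% labeled) {
      out <- c(out, svg_text(x + ring_r + 4, y + 3, ent$name,
                             style$label_font_size))
    }
  }
  out <- c(out, "</g>", "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Render a pruned tree to an SVG fragment
#'
#' The chain from the root to the selected element's parent is drawn left
#' to right, the parent's components as a column on the right; every glyph
#' carries its label (labels live here, not in the symbolic overview). The
#' selected element is emphasized and underlined.
#'
#' @param ptv A [prune_tree()] result.
#' @param model The containing model (for names and kinds).
#' @param style A [style_config()].
#' @return SVG document as a character scalar.
#' @export
render_pruned_tree_svg <- function(ptv, model, style = style_config()) {
  step_x <- 90
  step_y <- 34
  r <- style$node_radius
  x0 <- 30
  y0 <- 40
  n_chain <- length(ptv$chain)
  width <- x0 + step_x * (n_chain + 1L) + 120
  height <- y0 + step_y * max(length(ptv$children), 1L) + 40
  out <- paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\"",
                " width=\"", fmt(width), "\" height=\"", fmt(height),
                "\" viewBox=\"0 0 ", fmt(width), " ", fmt(height), "\">")
  glyph <- function(id, x, y, cls, selected) {
    ent <- model$entities[[id]]
    fill <- if (selected) style$selected_gray
            else if (ent$kind == "complex") style$hierarchy_fill[1L]
            else "#ffffff"
    g <- if (ent$kind == "protein") {
      paste0("<circle class=\"", cls, "\" data-entity=\"", xml_escape(id),
             "\" cx=\"", fmt(x), "\" cy=\"", fmt(y), "\" r=\"", fmt(r),
             "\" fill=\"", fill, "\" stroke=\"#333333\"/>")
    } else {
      paste0("<rect class=\"", cls, "\" data-entity=\"", xml_escape(id),
             "\" x=\"", fmt(x - r), "\" y=\"", fmt(y - r), "\" width=\"",
             fmt(2 * r), "\" height=\"", fmt(2 * r), "\" fill=\"", fill,
             "\" stroke=\"#333333\"/>")
    }
    weight <- if (selected) " font-weight=\"bold\"" else ""
    lab <- svg_text(x + r + 4, y + 3, ent$name, style$label_font_size, weight)
    under <- if (selected) {
      w <- nchar(ent$name) * style$label_font_size * 0.6
      paste0("<line class=\"underline\" x1=\"", fmt(x + r + 4), "\" y1=\"",
             fmt(y + 6), "\" x2=\"", fmt(x + r + 4 + w), "\" y2=\"",
             fmt(y + 6), "\" stroke=\"#333333\"/>")
    } else NULL
    c(g, lab, under)
  }
  cx <- x0
  for (id in ptv$chain) {
    out <- c(out, glyph(id, cx, y0, "chain-glyph", FALSE))
    out <- c(out, paste0("<line class=\"chain-link\" x1=\"", fmt(cx + r),
                         "\" y1=\"", fmt(y0), "\" x2=\"", fmt(cx + step_x - r),
                         "\" y2=\"", fmt(y0), "\" stroke=\"#999999\"/>"))
    cx <- cx + step_x
  }
  cy <- y0
  for (id in ptv$children) {
    out <- c(out, glyph(id, cx, cy, "child-glyph", id == ptv$selected))
    cy <- cy + step_y
  }
  out <- c(out, "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}
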