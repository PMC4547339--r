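two_pathway_graph <- function() {
  # P1: A -> B -> C ; P2: D -> E ; X shared member of both (no edges)
  ents <- lapply(c("A", "B", "C", "D", "E", "X"), entity)
  rx <- list(reaction("r1", "A", "B", "P1"), reaction("r2", "B", "C", "P1"),
             reaction("r3", "D", "E", "P2"))
  pw <- list(pathway("P1", entity_ids = c("A", "B", "C", "X"),
                     reaction_ids = c("r1", "r2")),
             pathway("P2", entity_ids = c("D", "E", "X"),
                     reaction_ids = "r3"))
  build_graph(pathway_model(ents, rx, pw))
}

test_that("keyword matching is case-insensitive substring with containment", {
  m <- pathway_model(entities = list(
    entity("o1", name = "ORC1"),
    entity("c1", name = "big-complex", kind = "complex", components = "o2"),
    entity("o2", name = "CDC6"),
    entity("z", name = "GMNN")))
  expect_true(match_keywords("o1", "ORC", m))
  expect_true(match_keywords("o1", c("nohit", "orc1"), m))
  expect_false(match_keywords("z", "ORC", m))
  expect_true(match_keywords("c1", "cdc6", m))    # via contained protein
  expect_true(match_keywords("c1", "big", m))     # via own name
  expect_true(match_keywords("z", character(0), m))  # empty = no filter
})

test_that("visibility combines revealed set, pathway membership and keywords", {
  g <- two_pathway_graph()
  v <- full_view(g)
  expect_setequal(visible_elements(g, v)$nodes, names(g$entities))

  # all pathways hidden -> nothing
  v0 <- view_state(revealed_nodes = names(g$entities),
                   revealed_edges = g$edges[, 1:3])
  expect_error(view_state(revealed_edges = g$edges[, 1:3]), "revealed")
  expect_length(visible_elements(g, v0)$nodes, 0L)

  # hide P2: only elements with a remaining visible membership survive
  v1 <- view_state(visible_pathways = "P1",
                   revealed_nodes = names(g$entities),
                   revealed_edges = g$edges[, 1:3])
  vis1 <- visible_elements(g, v1)
  expect_setequal(vis1$nodes, c("A", "B", "C", "X"))  # X: at-least-one rule
  expect_true(all(vis1$edges$pathway_id == "P1"))

  # keyword filter applies to nodes, and hides incident edges
  v2 <- view_state(visible_pathways = c("P1", "P2"),
                   keywords = "A",
                   revealed_nodes = names(g$entities),
                   revealed_edges = g$edges[, 1:3])
  expect_setequal(visible_elements(g, v2)$nodes, "A")
  expect_equal(nrow(visible_elements(g, v2)$edges), 0L)
})

edge_key_str <- function(e) paste(e$source, e$target, e$pathway_id)

test_that("visibility is monotone non-increasing as pathways hide", {
  m <- generate_fixture(fixture_config(seed = 12, n_pathways = 4))
  g <- build_graph(m)
  pws <- names(g$pathways)
  prev <- NULL
  for (k in rev(seq_along(pws))) {
    v <- view_state(visible_pathways = pws[seq_len(k)],
                    revealed_nodes = names(g$entities),
                    revealed_edges = g$edges[, 1:3])
    cur <- visible_elements(g, v)
    if (!is.null(prev)) {
      expect_true(all(cur$nodes %in% prev$nodes))
      expect_true(all(edge_key_str(cur$edges) %in% edge_key_str(prev$edges)))
    }
    prev <- cur
  }
})

test_that("sub-pathway elements stay visible through their ancestor", {
  ents <- lapply(c("A", "B"), entity)
  rx <- list(reaction("r1", "A", "B", "S"))
  pw <- list(pathway("P"), pathway("S", parent_id = "P",
                                   entity_ids = c("A", "B"),
                                   reaction_ids = "r1"))
  g <- build_graph(pathway_model(ents, rx, pw))
  # only the parent is selected; the sub-pathway's elements inherit it
  v <- view_state(visible_pathways = "P", revealed_nodes = c("A", "B"),
                  revealed_edges = g$edges[, 1:3])
  vis <- visible_elements(g, v)
  expect_setequal(vis$nodes, c("A", "B"))
  expect_equal(nrow(vis$edges), 1L)
})

test_that("downstream and upstream steps return filtered adjacency deltas", {
  g <- two_pathway_graph()
  v <- view_state(visible_pathways = c("P1", "P2"), revealed_nodes = "B")
  d <- downstream_step(g, "B", v)
  expect_equal(d$nodes, "C")
  expect_equal(nrow(d$edges), 1L)
  u <- upstream_step(g, "B", v)
  expect_equal(u$nodes, "A")

  # sink node -> empty downstream delta
  expect_length(downstream_step(g, "C", v)$nodes, 0L)
  expect_error(downstream_step(g, "NOPE", v), "NOPE")

  # out-edge whose pathway is hidden is excluded
  ents <- lapply(c("A", "B", "C"), entity)
  rx <- list(reaction("r1", "A", "B", "P1"), reaction("r2", "A", "C", "P2"))
  pw <- list(pathway("P1", entity_ids = c("A", "B"), reaction_ids = "r1"),
             pathway("P2", entity_ids = c("A", "C"), reaction_ids = "r2"))
  g2 <- build_graph(pathway_model(ents, rx, pw))
  v2 <- view_state(visible_pathways = "P1", revealed_nodes = "A")
  expect_equal(downstream_step(g2, "A", v2)$nodes, "B")
})

test_that("upstream on the reversed graph equals downstream on the original", {
  for (seed in 1:4) {
    m <- rand_dag_model(n = 9, p = 0.3, seed = seed)
    g <- build_graph(m)
    # reversed model: swap every reaction
    rev_rx <- lapply(m$reactions, function(r)
      reaction(r$id, r$outputs, r$inputs, r$pathway_ids))
    grev <- build_graph(pathway_model(unname(m$entities), unname(rev_rx),
                                      unname(m$pathways)))
    v <- view_state(visible_pathways = "P1",
                    revealed_nodes = names(g$entities))
    for (n in names(g$entities)) {
      d1 <- downstream_step(g, n, v)
      d2 <- upstream_step(grev, n, v)
      expect_equal(d1$nodes, d2$nodes)
    }
  }
})

test_that("hidden-step markers track unrevealed adjacency and clear on expansion", {
  g <- two_pathway_graph()
  v <- view_state(visible_pathways = c("P1", "P2"), revealed_nodes = "B")
  mk <- hidden_step_markers(g, v)
  row <- mk[mk$node == "B", ]
  expect_true(row$has_hidden_upstream)
  expect_true(row$has_hidden_downstream)

  v2 <- apply_delta(v, downstream_step(g, "B", v))
  row2 <- hidden_step_markers(g, v2)
  expect_false(row2[row2$node == "B", ]$has_hidden_downstream)
  expect_true(row2[row2$node == "B", ]$has_hidden_upstream)

  vfull <- full_view(g)
  mkf <- hidden_step_markers(g, vfull)
  expect_false(any(mkf$has_hidden_upstream | mkf$has_hidden_downstream))
})

test_that("repeated expansion reaches the full visible graph (closure)", {
  m <- generate_fixture(fixture_config(seed = 3, n_entities = 25,
                                       n_reactions = 30))
  g <- build_graph(m)
  v <- view_state(visible_pathways = names(g$pathways),
                  revealed_nodes = names(g$entities))
  repeat {
    grew <- FALSE
    for (n in v$revealed_nodes) {
      d <- downstream_step(g, n, v)
      if (length(d$nodes) + nrow(d$edges) > 0L) {
        v <- apply_delta(v, d)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  vis <- visible_elements(g, v)
  expect_setequal(vis$nodes, visible_elements(g, full_view(g))$nodes)
  expect_equal(nrow(vis$edges), nrow(g$edges))
})

test_that("intermediate subgraph matches the diamond worked example", {
  g <- build_graph(diamond_model())
  v <- view_state(visible_pathways = "P1", revealed_nodes = c("A", "D"))
  d <- intermediate_subgraph(g, "A", "D", v)
  expect_setequal(c(d$nodes, "A", "D"), c("A", "B", "C", "D"))
  expect_equal(nrow(d$edges), 4L)
  expect_false("X" %in% d$nodes)  # dangling branch excluded
  # oracle: X lies on no simple A->D path
  paths <- enumerate_simple_paths(g$edges, "A", "D")
  expect_false("X" %in% unlist(paths))

  # no path -> empty delta, not an error
  d0 <- intermediate_subgraph(g, "D", "A", v)
  expect_length(d0$nodes, 0L)
  expect_equal(nrow(d0$edges), 0L)
})

test_that("intermediate subgraph equals the union of simple paths on DAGs", {
  checked <- 0L
  for (seed in 1:40) {
    m <- rand_dag_model(n = sample(c(6L, 9L, 12L), 1), p = 0.3, seed = seed)
    g <- build_graph(m)
    nodes <- names(g$entities)
    v <- view_state(visible_pathways = "P1", revealed_nodes = nodes)
    pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
    pairs <- utils::head(pairs[pairs$s != pairs$t, ], 10)
    for (i in seq_len(nrow(pairs))) {
      s <- pairs$s[i]; t <- pairs$t[i]
      d <- intermediate_subgraph(g, s, t, view_state(
        visible_pathways = "P1", revealed_nodes = c(s, t)))
      got <- sort(unique(c(d$nodes, if (length(d$nodes) || nrow(d$edges)) c(s, t))))
      oracle <- sort(unique(unlist(enumerate_simple_paths(g$edges, s, t))))
      if (length(oracle) < 2L) oracle <- character(0)
      expect_equal(got, oracle)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 100L)
})

test_that("hover context highlights co-pathway elements and labels them", {
  g <- two_pathway_graph()
  v <- full_view(g)
  ctx <- highlight_context(g, "A", v)
  expect_setequal(ctx$highlighted$nodes, c("A", "B", "C", "X"))
  expect_setequal(ctx$desaturated$nodes, c("D", "E"))
  expect_equal(ctx$labeled, ctx$highlighted$nodes)
  expect_true(all(ctx$highlighted$edges$pathway_id == "P1"))

  # element in both pathways -> union highlighted, nothing desaturated
  ctx2 <- highlight_context(g, "X", v)
  expect_setequal(ctx2$highlighted$nodes, names(g$entities))
  expect_length(ctx2$desaturated$nodes, 0L)

  # single-pathway graph: everything highlighted
  g1 <- build_graph(diamond_model())
  ctx3 <- highlight_context(g1, "A", full_view(g1))
  expect_length(ctx3$desaturated$nodes, 0L)
})

test_that("queries are pure and view states round-trip through JSON", {
  g <- two_pathway_graph()
  v <- view_state(visible_pathways = c("P1", "P2"), revealed_nodes = "B",
                  keywords = c("OR", "cd"), hover_target = "B")
  d1 <- downstream_step(g, "B", v)
  d2 <- downstream_step(g, "B", v)
  expect_identical(d1, d2)
  txt <- write_view_json(v)
  v2 <- read_view_json(txt)
  expect_identical(v2$visible_pathways, v$visible_pathways)
  expect_identical(v2$keywords, v$keywords)
  expect_identical(v2$hover_target, v$hover_target)
  expect_identical(write_view_json(v2), txt)
})
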