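count_elems <- function(svg, xpath) {
  doc <- xml2::read_xml(svg)
  length(xml2::xml_find_all(doc, xpath))
}

render_fixture <- function(seed = 21, ...) {
  m <- generate_fixture(fixture_config(seed = seed, n_pathways = 3,
                                       n_entities = 18, n_reactions = 15))
  g <- build_graph(m)
  lay <- compute_layout(g, seed = 1)
  list(model = m, graph = g, layout = lay)
}

test_that("glyph and lane counts conserve the visible element counts", {
  f <- render_fixture()
  for (seed in 1:4) {
    keep <- withr::with_seed(seed,
      sample(names(f$graph$entities), 12))
    v <- view_state(visible_pathways = names(f$graph$pathways),
                    revealed_nodes = keep,
                    revealed_edges = f$graph$edges[
                      f$graph$edges$source %in% keep &
                        f$graph$edges$target %in% keep, 1:3])
    svg <- render_svg(f$graph, f$layout, v)
    vis <- visible_elements(f$graph, v)
    n_glyphs <- count_elems(svg, "//*[@class='node-glyph']")
    expect_equal(n_glyphs, length(vis$nodes))
    n_lanes <- count_elems(svg, "//*[@class='lane']")
    grp <- sum(vapply(edge_groups(structure(
      list(entities = f$graph$entities, pathways = f$graph$pathways,
           edges = vis$edges), class = "pathway_graph")),
      function(g) nrow(g$lanes), 0L))
    expect_equal(n_lanes, grp)
  }
})

test_that("membership ring count equals visible membership count per node", {
  f <- render_fixture()
  v <- full_view(f$graph)
  svg <- render_svg(f$graph, f$layout, v)
  doc <- xml2::read_xml(svg)
  for (id in sample(names(f$graph$entities), 8)) {
    rings <- xml2::xml_find_all(doc, sprintf(
      "//*[@class='ring' and @data-node='%s']", id))
    expect_length(rings, length(intersect(memberships(f$graph, id),
                                          v$visible_pathways)))
  }
})

test_that("a two-pathway node carries exactly two border rings", {
  ents <- list(entity("X"), entity("Y"), entity("Z"))
  rx <- list(reaction("r1", "X", "Y", "P1"), reaction("r2", "X", "Z", "P2"))
  pw <- list(pathway("P1", entity_ids = c("X", "Y"), reaction_ids = "r1"),
             pathway("P2", entity_ids = c("X", "Z"), reaction_ids = "r2"))
  g <- build_graph(pathway_model(ents, rx, pw))
  svg <- render_svg(g, compute_layout(g), full_view(g))
  expect_equal(count_elems(svg, "//*[@class='ring' and @data-node='X']"), 2L)
  expect_equal(count_elems(svg, "//*[@class='ring' and @data-node='Y']"), 1L)
})

test_that("a both-direction lane is one path with tip markers at both ends", {
  ents <- lapply(c("A", "B"), entity)
  rx <- list(reaction("r1", "A", "B", "P1"), reaction("r2", "B", "A", "P1"))
  pw <- list(pathway("P1", entity_ids = c("A", "B"),
                     reaction_ids = c("r1", "r2")))
  g <- build_graph(pathway_model(ents, rx, pw))
  svg <- render_svg(g, compute_layout(g), full_view(g))
  expect_equal(count_elems(svg, "//*[@class='lane']"), 1L)
  expect_equal(count_elems(svg, "//*[@class='tip']"), 2L)
})

test_that("empty visible sets still render a legend-only valid SVG", {
  f <- render_fixture()
  v <- view_state()  # nothing visible
  svg <- render_svg(f$graph, f$layout, v)
  expect_equal(count_elems(svg, "//*[@class='node-glyph']"), 0L)
  expect_equal(count_elems(svg, "//*[@class='legend-entry']"),
               length(f$graph$pathways))
})

test_that("hidden pathways are listed in gray in the legend", {
  f <- render_fixture()
  pws <- names(f$graph$pathways)
  v <- view_state(visible_pathways = pws[1],
                  revealed_nodes = names(f$graph$entities),
                  revealed_edges = f$graph$edges[, 1:3])
  doc <- xml2::read_xml(render_svg(f$graph, f$layout, v))
  hidden_fill <- xml2::xml_attr(xml2::xml_find_first(doc, sprintf(
    "//*[@class='legend-entry' and @data-pathway='%s']", pws[2])), "fill")
  visible_fill <- xml2::xml_attr(xml2::xml_find_first(doc, sprintf(
    "//*[@class='legend-entry' and @data-pathway='%s']", pws[1])), "fill")
  expect_equal(hidden_fill, "#999999")
  expect_false(visible_fill == "#999999")
})

test_that("hover desaturates other pathways and labels only the context", {
  ents <- lapply(c("A", "B", "C", "D"), entity)
  rx <- list(reaction("r1", "A", "B", "P1"), reaction("r2", "C", "D", "P2"))
  pw <- list(pathway("P1", entity_ids = c("A", "B"), reaction_ids = "r1"),
             pathway("P2", entity_ids = c("C", "D"), reaction_ids = "r2"))
  g <- build_graph(pathway_model(ents, rx, pw))
  v <- view_state(visible_pathways = c("P1", "P2"),
                  revealed_nodes = c("A", "B", "C", "D"),
                  revealed_edges = g$edges[, 1:3], hover_target = "A")
  sty <- style_config()
  doc <- xml2::read_xml(render_svg(g, compute_layout(g), v, sty))
  cfill <- xml2::xml_attr(xml2::xml_find_first(
    doc, "//*[@class='node-glyph' and @data-node='C']"), "fill")
  expect_equal(cfill, sty$desaturated)
  labels <- xml2::xml_text(xml2::xml_find_all(
    doc, "//*[@class='nodes']//*[@class='label']"))
  expect_setequal(labels, c("A", "B"))

  # no hover: no labels by default; always_label shows all
  v2 <- view_state(visible_pathways = c("P1", "P2"),
                   revealed_nodes = c("A", "B", "C", "D"))
  doc2 <- xml2::read_xml(render_svg(g, compute_layout(g), v2, sty))
  expect_length(xml2::xml_find_all(
    doc2, "//*[@class='nodes']//*[@class='label']"), 0L)
  doc3 <- xml2::read_xml(render_svg(
    g, compute_layout(g), v2, style_config(always_label = TRUE)))
  expect_length(xml2::xml_find_all(
    doc3, "//*[@class='nodes']//*[@class='label']"), 4L)
})

test_that("hidden-step triangles appear only while steps are unrevealed", {
  g <- build_graph(edge_list_model(list(c("A", "B"), c("B", "C"))))
  v <- view_state(visible_pathways = "P1", revealed_nodes = "B")
  lay <- compute_layout(g)
  svg <- render_svg(g, lay, v)
  expect_equal(count_elems(svg, "//*[@class='marker-up' and @data-node='B']"), 1L)
  expect_equal(count_elems(svg, "//*[@class='marker-down' and @data-node='B']"), 1L)
  vfull <- full_view(g)
  svgf <- render_svg(g, lay, vfull)
  expect_equal(count_elems(svgf, "//*[@class='marker-up']"), 0L)
  expect_equal(count_elems(svgf, "//*[@class='marker-down']"), 0L)
})

test_that("enlarged complexes render their packed structure and push neighbours", {
  ents <- list(entity("big", kind = "complex", components = c("p1", "p2")),
               entity("p1"), entity("p2"), entity("near"))
  rx <- list(reaction("r1", "near", "big", "P1"))
  pw <- list(pathway("P1", entity_ids = c("big", "near"),
                     reaction_ids = "r1"))
  m <- pathway_model(ents, rx, pw)
  g <- build_graph(m)
  v <- view_state(visible_pathways = "P1",
                  revealed_nodes = c("big", "near"),
                  revealed_edges = g$edges[, 1:3],
                  enlarged_complexes = "big")
  svg <- render_svg(g, compute_layout(g), v, model = m)
  expect_equal(count_elems(svg, "//*[@class='overview-complex']"), 1L)
  expect_equal(count_elems(svg, "//*[@class='overview-protein']"), 2L)
  # enlarging a protein is rejected
  vbad <- view_state(visible_pathways = "P1",
                     revealed_nodes = c("big", "near"),
                     enlarged_complexes = "near")
  expect_error(render_svg(g, compute_layout(g), vbad, model = m),
               "not a complex")
})

test_that("SVG output is byte-identical across repeated runs", {
  f <- render_fixture()
  v <- full_view(f$graph, keywords = character(0))
  v$hover_target <- names(f$graph$entities)[1]
  s1 <- render_svg(f$graph, compute_layout(f$graph, seed = 5), v)
  s2 <- render_svg(f$graph, compute_layout(f$graph, seed = 5), v)
  expect_identical(s1, s2)
  expect_silent(xml2::read_xml(s1))
})

test_that("pruned-tree SVG shows labelled chain and children with emphasis", {
  m <- nested_complex_model()
  pt <- prune_tree("A", "G", m)
  svg <- render_pruned_tree_svg(pt, m)
  expect_equal(count_elems(svg, "//*[@class='chain-glyph']"), 3L)
  expect_equal(count_elems(svg, "//*[@class='child-glyph']"), 4L)
  expect_equal(count_elems(svg, "//*[@class='label']"), 7L)
  doc <- xml2::read_xml(svg)
  sel <- xml2::xml_find_first(doc,
    "//*[@class='child-glyph' and @data-entity='G']")
  expect_equal(xml2::xml_attr(sel, "fill"), style_config()$selected_gray)
  expect_equal(count_elems(svg, "//*[@class='underline']"), 1L)

  # degenerate root selection: a single glyph
  pt0 <- prune_tree("A", "A", m)
  svg0 <- render_pruned_tree_svg(pt0, m)
  expect_equal(count_elems(svg0, "//*[@class='child-glyph']"), 1L)
  expect_equal(count_elems(svg0, "//*[@class='chain-glyph']"), 0L)
})
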