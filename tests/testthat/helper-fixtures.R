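# Builders for tiny in-code fixtures and independent oracles.

# Fig-style nested complex: A > B > C > {D, E, F, G}
nested_complex_model <- function() {
  pathway_model(entities = list(
    entity("A", kind = "complex", components = "B"),
    entity("B", kind = "complex", components = "C"),
    entity("C", kind = "complex", components = c("D", "E", "F", "G")),
    entity("D"), entity("E"), entity("F"), entity("G")))
}

# Diamond A -> {B, C} -> D plus dangling branch B -> X, one pathway.
diamond_model <- function() {
  ents <- lapply(c("A", "B", "C", "D", "X"), entity)
  rx <- list(reaction("r1", "A", "B", "P1"), reaction("r2", "A", "C", "P1"),
             reaction("r3", "B", "D", "P1"), reaction("r4", "C", "D", "P1"),
             reaction("r5", "B", "X", "P1"))
  pw <- list(pathway("P1", entity_ids = c("A", "B", "C", "D", "X"),
                     reaction_ids = paste0("r", 1:5)))
  pathway_model(ents, rx, pw)
}

# Directed chain/cycle over the given edge list, one reaction per edge.
edge_list_model <- function(edges, pathway_ids = "P1") {
  nodes <- sort(unique(unlist(edges)))
  rx <- lapply(seq_along(edges), function(i)
    reaction(sprintf("r%02d", i), edges[[i]][1], edges[[i]][2], pathway_ids[
      (i - 1L) %% length(pathway_ids) + 1L]))
  pws <- lapply(sort(unique(pathway_ids)), function(p)
    pathway(p, entity_ids = nodes,
            reaction_ids = vapply(Filter(function(r) p %in% r$pathway_ids, rx),
                                  `[[`, "", "id")))
  pathway_model(lapply(nodes, entity), rx, pws)
}

# Random single-pathway DAG on n nodes; edge i->j (i < j) with prob p.
rand_dag_model <- function(n, p, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n))
    edges <- list()
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (stats::runif(1) < p) edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
      }
    }
    if (length(edges) == 0L) edges <- list(c(ids[1], ids[2]))
    edge_list_model(edges)
  })
}

# Random containment tree: one root complex, random nesting.
rand_tree_model <- function(n, max_depth, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("T%02d", seq_len(n))
    parent <- integer(n)
    depth <- integer(n)
    for (i in 2:n) {
      cand <- which(depth[1:(i - 1L)] < max_depth)
      parent[i] <- cand[sample.int(length(cand), 1L)]
      depth[i] <- depth[parent[i]] + 1L
    }
    ents <- lapply(seq_len(n), function(i) {
      kids <- ids[parent == i]
      if (length(kids) > 0L || i == 1L) {
        entity(ids[i], kind = "complex", components = kids)
      } else entity(ids[i])
    })
    list(model = pathway_model(entities = ents), ids = ids,
         parent = parent, depth = depth)
  })
}

# Oracle: all simple directed paths between two nodes (exhaustive DFS).
enumerate_simple_paths <- function(edges, from, to) {
  paths <- list()
  walk <- function(v, path) {
    if (v == to) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (w in sort(unique(edges$target[edges$source == v]))) {
      if (!w %in% path) walk(w, c(path, w))
    }
  }
  walk(from, from)
  paths
}

# Oracle: crossings of a two-layer drawing by exhaustive pair checking on
# index orderings (for bipartite cases).
bipartite_crossings <- function(top, bottom, edges) {
  cnt <- 0L
  if (nrow(edges) < 2L) return(0L)
  for (i in seq_len(nrow(edges) - 1L)) {
    for (j in (i + 1L):nrow(edges)) {
      a1 <- match(edges$source[i], top); b1 <- match(edges$target[i], bottom)
      a2 <- match(edges$source[j], top); b2 <- match(edges$target[j], bottom)
      if (!anyNA(c(a1, b1, a2, b2)) &&
          ((a1 - a2) * (b1 - b2) < 0)) cnt <- cnt + 1L
    }
  }
  cnt
}
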