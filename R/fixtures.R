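# Seeded synthetic pathway-set generator. Emulates the shape of a multi-
# pathway analysis session (several overlapping pathways, nested complexes,
# occasional feedback cycles) at arbitrary, controllable scale.

# Realistic display names seeded from cell-cycle / DNA-replication actors so
# keyword-filter examples read naturally; padded with PROT####/CPLX#### ids.
PROTEIN_VOCAB <- c("ORC1", "ORC2", "ORC3", "ORC4", "ORC5", "ORC6", "CDC6",
                   "CDT1", "MCM10", "CDC45", "MCM2", "MCM3", "MCM4", "MCM5",
                   "MCM6", "MCM7", "UBIQUITIN", "GMNN", "CDK2", "CCNE1")
COMPLEX_VOCAB <- c("preRC", "ORC-origin", "MCM2-7", "CDC6-ORC-origin",
                   "MCM10-preRC", "active-preRC")

#' Fixture generator configuration
#'
#' @param n_pathways Number of pathways (0 gives an empty model).
#' @param n_entities Number of entities shared by the model.
#' @param overlap_fraction Fraction of entities that are members of every
#'   pathway (the rest belong to exactly one).
#' @param complex_fraction Fraction of entities that are complexes.
#' @param max_nesting_depth Maximum complex containment depth (>= 1).
#' @param n_reactions Number of reactions to attempt (reactions that cannot
#'   be placed in a too-small pathway are dropped).
#' @param max_participants Maximum inputs (and outputs) per reaction.
#' @param cycle_probability Probability that a reaction is oriented against
#'   the acyclic skeleton, creating directed cycles.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_pathways = 6L, n_entities = 60L,
                           overlap_fraction = 0.2, complex_fraction = 0.3,
                           max_nesting_depth = 3L, n_reactions = 40L,
                           max_participants = 3L, cycle_probability = 0.1,
                           seed = 1L) {
  cfg <- list(n_pathways = as.integer(n_pathways),
              n_entities = as.integer(n_entities),
              overlap_fraction = overlap_fraction,
              complex_fraction = complex_fraction,
              max_nesting_depth = as.integer(max_nesting_depth),
              n_reactions = as.integer(n_reactions),
              max_participants = as.integer(max_participants),
              cycle_probability = cycle_probability,
              seed = as.integer(seed))
  if (cfg$n_pathways < 0L || cfg$n_entities < 0L || cfg$n_reactions < 0L) {
    stop("invalid fixture config: counts must be non-negative", call. = FALSE)
  }
  for (f in c("overlap_fraction", "complex_fraction", "cycle_probability")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("invalid fixture config: ", f, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$max_nesting_depth < 1L) {
    stop("invalid fixture config: max_nesting_depth must be >= 1",
         call. = FALSE)
  }
  if (cfg$max_participants < 1L) {
    stop("invalid fixture config: max_participants must be >= 1",
         call. = FALSE)
  }
  structure(cfg, class = "fixture_config")
}

# sample() without the length-1 surprise.
pick <- function(x, size) x[sample.int(length(x), size)]

#' Generate a synthetic pathway model
#'
#' Entities are split into proteins and complexes; complex containment is
#' built bottom-up so its height never exceeds `max_nesting_depth` and can
#' never cycle. A fraction of entities is shared across all pathways, the
#' rest are partitioned. Reactions follow an acyclic rank skeleton; with
#' probability `cycle_probability` a reaction is flipped against the ranks,
#' injecting directed cycles.
#'
#' @param config A [fixture_config()].
#' @return A validated `pathway_model`; identical seeds give identical
#'   models (the caller's RNG state is left untouched).
#' @export
generate_fixture <- function(config = fixture_config()) {
  if (!inherits(config, "fixture_config")) config <- do.call(fixture_config, config)
  if (config$n_pathways == 0L || config$n_entities == 0L) {
    return(pathway_model())
  }
  withr::with_seed(config$seed, generate_fixture_impl(config))
}

generate_fixture_impl <- function(cfg) {
  n_complex <- min(round(cfg$complex_fraction * cfg$n_entities),
                   cfg$n_entities - 1L)
  n_prot <- cfg$n_entities - n_complex
  prot_ids <- sprintf("PROT%04d", seq_len(n_prot))
  prot_names <- c(PROTEIN_VOCAB, prot_ids)[seq_len(n_prot)]
  cplx_ids <- if (n_complex > 0L) sprintf("CPLX%04d", seq_len(n_complex)) else character(0)
  cplx_names <- if (n_complex > 0L) c(COMPLEX_VOCAB, cplx_ids)[seq_len(n_complex)] else character(0)

  entities <- lapply(seq_len(n_prot), function(i)
    entity(prot_ids[i], name = prot_names[i], kind = "protein"))

  # Bottom-up containment: complex i may contain proteins and any already
  # built complex whose subtree height leaves room under the depth cap.
  height <- stats::setNames(rep(0L, n_prot), prot_ids)
  built <- character(0)
  for (i in rev(seq_len(n_complex))) {
    ok_complex <- built[height[built] < cfg$max_nesting_depth]
    pool <- c(prot_ids, ok_complex)
    k <- min(length(pool), sample.int(3L, 1L))
    comps <- sort(pick(pool, k))
    h <- if (length(comps)) 1L + max(height[comps]) else 1L
    height[cplx_ids[i]] <- h
    built <- c(built, cplx_ids[i])
    entities[[length(entities) + 1L]] <-
      entity(cplx_ids[i], name = cplx_names[i], kind = "complex",
             components = comps)
  }
  ent_ids <- vapply(entities, `[[`, "", "id")
  rank <- stats::setNames(seq_along(ent_ids), sort(ent_ids))

  pw_ids <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  n_shared <- round(cfg$overlap_fraction * cfg$n_entities)
  shared <- if (n_shared > 0L) sort(pick(ent_ids, n_shared)) else character(0)
  rest <- setdiff(ent_ids, shared)
  assignment <- stats::setNames(
    pw_ids[(seq_along(rest) - 1L) %% cfg$n_pathways + 1L], rest)
  members <- lapply(pw_ids, function(pid)
    sort(c(shared, names(assignment)[assignment == pid])))
  names(members) <- pw_ids

  reactions <- list()
  rix <- 0L
  for (j in seq_len(cfg$n_reactions)) {
    pid <- pick(pw_ids, 1L)
    pool <- members[[pid]]
    if (length(pool) < 2L) next
    pool <- pool[order(rank[pool])]
    split_at <- sample.int(length(pool) - 1L, 1L)
    lower <- pool[seq_len(split_at)]
    upper <- pool[(split_at + 1L):length(pool)]
    n_in <- min(length(lower), sample.int(cfg$max_participants, 1L))
    n_out <- min(length(upper), sample.int(cfg$max_participants, 1L))
    ins <- pick(lower, n_in)
    outs <- pick(upper, n_out)
    if (stats::runif(1) < cfg$cycle_probability) {
      tmp <- ins; ins <- outs; outs <- tmp  # back-edge against the skeleton
    }
    rix <- rix + 1L
    reactions[[rix]] <- reaction(sprintf("RX%04d", rix), ins, outs, pid)
  }

  rxn_by_pw <- lapply(pw_ids, function(pid)
    vapply(Filter(function(r) pid %in% r$pathway_ids, reactions), `[[`, "", "id"))
  names(rxn_by_pw) <- pw_ids
  pathways <- lapply(pw_ids, function(pid)
    pathway(pid, name = paste0("Pathway ", sub("^PW", "", pid)),
            entity_ids = members[[pid]], reaction_ids = rxn_by_pw[[pid]]))

  pathway_model(entities = entities, reactions = reactions,
                pathways = pathways)
}
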