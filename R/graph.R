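#' Degradation graph data structure
#'
#' A degradation graph is a directed acyclic graph describing a proteolytic
#' process. Real nodes are peptides (identified by their sequence), edges are
#' proteolytic reactions directed from the degraded to the generated peptide.
#' An endoproteolytic cleavage of peptide u after residue c is represented by
#' a pseudo-node `u|c` with one incoming reaction edge (carrying the rate)
#' and two outgoing pseudo-edges to the prefix and suffix fragments;
#' pseudo-edges carry no rate parameter.
#'
#' Node identifiers are the peptide sequences themselves (real nodes) or
#' `"<parent>|<cut>"` (pseudo-nodes), which makes deduplication by sequence
#' automatic and all graph operations deterministic.
#'
#' @param seed_sequence Amino-acid sequence of the seed (base) peptide, the
#'   root of the graph. Length >= 2.
#' @param table Mass table, see [mass_table()].
#' @return Object of class `degradation_graph`: a list with `nodes` and
#'   `edges` data frames and the `root` node id.
#' @examples
#' g <- degradation_graph("DSGEGDFLAEGGGVR")
#' g
#' @export
degradation_graph <- function(seed_sequence, table = mass_table()) {
  .assert_sequence(seed_sequence)
  if (nchar(seed_sequence) < 2L) {
    stop("seed sequence must have length >= 2", call. = FALSE)
  }
  nodes <- data.frame(
    id = seed_sequence, type = "peptide", sequence = seed_sequence,
    mass = compute_mass(seed_sequence, table), is_seed = TRUE,
    parent_sequence = NA_character_, cut_pos = NA_integer_,
    ambiguous_with = NA_character_, stringsAsFactors = FALSE
  )
  edges <- data.frame(
    id = character(0), source = character(0), target = character(0),
    kind = character(0), rate_param = character(0), stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges, root = seed_sequence),
            class = "degradation_graph")
}

#' @export
print.degradation_graph <- function(x, ...) {
  nreal <- sum(x$nodes$type == "peptide")
  npseudo <- sum(x$nodes$type == "pseudo")
  nreact <- sum(x$edges$kind != "pseudo")
  cat(sprintf(
    "degradation graph: %d peptide node(s), %d pseudo-node(s), %d reaction(s)\n",
    nreal, npseudo, nreact))
  cat(sprintf("root: %s (%.4f Da)\n", x$root,
              x$nodes$mass[x$nodes$id == x$root]))
  invisible(x)
}

#' Real (peptide) nodes of a degradation graph
#' @param graph A `degradation_graph`.
#' @return Data frame of peptide nodes.
#' @export
real_nodes <- function(graph) {
  graph$nodes[graph$nodes$type == "peptide", , drop = FALSE]
}

#' Non-pseudo reaction edges of a degradation graph
#' @param graph A `degradation_graph`.
#' @return Data frame of edges with kind in exo_N/exo_C/endo (the edges that
#'   carry rate parameters).
#' @export
reaction_edges <- function(graph) {
  graph$edges[graph$edges$kind != "pseudo", , drop = FALSE]
}

.has_node <- function(graph, id) id %in% graph$nodes$id

.ensure_peptide_node <- function(graph, sequence, table = mass_table(),
                                 ambiguous_with = NA_character_) {
  if (.has_node(graph, sequence)) {
    if (!is.na(ambiguous_with)) {
      i <- which(graph$nodes$id == sequence)
      cur <- graph$nodes$ambiguous_with[i]
      alts <- unique(c(
        if (!is.na(cur)) strsplit(cur, ";", fixed = TRUE)[[1L]],
        ambiguous_with))
      graph$nodes$ambiguous_with[i] <- paste(sort(alts), collapse = ";")
    }
    return(graph)
  }
  graph$nodes <- rbind(graph$nodes, data.frame(
    id = sequence, type = "peptide", sequence = sequence,
    mass = compute_mass(sequence, table), is_seed = FALSE,
    parent_sequence = NA_character_, cut_pos = NA_integer_,
    ambiguous_with = ambiguous_with, stringsAsFactors = FALSE
  ))
  graph
}

.add_edge_row <- function(graph, source, target, kind) {
  id <- paste(kind, source, target, sep = ":")
  if (id %in% graph$edges$id) return(graph)
  graph$edges <- rbind(graph$edges, data.frame(
    id = id, source = source, target = target, kind = kind,
    rate_param = if (kind == "pseudo") NA_character_ else id,
    stringsAsFactors = FALSE
  ))
  graph
}

#' Add an exoproteolytic reaction to a degradation graph
#'
#' Creates the child node if absent (deduplicated by sequence) and connects
#' parent to child with an edge labelled `exo_N` or `exo_C` depending on
#' which terminus was removed. Idempotent for identical calls.
#'
#' @param graph A `degradation_graph`.
#' @param parent_id Id (= sequence) of the degraded peptide node.
#' @param child_sequence Sequence obtained by removing one terminal residue.
#' @param ambiguous_with Optional sequence of an isobaric alternative child
#'   recorded on the node (used by the builder for I/L ambiguity).
#' @return List with components `graph` (updated), `edge_id`, `node_id`.
#' @export
add_exo_reaction <- function(graph, parent_id, child_sequence,
                             ambiguous_with = NA_character_) {
  stopifnot(inherits(graph, "degradation_graph"))
  if (!.has_node(graph, parent_id)) {
    stop(sprintf("parent node '%s' not in graph", parent_id), call. = FALSE)
  }
  parent_seq <- graph$nodes$sequence[graph$nodes$id == parent_id]
  kids <- exo_children(parent_seq)
  if (length(kids) == 0L) {
    stop("cannot apply an exo reaction to a single-residue peptide",
         call. = FALSE)
  }
  if (!(child_sequence %in% kids)) {
    stop(sprintf("'%s' is not an exo child of '%s'", child_sequence,
                 parent_seq), call. = FALSE)
  }
  n <- nchar(parent_seq)
  kind <- if (child_sequence == substr(parent_seq, 2L, n)) "exo_N" else "exo_C"
  graph <- .ensure_peptide_node(graph, child_sequence,
                                ambiguous_with = ambiguous_with)
  graph <- .add_edge_row(graph, parent_id, child_sequence, kind)
  list(graph = graph,
       edge_id = paste(kind, parent_id, child_sequence, sep = ":"),
       node_id = child_sequence)
}

#' Add an endoproteolytic reaction to a degradation graph
#'
#' Inserts the pseudo-node for the cut, the rate-carrying endo edge from the
#' parent, both fragment nodes (deduplicated by sequence) and the two
#' rate-free pseudo-edges. Idempotent.
#'
#' @param graph A `degradation_graph`.
#' @param parent_id Id of the degraded peptide node.
#' @param cut Cut position c (1-based, cut after residue c),
#'   1 <= c <= length-1.
#' @return List with `graph`, `pseudo_id` and `child_ids` (prefix, suffix).
#' @export
add_endo_reaction <- function(graph, parent_id, cut) {
  stopifnot(inherits(graph, "degradation_graph"))
  if (!.has_node(graph, parent_id)) {
    stop(sprintf("parent node '%s' not in graph", parent_id), call. = FALSE)
  }
  parent_seq <- graph$nodes$sequence[graph$nodes$id == parent_id]
  n <- nchar(parent_seq)
  cut <- as.integer(cut)
  if (is.na(cut) || cut < 1L || cut > n - 1L) {
    stop(sprintf("cut position must lie in 1..%d", n - 1L), call. = FALSE)
  }
  prefix <- substr(parent_seq, 1L, cut)
  suffix <- substr(parent_seq, cut + 1L, n)
  pseudo_id <- paste0(parent_seq, "|", cut)
  if (!.has_node(graph, pseudo_id)) {
    graph$nodes <- rbind(graph$nodes, data.frame(
      id = pseudo_id, type = "pseudo", sequence = NA_character_,
      mass = NA_real_, is_seed = FALSE, parent_sequence = parent_seq,
      cut_pos = cut, ambiguous_with = NA_character_, stringsAsFactors = FALSE
    ))
  }
  graph <- .ensure_peptide_node(graph, prefix)
  graph <- .ensure_peptide_node(graph, suffix)
  graph <- .add_edge_row(graph, parent_id, pseudo_id, "endo")
  graph <- .add_edge_row(graph, pseudo_id, prefix, "pseudo")
  graph <- .add_edge_row(graph, pseudo_id, suffix, "pseudo")
  list(graph = graph, pseudo_id = pseudo_id, child_ids = c(prefix, suffix))
}

#' Topological order of graph nodes
#'
#' Orders nodes so that every edge points forward; ties are broken by node
#' id, making the order (and everything downstream that iterates over it)
#' deterministic.
#'
#' @param graph A `degradation_graph`.
#' @return Character vector of node ids.
#' @export
topological_order <- function(graph) {
  ids <- graph$nodes$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  tt <- table(graph$edges$target)
  indeg[names(tt)] <- as.integer(tt)
  out <- character(0)
  avail <- sort(ids[indeg == 0L])
  indeg_env <- indeg
  while (length(avail) > 0L) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    tgts <- graph$edges$target[graph$edges$source == v]
    for (w in tgts) {
      indeg_env[w] <- indeg_env[w] - 1L
      if (indeg_env[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(out) != length(ids)) {
    stop("graph contains a cycle; not a valid degradation graph",
         call. = FALSE)
  }
  out
}

.reachable_from_root <- function(graph) {
  reach <- graph$root
  frontier <- graph$root
  while (length(frontier) > 0L) {
    nxt <- unique(graph$edges$target[graph$edges$source %in% frontier])
    nxt <- setdiff(nxt, reach)
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  reach
}

#' Validate a degradation graph
#'
#' Checks all structural invariants: unique peptide sequences, masses
#' consistent with the mass table, edge typing (exo edges drop exactly one
#' terminal residue, endo edges point at pseudo-nodes with one parent and
#' two pseudo-edges to the cut products), acyclicity, and reachability of
#' every node from the root.
#'
#' @param graph A `degradation_graph`.
#' @return The graph, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "degradation_graph"))
  nodes <- graph$nodes
  edges <- graph$edges
  if (!(graph$root %in% nodes$id)) stop("root node missing", call. = FALSE)
  if (!nodes$is_seed[nodes$id == graph$root]) {
    stop("root node is not flagged as seed", call. = FALSE)
  }
  rn <- nodes[nodes$type == "peptide", ]
  if (anyDuplicated(rn$sequence)) {
    stop("duplicate peptide sequences among real nodes", call. = FALSE)
  }
  for (i in seq_len(nrow(rn))) {
    m <- compute_mass(rn$sequence[i])
    if (abs(m - rn$mass[i]) > 1e-6) {
      stop(sprintf("node '%s' mass inconsistent with its sequence",
                   rn$id[i]), call. = FALSE)
    }
  }
  ntype <- stats::setNames(nodes$type, nodes$id)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (!(e$source %in% nodes$id) || !(e$target %in% nodes$id)) {
      stop(sprintf("edge '%s' references a missing node", e$id),
           call. = FALSE)
    }
    if (e$kind %in% c("exo_N", "exo_C")) {
      if (ntype[e$source] != "peptide" || ntype[e$target] != "peptide") {
        stop(sprintf("exo edge '%s' must connect two peptide nodes", e$id),
             call. = FALSE)
      }
      ps <- nodes$sequence[nodes$id == e$source]
      cs <- nodes$sequence[nodes$id == e$target]
      np <- nchar(ps)
      ok <- (e$kind == "exo_N" && cs == substr(ps, 2L, np)) ||
        (e$kind == "exo_C" && cs == substr(ps, 1L, np - 1L))
      if (!ok) {
        stop(sprintf("exo edge '%s' does not remove one terminal residue",
                     e$id), call. = FALSE)
      }
    } else if (e$kind == "endo") {
      if (ntype[e$source] != "peptide" || ntype[e$target] != "pseudo") {
        stop(sprintf("endo edge '%s' must connect peptide to pseudo-node",
                     e$id), call. = FALSE)
      }
    } else if (e$kind == "pseudo") {
      if (ntype[e$source] != "pseudo" || ntype[e$target] != "peptide") {
        stop(sprintf("pseudo-edge '%s' must connect pseudo-node to peptide",
                     e$id), call. = FALSE)
      }
      if (!is.na(e$rate_param)) {
        stop(sprintf("pseudo-edge '%s' must not carry a rate", e$id),
             call. = FALSE)
      }
    } else {
      stop(sprintf("unknown edge kind '%s'", e$kind), call. = FALSE)
    }
  }
  pn <- nodes[nodes$type == "pseudo", ]
  for (i in seq_len(nrow(pn))) {
    p <- pn[i, ]
    inc <- edges[edges$target == p$id, ]
    out <- edges[edges$source == p$id, ]
    if (nrow(inc) != 1L || inc$kind != "endo") {
      stop(sprintf("pseudo-node '%s' must have exactly one endo in-edge",
                   p$id), call. = FALSE)
    }
    if (nrow(out) != 2L || any(out$kind != "pseudo")) {
      stop(sprintf("pseudo-node '%s' must have exactly two pseudo-edges",
                   p$id), call. = FALSE)
    }
    np <- nchar(p$parent_sequence)
    expect <- c(substr(p$parent_sequence, 1L, p$cut_pos),
                substr(p$parent_sequence, p$cut_pos + 1L, np))
    if (!setequal(out$target, unique(expect))) {
      stop(sprintf("pseudo-node '%s' children do not match its cut", p$id),
           call. = FALSE)
    }
  }
  topological_order(graph)
  unreached <- setdiff(nodes$id, .reachable_from_root(graph))
  if (length(unreached) > 0L) {
    stop(sprintf("node(s) not reachable from root: %s",
                 paste(unreached, collapse = ", ")), call. = FALSE)
  }
  invisible(graph)
}

#' Partition peptide nodes into isobaric mass groups
#'
#' Single-linkage grouping of the real-node masses: nodes whose masses are
#' within `tolerance` of a chain of neighbours end up in one group, because
#' a mass spectrometer cannot tell them apart and their signal is a single
#' intensity trace.
#'
#' @param graph A `degradation_graph`.
#' @param tolerance Non-negative grouping tolerance.
#' @param unit `"da"` (default) or `"ppm"`.
#' @return List of class `isobaric_groups` with `members` (list of character
#'   vectors of node ids per group, ordered by mass), `mass` (representative
#'   mass = mean of member masses) and `sequences` (list parallel to
#'   `members`).
#' @export
isobaric_groups <- function(graph, tolerance = 0.1, unit = c("da", "ppm")) {
  unit <- match.arg(unit)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  rn <- real_nodes(graph)
  ord <- order(rn$mass, rn$id)
  rn <- rn[ord, , drop = FALSE]
  grp <- integer(nrow(rn))
  g <- 1L
  grp[1L] <- g
  if (nrow(rn) > 1L) {
    for (i in 2:nrow(rn)) {
      gap <- rn$mass[i] - rn$mass[i - 1L]
      tol_da <- if (unit == "ppm") {
        tolerance * 1e-6 * mean(rn$mass[(i - 1L):i])
      } else tolerance
      if (gap > tol_da) g <- g + 1L
      grp[i] <- g
    }
  }
  members <- split(rn$id, grp)
  sequences <- split(rn$sequence, grp)
  mass <- vapply(split(rn$mass, grp), mean, numeric(1))
  structure(list(members = unname(members), mass = unname(mass),
                 sequences = unname(sequences)),
            class = "isobaric_groups")
}

#' Restrict a degradation graph to a subset of its reactions
#'
#' Builds the subgraph induced by keeping only the given rate-carrying
#' (non-pseudo) reaction edges: starting from the root, reactions fire only
#' if their substrate is reachable; endo reactions bring along their
#' pseudo-node and both pseudo-edges. Used by the structure search.
#'
#' @param graph A `degradation_graph`.
#' @param keep_edge_ids Ids of non-pseudo edges to retain.
#' @return A `degradation_graph`, or `NULL` if some requested edge can never
#'   fire (its substrate is unreachable with the kept edge set), in which
#'   case the subset is equivalent to a smaller one.
#' @export
subgraph_from_reactions <- function(graph, keep_edge_ids) {
  re <- reaction_edges(graph)
  keep <- re[re$id %in% keep_edge_ids, , drop = FALSE]
  if (nrow(keep) != length(unique(keep_edge_ids))) {
    stop("unknown reaction edge id(s)", call. = FALSE)
  }
  reach <- graph$root
  used <- character(0)
  node_keep <- graph$root
  repeat {
    fire <- keep$id[keep$source %in% reach & !(keep$id %in% used)]
    if (length(fire) == 0L) break
    for (eid in fire) {
      e <- keep[keep$id == eid, ]
      if (e$kind == "endo") {
        pe <- graph$edges[graph$edges$source == e$target &
                            graph$edges$kind == "pseudo", ]
        node_keep <- unique(c(node_keep, e$target, pe$target))
        reach <- unique(c(reach, pe$target))
      } else {
        node_keep <- unique(c(node_keep, e$target))
        reach <- unique(c(reach, e$target))
      }
      used <- c(used, eid)
    }
  }
  if (length(used) != nrow(keep)) return(NULL)
  sub <- graph
  sub$nodes <- graph$nodes[graph$nodes$id %in% node_keep, , drop = FALSE]
  keep_all <- c(used, graph$edges$id[graph$edges$kind == "pseudo" &
                                       graph$edges$source %in% node_keep])
  sub$edges <- graph$edges[graph$edges$id %in% keep_all, , drop = FALSE]
  rownames(sub$nodes) <- NULL
  rownames(sub$edges) <- NULL
  sub
}

#' Canonical identifier for a subgraph's reaction set
#'
#' @param graph A `degradation_graph` (typically a subgraph).
#' @return A single string: the sorted non-pseudo edge ids joined by ";".
#'   Two subgraphs are the same model iff their hashes are equal.
#' @export
reaction_set_hash <- function(graph) {
  paste0("{", paste(sort(reaction_edges(graph)$id), collapse = ";"), "}")
}
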