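#' Goodness-of-fit score: mean Pearson correlation
#'
#' Averages, over all mass groups explained by the fitted model, the
#' Pearson correlation between the observed and the predicted intensity
#' trace (computed over time points where both are available). A trace
#' with zero variance on either side contributes 0 — a constant signal
#' carries no evidence about the dynamics.
#'
#' @param fit A `kinetic_fit`.
#' @param observed The `intensity_matrix` the fit was computed against.
#' @return S_corr in \[-1, 1\].
#' @export
score_corr <- function(fit, observed) {
  rows <- fit$explained_rows
  if (length(rows) == 0L) {
    stop("fit explains no observed mass group", call. = FALSE)
  }
  rho <- vapply(rows, function(r) {
    o <- observed$values[r, ]
    p <- fit$predicted[r, ]
    keep <- !is.na(o) & !is.na(p)
    if (sum(keep) < 2L) return(0)
    o <- o[keep]
    p <- p[keep]
    if (stats::sd(o) == 0 || stats::sd(p) == 0) return(0)
    stats::cor(o, p)
  }, numeric(1))
  mean(rho)
}

#' Conserved-variability score of a subgraph
#'
#' The fraction of the total signal standard deviation of the full graph's
#' mass groups that is retained by the groups the subgraph still explains:
#' `S_var = sum_{m in M_sub} sigma_m / sum_{m in M_full} sigma_m`. Equals 1
#' for the full graph; dropping only flat (sigma = 0) traces keeps it at 1.
#'
#' @param subgraph A `degradation_graph` (subgraph of `full_graph`).
#' @param full_graph The full `degradation_graph`.
#' @param observed The `intensity_matrix` of the full graph.
#' @return S_var in \[0, 1\]; defined as 1 when all sigma are zero.
#' @export
score_var <- function(subgraph, full_graph, observed) {
  sub_rows <- .explained_rows(subgraph, observed)
  full_rows <- .explained_rows(full_graph, observed)
  denom <- sum(observed$sigma[full_rows])
  if (denom == 0) return(1)
  sum(observed$sigma[sub_rows]) / denom
}

.explained_rows <- function(graph, observed) {
  model <- graph_to_ode(graph, group_tolerance = observed$tolerance)
  m <- .map_states(model, observed)
  sort(unique(m[!is.na(m)]))
}

#' Weighted combination of the two score components
#'
#' @param s_corr Correlation component.
#' @param s_var Variability component.
#' @param w1,w2 Non-negative weights (normalized to sum 1 on input).
#' @return `S = w1 * s_corr + w2 * s_var`.
#' @export
combined_score <- function(s_corr, s_var, w1 = 0.5, w2 = 0.5) {
  if (w1 < 0 || w2 < 0) stop("score weights must be >= 0", call. = FALSE)
  s <- w1 + w2
  if (s == 0) stop("at least one score weight must be > 0", call. = FALSE)
  (w1 / s) * s_corr + (w2 / s) * s_var
}

#' Removable reactions of a degradation graph
#'
#' The trimming move set of the structure search. A reaction is removable
#' when it either
#' * produces at least one leaf (a peptide node that is not itself
#'   degraded further) — trimming it peels the graph from the outside in;
#'   or
#' * is redundant: its removal (with cleanup) deletes no peptide node at
#'   all, because every product is still produced by another reaction.
#'   These are the "multiple explanations for one peptide" edges the
#'   structure optimization is meant to resolve.
#'
#' Together the two cases make every connected root-containing subgraph
#' reachable by successive single trims, so a beam wide enough to keep
#' all candidates reproduces the exhaustive ranking.
#'
#' @param graph A `degradation_graph`.
#' @return Character vector of non-pseudo edge ids.
#' @export
terminal_reactions <- function(graph) {
  re <- reaction_edges(graph)
  if (nrow(re) == 0L) return(character(0))
  sources <- unique(graph$edges$source[graph$edges$kind != "pseudo"])
  is_leaf <- function(id) !(id %in% sources)
  n_real <- nrow(real_nodes(graph))
  keep <- vapply(seq_len(nrow(re)), function(i) {
    e <- re[i, ]
    prods <- if (e$kind == "endo") {
      graph$edges$target[graph$edges$source == e$target &
                           graph$edges$kind == "pseudo"]
    } else e$target
    if (any(vapply(prods, is_leaf, logical(1)))) return(TRUE)
    ## redundant alternative explanation: nothing disappears with it
    nrow(real_nodes(trim_reaction(graph, e$id))) == n_real
  }, logical(1))
  sort(re$id[keep])
}

#' Remove one reaction from a degradation graph, with cleanup
#'
#' Deletes the reaction edge (for an endo reaction also its pseudo-node and
#' both pseudo-edges) and then every node no longer reachable from the
#' root, together with all incident edges. The root is never removed.
#'
#' @param graph A `degradation_graph`.
#' @param edge_id Id of a non-pseudo edge.
#' @return The trimmed `degradation_graph`.
#' @export
trim_reaction <- function(graph, edge_id) {
  e <- graph$edges[graph$edges$id == edge_id, ]
  if (nrow(e) != 1L || e$kind == "pseudo") {
    stop(sprintf("'%s' is not a removable reaction edge", edge_id),
         call. = FALSE)
  }
  drop_edges <- edge_id
  if (e$kind == "endo") {
    drop_edges <- c(drop_edges,
                    graph$edges$id[graph$edges$source == e$target])
  }
  g <- graph
  g$edges <- g$edges[!(g$edges$id %in% drop_edges), , drop = FALSE]
  reach <- .reachable_from_root(g)
  g$nodes <- g$nodes[g$nodes$id %in% reach, , drop = FALSE]
  g$edges <- g$edges[g$edges$source %in% reach & g$edges$target %in% reach,
                     , drop = FALSE]
  rownames(g$nodes) <- NULL
  rownames(g$edges) <- NULL
  g
}

.score_one <- function(graph, full_graph, observed, weights, options,
                       parent = NA_character_) {
  fit <- fit_kinetics(graph, observed, options)
  s_corr <- score_corr(fit, observed)
  s_var <- score_var(graph, full_graph, observed)
  list(graph = graph, fit = fit, s_corr = s_corr, s_var = s_var,
       score = combined_score(s_corr, s_var, weights[1L], weights[2L]),
       hash = reaction_set_hash(graph),
       n_edges = nrow(reaction_edges(graph)), parent = parent)
}

.rank_records <- function(records) {
  ord <- order(-vapply(records, `[[`, numeric(1), "score"),
               vapply(records, `[[`, numeric(1), "n_edges"),
               vapply(records, `[[`, character(1), "hash"))
  records[ord]
}

.as_search_result <- function(records, n_evaluated, method) {
  records <- .rank_records(records)
  ranking <- data.frame(
    rank = seq_along(records),
    score = vapply(records, `[[`, numeric(1), "score"),
    s_corr = vapply(records, `[[`, numeric(1), "s_corr"),
    s_var = vapply(records, `[[`, numeric(1), "s_var"),
    n_edges = vapply(records, `[[`, numeric(1), "n_edges"),
    hash = vapply(records, `[[`, character(1), "hash"),
    stringsAsFactors = FALSE
  )
  structure(list(ranking = ranking, results = records,
                 n_evaluated = n_evaluated, method = method),
            class = "subgraph_search")
}

#' @export
print.subgraph_search <- function(x, ...) {
  cat(sprintf("%s subgraph search: %d model(s) evaluated\n", x$method,
              x$n_evaluated))
  print(utils::head(x$ranking[, c("rank", "score", "s_corr", "s_var",
                                  "n_edges")], 5L))
  invisible(x)
}

#' Leaf-trimming beam search over subgraph structures
#'
#' Starts from the full graph (fitted and scored), then repeatedly removes
#' every terminal reaction of every frontier graph separately, fitting and
#' scoring each new subgraph (deduplicated by reaction set so no model is
#' fitted twice). After each round the frontier becomes the global top-q
#' models; the search stops when a round adds no new model to the global
#' top-q. Ties on equal score are broken towards fewer reactions
#' (parsimony), then lexicographically, so rankings are deterministic.
#'
#' @param graph The initial (full) `degradation_graph`.
#' @param observed The `intensity_matrix` of the full graph.
#' @param q Beam width (number of models carried to the next round).
#' @param weights Length-2 non-negative vector `(w1, w2)` for
#'   [combined_score()].
#' @param options `fit_options` used for every fit.
#' @return A `subgraph_search` object: `ranking` data frame and the scored
#'   records in rank order.
#' @export
heuristic_search <- function(graph, observed, q = 3L,
                             weights = c(0.5, 0.5),
                             options = fit_options()) {
  stopifnot(q >= 1L)
  seen <- new.env(parent = emptyenv())
  rec0 <- .score_one(graph, graph, observed, weights, options)
  seen[[rec0$hash]] <- TRUE
  all_recs <- list(rec0)
  frontier <- list(rec0)
  top_hashes <- function() {
    ranked <- .rank_records(all_recs)
    vapply(utils::head(ranked, q), `[[`, character(1), "hash")
  }
  repeat {
    before <- top_hashes()
    added <- FALSE
    for (rec in frontier) {
      for (eid in terminal_reactions(rec$graph)) {
        trimmed <- trim_reaction(rec$graph, eid)
        h <- reaction_set_hash(trimmed)
        if (!is.null(seen[[h]])) next
        seen[[h]] <- TRUE
        nr <- .score_one(trimmed, graph, observed, weights, options,
                         parent = rec$hash)
        all_recs[[length(all_recs) + 1L]] <- nr
        added <- TRUE
      }
    }
    if (!added) break
    after <- top_hashes()
    if (setequal(before, after)) break
    frontier <- utils::head(.rank_records(all_recs), q)
  }
  .as_search_result(all_recs, length(all_recs), "heuristic")
}

#' Exhaustive subgraph enumeration (oracle for small graphs)
#'
#' Enumerates every subset of the rate-carrying reactions that yields a
#' connected, root-containing subgraph in which all kept reactions can
#' fire, fits and scores each one. Exponential in the reaction count and
#' therefore capped.
#'
#' @param graph A `degradation_graph`.
#' @param observed The `intensity_matrix` of the full graph.
#' @param weights Score weights, see [combined_score()].
#' @param options `fit_options`.
#' @param cap Maximum number of non-pseudo reactions (default 12).
#' @return A `subgraph_search` object.
#' @export
exhaustive_search <- function(graph, observed, weights = c(0.5, 0.5),
                              options = fit_options(), cap = 12L) {
  ids <- sort(reaction_edges(graph)$id)
  ne <- length(ids)
  if (ne > cap) {
    stop(sprintf(
      "graph has %d reactions; exhaustive enumeration capped at %d",
      ne, cap), call. = FALSE)
  }
  recs <- list()
  for (mask in 0:(2^ne - 1L)) {
    keep <- ids[bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L]
    sub <- subgraph_from_reactions(graph, keep)
    if (is.null(sub)) next
    recs[[length(recs) + 1L]] <-
      .score_one(sub, graph, observed, weights, options)
  }
  .as_search_result(recs, length(recs), "exhaustive")
}
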