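#' Build a degradation graph from a mass-spectrometry time series
#'
#' Implements the greedy construction loop: for every spectrum in turn, a
#' verification pass matches all current graph nodes by peptide mass
#' fingerprinting and queues the identified ones, then an extension pass
#' pops queued nodes and probes their possible degradation products — the
#' two single-terminal (exo) removals, and every internal cut whose *both*
#' fragments can be matched in the spectrum (endo). Newly created nodes are
#' queued for further extension within the same spectrum. Verification
#' never removes nodes; a node unmatched at a time point is simply missing
#' there.
#'
#' Every candidate sequence is matched at most once per spectrum (memoised),
#' so the total number of peak lookups is bounded by `N * n * (n + 1) / 2`
#' for a length-n seed and N spectra.
#'
#' When the two exo children of a node are isobaric (the I/L terminal
#' ambiguity) one canonical node — the lexicographically smaller sequence —
#' is kept and the alternative sequence is recorded in its
#' `ambiguous_with` annotation.
#'
#' @param timeseries An `ms_timeseries` (N >= 2 spectra).
#' @param seed Seed (base) peptide sequence.
#' @param tolerance Match tolerance (default 0.3 Da, MALDI reflector-scale
#'   PMF).
#' @param unit `"da"` or `"ppm"`.
#' @param charge Assumed charge state.
#' @param min_match_length Minimum fragment length eligible for PMF
#'   matching (default 2; free single amino acids fall below the usable
#'   mass range).
#' @return Object of class `degradation_build`: list with `graph`,
#'   `intensities` (an [intensity_matrix()] over the final graph's isobaric
#'   groups), `node_traces` (real nodes x times, `NA` = unmatched),
#'   `lookup_count` and `lookup_bound`.
#' @export
build_graph <- function(timeseries, seed, tolerance = 0.3, unit = "da",
                        charge = 1L, min_match_length = 2L) {
  stopifnot(inherits(timeseries, "ms_timeseries"))
  graph <- degradation_graph(seed)
  n_times <- length(timeseries$times)
  counter <- 0L
  ann <- new.env(parent = emptyenv())
  note <- function(node, j, intensity) {
    key <- node
    cur <- if (!is.null(ann[[key]])) ann[[key]] else rep(NA_real_, n_times)
    cur[j] <- intensity
    ann[[key]] <- cur
  }

  for (j in seq_len(n_times)) {
    spec <- timeseries$spectra[[j]]
    memo <- new.env(parent = emptyenv())
    lookup <- function(sequence) {
      if (nchar(sequence) < min_match_length) return(NULL)
      if (!is.null(memo[[sequence]])) {
        return(if (identical(memo[[sequence]], "miss")) NULL
               else memo[[sequence]])
      }
      hit <- match_peak(spec, compute_mass(sequence), tolerance, unit,
                        charge)
      counter <<- counter + 1L
      memo[[sequence]] <- if (is.null(hit)) "miss" else hit
      hit
    }

    ## verification: deterministic topological order, ties by sequence
    L <- character(0)
    queued <- character(0)
    for (v in topological_order(graph)) {
      if (graph$nodes$type[graph$nodes$id == v] != "peptide") next
      hit <- lookup(v)
      if (!is.null(hit)) {
        note(v, j, hit$intensity)
        L <- c(L, v)
        queued <- c(queued, v)
      }
    }

    ## extension: FIFO until the queue is exhausted
    extended <- character(0)
    push <- function(id) {
      if (!(id %in% queued)) {
        L <<- c(L, id)
        queued <<- c(queued, id)
      }
    }
    while (length(L) > 0L) {
      u <- L[1L]
      L <- L[-1L]
      if (u %in% extended) next
      extended <- c(extended, u)
      useq <- graph$nodes$sequence[graph$nodes$id == u]
      nu <- nchar(useq)
      if (nu < 2L) next

      kids <- exo_children(useq)
      if (length(kids) == 2L &&
          all(nchar(kids) >= min_match_length) &&
          abs(compute_mass(kids[1L]) - compute_mass(kids[2L])) < 1e-9 &&
          kids[1L] != kids[2L]) {
        ## isobaric exo pair (I/L-type ambiguity): keep the canonical child
        canon <- min(kids)
        other <- setdiff(kids, canon)
        hit <- lookup(canon)
        if (!is.null(hit)) {
          res <- add_exo_reaction(graph, u, canon, ambiguous_with = other)
          graph <- res$graph
          note(canon, j, hit$intensity)
          push(canon)
        }
      } else {
        for (child in kids) {
          hit <- lookup(child)
          if (!is.null(hit)) {
            res <- add_exo_reaction(graph, u, child)
            graph <- res$graph
            note(child, j, hit$intensity)
            push(child)
          }
        }
      }

      if (nu >= 2L) {
        sp <- endo_splits(useq)
        for (k in seq_len(nrow(sp))) {
          hp <- lookup(sp$prefix[k])
          if (is.null(hp)) next
          hs <- lookup(sp$suffix[k])
          if (is.null(hs)) next
          res <- add_endo_reaction(graph, u, sp$cut[k])
          graph <- res$graph
          note(sp$prefix[k], j, hp$intensity)
          note(sp$suffix[k], j, hs$intensity)
          push(sp$prefix[k])
          push(sp$suffix[k])
        }
      }
    }
  }

  rn <- real_nodes(graph)
  node_traces <- t(vapply(rn$id, function(id) {
    if (!is.null(ann[[id]])) ann[[id]] else rep(NA_real_, n_times)
  }, numeric(n_times)))
  rownames(node_traces) <- rn$id
  n_seed <- nchar(seed)
  structure(list(
    graph = graph,
    intensities = intensity_matrix(graph, timeseries, tolerance, unit,
                                   charge),
    node_traces = node_traces,
    lookup_count = counter,
    lookup_bound = n_times * n_seed * (n_seed + 1L) / 2L
  ), class = "degradation_build")
}

#' @export
print.degradation_build <- function(x, ...) {
  print(x$graph)
  cat(sprintf("peak lookups: %d (worst-case bound %d)\n",
              x$lookup_count, x$lookup_bound))
  invisible(x)
}
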