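#' Write a degradation graph to JSON
#'
#' The JSON schema is a direct image of the in-memory structure:
#' `{"format": "degradation-graph", "version": 1, "root": ...,
#' "nodes": [...], "edges": [...]}`. Any extra node or edge columns (e.g.
#' annotations added by callers) are carried through unchanged.
#'
#' @param graph A `degradation_graph`.
#' @param path Output file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_graph_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "degradation_graph"))
  obj <- list(format = "degradation-graph", version = 1L,
              root = graph$root, nodes = graph$nodes, edges = graph$edges)
  txt <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read a degradation graph from JSON
#'
#' @param path File path, or a JSON string produced by [write_graph_json()].
#' @return A `degradation_graph` (validated).
#' @export
read_graph_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop(sprintf(
                    "cannot parse graph JSON: %s", conditionMessage(e)),
                    call. = FALSE))
  if (!identical(obj$format, "degradation-graph")) {
    stop("not a degradation-graph JSON file (missing format marker)",
         call. = FALSE)
  }
  if (is.null(obj$nodes) || NROW(obj$nodes) == 0L) {
    stop("graph JSON contains no nodes", call. = FALSE)
  }
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- if (NROW(obj$edges) == 0L) {
    data.frame(id = character(0), source = character(0),
               target = character(0), kind = character(0),
               rate_param = character(0), stringsAsFactors = FALSE)
  } else as.data.frame(obj$edges, stringsAsFactors = FALSE)
  nodes$cut_pos <- as.integer(nodes$cut_pos)
  g <- structure(list(nodes = nodes, edges = edges, root = obj$root),
                 class = "degradation_graph")
  validate_graph(g)
  g
}

.graph_to_igraph <- function(graph, rates = NULL) {
  vdf <- graph$nodes
  names(vdf)[names(vdf) == "id"] <- "name"
  vdf$sequence[is.na(vdf$sequence)] <- ""
  vdf$parent_sequence[is.na(vdf$parent_sequence)] <- ""
  vdf$ambiguous_with[is.na(vdf$ambiguous_with)] <- ""
  vdf$cut_pos[is.na(vdf$cut_pos)] <- -1L
  vdf$mass[is.na(vdf$mass)] <- -1
  vdf$is_seed <- as.integer(vdf$is_seed)
  edf <- graph$edges[, c("source", "target", "id", "kind", "rate_param")]
  names(edf)[1:2] <- c("from", "to")
  edf$rate_param[is.na(edf$rate_param)] <- ""
  edf$rate <- if (is.null(rates)) -1 else {
    r <- rates[edf$id]
    r[is.na(r)] <- -1
    unname(r)
  }
  ig <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  igraph::graph_attr(ig, "root") <- graph$root
  ig
}

#' Export a degradation graph to GraphML
#'
#' Pseudo-nodes are flagged by the `type` vertex attribute; edge `rate`
#' attributes are filled from `rates` when supplied (e.g. from a fit), and
#' set to -1 otherwise.
#'
#' @param graph A `degradation_graph`.
#' @param path Output file path (.graphml).
#' @param rates Optional named vector of fitted rates, names = edge ids.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, rates = NULL) {
  ig <- .graph_to_igraph(graph, rates)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Read a degradation graph from GraphML
#'
#' @param path A .graphml file written by [write_graphml()].
#' @return A `degradation_graph` (validated).
#' @export
read_graphml <- function(path) {
  ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                 error = function(e) stop(sprintf(
                   "cannot parse GraphML file '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  vdf <- igraph::as_data_frame(ig, what = "vertices")
  edf <- igraph::as_data_frame(ig, what = "edges")
  nodes <- data.frame(
    id = vdf$name, type = vdf$type,
    sequence = ifelse(vdf$sequence == "", NA_character_, vdf$sequence),
    mass = ifelse(vdf$mass < 0, NA_real_, vdf$mass),
    is_seed = as.logical(vdf$is_seed),
    parent_sequence = ifelse(vdf$parent_sequence == "", NA_character_,
                             vdf$parent_sequence),
    cut_pos = ifelse(vdf$cut_pos < 0L, NA_integer_,
                     as.integer(vdf$cut_pos)),
    ambiguous_with = ifelse(vdf$ambiguous_with == "", NA_character_,
                            vdf$ambiguous_with),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    id = edf$id, source = edf$from, target = edf$to, kind = edf$kind,
    rate_param = ifelse(edf$rate_param == "", NA_character_,
                        edf$rate_param),
    stringsAsFactors = FALSE
  )
  root <- igraph::graph_attr(ig, "root")
  g <- structure(list(nodes = nodes, edges = edges, root = root),
                 class = "degradation_graph")
  validate_graph(g)
  g
}

#' Export a degradation graph to Graphviz DOT
#'
#' Peptide nodes are boxes labelled with sequence and mass; pseudo-nodes are
#' small diamonds; pseudo-edges are dashed; rate-carrying edges are labelled
#' with their fitted rate when `rates` is given.
#'
#' @param graph A `degradation_graph`.
#' @param path Output file path (.dot).
#' @param rates Optional named vector of fitted rates, names = edge ids.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path, rates = NULL) {
  q <- function(x) paste0('"', gsub('"', '\\"', x, fixed = TRUE), '"')
  lines <- c("digraph degradation {", "  rankdir=TB;")
  for (i in seq_len(nrow(graph$nodes))) {
    nd <- graph$nodes[i, ]
    if (nd$type == "pseudo") {
      lines <- c(lines, sprintf(
        "  %s [shape=diamond, width=0.25, height=0.25, label=%s];",
        q(nd$id), q(paste0("c=", nd$cut_pos))))
    } else {
      lines <- c(lines, sprintf(
        "  %s [shape=box, label=%s];", q(nd$id),
        q(sprintf("%s\\n%.3f Da", nd$sequence, nd$mass))))
    }
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    style <- if (e$kind == "pseudo") ", style=dashed" else ""
    lab <- ""
    if (e$kind != "pseudo" && !is.null(rates) && e$id %in% names(rates)) {
      lab <- sprintf(", label=%s", q(sprintf("%.3g/h", rates[[e$id]])))
    }
    lines <- c(lines, sprintf("  %s -> %s [%s%s%s];", q(e$source),
                              q(e$target),
                              sprintf("color=%s",
                                      if (e$kind == "endo") "red" else "black"),
                              style, lab))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
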