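test_that("exo reactions connect nodes differing by one terminal residue", {
  g <- degradation_graph("GAVLK")
  res <- add_exo_reaction(g, "GAVLK", "AVLK")
  g <- res$graph
  expect_identical(res$node_id, "AVLK")
  e <- g$edges[g$edges$id == res$edge_id, ]
  expect_identical(e$kind, "exo_N")
  # idempotent
  res2 <- add_exo_reaction(g, "GAVLK", "AVLK")
  expect_identical(nrow(res2$graph$edges), nrow(g$edges))
  expect_identical(nrow(res2$graph$nodes), nrow(g$nodes))
  # inconsistent child
  expect_error(add_exo_reaction(g, "GAVLK", "GAV"), "not an exo child")
  # single-residue parent cannot degrade further
  g2 <- add_exo_reaction(
    add_exo_reaction(g, "AVLK", "VLK")$graph, "VLK", "VL")$graph
  g2 <- add_exo_reaction(g2, "VL", "V")$graph
  expect_error(add_exo_reaction(g2, "V", ""), "single-residue")
})

test_that("endo reactions create a pseudo-node wired to both fragments", {
  g <- degradation_graph("GAVLK")
  res <- add_endo_reaction(g, "GAVLK", 2L)
  g <- res$graph
  expect_identical(res$child_ids, c("GA", "VLK"))
  pn <- g$nodes[g$nodes$id == res$pseudo_id, ]
  expect_identical(pn$type, "pseudo")
  expect_identical(pn$cut_pos, 2L)
  inc <- g$edges[g$edges$target == res$pseudo_id, ]
  out <- g$edges[g$edges$source == res$pseudo_id, ]
  expect_identical(nrow(inc), 1L)
  expect_identical(inc$kind, "endo")
  expect_identical(nrow(out), 2L)
  expect_true(all(out$kind == "pseudo"))
  expect_true(all(is.na(out$rate_param)))
  expect_silent(validate_graph(g))
  # idempotent
  res2 <- add_endo_reaction(g, "GAVLK", 2L)
  expect_identical(nrow(res2$graph$edges), nrow(g$edges))
  expect_error(add_endo_reaction(g, "GAVLK", 5L), "cut position")
})

test_that("graphs stay acyclic and fully reachable, and edges shorten sequences", {
  sys <- preset_system("branched_endo_large")
  g <- sys$graph
  expect_silent(validate_graph(g))
  ord <- topological_order(g)
  pos <- stats::setNames(seq_along(ord), ord)
  for (i in seq_len(nrow(g$edges))) {
    expect_lt(pos[[g$edges$source[i]]], pos[[g$edges$target[i]]])
  }
  re <- reaction_edges(g)
  len <- function(id) nchar(g$nodes$sequence[g$nodes$id == id])
  for (i in seq_len(nrow(re))) {
    if (re$kind[i] == "endo") next
    expect_lt(len(re$target[i]), len(re$source[i]))
  }
})

test_that("complete degradation closure has at most n(n+1)/2 peptide nodes", {
  seq0 <- "GAVLKF"
  n <- nchar(seq0)
  g <- degradation_graph(seq0)
  frontier <- seq0
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (p in frontier) {
      for (child in exo_children(p)) {
        isnew <- !(child %in% g$nodes$id)
        g <- add_exo_reaction(g, p, child)$graph
        if (isnew) nxt <- c(nxt, child)
      }
      if (nchar(p) >= 2L) {
        for (cut in seq_len(nchar(p) - 1L)) {
          pre_new <- !(substr(p, 1, cut) %in% g$nodes$id)
          suf_new <- !(substr(p, cut + 1, nchar(p)) %in% g$nodes$id)
          res <- add_endo_reaction(g, p, cut)
          g <- res$graph
          nxt <- c(nxt, res$child_ids[c(pre_new, suf_new)])
        }
      }
    }
    frontier <- unique(nxt)
  }
  expect_lte(nrow(real_nodes(g)), n * (n + 1) / 2)
  expect_silent(validate_graph(g))
})

test_that("isobaric grouping is single-linkage within tolerance", {
  g <- degradation_graph("GAVLK")
  g <- add_exo_reaction(g, "GAVLK", "AVLK")$graph
  gr0 <- isobaric_groups(g, tolerance = 0)
  expect_length(gr0$mass, 2L)
  gr_big <- isobaric_groups(g, tolerance = 100)
  expect_length(gr_big$mass, 1L)
  expect_equal(gr_big$mass,
               mean(real_nodes(g)$mass))
  # equal-mass I/L variants share a group at tolerance 0
  g2 <- degradation_graph("IHPFHL")
  g2 <- add_exo_reaction(g2, "IHPFHL", "IHPFH")$graph
  g2 <- add_exo_reaction(g2, "IHPFHL", "HPFHL")$graph
  gr2 <- isobaric_groups(g2, tolerance = 0)
  sizes <- vapply(gr2$members, length, integer(1))
  expect_identical(sort(sizes), c(1L, 2L))
})

test_that("subgraph restriction keeps only firable reactions", {
  sys <- preset_system("branched_endo_small")
  ids <- reaction_edges(sys$graph)$id
  full <- subgraph_from_reactions(sys$graph, ids)
  expect_same_reactions(full, sys$graph)
  # an orphan reaction (substrate unreachable) invalidates the subset
  endo_id <- ids[grepl("^endo", ids)]
  downstream <- setdiff(ids, endo_id)
  expect_null(subgraph_from_reactions(sys$graph, downstream[1]))
  # root-only subgraph
  sub0 <- subgraph_from_reactions(sys$graph, character(0))
  expect_identical(nrow(real_nodes(sub0)), 1L)
  expect_silent(validate_graph(sub0))
})

test_that("JSON serialization round-trips, rejects empty graphs, keeps extras", {
  sys <- preset_system("branched_endo_small")
  g <- sys$graph
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, path)
  g2 <- read_graph_json(path)
  expect_identical(g2$root, g$root)
  expect_identical(g2$nodes$id, g$nodes$id)
  expect_identical(g2$edges$id, g$edges$id)
  expect_equal(g2$nodes$mass, g$nodes$mass)
  # unknown node attribute passes through
  g$nodes$note <- paste0("n", seq_len(nrow(g$nodes)))
  write_graph_json(g, path)
  g3 <- read_graph_json(path)
  expect_identical(g3$nodes$note, g$nodes$note)
  # malformed / empty input
  writeLines('{"format": "degradation-graph", "nodes": []}', path)
  expect_error(read_graph_json(path), "no nodes")
  writeLines("not json at all {", path)
  expect_error(read_graph_json(path), "parse")
})

test_that("GraphML round-trips through igraph with pseudo-nodes flagged", {
  sys <- preset_system("branched_endo_medium")
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(sys$graph, path, rates = sys$rates)
  g2 <- read_graphml(path)
  expect_identical(sort(g2$nodes$id), sort(sys$graph$nodes$id))
  expect_setequal(g2$edges$id, sys$graph$edges$id)
  expect_identical(g2$root, sys$graph$root)
  expect_identical(sum(g2$nodes$type == "pseudo"),
                   sum(sys$graph$nodes$type == "pseudo"))
  expect_silent(validate_graph(g2))
})

test_that("DOT export writes parseable text with pseudo-node styling", {
  sys <- preset_system("branched_endo_small")
  path <- withr::local_tempfile(fileext = ".dot")
  write_dot(sys$graph, path, rates = sys$rates)
  txt <- readLines(path)
  expect_identical(txt[1], "digraph degradation {")
  expect_true(any(grepl("diamond", txt)))
  expect_true(any(grepl("style=dashed", txt)))
  expect_true(any(grepl("/h", txt)))
})
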