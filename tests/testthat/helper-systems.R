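# Shared fixtures, all built in code.

# Two-step chain with an I/L-ambiguous first product: the exo children of
# IHPFHL (HPFHL and IHPFH) are isobaric, so reconstruction must pick a
# canonical node and record the alternative.
il_system <- function() {
  g <- degradation_graph("IHPFHL")
  r1 <- add_exo_reaction(g, "IHPFHL", "IHPFH")
  g <- r1$graph
  r2 <- add_exo_reaction(g, "IHPFH", "HPFH")
  g <- r2$graph
  ground_truth_system(
    g, stats::setNames(c(0.7, 0.3), c(r1$edge_id, r2$edge_id)),
    name = "il_ambiguous")
}

# Tiny 2-reaction system used where fit speed matters more than realism.
tiny_chain <- function(k1 = 0.8, k2 = 0.3) {
  g <- degradation_graph("GAVLK")
  r1 <- add_exo_reaction(g, "GAVLK", "AVLK")
  g <- r1$graph
  r2 <- add_exo_reaction(g, "AVLK", "AVL")
  g <- r2$graph
  ground_truth_system(
    g, stats::setNames(c(k1, k2), c(r1$edge_id, r2$edge_id)),
    name = "tiny_chain")
}

# Peak list containing every substring (length >= min_len) of a sequence,
# all at unit intensity: the builder's fully-matching worst case.
all_substring_peaks <- function(sequence, min_len = 1L, intensity = 100) {
  n <- nchar(sequence)
  subs <- unique(unlist(lapply(seq_len(n), function(a) {
    vapply(a:n, function(b) substr(sequence, a, b), character(1))
  })))
  subs <- subs[nchar(subs) >= min_len]
  mz <- unique(round(mass_to_mz(vapply(subs, compute_mass, numeric(1))), 6))
  peak_list(mz, rep(intensity, length(mz)))
}

expect_same_reactions <- function(graph_a, graph_b) {
  expect_setequal(reaction_edges(graph_a)$id, reaction_edges(graph_b)$id)
}
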