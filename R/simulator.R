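#' Define a ground-truth proteolytic system for simulation
#'
#' @param graph A validated `degradation_graph` (the true structure).
#' @param rates Named positive vector, one rate (1/h) per non-pseudo edge.
#' @param x0 True initial concentration of the seed peptide (a.u.).
#' @param c_p Transformation factors: single number or named vector over
#'   peptide nodes.
#' @param name System label.
#' @return Object of class `ground_truth_system`.
#' @export
ground_truth_system <- function(graph, rates, x0 = 10, c_p = 1,
                                name = "custom") {
  validate_graph(graph)
  re <- reaction_edges(graph)
  if (!setequal(names(rates), re$id)) {
    stop("rates must be named by the graph's non-pseudo edge ids",
         call. = FALSE)
  }
  if (any(rates <= 0)) stop("true rates must be > 0", call. = FALSE)
  rn <- real_nodes(graph)
  if (length(c_p) == 1L && is.null(names(c_p))) {
    c_p <- stats::setNames(rep(c_p, nrow(rn)), rn$id)
  }
  if (!all(rn$id %in% names(c_p)) || any(c_p[rn$id] <= 0)) {
    stop("c_p must be positive and cover every peptide node",
         call. = FALSE)
  }
  structure(list(graph = graph, rates = rates[sort(names(rates))],
                 x0 = x0, c_p = c_p[rn$id], name = name),
            class = "ground_truth_system")
}

#' @export
print.ground_truth_system <- function(x, ...) {
  cat(sprintf("ground-truth system '%s'\n", x$name))
  print(x$graph)
  invisible(x)
}

#' Built-in ground-truth systems
#'
#' `fpa_chain` is the fibrinopeptide-A N-terminal exo chain
#' DSGEGDFLAEGGGVR -> SGEGDFLAEGGGVR -> GEGDFLAEGGGVR -> EGDFLAEGGGVR
#' (3 exo reactions). The `branched_endo_*` systems mix endo- and
#' exoproteolytic reactions on peptide seeds of increasing length
#' (angiotensin I 10-mer, an endothelin-1 21-mer fragment, and
#' somatostatin-28), giving graphs with pseudo-nodes and branch points.
#' Rates are package defaults chosen so that the seed is mostly consumed
#' and every product visibly rises within the 5 h observation window.
#'
#' @param name One of `"fpa_chain"`, `"branched_endo_small"`,
#'   `"branched_endo_medium"`, `"branched_endo_large"`.
#' @return A `ground_truth_system`.
#' @export
preset_system <- function(name) {
  presets <- c("fpa_chain", "branched_endo_small", "branched_endo_medium",
               "branched_endo_large")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets)) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 as.character(name)[1L], paste(presets, collapse = ", ")),
         call. = FALSE)
  }
  exo <- function(g, parent, child, k) {
    r <- add_exo_reaction(g$graph, parent, child)
    g$graph <- r$graph
    g$rates[r$edge_id] <- k
    g
  }
  endo <- function(g, parent, cut, k) {
    r <- add_endo_reaction(g$graph, parent, cut)
    g$graph <- r$graph
    g$rates[paste("endo", parent, r$pseudo_id, sep = ":")] <- k
    g
  }
  g <- switch(name,
    fpa_chain = {
      s <- list(graph = degradation_graph("DSGEGDFLAEGGGVR"),
                rates = numeric(0))
      s <- exo(s, "DSGEGDFLAEGGGVR", "SGEGDFLAEGGGVR", 1.2)
      s <- exo(s, "SGEGDFLAEGGGVR", "GEGDFLAEGGGVR", 0.6)
      exo(s, "GEGDFLAEGGGVR", "EGDFLAEGGGVR", 0.3)
    },
    branched_endo_small = {
      s <- list(graph = degradation_graph("DRVYIHPFHL"),
                rates = numeric(0))
      s <- endo(s, "DRVYIHPFHL", 5L, 0.8)
      s <- exo(s, "DRVYI", "DRVY", 0.4)
      exo(s, "HPFHL", "PFHL", 0.25)
    },
    branched_endo_medium = {
      s <- list(graph = degradation_graph("CSCSSLMDKECVYFCHLDIIW"),
                rates = numeric(0))
      s <- endo(s, "CSCSSLMDKECVYFCHLDIIW", 10L, 0.9)
      s <- endo(s, "CVYFCHLDIIW", 5L, 0.5)
      s <- exo(s, "CSCSSLMDKE", "SCSSLMDKE", 0.35)
      s <- exo(s, "SCSSLMDKE", "SCSSLMDK", 0.2)
      exo(s, "HLDIIW", "HLDII", 0.15)
    },
    branched_endo_large = {
      s <- list(graph = degradation_graph("SANSNPAMAPRERKAGCKNFFWKTFTSC"),
                rates = numeric(0))
      s <- endo(s, "SANSNPAMAPRERKAGCKNFFWKTFTSC", 14L, 1.0)
      s <- endo(s, "SANSNPAMAPRERK", 10L, 0.45)
      s <- exo(s, "SANSNPAMAPRERKAGCKNFFWKTFTSC",
               "ANSNPAMAPRERKAGCKNFFWKTFTSC", 0.3)
      s <- exo(s, "AGCKNFFWKTFTSC", "AGCKNFFWKTFTS", 0.25)
      s <- exo(s, "AGCKNFFWKTFTS", "AGCKNFFWKTFT", 0.12)
      exo(s, "RERK", "ERK", 0.1)
    })
  ground_truth_system(g$graph, g$rates, x0 = 10, c_p = 1, name = name)
}

#' Random ground-truth system
#'
#' Draws a random degradation process for oracle experiments: a random
#' seed peptide, a random mix of exo and endo reactions applied to
#' randomly chosen existing peptides, and rates drawn uniformly from
#' `rate_range`. Deterministic given `seed`; the caller's RNG state is
#' untouched.
#'
#' @param seed Integer RNG seed.
#' @param n_reactions Number of rate-carrying reactions to draw.
#' @param seq_length Length of the random seed peptide.
#' @param rate_range Range the true rates are drawn from (1/h).
#' @param p_endo Probability that a drawn reaction is endoproteolytic.
#' @return A `ground_truth_system`.
#' @export
random_system <- function(seed, n_reactions = 4L, seq_length = 12L,
                          rate_range = c(0.15, 1.2), p_endo = 0.35) {
  stopifnot(seq_length >= 4L, n_reactions >= 1L)
  rng <- .seeded_rng(seed)
  aa <- names(mass_table()$residues)
  seq0 <- paste(aa[rng$sample_int(20L, seq_length, replace = TRUE)],
                collapse = "")
  graph <- degradation_graph(seq0)
  rates <- numeric(0)
  guard <- 0L
  while (length(rates) < n_reactions && guard < 200L) {
    guard <- guard + 1L
    rn <- real_nodes(graph)
    rn <- rn[nchar(rn$sequence) >= 3L, , drop = FALSE]
    if (nrow(rn) == 0L) break
    parent <- rn$id[rng$sample_int(nrow(rn), 1L)]
    plen <- nchar(parent)
    k <- rate_range[1L] + diff(rate_range) * rng$runif(1L)
    if (rng$runif(1L) < p_endo && plen >= 4L) {
      cut <- 1L + rng$sample_int(plen - 3L, 1L)  # keep fragments >= 2
      pid <- paste0(parent, "|", cut)
      eid <- paste("endo", parent, pid, sep = ":")
      if (eid %in% names(rates)) next
      res <- add_endo_reaction(graph, parent, cut)
      graph <- res$graph
      rates[eid] <- k
    } else {
      kids <- exo_children(parent)
      kids <- kids[nchar(kids) >= 2L]
      if (length(kids) == 0L) next
      child <- kids[rng$sample_int(length(kids), 1L)]
      ## skip children that collide with an existing distinct sequence
      ## mass (keeps the oracle instances clean of accidental isobars)
      res <- add_exo_reaction(graph, parent, child)
      eid <- res$edge_id
      if (eid %in% names(rates)) next
      graph <- res$graph
      rates[eid] <- k
    }
  }
  ground_truth_system(graph, rates, x0 = 10, c_p = 1,
                      name = sprintf("random_%d", seed))
}

#' Sampling-time schemes for simulated time series
#'
#' The `study1` scheme reproduces the dense-early design: 10 points over
#' 5 h, five during the first hour and five spread equally over the
#' remaining four hours. `uniform` gives `n` equally spaced points over
#' `(0, t_max]`; `explicit` passes `times` through after validation.
#'
#' @param scheme `"study1"`, `"uniform"` or `"explicit"`.
#' @param n,t_max Parameters of the `uniform` scheme.
#' @param times Explicit strictly increasing time vector.
#' @return Numeric vector of acquisition times (hours).
#' @export
sample_times <- function(scheme = c("study1", "uniform", "explicit"),
                         n = 10L, t_max = 5, times = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    study1 = c(seq(0.2, 1, by = 0.2), seq(1.8, 5, by = 0.8)),
    uniform = {
      stopifnot(n >= 2L, t_max > 0)
      seq(t_max / n, t_max, length.out = n)
    },
    explicit = {
      if (is.null(times) || any(diff(times) <= 0)) {
        stop("explicit scheme needs a strictly increasing time vector",
             call. = FALSE)
      }
      as.numeric(times)
    })
}

## Deterministic decoy placement: decoys mimic *possible* fragments (exo
## children of true nodes that are not themselves true products) so the
## greedy builder picks them up, while staying >= 1.5 * tolerance away
## from every true group mass so they never steal a true match.
.decoy_candidates <- function(system, tolerance) {
  truth_seqs <- real_nodes(system$graph)$sequence
  order_ids <- intersect(topological_order(system$graph), truth_seqs)
  true_mass <- vapply(truth_seqs, compute_mass, numeric(1))
  cands <- character(0)
  for (p in order_ids) {
    for (child in sort(exo_children(p))) {
      if (child %in% truth_seqs || child %in% cands) next
      if (nchar(child) < 2L) next
      m <- compute_mass(child)
      if (min(abs(true_mass - m)) < 1.5 * tolerance) next
      cands <- c(cands, child)
    }
  }
  cands
}

#' Simulate a ground-truthed mass-spectrometry time series
#'
#' Integrates the true ODE system, transforms concentrations into
#' noise-free group intensities (`I = c_p * x`, isobars pooled), applies
#' multiplicative Gaussian noise `I * max(1 + e, 0)` with
#' `e ~ N(0, cv)` (signal variability as an intensity-dependent deviation,
#' truncated so intensities stay non-negative), optionally injects decoy
#' peaks at masses of plausible-but-false fragments, and emits one
#' centroided peak list per time point. Regenerating with the same seed is
#' bit-identical; the caller's RNG state is left untouched.
#'
#' @param system A `ground_truth_system`.
#' @param times Acquisition times, see [sample_times()].
#' @param cv Signal variability (standard deviation as a fraction of the
#'   true intensity; 0 = noise-free).
#' @param decoys Number of decoy peaks to inject (0 = none).
#' @param seed Integer RNG seed.
#' @param decoy_dynamics `"flat"`, `"decay"` or `"random_walk"` — the
#'   decoy intensity time course.
#' @param decoy_level Decoy intensity as a fraction of the largest
#'   noise-free signal.
#' @param decoy_offset Mass offset (Da) added to each decoy's fragment
#'   mass; must stay below `tolerance` for the decoy to be matchable.
#' @param tolerance Match tolerance the decoy placement respects.
#' @param charge Charge state for the emitted m/z values.
#' @return Object of class `simulation_record`: list with `timeseries`
#'   (an [ms_timeseries()]), `clean` and `noisy` group-intensity matrices,
#'   `group_mass`, `decoys` (data frame with sequence, mass, m/z), the
#'   inputs, and the seed.
#' @export
simulate_system <- function(system, times = sample_times("study1"),
                            cv = 0.1, decoys = 0L, seed = 1L,
                            decoy_dynamics = c("flat", "decay",
                                               "random_walk"),
                            decoy_level = 0.2, decoy_offset = 0.05,
                            tolerance = 0.3, charge = 1L) {
  stopifnot(inherits(system, "ground_truth_system"), cv >= 0)
  decoy_dynamics <- match.arg(decoy_dynamics)
  model <- graph_to_ode(system$graph, group_tolerance = tolerance)
  traj <- integrate_kinetics(model, system$rates, system$x0, times)
  clean <- predict_intensities(traj, model, system$c_p)
  nt <- length(times)

  decoy_df <- data.frame(sequence = character(0), mass = numeric(0),
                         mz = numeric(0), stringsAsFactors = FALSE)
  decoy_clean <- matrix(0, 0L, nt)
  if (decoys > 0L) {
    cands <- .decoy_candidates(system, tolerance)
    if (length(cands) < decoys) {
      stop(sprintf("only %d decoy candidate fragments available",
                   length(cands)), call. = FALSE)
    }
    picked <- cands[seq_len(decoys)]
    mass <- vapply(picked, compute_mass, numeric(1)) + decoy_offset
    decoy_df <- data.frame(sequence = picked, mass = mass,
                           mz = mass_to_mz(mass, charge),
                           stringsAsFactors = FALSE)
  }

  rng <- .seeded_rng(seed)
  noisy <- clean
  if (cv > 0) {
    eps <- matrix(rng$rnorm(length(clean), sd = cv), nrow(clean), nt)
    noisy <- clean * pmax(1 + eps, 0)
  }
  if (decoys > 0L) {
    base_level <- decoy_level * max(clean)
    decoy_clean <- t(vapply(seq_len(decoys), function(i) {
      switch(decoy_dynamics,
        flat = rep(base_level, nt),
        decay = base_level * exp(-0.5 * times),
        random_walk = base_level *
          cumprod(exp(rng$rnorm(nt, sd = 0.15))))
    }, numeric(nt)))
    decoy_noisy <- decoy_clean
    if (cv > 0) {
      eps_d <- matrix(rng$rnorm(length(decoy_clean), sd = cv),
                      decoys, nt)
      decoy_noisy <- decoy_clean * pmax(1 + eps_d, 0)
    }
  }

  group_mz <- mass_to_mz(model$groups$mass, charge)
  spectra <- lapply(seq_len(nt), function(j) {
    mz <- group_mz
    ii <- noisy[, j]
    if (decoys > 0L) {
      mz <- c(mz, decoy_df$mz)
      ii <- c(ii, decoy_noisy[, j])
    }
    keep <- ii > 0
    peak_list(mz[keep], ii[keep])
  })

  structure(list(
    timeseries = ms_timeseries(times, spectra),
    clean = clean, noisy = noisy, group_mass = model$groups$mass,
    decoys = decoy_df, system = system, times = times, cv = cv,
    seed = seed
  ), class = "simulation_record")
}

#' Compare a reconstructed degradation graph against the ground truth
#'
#' Reactions are matched between truth and reconstruction by their
#' (substrate, product, mechanism) identity; a reconstruction node that
#' records an isobaric alternative (`ambiguous_with`, the I/L case) counts
#' as matching either sequence, and for such ambiguous products the exo
#' terminus label is not held against the match (the two readings remove
#' opposite termini). Rate errors are reported for matched reactions when
#' a fit is supplied.
#'
#' @param truth A `ground_truth_system` (or `degradation_graph`).
#' @param reconstructed The reconstructed `degradation_graph`.
#' @param fit Optional `kinetic_fit` on the reconstructed graph.
#' @return Object of class `recovery_report`: `precision`, `recall`,
#'   `n_truth`, `n_recon`, `rates` (data frame with true and estimated
#'   rate and relative error per matched reaction) and
#'   `median_rate_error`.
#' @export
recovery_report <- function(truth, reconstructed, fit = NULL) {
  truth_graph <- if (inherits(truth, "ground_truth_system")) truth$graph
                 else truth
  true_rates <- if (inherits(truth, "ground_truth_system")) truth$rates
                else NULL

  alt <- function(graph) {
    rn <- real_nodes(graph)
    out <- list()
    for (i in seq_len(nrow(rn))) {
      a <- c(rn$sequence[i],
             if (!is.na(rn$ambiguous_with[i]))
               strsplit(rn$ambiguous_with[i], ";", fixed = TRUE)[[1L]])
      out[[rn$id[i]]] <- a
    }
    out
  }
  recon_alt <- alt(reconstructed)

  key <- function(graph, e) {
    if (e$kind == "endo") {
      p <- graph$nodes[graph$nodes$id == e$target, ]
      sprintf("endo:%s@%d", e$source, p$cut_pos)
    } else {
      sprintf("%s:%s>%s", e$kind, e$source, e$target)
    }
  }
  te <- reaction_edges(truth_graph)
  re <- reaction_edges(reconstructed)
  truth_keys <- vapply(seq_len(nrow(te)),
                       function(i) key(truth_graph, te[i, ]), character(1))

  ## equivalence of a reconstructed edge with a truth edge, honouring
  ## recorded isobaric alternatives on source and target
  matches <- function(i_re, i_te) {
    a <- re[i_re, ]
    b <- te[i_te, ]
    if ((a$kind == "endo") != (b$kind == "endo")) return(FALSE)
    src_ok <- b$source %in% recon_alt[[a$source]]
    if (!src_ok) return(FALSE)
    if (a$kind == "endo") {
      pa <- reconstructed$nodes[reconstructed$nodes$id == a$target, ]
      pb <- truth_graph$nodes[truth_graph$nodes$id == b$target, ]
      return(pa$cut_pos == pb$cut_pos)
    }
    tgt_ok <- b$target %in% recon_alt[[a$target]]
    if (!tgt_ok) return(FALSE)
    ambiguous <- length(recon_alt[[a$target]]) > 1L ||
      length(recon_alt[[a$source]]) > 1L
    a$kind == b$kind || ambiguous
  }

  matched_te <- rep(NA_integer_, nrow(te))
  for (i in seq_len(nrow(re))) {
    for (j in seq_len(nrow(te))) {
      if (!is.na(matched_te[j])) next
      if (matches(i, j)) {
        matched_te[j] <- i
        break
      }
    }
  }
  n_matched <- sum(!is.na(matched_te))
  precision <- if (nrow(re) == 0L) 1 else n_matched / nrow(re)
  recall <- if (nrow(te) == 0L) 1 else n_matched / nrow(te)

  rates <- data.frame(reaction = character(0), true = numeric(0),
                      estimated = numeric(0), rel_error = numeric(0),
                      stringsAsFactors = FALSE)
  if (!is.null(fit) && !is.null(true_rates)) {
    for (j in which(!is.na(matched_te))) {
      i <- matched_te[j]
      k_true <- unname(true_rates[te$id[j]])
      k_est <- unname(fit$rates[re$id[i]])
      if (is.na(k_true) || is.na(k_est)) next
      rates <- rbind(rates, data.frame(
        reaction = truth_keys[j], true = k_true, estimated = k_est,
        rel_error = abs(k_est - k_true) / k_true,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(
    precision = precision, recall = recall, n_truth = nrow(te),
    n_recon = nrow(re), rates = rates,
    median_rate_error = if (nrow(rates) > 0)
      stats::median(rates$rel_error) else NA_real_
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery: precision %.3f, recall %.3f (%d true, %d reconstructed)\n",
    x$precision, x$recall, x$n_truth, x$n_recon))
  if (nrow(x$rates) > 0) {
    cat(sprintf("median relative rate error: %.4f\n",
                x$median_rate_error))
  }
  invisible(x)
}
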