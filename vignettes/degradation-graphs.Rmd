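---
title: "Modelling proteolytic processes with degradation graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling proteolytic processes with degradation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degraph)
```

## The problem

When a peptide probe is incubated with proteases — a purified enzyme, or
an uncharacterized mixture such as urine proteins — it is progressively
cut into fragments. MALDI-TOF spectra taken at successive incubation
times show the substrate peak shrinking while fragment peaks appear and
grow. Two reaction mechanisms generate fragments: *exoproteolytic*
cleavage removes a single residue from the N- or C-terminus, and
*endoproteolytic* cleavage cuts at an internal position, producing two
fragments at once. The analysis goal is threefold: recover which
fragments arose, which reactions connect them, and how fast each
reaction ran.

`degraph` represents the answer as a **degradation graph**: peptides are
nodes, reactions are directed edges from the degraded to the generated
peptide. An endo cleavage of peptide $u$ after residue $c$ is mediated
by a *pseudo-node* $v_{u,c}$ — one rate-carrying edge enters it from
$u$, and two rate-free *pseudo-edges* leave it to the prefix
$s(u)[1..c]$ and suffix $s(u)[c+1..]$, so that one reaction remains one
rate even though it has two products.

## Graph construction from peak lists

`build_graph()` alternates two steps over the spectra in time order:

* **Verification** — every peptide currently in the graph is looked up
  in the spectrum by peptide mass fingerprinting (the most intense peak
  within the m/z tolerance window wins; ties go to the smaller mass
  error, then the lower m/z). Matched nodes enter a FIFO queue.
  Verification never deletes nodes: a fragment that was seen once stays
  in the graph and simply has a missing observation at times where its
  peak is absent.
* **Extension** — nodes are popped from the queue; their two exo
  children are matched, and every internal cut is probed, a pseudo-node
  being added only when *both* fragments of the cut are found in the
  same spectrum. New nodes join the queue, so a product can cascade
  within one spectrum.

Matching is memoised per spectrum, which bounds the total number of
peak lookups by $N \cdot n(n+1)/2$ for a length-$n$ seed and $N$
spectra — the number of distinct substrings is the worst case, and the
test suite asserts the bound on a fully matching series.

The construction is deliberately greedy: any signal that could be a
fragment of the seed is taken in, including *decoy* signals that merely
happen to sit at a plausible fragment mass. Pruning those is the job of
the structure search, not of construction.

Two conventions matter downstream:

* Cut positions are 1-based and mean "after residue $c$".
* When the two exo children of a node are isobaric — the classic case
  being a peptide with isoleucine at one terminus and leucine at the
  other, whose two single-residue removals weigh exactly the same — the
  spectrum cannot distinguish them. The builder keeps one canonical
  node (the lexicographically smaller sequence) and records the other
  reading in the node's `ambiguous_with` annotation, so the ambiguity
  is visible rather than silently duplicated as two states with
  identical evidence.

## Kinetics

Each reaction is first-order mass action in its substrate: exo
$u \to v$ with rate $k$ contributes $-k[u]$ to $d[u]/dt$ and $+k[u]$ to
$d[v]/dt$; endo $u \to (v, w)$ feeds both products with the same flux,
so molecule count grows at endo events. The seed has a fixed starting
concentration and no production term (the incubation is ex vivo), and
saturation of products is neglected. The system is therefore linear
with constant coefficients, $\dot{x} = A(k)\,x$.

Because the graph is acyclic, $A$ is triangular in topological order
and `integrate_kinetics()` solves it by eigendecomposition — repeated
eigenvalues are fine as long as $A$ is diagonalizable, which covers the
common case of several terminal products (all eigenvalue 0). Defective
cases (e.g. equal-rate chains) fall back to the matrix exponential,
computed once per distinct time step and propagated. A generic stiff
solver (`deSolve::lsoda`) is available as an independent cross-check;
the test suite holds all paths together to $10^{-8}$.

A mass spectrometer reports intensities, not concentrations. For a
single peptide a linear relationship is a standard and reasonable
assumption, so each peptide carries a transformation factor $c_p > 0$
and the predicted intensity of an observed mass $m$ is the linear
combination over its isobaric group,
$I(m, t) = \sum_{p \in P(m)} c_p x_p(t)$. Peptides whose masses fall
within the grouping tolerance are pooled by single linkage and share
one observed trace.

## Parameter estimation

`fit_kinetics()` minimizes the weighted least-squares objective

$$E = \sum_{m} \sum_{j} w(m, t_j)\,\bigl(I_{obs}(m, t_j) -
I_{model}(m, t_j)\bigr)^2$$

over the rates, the transformation factors and the seed's initial
concentration. Missing observations contribute no term — absence of a
peak reflects detectability, not zero concentration. The default
*relative* weighting $w = 1/\max(I_{obs}, \varepsilon)^2$ (with
$\varepsilon$ a floor of $10^{-6}$ times the largest observed
intensity) keeps traces of different magnitude comparable; absolute
weighting is available.

Numerically the fit exploits that $E$ is linear in the $c_p$: for any
candidate rate vector the optimal factors of each mass group solve a
small weighted linear least-squares problem in closed form (clipped to
stay positive), and the bounded Levenberg–Marquardt iteration
(`minpack.lm::nls.lm`, rates bounded below by 0) runs over the rates
alone. This variable projection halves the parameter count, removes
the scale-gauge direction from the nonlinear search, and in practice
converges in tens of iterations.

Two structural facts deserve explicit handling:

* **Scale gauge.** $I = c_p\,x(t; x_0)$ is invariant under
  $(c_p/\alpha,\ \alpha x_0)$. With $x_0$ free (the default) the fit
  reports the representative with $\overline{c_p} = 1$; pinning
  `x0_fixed` in `fit_options()` fixes the scale instead. Ratios of
  transformation factors and all rates are gauge-invariant and hence
  comparable across runs.
* **Initial values.** Nothing is known about the system a priori, so
  rates start from a shortest-path scheme: for every node the incoming
  reaction on a shortest reaction path to the root starts at
  `r_primary` (default 1.0 / h), all other incoming reactions at
  `r_secondary` (default 0.01 / h), and all factors at `c_init = 1`.
  Primary-path reactions dominate the early dynamics, which is what
  makes this a sensible start; ties are broken lexicographically so
  fits are reproducible to the bit. The returned objective is never
  allowed to exceed the scheme start's objective.

Degenerate inputs (no usable signal) return a flagged,
non-converged result with finite objective rather than an exception.

## Scoring and structure search

Greedy construction overestimates the process, so subgraphs of the
initial graph (connected, root-containing) are ranked by a
two-component score:

* $S_{corr}$ — the mean Pearson correlation between observed and
  predicted traces over the mass groups the subgraph explains. Flat
  traces (zero variance on either side) contribute 0: a constant signal
  carries no dynamic evidence.
* $S_{var} = \sum_{m \in M_{G'}} \sigma_m / \sum_{m \in M_G} \sigma_m$
  — the fraction of the full graph's total signal standard deviation
  that the subgraph retains. It is 1 for the full graph, and dropping
  only flat decoys keeps it at 1; it is defined as 1 when all
  $\sigma_m$ are zero.

The combined score is $S = w_1 S_{corr} + w_2 S_{var}$ with weights
normalized to sum 1. The default is $w = (0.5, 0.5)$; for low-quality
data (heavy noise, sparse sampling) a preset shifting weight toward
$S_{var}$, e.g. $(0.3, 0.7)$, is the documented alternative, reflecting
that the fit component is then the less reliable witness.

`heuristic_search()` is a beam search: the frontier starts at the full
graph; each round removes every removable reaction of every frontier
graph separately, fits and scores each new subgraph (deduplicated by
reaction set, so nothing is fitted twice), and carries the global top
$q$ (default 3) into the next round. It stops when a round adds nothing
to the global top $q$. The stopping phrase admits a second reading —
continue while *any* evaluated graph outside the top $q$ is untrimmed —
which would make the search nearly exhaustive; the implemented rule is
the beam-style one, and `exhaustive_search()` (capped at 12 reactions)
is provided as the oracle for small instances.

The removable set contains reactions that produce at least one leaf,
*plus* redundant reactions whose removal deletes no peptide at all
because every product still has another producer. The second kind is
exactly the "multiple explanations for one peptide, only one of them
true" situation that motivates the structure optimization in the first
place, and including it makes every connected root-containing subgraph
reachable by single trims — so a sufficiently wide beam provably
reproduces the exhaustive ranking, which the test suite asserts.

Ties on equal score go to the model with fewer reactions (parsimony),
then lexicographically, so rankings are deterministic.

A known limitation, visible in the decoy experiments: when a decoy
signal sits on a *parallel route* to a true fragment (the decoy is
itself a plausible fragment one residue away), the route through the
decoy and the direct true reaction explain nearly the same data, the
score difference is at noise level, and a narrow beam can keep the
decoy route or retain the spurious reactions with non-negligible rates.
This is an identifiability limit of MS1 time-series data, the same one
that makes the I/L terminal ambiguity unresolvable in principle.

## The simulator

`simulate_system()` generates ground-truthed data so the whole chain is
verifiable end to end. It integrates the true ODE system, pools isobars,
and emits centroided peak lists containing exactly the group peaks
(plus optional decoys).

* **Noise model.** Signal variability is intensity-dependent:
  $I_{noisy} = I \cdot \max(1 + \epsilon, 0)$ with
  $\epsilon \sim N(0, CV)$. The truncation keeps intensities
  non-negative; a Monte-Carlo test confirms the realized dispersion
  matches the nominal CV. Spectra are centroided by construction — no
  profile peaks, isotope envelopes, baselines or chemical noise floors;
  passing tests therefore demonstrate correctness of the inference
  chain, not robustness to raw-spectrum artefacts.
* **Sampling schemes.** `study1` is the dense-early design: 10 points
  over 5 h of incubation, five in the first hour (where the dynamics
  are fastest) and five spread equally over the rest.
* **Decoys** mimic false identifications: peaks placed at the mass of a
  *plausible but false* fragment (an exo child of a true node that is
  not itself a true product, offset by 0.05 Da, within matching
  tolerance) while staying at least 1.5 tolerances away from every true
  mass so they never steal a true match. Their dynamics are flat
  (default, at 20% of the strongest signal), decaying, or a random
  walk. Flat is the adversarial default: a constant trace is what a
  contaminant or matrix signal looks like.
* **Presets.** `fpa_chain` is the fibrinopeptide-A N-terminal exo chain
  (3 reactions, rates 1.2 / 0.6 / 0.3 per hour, seed concentration 10,
  unit transformation factors — chosen so the substrate is mostly
  consumed and every product rises visibly within the 5 h window). The
  `branched_endo_*` presets put 1–2 endo cuts and 2–4 exo steps on
  angiotensin I, an endothelin-1 fragment and somatostatin-28
  respectively, with rates between 0.1 and 1.0 per hour. Truth (graph,
  rates, factors) is always serialized next to the data.

Everything is seeded: the same (system, times, CV, seed) produces
bit-identical output, and the caller's RNG state is never touched.

## Problem sizes and tolerances used in the checks

The test suite runs the full chain at the study conditions: the noise
sweep uses CV ∈ {0, 0.1, 0.2, 0.3, 0.4} with 20 seeds per level on the
3-reaction chain; decoy pruning uses the 5-reaction branched system
with 3 flat decoys at CV = 0.1, beam widths 2 and 3, 20 seeds each; the
oracle comparison uses 20 random 4-reaction systems at CV = 0.1. The
acceptance script recomputes the same quantities at reduced replicate
counts (5 per noise level, 10 decoy runs, 8 oracle instances) so a
single pass stays fast while every number is still computed from
scratch. ODE correctness is held to closed forms at $10^{-6}$
absolute; solver cross-checks at $10^{-8}$; noise-free rate recovery
to 1% relative.

## Known limitations

* MS1-only evidence: isobaric ambiguities (I/L) are recorded, never
  resolved; MS/MS integration is out of scope.
* A single seed peptide per analysis; unobserved intermediate peptides
  are not bridged.
* The intensity–concentration map is linear per peptide; detector
  saturation and ionization competition are not modelled.
* The beam search inherits the leaf-trimming move set's greediness:
  parallel decoy routes at noise-level score differences can survive
  (see above).
* Peak lists are read from CSV/TSV (plus a manifest); raw or profile
  formats are expected to be centroided upstream.
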