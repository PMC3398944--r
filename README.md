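# degraph

Reconstruct proteolytic processes from mass-spectrometry time series.

When a peptide probe is incubated with proteases and spectra are taken
at successive time points, the substrate peak shrinks while fragment
peaks appear and grow. `degraph` turns such a series of centroided peak
lists plus the seed peptide sequence into:

1. a **degradation graph** — peptides as nodes, exo- and
   endoproteolytic reactions as directed edges, internal cleavages
   represented by pseudo-nodes so that one reaction keeps one rate
   parameter even with two products;
2. **kinetic rate estimates** — the graph translates into a first-order
   mass-action ODE system `dx/dt = A(k) x`; rates `k`, per-peptide
   intensity transformation factors `c_p` (predicted intensity of an
   observed mass is `I(m,t) = Σ_{p∈P(m)} c_p x_p(t)` over its isobaric
   group) and the seed's initial concentration are estimated by bounded
   weighted nonlinear least squares;
3. a **ranked list of substructures** — subgraphs are scored by
   `S = w1·S_corr + w2·S_var`, where `S_corr` is the mean Pearson
   correlation between observed and predicted traces and `S_var` the
   fraction of total signal standard deviation the subgraph retains,
   and searched by an iterative leaf-trimming beam search (width `q`),
   with an exhaustive oracle for small graphs.

A seeded simulator generates ground-truthed noisy peak-list series
(intensity-dependent noise, decoy peaks, configurable sampling
schemes), so the entire inference chain is verifiable without external
data.

## Worked example

```r
library(degraph)

# ground truth: fibrinopeptide A degraded by three N-terminal exo cuts
sys <- preset_system("fpa_chain")
sys$rates
#> exo_N:DSGEGDFLAEGGGVR:SGEGDFLAEGGGVR  exo_N:GEGDFLAEGGGVR:EGDFLAEGGGVR
#>                                  1.2                               0.3
#>   exo_N:SGEGDFLAEGGGVR:GEGDFLAEGGGVR
#>                                  0.6

# simulate 10 spectra over 5 h (dense-early sampling), 10% noise
sim <- simulate_system(sys, times = sample_times("study1"),
                       cv = 0.1, seed = 7)

# reconstruct the graph from the peak lists alone
built <- build_graph(sim$timeseries, seed = "DSGEGDFLAEGGGVR")
built
#> degradation graph: 4 peptide node(s), 0 pseudo-node(s), 3 reaction(s)
#> root: DSGEGDFLAEGGGVR (1464.6481 Da)
#> peak lookups: 510 (worst-case bound 1200)

# estimate the kinetics
fit <- fit_kinetics(built$graph, built$intensities)
round(fit$rates[names(sys$rates)], 3)
#> exo_N:DSGEGDFLAEGGGVR:SGEGDFLAEGGGVR  exo_N:GEGDFLAEGGGVR:EGDFLAEGGGVR
#>                                1.205                             0.300
#>   exo_N:SGEGDFLAEGGGVR:GEGDFLAEGGGVR
#>                                0.620

# compare against the known truth
recovery_report(sys, built$graph, fit)
#> recovery: precision 1.000, recall 1.000 (3 true, 3 reconstructed)
#> median relative rate error: 0.0039
```

All three reactions are recovered exactly and the rates land within a
few percent of the truth at 10% signal variability. On data containing
decoy signals, `heuristic_search(built$graph, built$intensities, q = 3)`
ranks candidate subgraphs and the report shows how much of the process
survives in the winner.

The one-shot pipeline (simulate/load → normalize → build → fit →
select → evaluate) is `run_pipeline(run_config(...), out_dir)`; a thin
command-line wrapper with `simulate`, `build`, `fit`, `select` and
`run` subcommands ships in `inst/cli/degraph.R`.

Graphs serialize to GraphML, DOT (pseudo-nodes drawn as diamonds,
fitted rates as edge labels) and a documented JSON schema; peak lists
are headerless 2-column CSV/TSV behind a `time_hours,file` manifest.

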