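# pcnet

Regularized partial-correlation networks for psychometric questionnaire
data, with edge-weight accuracy bootstrapping and shortest-pathways
analysis. The package is aimed at researchers who analyse eating-disorder
(EDI-2) and childhood-maltreatment (CTQ) subscale scores as a symptom
network and want to trace *how* maltreatment experiences connect to
ED-specific symptoms (body dissatisfaction, bulimia) through the rest of the
psychopathology, with every stage testable against planted ground truth.

## What it computes

Given an $n \times p$ table of integer subscale scores, the network is a
Gaussian graphical model: edge weights are partial correlations
$w_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$, where the precision matrix
$K = \Sigma^{-1}$ is estimated by the graphical lasso

$$\hat K(\lambda) = \arg\max_{K \succ 0} \; \log\det K - \mathrm{tr}(SK)
  - \lambda \textstyle\sum_{i\neq j} |K_{ij}|$$

over a 100-point logarithmic penalty grid, with the penalty selected by the
extended BIC, $\mathrm{EBIC}_\gamma = -2L + E\log n + 4E\gamma\log p$
(default $\gamma = 0.5$). Around that core:

* **`bootstrap_edges()`** — nonparametric case-resampling bootstrap of the
  *full* estimation chain (default $B = 2500$), percentile CIs and selection
  proportions per edge;
* **`shortest_pathways()`** — Dijkstra on the inverse-weight distance graph
  ($d_{ij} = 1/|w_{ij}|$) with full co-optimal route recovery, from each
  maltreatment node to each ED-specific symptom;
* **`group_comparison()`** — two-group descriptives: Mann–Whitney per
  subscale, chi-squared on CTQ cut-off occurrence (EN ≥ 15, EA ≥ 10,
  SA/PN/PA ≥ 8);
* **`planted_topology_spec()` / `generate_dataset()`** — synthetic integer
  questionnaire data from a known sparse partial-correlation graph,
  including ready-made "BN" and "BED" topologies at the published group
  sizes (n = 181 / 144) and marginal means/SDs;
* **`run_pipeline()`** — the end-to-end driver writing adjacency/edge-list
  CSVs, GraphML, bootstrap tables, pathway JSON, the comparison table and a
  reproducibility manifest.

## Worked example

```r
library(pcnet)

spec <- planted_topology_spec("BN", n_subjects = 2000, seed = 5)
net  <- estimate_network(generate_dataset(spec))
net
#> Regularized partial-correlation network (BN)
#>   nodes: 16, edges: 31 of 120 possible
#>   n = 2000, gamma = 0.5, lambda* = 0.05054 (grid index 55)

pw <- shortest_pathways(net)
pw$pairs[["emotional_neglect->bulimia"]]$paths[[1]]
#> [1] "emotional_neglect" "emotional_abuse" "ineffectiveness"
#> [4] "interoceptive_awareness" "bulimia"
```

The fitted network keeps 31 of 120 possible edges at the EBIC-selected
penalty. The shortest route from emotional neglect to bulimia runs through
emotional abuse, ineffectiveness and interoceptive awareness — exactly the
planted chain: every maltreatment node reaches the ED-specific symptoms via
the emotional-abuse node, and the recovered pathway reproduces it from
simulated scores alone.

```r
bt <- bootstrap_edges(generate_dataset(spec), B = 200, seed = 42)
summary(bt)   # per-edge estimates, percentile CIs, selection proportions
```

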