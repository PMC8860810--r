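---
title: "Regularized partial-correlation networks, edge-weight accuracy and shortest pathways"
author: "pcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized partial-correlation networks, edge-weight accuracy and shortest pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnet)
```

## The model

pcnet analyses questionnaire subscale data — here, the 11 EDI-2
eating-disorder psychopathology subscales and the 5 CTQ childhood-maltreatment
subscales — as a Gaussian graphical model. The nodes are the subscale
sum-scores; an edge between two nodes is the *partial correlation* between
them, the association that remains after conditioning on every other variable
in the network. If $K = \Sigma^{-1}$ is the precision matrix of the
(latent, quasi-continuous) scores, the edge weights are

$$ w_{ij} \;=\; -\,\frac{K_{ij}}{\sqrt{K_{ii}K_{jj}}}, \qquad i \neq j, $$

and $w_{ij} = 0$ exactly when the two subscales are conditionally
independent. Because a 16-node network has 120 free edges and clinical
samples have only a few hundred participants, the precision matrix is
estimated by the graphical lasso: the $\ell_1$-penalized Gaussian maximum
likelihood problem

$$ \hat K(\lambda) \;=\; \arg\max_{K \succ 0}\;
   \log\det K - \operatorname{tr}(SK) - \lambda \sum_{i \neq j} |K_{ij}|, $$

with $S$ the sample correlation matrix. The penalty shrinks small partial
correlations to exactly zero, producing a sparse, interpretable network. The
diagonal is not penalized; at $\lambda \ge \max_{i\neq j}|S_{ij}|$ the
solution is exactly diagonal, which anchors the penalty grid.

The penalty is chosen by the extended Bayesian information criterion,

$$ \mathrm{EBIC}_\gamma(\lambda) = -2L(\lambda) + E(\lambda)\log n +
   4\,E(\lambda)\,\gamma \log p, $$

where $L = \tfrac{n}{2}(\log\det K - \operatorname{tr}(SK))$, $E$ is the
number of selected edges, and $\gamma \ge 0$ trades likelihood against
sparsity. $\gamma = 0$ is the ordinary BIC; the package default
$\gamma = 0.5$ is the conventional choice in psychometric network analysis
and deliberately errs toward sparser graphs. Ties on the grid are broken
toward the larger penalty, i.e. the sparser model.

`estimate_network()` runs the whole chain — correlation matrix (Pearson by
default; subscale sums are quasi-continuous, and Spearman is available for
heavy-tailed data), a 100-point logarithmic penalty grid down to
$\lambda_{\max}/100$, the glasso path (block coordinate descent implemented
in compiled code, warm-started along the path), EBIC selection — and returns
a fitted `pcor_network` object with the usual `print`, `summary`, `coef`,
`plot` and `simulate` methods.

```{r estimate}
spec <- planted_topology_spec("BN", n_subjects = 2000, seed = 5)
net <- estimate_network(generate_dataset(spec))
net
```

## Edge-weight accuracy by nonparametric bootstrap

`bootstrap_edges()` quantifies the sampling accuracy of the edge weights by
case resampling: subjects are drawn with replacement and the *entire*
estimation chain — correlation, grid, glasso, EBIC selection — is re-run on
every resample, so the intervals reflect both sampling noise and model
selection. Percentile confidence intervals (default 2.5%/97.5%) summarize
the replicate distribution, along with the proportion of replicates in which
each edge is selected at all. The conventional replicate count for this
analysis is $B = 2500$; the package's tests use $B = 200$ as a scaled-down
surrogate.

Two properties of these intervals deserve emphasis. First, a percentile CI
need not bracket the bootstrap mean, and the table makes no such claim.
Second — a known limitation of bootstrapping regularized estimators — the
intervals describe the variability of the *shrunken* estimates, not
calibrated coverage of the unshrunken truth: EBIC-glasso biases weights
toward zero, and for a planted weight of 0.25–0.35 at $n = 500$ the measured
coverage of the 95% percentile interval is near 55–60%, with weak edges
often yielding degenerate $[0, 0]$ intervals when they are rarely selected.
The bootstrap table is therefore an accuracy (stability) display, exactly as
it is used in applied network papers, not an inferential guarantee.

Replicate seeds are derived from the master seed by a counter scheme, so any
single replicate can be reproduced independently of execution order;
resamples with a zero-variance column are redrawn (counted, and aborted if
redraws exceed $10B$).

## Shortest pathways

To trace how a maltreatment node reaches a symptom node through the network,
the weight matrix is converted to distances $d_{ij} = 1/|w_{ij}|$ (absent
edge = infinite distance): stronger conditional associations are shorter
steps, and the absolute value is used because negative edges still transmit
association. Dijkstra's algorithm then finds, for each source–target pair,
the route(s) minimizing the summed distance. The implementation keeps full
predecessor *sets*, so all co-optimal routes are recovered and reported in a
deterministic order (by node-index sequence); silent tie-breaking would make
results irreproducible. Signed weights are kept on every reported edge so
that claims about positive associations along a pathway can be checked. The
union of all shortest routes — the pathway subgraph drawn with continuous
lines in the field's figures — is returned and exportable to GraphML with an
`on_shortest_path` edge attribute.

A hop-count reading of "shortest" (every present edge has length 1) is
available via `unweighted = TRUE`; the inverse-weight metric is the default
because it is the established convention of the shortest-pathways
methodology on weighted association networks.

```{r paths}
pw <- shortest_pathways(net)
pw$pairs[["emotional_abuse->bulimia"]]$paths
```

## Synthetic data with planted ground truth

No participant-level data accompany the analyses this package reproduces, so
every stage is exercised on synthetic datasets with known structure.
`synthetic_spec()` fixes a sparse partial-correlation target, per-variable
means and SDs on the questionnaire scale, integer score bounds, a sample
size and a seed; `generate_dataset()` draws latent multivariate-normal
vectors whose correlation structure is implied by the target (precision
built with unit conditional variances — the canonical representative of the
scale equivalence class — then standardized to unit marginal variance),
rescales and shifts them to the questionnaire scale, rounds half-away-from-
zero and clips to the bounds. Rounding-plus-clipping is a deliberate,
deterministic discretization: subscale *sums* are quasi-continuous, so
item-level ordinal machinery (IRT) would add complexity without changing
what the tests can show.

`planted_topology_spec()` returns ready-made ground truths for the two
clinical groups: all maltreatment nodes converge on emotional abuse
(weight 0.30), which reaches body dissatisfaction and bulimia through
ineffectiveness (BN) or impulsivity (BED) and, in both groups,
interoceptive awareness on the way to bulimia (chain weights 0.40), plus
peripheral ED–ED edges at $|w| = 0.20$. The weights are set so that
EBIC-glasso at $\gamma = 0.5$ can detect the planted chains at the default
clinical sample sizes (detection needs roughly
$n\rho^2 \gtrsim \log n + 2\log p \approx 10.5$ at $n = 144$, i.e.
$|\rho| \gtrsim 0.27$), while the peripheral weights stay small enough that
a detour around a planted chain (shortest peripheral detour
$\ge 2 \times 1/0.20$) can never undercut the chain itself
($\le 1/0.40$ per hop). Group sample sizes default to 181 (BN) and 144 (BED) and the marginal means/SDs default
to the published clinical group values, e.g. BN ineffectiveness
$12.85 \pm 7.89$. CTQ bounds are $[5, 25]$ (standard CTQ-SF scoring); EDI-2
item counts are not standardized across versions, so EDI-2 bounds are
permissive defaults ($[0, 3\times$ nominal item count$]$) and fully
configurable.

What the generator does **not** emulate: item-level response processes,
skewed/zero-inflated margins typical of abuse subscales (the latent scale is
symmetric), missing data, and measurement unreliability. Passing recovery
tests therefore shows the estimation chain is correct and well calibrated
under a Gaussian-with-discretization regime, not that real questionnaire
data meet those assumptions.

## Group descriptives

`group_comparison()` reproduces the layout of a clinical characteristics
table: per-variable Mann–Whitney tests (group-1 $U$ convention, so
$U + U' = n_1 n_2$; exact p when there are no ties and $n_1 n_2 \le 400$,
otherwise the normal approximation with tie and continuity corrections) and,
per maltreatment type, occurrence above the standard CTQ cut-offs
(EN $\ge 15$, EA $\ge 10$, SA/PN/PA $\ge 8$, inclusive) compared by the
uncorrected Pearson chi-squared test (Yates correction available). No
multiplicity adjustment is applied, matching common practice for such
descriptive tables.

## Numerical choices and edge cases

* An edge is "present" when $|w_{ij}| > 10^{-8}$; exact zeros are
  solver-dependent, a tolerance is not.
* The glasso outer loop stops when the largest covariance update falls below
  `tol` (default $10^{-4}$) times the mean absolute off-diagonal of $S$;
  non-convergence is an error naming the penalty, never a silent return.
* Correlation matrices that fail PSD by more than $-10^{-8}$ in the smallest
  eigenvalue are repaired by eigenvalue clipping and re-standardization —
  with a loud warning and a metadata flag, because a badly indefinite input
  usually signals a data problem.
* The log-likelihood uses the denominator-$n$ covariance convention,
  consistent with the likelihood inside the glasso objective (immaterial for
  correlation input).
* `generate_dataset()` restores the global RNG state, so simulation code
  around it is unaffected.
* Degenerate inputs error early with informative messages: zero-variance
  columns (named), $n < 3$, infeasible partial-correlation targets (most
  negative eigenvalue reported), unknown node names (valid names listed).

## Problem sizes used in the test suite

The packaged experiments run at deliberately moderate sizes chosen to make
their conclusions stable: oracle equivalence on 20 six-node problems;
Dijkstra versus exhaustive enumeration on 200 random connected graphs of up
to 7 nodes; edge recovery at $p = 16$, $n = 1000$ over 20 seeds; null
sparsity at $n = 500$ over 100 seeds; bootstrap coverage at $p = 8$,
$n = 500$, $B = 200$ over 100 datasets; pathway recovery at $n = 2000$.

## Known limitations

* Pearson (or Spearman) input only; polychoric correlations and mixed
  graphical models are out of scope.
* The shortest-pathway analysis has no accompanying stability measure; a
  principled stability test for pathways is an open methodological question,
  and anything added here would be an extension rather than a reproduction
  of established practice.
* Bootstrap percentile intervals around regularized weights under-cover the
  generating truth (see above); they are reported as accuracy displays.
* No network comparison test between groups is provided; the two group
  networks are estimated independently.
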