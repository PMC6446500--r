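---
title: "Finding modulated sub-graphs: model, heuristic and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding modulated sub-graphs: model, heuristic and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfinder)
```

## The problem

A differential gene expression analysis (DGEA) assigns each gene a p-value
and a log-fold change, one gene at a time. Regulatory perturbations,
however, propagate through interaction networks: a stimulus entering at
one gene shifts the expression of a whole connected neighborhood, often
leaving each member just short of genome-wide significance. Thresholding
per-gene p-values then fragments the affected region into scattered hits.
`msfinder` scores connected gene sets *jointly*, treating the member
p-values as dependent replicate measurements of one underlying sub-graph
level signal, and searches the network for connected sets whose joint
significance cannot be explained gene by gene.

## Combining dependent p-values

Each p-value $T_i$ is transformed to its normal score
$t_i = \Phi^{-1}(1 - T_i)$ (small p, large positive score). Under a gene's
null, $T_i$ is uniform and $t_i$ standard normal. Vicinal genes are
correlated, so Stouffer-style combination with independence assumptions
would overstate the evidence. We use Hartung's weighted inverse-normal
statistic for dependent p-values,

$$
t(\rho) = \frac{\sum_i \lambda_i t_i}
{\sqrt{(1-\rho)\sum_i\lambda_i^2 + \rho(\sum_i\lambda_i)^2}},
$$

with unit weights $\lambda_i = 1$ and the common pairwise correlation
estimated by the moment estimator $\hat\rho = 1 - \frac{1}{n-1}\sum_i(t_i -
\bar t)^2$, clamped to the admissible range $[-1/(n-1),\, 1]$. The
sub-graph's combined p-value is $1 - \Phi(t(\rho))$; at $\rho = 0$ the
statistic is Stouffer's $\sum t_i/\sqrt n$, at $\rho = 1$ the mean score
(no information gain from correlated replicates).

Three numerical choices matter here:

* **Clamping.** Every p-value is clamped to $[10^{-15},\, 1-10^{-15}]$
  before the transform; $\Phi^{-1}$ diverges at the endpoints, and the
  clamp preserves ordering while keeping scores finite. The upper-tail
  quantile is evaluated as `qnorm(p, lower.tail = FALSE)`: computing the
  literal difference `1 - p` first would lose about seven significant
  digits of the score at $p \approx 10^{-11}$.
* **The correlation actually plugged in.** `estimate_rho()` reports the
  clamped estimator, but when `combine_pvalues()` inserts an *estimated*
  correlation into $t(\rho)$ it floors it at zero. With unit weights the
  denominator $(1-\rho)n + \rho n^2$ is exactly zero at the clamp boundary
  $\rho = -1/(n-1)$ (two scores $\{0, 2\}$ estimate $\hat\rho = -1$ and
  would divide by zero), and more fundamentally a negative *common*
  correlation rewards discordant score sets — the opposite of what joint
  modulation means. The model is that neighborhood genes are
  non-negatively correlated replicates; heterogeneity beyond independence
  is treated as independence, not as evidence. Both `rho_hat` and
  `rho_used` are reported. An explicitly supplied `rho` (e.g. for null
  calibration at $\rho = 0$) is used exactly.
* **Log-scale comparisons.** The search compares candidate sub-graphs on
  $\log p$ (`pnorm(..., log.p = TRUE)`); the p-value itself underflows to
  zero near $t(\rho) \gtrsim 39$, which would turn strict improvements
  into spurious ties and stall the search on strong signals.

A consequence of the variance-based estimator worth knowing: two genes
with *nearly identical* significant p-values estimate $\hat\rho \approx 1$,
so their combination collapses to the mean score and cannot beat the
better gene alone. Joint evidence accumulates through neighborhoods with
*spread* in their scores; two identical strong hits are treated as one
redundant measurement, by design of the estimator.

## The search heuristic

Scoring every connected subset is infeasible, so the search proceeds in
four deterministic steps. All membership decisions use the *undirected*
view of the network — statistical co-modulation has no direction — while
edge directions are kept for the topology annotation. All acceptance tests
require a *strict* decrease of the combined p-value, which bounds every
step and guarantees termination; all candidate orderings are by
(p-value, gene id), so identical inputs give bit-identical results.

1. **Initialize.** While an unassigned gene with $p \le$ `seed_alpha`
   (default 0.05) exists, seed at the smallest such p-value and repeatedly
   add the first unassigned immediate neighbor — in ascending (p, id)
   order — whose addition improves the score (`neighbor_rule = "best"`
   instead evaluates all neighbors and takes the best improvement; on the
   small-instance oracle benchmark in the test suite both variants attain
   the same optima, so the cheaper first-improvement rule is the default).
   Without the seed gate every gene would eventually seed a singleton;
   with it, the unreported remainder is exactly the genes with no
   individually suggestive evidence that no growing sub-graph claimed.
2. **Extend.** For each sub-graph, enumerate all simple paths of up to
   `max_extension_len` (default 2, range 1–3; the bound counts *genes*,
   not edges) unassigned genes starting from any member, in ascending
   order of the path's own combined p-value; accept a path when adding all
   its genes improves the sub-graph, restart enumeration after each
   acceptance, and iterate to a fixpoint. This is what bridges short gaps:
   an unsignificant connector gene can be carried by a significant gene
   behind it, while a one-gene path to the same connector fails.
   Extension paths may not touch other sub-graphs' members — crossing over
   is merging's job.
3. **Merge.** For every pair of sub-graphs, a bounded-depth search finds
   connector paths of up to `max_connector_len` (default 2, range 0–3)
   unassigned genes; the best connector minimizes the merged combined
   p-value (ties: shorter, then lexicographic). A merge is accepted only
   when the merged score improves on **both** parents; pairs are processed
   in ascending order of their better parent, the pair list is rebuilt
   after each acceptance, and the step iterates to a fixpoint. Cached pair
   evaluations are invalidated when a parent changes or a cached
   connector gene is claimed; because the free-gene pool only shrinks, a
   cached rejection can never turn into an acceptance, so the cache is
   exact.
4. **Finalize.** Report sub-graphs with at least `report_min_size`
   (default 2) genes and combined p-value at most `report_alpha` (default
   0.05), renumbered in ascending combined p-value, each with its induced
   directed edge set.

Genes present in the network but lacking a usable DGEA p-value are
invisible to the search (they can be neither members nor connectors):
every member must contribute a score to $t(\rho)$.

## Sources, sinks, impact, reliability

Within a sub-graph's induced directed edges, a **source** has no incoming
and at least one outgoing edge; a **sink** the reverse. Cyclic sub-graphs
may have neither. Each source's **impact score** is
$100 \cdot n_{\downarrow} / (|V|-1)$ where $n_{\downarrow}$ counts the
members reachable from it by directed edges — an upper bound on how much
of the sub-graph's perturbation the source could have introduced. The
prose notion "relative number of downstream genes" is ambiguous between
direct targets and full reachability; reachability is the default because
it matches the entry-point interpretation, and `impact = "immediate"`
switches to direct targets. Impact scores are deliberately *not*
normalized across sources: downstream sets overlap, and comparability
within a sub-graph is what matters.

The **reliability check** asks whether a source really marks the border
between two regulation regimes: Welch's two-sample t-test on
log-transformed p-values of the genes just downstream (the source's direct
targets inside the sub-graph; `reliability_group = "reachable"` widens
this to the full downstream set) versus the source's direct regulators in
the *global* network — inside the sub-graph a source has no upstream genes
by definition, so the upstream regime is only observable globally. Welch's
unequal-variance form avoids an unjustifiable homoskedasticity assumption
between a significant and an unsignificant group. The natural log is used;
the base is immaterial since rescaling both groups leaves $t$ unchanged
(asserted in the tests). Groups with fewer than two usable members yield a
flagged not-computable result rather than an error, and no multiplicity
correction is applied across sources — the numbers are descriptive
prioritization aids, not hypothesis tests.

## The planted-module simulator

`generate_instance()` draws a directed Erdős–Rényi network (default mean
out-degree 3, i.e. total degree ≈ 6, the order of magnitude of curated
functional-interaction networks; a preferential-attachment option gives
hub-dominated topologies), selects a connected module by a random walk on
the undirected view, and assigns planted p-values from
$\mathrm{Beta}(a, 1)$ with $a = 0.1$ by default — a standard one-parameter
signal model for p-value mixtures whose mean $a/(a+1) \approx 0.09$ leaves
roughly a quarter of planted genes *above* the 0.05 cutoff, exactly the
regime where joint scoring should outperform thresholding. Background
p-values are uniform; log-fold changes are $N(\pm 2, 1)$ for planted and
$N(0,1)$ for background genes. $a = 1$ is the exact null.
`perturb_pvalues()` adds $N(0, \sigma)$ noise to every normal score and
re-derives the p-values — the score-space stand-in for re-running a DGEA
on noise-injected counts, which perturbs p-values across their whole
range without simulating reads.

What the simulator does *not* emulate: realistic degree distributions and
community structure of curated networks, correlated noise between
neighboring genes (DGEA errors are not independent across a regulon),
missing p-values, and any count-level error model. Passing the recall and
fragmentation benchmarks therefore demonstrates the algorithm's behavior
under its own stated signal model, not performance on any particular real
dataset.

Problem sizes used by the test suite and the acceptance script — 500-gene
networks with 40-gene modules, 20–100 replicates, and exhaustive-oracle
comparisons on networks of at most 8 nodes (where all connected subsets
containing a seed-eligible gene can be enumerated) — were chosen as the
smallest scales at which the relevant contrasts (fragmentation vs.
thresholding, noise robustness, heuristic optimality) are stable across
seeds.

## Known limitations

* **Selection bias under the null.** Greedy growth maximizing joint
  significance is an optimizing selection: even on a pure-null instance
  the search typically assembles one moderate sub-graph with a small
  combined p-value by picking the best neighbor at every step. The
  combined p-value of a *reported* sub-graph is therefore not a calibrated
  null probability for "a sub-graph like this arises by chance"; it is a
  ranking score. Interpretation should lean on the planted-recall and
  fragmentation comparisons, on effect sizes, and on the reliability
  checks — not on the raw combined p-value of a selected set.
* **Equal weights.** $\lambda_i = 1$ throughout; the machinery supports
  weights, but no principled per-gene weighting is shipped.
* **A single common $\rho$** is a coarse model of a neighborhood's
  dependence structure; it is what makes the combination tractable.
* Sub-graphs are disjoint: a gene belongs to at most one reported module,
  so overlapping regulatory programs are split, not shared.
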