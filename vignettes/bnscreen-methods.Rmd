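---
title: "Screening Boolean networks for dynamic drivers with static measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening Boolean networks for dynamic drivers with static measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bnscreen)
library(dplyr)
```

## The problem

A Boolean network models a regulatory system as $n$ binary variables
$x_g \in \{0, 1\}$, one per gene, each updated by a fixed logic function
$f_g$ of its regulators. Under synchronous updating every trajectory of the
$2^n$-state system eventually enters an attractor — a fixed point or cycle —
and attractors are the model's phenotypes. The genes that matter
therapeutically are those whose perturbation (permanent knock-out or
over-expression) reshapes the attractor landscape. Finding them by
simulation requires an attractor analysis per gene and perturbation, which
scales exponentially with $n$ and becomes infeasible for large models.

bnscreen implements a screening strategy that predicts these dynamically
relevant genes from *static* properties of the interaction graph alone, then
— on models small enough to simulate — quantifies how well the static screen
recovers the genes that a full perturbation analysis would flag, and
characterizes the selected genes. The screen combines two measures:

* **Vertex betweenness (VB)** — for node $g$, the sum over ordered node
  pairs of the fraction of shortest directed paths through $g$. High-VB
  nodes are bottlenecks between modules.
* **Determinative power (DP)** — the sum over a node's targets of the
  mutual information between the node's state and the target's function
  output, $DP_g = \sum_{g'} MI(X_g; f_{g'}(X))$, under independent
  Bernoulli node states. High-DP nodes dominate their targets' logic.

Genes in the top $T\%$ of *both* rankings form the selection. Selected genes
are then split by comparing percentile ranks: a **positive mismatch**
("gatekeeper") ranks higher on the VB/DP average than on connectivity — high
influence without high degree — while a **negative mismatch** does not.
Hubs (connectivity z-score $\ge 2.5$) are flagged orthogonally.

## Dynamic ground truth

The reference against which the static screen is judged is a perturbation
analysis. For each gene $g$ and perturbation $P \in \{KO, OE\}$ the gene's
function is replaced by the constant 0 or 1 and the attractors recomputed.
Attractors are summarized as trinary vectors (0 off, 1 on, 0.5 oscillating,
regardless of period or duty cycle); for comparison, the perturbed gene's
own component is removed and duplicate reduced summaries collapse to a set.
Three measures are taken, each reported as the maximum over the two
perturbations:

* **gain** — reduced summaries present after perturbation but not before;
* **loss** — original reduced summaries with no match afterwards;
* **shift** — the mean, over perturbed attractors, of the distance to the
  closest original attractor, where the distance sums absolute trinary
  differences over all genes except the perturbed one.

The printed definition of the loss measure in the literature this method
descends from reduces, read literally, to the *intersection* of the two
attractor sets, which contradicts its own description as the number of
unmatched originals; bnscreen implements the described meaning (set
difference). The shift is implemented exactly as the max-over-perturbations
of a mean of minima, its customary form.

Per network, each measure is ranked ascending with average-rank ties and the
three ranks are averaged and divided by $n$, giving the dynamic impact
percentile $I_g \in (0, 1]$. "High-impact" genes at threshold $T$ are the
top $\lceil Tn/100 \rceil$ by $I_g$.

```{r}
t3 <- read_boolnet(system.file("extdata", "toy3.bn", package = "bnscreen"))
find_attractors(t3)
perturbation_impact(t3, "B")
```

## The screen and the sweep

At a threshold $T$, the top set of a score vector is the
$\lceil T n / 100 \rceil$ highest-ranked genes; ties are broken
deterministically (score, then gene name) so the set size is exact. The
default selection is $VB_T \cap DP_T$ at $T = 73$; union and single-measure
selectors are available. Sensitivity and specificity against the high-impact
labels are computed per network and macro-averaged across the collection at
every $T \in \{1, \dots, 100\}$; the *crossing threshold* is the $T$
minimizing $|\overline{sens} - \overline{spec}|$ (ties to the smaller $T$).
At $T = 100$ both are 1 by construction.

```{r, fig.width = 6, fig.height = 4}
nets <- generate_network_collection(10, size_range = c(8, 12), seed = 42)
scr <- screen_collection(nets)
glance(scr)
autoplot(scr$sweep)
```

## Classification and information flow

Within each network, percentile ranks (average-rank ties, divided by $n$)
are computed for VB, DP and total degree. A selected gene is a positive
mismatch iff its VB/DP percentile average strictly exceeds its connectivity
percentile, otherwise a negative mismatch; unselected genes are `NS`. The
hub flag uses the connectivity z-score
$C_g = (\delta_g - \bar\delta)/\sigma$ with the sample standard deviation (a
robust median/MAD variant is available; a self-loop adds one to in- and one
to out-degree). Input nodes — constants or self-identities, the idiom for
external stimuli — are flagged separately, since they carry signals into the
model without being regulated by it.

The gatekeeper interpretation is probed through information flow: for every
(non-hub, hub) pair, all simple directed paths are enumerated, each path is
scored by its mean edge mutual information ($MI_p \in [0,1]$), and the
pair's best path is kept. Distributions of these maxima are compared between
start-node classes with two-sided Wilcoxon rank-sum tests, Bonferroni
corrected. For small groups the exact permutation null is enumerated on
average ranks (so tied data are handled exactly); larger groups use the
normal approximation with tie correction. Pairs with no connecting path are
dropped, not scored zero.

```{r}
head(scr$path_mi)
if (length(unique(scr$path_mi$class)) >= 2) compare_groups(scr$path_mi)
```

## Comparator features

Three classic static features are computed for comparison: canalysing
variables (an input one of whose values alone fixes the function's output,
levels counted across the network), signed network motifs (coherent and
incoherent type-1 feed-forward loops and bifans), and feedback vertex sets.
Motif conventions are fixed and documented — FFLs are ordered triples of
distinct nodes typed only when all three edges are unambiguously signed;
bifans are counted once per node set; self-loops never participate — because
published totals for such counts are convention-sensitive. The FVS is exact
(subset search over the cyclic core with a lexicographic tie-break) up to a
configurable core size and work budget, beyond which a greedy heuristic is
used and flagged; acyclicity after removal is asserted on every call.

## The synthetic generator

`generate_random_network(n, k, bias, seed)` draws $k$ distinct regulators
per gene uniformly and i.i.d. Bernoulli(bias) truth tables — the standard
random ensemble, used for oracle-equivalence testing.
`generate_network_collection()` emulates a *curated model collection*
instead: per-gene in-degrees drawn from a range (default 1–3) and regulators
drawn with rank-weighted (Zipf-like) preference, default exponent 2, so a
few genes accumulate many targets. That exponent was chosen once so that
roughly 3% of genes reach the hub criterion, the rate typical of published
logical-model collections; sizes default to 8–16 genes so that exhaustive
attractor search (vectorized transition map plus pointer doubling over all
$2^n$ states) remains cheap. These are the package's study conditions for
its own end-to-end checks and for `scripts/acceptance.R`, which screens a
35-model synthetic collection.

What the generator does *not* emulate: curated models are enriched for
canalysing functions and coherent motifs far beyond random-table levels, and
their logic is biased toward monotone (unate) regulation. Passing tests on
synthetic collections therefore demonstrate the machinery's correctness and
the qualitative phenomena (hubs exist, gatekeepers appear, information flows
more reliably from them), not the quantitative statistics of any published
model set.

## Numerical choices and parameters

* **Truth-table bit order**: first-listed input is the most significant bit.
  Arbitrary, but fixed for reproducibility.
* **Edges are essential by default**: a listed regulator the function never
  responds to produces no edge (its mutual information is exactly 0);
  `mode = "syntactic"` restores verbatim parity with the model text.
* **DP state distribution**: independent Bernoulli with `bias = 0.5` per
  node, configurable. Entropies use $h(0) = h(1) = 0$ by continuity, and a
  floating-point guard clamps MI at 0 from below.
* **Exhaustive limit**: attractor search enumerates all states up to
  $n \le 25$ (configurable); beyond that, sampled search from
  `min(2^n, 100000)` seeded random starts returns the attractors reached —
  a subset — with trajectory memoization across starts.
* **z-scores**: sample (n−1) standard deviation by default (population via
  flag); MAD scaled by 1.4826. All-equal degrees give z = 0 everywhere with
  a `degenerate` flag rather than NaN.
* **Simple-path cap**: `max_len = NULL` enumerates unbounded simple paths,
  faithful to the definition; a cap is available because dense graphs hold
  exponentially many.
* **Whether degree counts self-loops once or twice per side is a genuine
  convention choice**; bnscreen counts a self-loop in both in- and
  out-degree (total +2), the igraph convention.

## Limitations

Only synchronous, deterministic updating is supported — no asynchronous or
probabilistic schemes. Sampled attractor search can miss small-basin
attractors, so dynamic measures for large models are estimates. Exact FVS
and unbounded path enumeration are exponential in the worst case and guarded
by budgets. Motif totals depend on counting conventions and should be
compared across tools only after aligning those conventions.
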