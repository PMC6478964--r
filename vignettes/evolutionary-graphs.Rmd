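---
title: "Fixation on evolutionary graphs: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation on evolutionary graphs: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evograph)
```

## The model

A population of constant size $N$ occupies the nodes of a connected,
undirected, unweighted simple graph, one individual per node. Two types
compete: a mutant with relative fitness $r > 0$ and residents with fitness 1.
Under **Birth-death (Bd)** updating, each elementary step picks an individual
to reproduce with probability proportional to fitness; its offspring replaces
a uniformly chosen neighbor. Under **death-Birth (dB)** updating, a uniformly
chosen individual dies and its neighbors compete, proportionally to fitness,
to fill the vacancy. Bd is the default everywhere in this package; dB is
implemented for comparison. Weighted links, self-loops, directed graphs, and
frequency-dependent fitness are out of scope.

Two quantities summarize the fate of a single mutant placed on a uniformly
chosen node: the **fixation probability** $\varphi$ (the chance its lineage
takes over all $N$ nodes) and the **mean conditional fixation time** $\tau$
(the expected number of elementary updates until takeover, given takeover).
On the complete graph — the well-mixed baseline — the probability has the
classical closed form
$$\varphi_{K_N}(r) = \frac{1 - 1/r}{1 - r^{-N}},$$
and by the isothermal property every regular graph shares this value under
Bd. A graph is an **amplifier** of selection if advantageous mutants
($r > 1$) fix with higher probability than on $K_N$ and disadvantageous ones
($r < 1$) with lower probability; a **suppressor** is the reverse; some
graphs switch from suppression to amplification at a critical $r$
(**piecewise suppressors**).

## Exact computation

The mutant-occupied node set $S$ performs an absorbing Markov chain on the
$2^N$ subsets of nodes, with $\varnothing$ and the full set absorbing. The
per-state gain and loss probabilities under Bd are
$$P(S \to S \cup \{j\}) = \frac{r}{F(S)} \sum_{i \in S,\, i \sim j}
\frac{1}{\deg i}, \qquad
P(S \to S \setminus \{j\}) = \frac{1}{F(S)} \sum_{i \notin S,\, i \sim j}
\frac{1}{\deg i},$$
with total fitness $F(S) = r\,|S| + (N - |S|)$; all remaining mass is a
self-loop. `fixation()` assembles this kernel for all states at once (states
are $N$-bit integers; the membership matrix multiplies against the
degree-scaled adjacency matrix) and solves the linear systems
$$\varphi(S) = \textstyle\sum_{S'} P(S \to S')\,\varphi(S'), \qquad
u(S) = \textstyle\sum_{S'} P(S \to S')\,u(S') + \varphi(S),$$
where $u(S) = \varphi(S)\,E[T \mid \text{fixation}]$, over the $2^N - 2$
transient states. Systems up to 2048 states are solved densely with LAPACK;
larger ones through a sparse LU (`Matrix`). The default size cap is
$N \le 16$ (65,534 transient states), raisable via `max_nodes`.

Numerical conventions worth stating explicitly:

* **Time counting.** Every elementary update — one birth plus one death —
  counts one step, *including* steps that do not change the state. This is
  the convention under which the conditional-time system above is well
  posed. The hard lower bound it implies for a single initial mutant is
  $N - 1$ state-changing gains, so $\tau_i \ge N - 1$; whether one
  additionally counts the mutant's arrival as a step (making the bound $N$)
  is a bookkeeping choice that shifts nothing else, and the package does
  not.
* **Uniform initialization.** With per-node values $\varphi_i$ and $\tau_i$,
  the uniform summaries are $\varphi = \tfrac1N \sum_i \varphi_i$ and
  $\tau = \sum_i \varphi_i \tau_i / \sum_i \varphi_i$. The $\varphi$-weighted
  time is the mean of the fixation-time distribution conditioned on fixation
  when the start node is uniform — conditioning and averaging commute with
  the fixation event — and it is exactly what the Monte Carlo estimator
  (`simulate_moran()`, mean steps among fixed replicates) converges to.
* **Degenerate inputs.** Disconnected graphs are rejected (fixation from a
  single mutant is then impossible and the chain is not irreducible on the
  transient set); $N = 1$ returns $\varphi = 1$, $\tau = 0$.

`simulate_moran()` is an independent stochastic oracle: a step-by-step C++
implementation of the same dynamics using R's RNG stream. The test suite
holds the exact solver to 3-standard-error agreement with it at $10^5$
replicates, and to $10^{-10}$ agreement with the closed form on regular
graphs.

## Enumeration and counting

`enumerate_connected_graphs()` produces one representative per isomorphism
class of connected graphs. The workhorse grows graphs by one node at a time:
every connected graph on $n$ nodes has a non-cut vertex, whose deletion
leaves a connected graph on $n - 1$ nodes, so attaching a new node to every
nonempty subset of every $(n-1)$-class and deduplicating by canonical label
is complete. Deduplication uses BLISS canonical forms (via igraph),
serialized as canonical graph6 strings that double as deterministic sort
keys and cache keys. A brute-force sweep over all $2^{\binom n2}$ labeled
edge sets (capped at $n \le 6$) is kept as the trusted oracle; the two
agree, and both agree with `count_graphs()`, which computes the number of
unlabeled graphs from the cycle index of the pair action of $S_n$ and
restricts to connected graphs by inverting the Euler transform — exact
128-bit integer arithmetic, so the $n = 10$ (11,716,571) and $n = 11$
(1,006,700,565) connected counts come out exactly without generating a
single graph. The native enumeration cap is $n = 8$ (11,117 classes);
larger sizes are read from external graph6 files (`geng n -c` output).

## Graph families at the edges of the probability–time plane

`build_plane()` scans all classes of a size and tags, by construction, the
families that trace the plane's borders. The generators follow recipes with
the node layout fixed (core first), so the sweeps in the tests and figures
are reproducible from seeds:

* **Comet-kites** `comet_kite(n, c, t)`: a clique of $c$ nodes, $t$ tail
  roots attached to clique node $c$, and each remaining node linked to a
  uniformly chosen current tail node (earlier extensions included — the tail
  regions grow like random recursive trees). Edge count is always
  $\binom c2 + t + (n - c - t)$. `standard_kite()` is the deterministic
  single-path-tail case.
* **Detours** `detour_graph(n, c)`: a clique core, an outer region of $o
  \sim \mathrm{Unif}\{2, \dots, \min(c, n - c - 1)\}$ nodes, and a sparse
  detour wired by adding random links from the remaining nodes to the outer
  region or detour until every detour node has degree $\ge 2$. The recipe
  leaves two choices open, fixed here as: each outer node joins a uniformly
  random nonempty subset of the core; and when the outer region fails to
  connect with the detour, only the detour wiring is redrawn (keeping $n$,
  $c$, $o$), with a 1000-attempt budget before erroring rather than looping
  forever. Duplicate links are collapsed. `standard_detour()` is the
  deterministic variant: $o = 2$, the outer nodes joined to the two halves
  of the core (ceiling/floor for odd cores), and a path detour from one
  outer node to the other. With $c = n - 2$ the path vanishes and the two
  bridge nodes join directly — exactly the **l-graph** (`l_graph()`), the
  known true suppressor family.
* **Generalized stars** `generalized_star(n, a, p)`: complete bipartite
  $K_{a, n-a}$ plus Bernoulli($p$) links inside the $a$-partition; $a = 1$
  is the star.
* **Coupled stars** `coupled_star(n, a)`: two joined centers with $a$ and
  $n - a - 2$ leaves; always a tree.

The category sweep used for tagging mirrors the construction grids
($c = 1..N{-}1$, $t \in \{1,2\}$ plus standard kites; detour cores
$c = 2..N{-}4$ plus all standard detours; $a = 1..N/2$ with $p$ on a
0.1-spaced grid, a desk-scale coarsening of a percent-resolution sweep;
coupled stars $a = 0..(N{-}2)/2$). A graph in several families gets the
first tag in the order generalized star, coupled star, detour, comet-kite —
the plain star is the degenerate $a = 0$ coupled star, and the order keeps
it with its usual family.

## Classification and temperature

`classify_graph()` compares exact $\varphi$ against the complete graph on a
fitness grid (default $\{0.5, 0.75, 1.25, 1.5, 1.75, 2\}$, the
several-values-of-$r$ practice of numerical classification; under dB the
reference is the exactly solved complete graph rather than the closed form).
Differences below `tolerance` ($10^{-9}$) count as zero, which is what makes
regular graphs classify as isothermal at machine precision. A sign change of
$\varphi - \varphi_{K_N}$ inside $r > 1$ yields the piecewise verdict, and
the crossing is bracketed on the grid and bisected with the exact solver to
a default width of $10^{-3}$ in $r$. A grid is only as good as its span:
the standard detour on 10 nodes with core 4 suppresses up to $r \approx
3.2$ and amplifies beyond, so a grid capped at 2 would (correctly, per the
sign pattern it sees) call it a suppressor. Verdicts are properties of the
isomorphism class: results are cached under canonical labels.

The **temperature** of node $j$, $T_j = \sum_{i \sim j} 1/\deg i$, is its
replacement rate under Bd up to the constant $1/N$; temperatures always sum
to $N$. `temperature_profile()` reports the population variance (denominator
$N$) of the $T_j$ as the graph's heterogeneity, and
`heterogeneity_correlation()` its Pearson correlation with $\varphi$ across
a graph set — Pearson because the claim being checked is a linear
association on a bounded range; the correlation is strongly positive across
all 112 classes of size 6 at $r = 1.25$.

## The genetic algorithm

`run_ga()` searches graph space for extremes of $\varphi$ or $\tau$ at fixed
$(N, r)$. Graphs are encoded as indicator vectors over the $\binom N2$
possible links ("gene codes"). Each generation: score the pool exactly with
the solver, keep the best $k$ as parents, build $m$ offspring by
recombination (each link inherited from either parent with probability 1/2,
redrawn until connected), and mutate (each link toggles with probability
$b/\binom N2$, a Binomial($\binom N2$, $b/\binom N2$) mutation count with
mean $b$). Defaults are $m = 120$, $k = 20$, $b = 1$, 5000 iterations;
reduced settings ($m = 40$, $k = 5$, 1000 iterations) recover all exhaustive
optima up to $N = 8$ in the tests, in the spirit of validating the heuristic
against the systematic scan before trusting it at sizes where no scan is
possible.

Where the recipe is silent, the package fixes:

* **Pairing:** both parents of an offspring are drawn uniformly with
  replacement from the top $k$, required distinct.
* **Connectivity after mutation:** regeneration until connected is specified
  for recombination; mutation gets the same treatment by necessity, since a
  disconnected graph has no defined fixation dynamics here.
* **Elitism:** the $k$ parents re-enter the evaluated pool next to their
  offspring, which is what makes the per-generation best score weakly
  monotone.
* **Initialization:** connected Erdős–Rényi graphs with link probability
  0.5 (unstated in the source recipe; 0.5 makes the initial population
  uniform over labeled graphs before the connectivity filter).
* **Tie-breaking:** equal scores resolve toward the lexicographically
  smallest canonical graph6 string, so a seeded run is fully deterministic.

Scores are cached by canonical label, so isomorphic graphs are never solved
twice — within a run (the invariant the `evaluations` field reports) or
across runs in a session.

## What the tests do and do not show

All validation inputs are generated in code: enumerated classes, seeded
Erdős–Rényi draws, and the family generators above. The suite works at desk
scale — exhaustive scans at $N \in \{6, 7, 8\}$, GA validation at
$N \in \{6, 8\}$ with the reduced settings, spot checks at $N = 10$
($2^{10}$-state solves), Monte Carlo at $10^5$ replicates — sizes chosen so
the full suite runs in a few minutes on one core while still exercising
every claim: the counts 112 / 11,117 / 11,716,571 / 1,006,700,565; the star
as $\varphi$-maximizer and the complete graph as $\tau$-minimizer; the
l-graph as true suppressor and the detour's suppression-to-amplification
switch; the slow coupled star against the matched two-center generalized
star. Passing them shows the machinery is exact and the landscape geometry
reproduces at these sizes; it says nothing about $N$ beyond the solver cap,
directed or weighted structures, or update rules other than Bd/dB, and the
GA remains a heuristic without optimality guarantees at sizes where no
exhaustive scan can confirm it.

## Known limitations

* The $2^N$ state space limits exact solves to roughly $N \le 16$ here
  (approaches exploiting no symmetry reach $N \approx 23$; approximation
  schemes are deliberately out of scope).
* graph6 I/O covers the single-byte-header dialect ($N \le 62$); sparse6
  and digraph6 are not supported.
* Exact counts stop at $n = 13$, the last size whose connected count is
  exactly representable as a double.
* Category tags are by construction (membership in a generator sweep), not
  a decision rule on arbitrary graphs; a graph outside the swept parameter
  grids stays "other".
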