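# evograph

Exact fixation probabilities and times for the Moran process on undirected,
unweighted graphs — and tools to explore the whole universe of small
evolutionary graphs.

## The problem

Population structure changes the fate of mutations. In evolutionary graph
theory, one individual sits on each node of a graph; a mutant of relative
fitness *r* competes against residents of fitness 1, and in every elementary
step of **Birth-death (Bd)** updating an individual reproduces with
probability proportional to fitness and its offspring replaces a random
neighbor (**death-Birth (dB)** updating is also implemented). Two quantities
decide whether a structure is useful — say, for designing an experimental
system where beneficial mutations should take over reliably *and* quickly:

- the **fixation probability** φ of a single, uniformly placed mutant, and
- the **mean conditional fixation time** τ, the expected number of update
  steps until takeover given takeover.

On the complete graph (the well-mixed baseline) φ has the classical closed
form (1 − 1/r)/(1 − r⁻ᴺ), and every regular graph matches it (the
isothermal property). *Amplifiers* of selection beat it for advantageous
mutants and fall below it for deleterious ones; *suppressors* are the
reverse; some graphs switch between the two regimes at a critical *r*.

The package computes φ and τ **exactly** by solving the 2ᴺ-state absorbing
Markov chain of the mutant set (default cap N ≤ 16), and around the solver
provides:

- enumeration of *all* connected graphs of a size (one representative per
  isomorphism class, native cap N = 8, graph6-file interop beyond) with
  exact analytic Pólya/Euler-transform counts as cross-check;
- generators for the extremal families: generalized stars, coupled stars,
  detour graphs, comet-kites, l-graphs;
- a genetic algorithm over graph space to find graphs minimizing or
  maximizing φ or τ when exhaustive scans are impossible;
- amplifier/suppressor/piecewise classification, node temperatures and
  heterogeneity, the probability–time plane with `autoplot()`, and
  broom-style `tidy()`/`glance()` on every result object;
- a Monte Carlo simulator (Rcpp) as an independent check of the solver, and
  graph6 / edge-list I/O interoperable with nauty's `geng`.

## Worked example

How much probability does the star buy, and at what cost in time, compared
with the well-mixed population of the same size?

```r
library(evograph)

fixation(star_graph(10), r = 1.25)
#> Moran fixation (Bd updating, r = 1.25)
#> graph6: IsaCCA?_?  N = 10
#> uniform fixation probability phi = 0.3099373
#> uniform conditional time     tau = 572.8

glance(fixation(complete_graph(10), r = 1.25))
#> # A tibble: 1 × 6
#>   n_nodes     r rule  phi_uniform tau_uniform graph6
#>     <dbl> <dbl> <chr>       <dbl>       <dbl> <chr>
#> 1      10  1.25 Bd          0.224        75.8 I~~~~~~~w
```

The star amplifies selection (φ = 0.310 vs 0.224 for K₁₀) but takes about
7.5 times longer to fix — the probability–time tradeoff in one pair of
numbers. A detour graph shows the opposite specialty, and its verdict can
flip with *r*:

```r
classify_graph(standard_detour(10, 4),
               r_grid = c(0.5, 0.8, 1.25, 1.5, 2, 3, 5, 8))
#> Graph IR`?OSF@w (N = 10, Bd): piecewise
#> suppression switches to amplification in r = (3.1875, 3.188477)
```

Below r ≈ 3.19 this graph suppresses selection, above it amplifies — the
"piecewise suppressor" behavior, with the critical fitness bracketed by
bisection against the exact solver. Counting, by contrast, needs no solver
at all:

```r
count_graphs(11)
#> # A tibble: 1 × 3
#>       n all_graphs connected_graphs
#>   <int>      <dbl>            <dbl>
#> 1    11 1018997864       1006700565
```

A billion connected graphs on 11 nodes is why exhaustive scans stop at
small sizes and the genetic algorithm (`run_ga()`, `ga_config()`) takes
over. Scans themselves are one call, `exhaustive_scan(8, r = 1.25)`, and
`build_plane(8, r = 1.25) |> autoplot()` draws the probability–time plane
with the extremal families highlighted.

A thin CLI over the same functions ships in `inst/cli/evograph`
(subcommands `fixation`, `scan`, `count`, `generate`, `ga`, `classify`), e.g.
`Rscript $(Rscript -e 'cat(system.file("cli","evograph",package="evograph"))') count --n 11`.

See the vignette (`vignettes/evolutionary-graphs.Rmd`) for the model, the
numerical conventions, and every design choice.

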