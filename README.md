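# echonet

Simulation toolkit for studying how **group homophily** shapes
**information spreading** on social networks — and when it produces
**echo chambers**.

The package is aimed at computational social scientists and network
epidemiologists who want a reproducible, tested implementation of the
following pipeline:

1. **Networks.** Scale-free networks grown by preferential attachment with
   a binary minority/majority attribute. The probability that a new node of
   group *g* attaches to an existing node *j* is

   Π<sub>j</sub> ∝ h·k<sub>j</sub> (same group) or (1−h)·k<sub>j</sub>
   (different group),

   with homophily h ∈ [0, 1]: h = 0.5 recovers group-blind
   Barabási–Albert growth, h = 1 fragments the network into two
   single-group components (`bah_network()`).
2. **Contagion.** Three single-seed models run to the absorbing state
   (`run_simple()`, `run_complex()`, `run_hybrid()`):
   *Simple* — one-shot SIR, each link attempted once with infectivity λ;
   *Complex* — strict threshold adoption (informed-neighbor fraction > T);
   *Hybrid* — the seed's group spreads by simple contagion with λ = 1
   while the other group adopts by the threshold rule.
3. **Observables.** The four group-to-group transmission probabilities
   IT<sub>ab</sub> (source group a, target group b), estimated by Monte
   Carlo as mean final informed densities (`estimate_it_matrix()`), and
   their exact linear decomposition into mean transmission ĪT, emissivity
   bias B<sub>E</sub>, receptivity bias B<sub>R</sub> and echo-chamber bias

   B<sub>EC</sub> = ½ (IT<sub>mm</sub> − IT<sub>mM</sub> − IT<sub>Mm</sub> + IT<sub>MM</sub>)

   (`bias_decompose()` / `bias_invert()`). B<sub>EC</sub> > 0 means
   within-group transmission dominates: an echo chamber.
4. **Phase analysis.** Final-density histograms over a threshold grid,
   detection of the critical threshold T<sub>c</sub> where the global
   maximum jumps from full contagion to no contagion — including the
   *divergent* case where spreading survives every threshold
   (`threshold_scan()`, `threshold_homophily_sweep()`).
5. **Empirical networks.** Readers for attributed edge lists, largest
   connected component extraction, and a simulation-matching estimator of
   the homophily parameter (`read_attributed_network()`,
   `estimate_homophily()`).

The hot loops (network growth, cascades, Monte-Carlo ensembles) run in
C++ through Rcpp on R's own RNG stream, so everything is reproducible
with `set.seed()` / `seed =` arguments.

## Worked example

Grow a homophilic network (N = 1000, 20% minority, h = 0.8), estimate the
hybrid-contagion transmission matrix at threshold T = 0.3, and decompose
it into biases:

```r
library(echonet)

g <- bah_network(1000, minority_fraction = 0.2, homophily = 0.8, seed = 42)
s <- group_degree_summary(g)
s$groups
#>      group n_nodes within_edges mean_degree max_degree
#> 1 minority     224           92    1.540179         11
#> 2 majority     776          746    2.130155         63

m <- estimate_it_matrix(bah_config(1000, homophily = 0.8),
                        dynamics_config("hybrid", threshold = 0.3),
                        n_realizations = 300, seed = 42)
m
#> Information-transmission matrix (source -> target)
#>           target
#> source     minority majority
#>   minority   0.0453   0.0056
#>   majority   0.4364   0.6580
#> standard errors: mm=0.0050 mM=0.0007 Mm=0.0133 MM=0.0185
#> M = 300 realizations per source group

bias_decompose(m)
#> Information-transmission biases
#>   mean IT        +0.2863
#>   emissivity     +0.5217  (>0: majority sources spread better)
#>   receptivity    +0.0909  (>0: majority targets receive more)
#>   echo chamber   +0.1307  (>0: within-group flow dominates)
```

Reading: in this strongly homophilic network, information seeded in the
majority reaches two thirds of the majority (IT_MM = 0.66) but information
seeded in the minority almost never reaches the majority
(IT_mM = 0.006) — a positive echo-chamber bias, even though the network is
fully connected. The hubs belong to the majority (maximum degree 63
vs 11).

Critical thresholds come from density scans; at h = 0.6 a majority-seeded
hybrid cascade still has a finite critical threshold:

```r
sc <- threshold_scan(bah_config(500, homophily = 0.6), "hybrid", "majority",
                     n_realizations = 200, seed = 42)
sc$critical
#> Critical threshold T_c = 0.12
```

At higher homophily the scan reports a *divergent* threshold: the
contagion phase persists for every T.

## Command line

A thin CLI over the same functions ships in `inst/cli/echonet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","echonet.R",package="echonet"))')" \
    generate --n 1000 --h 0.8 --fa 0.2 --rng-seed 5 --out-prefix net
```

Subcommands: `generate`, `simulate`, `it-matrix`, `biases`, `phase`,
`empirical` (the last runs read → largest component → homophily estimate →
hybrid IT matrix → biases on an attributed edge list). Options can come
from a YAML file via `--config`; explicit flags win, and the resolved
configuration is echoed into every output.

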