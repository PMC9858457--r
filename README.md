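# flicker

Local information dynamics and flickering emergence in Markovian systems.

Information-theoretic accounts of emergence score a system by how much its
past informs its own future: coarse-graining ("causal") emergence asks
whether a macro-scale model of a discrete Markov chain is more *effective*
than the micro-scale one, and integrated (ΦID) emergence asks whether the
*whole* of a multi-element system synergistically predicts its own future
beyond what its parts do. Both are expectations of a temporal mutual
information — and the pointwise terms of that expectation can be negative.
`flicker` computes both families of measures **per transition**, exposing
the moments where an on-average emergent structure locally inverts sign and
becomes misinformative ("flickering emergence"). It is aimed at researchers
in complex systems, network neuroscience and systems biology who work with
transition-matrix models, Boolean networks, or random walkers on weighted
graphs.

## The measures

For a chain with row-stochastic TPM $P(x_t \mid x_{t-1})$ and a prior over
past states:

* local excess entropy of one transition
  $e(x) = \log_2 \frac{P(x_{t-1},x_t)}{P(x_{t-1})P(x_t)}$ (bits; sign-free),
  with expectation $E(X) = I(X_{t-1}; X_t) \ge 0$;
* effective information $F(X) = E(X)$ under a uniform prior, effectiveness
  $\bar F(X) = F(X)/\log_2 N \in [0,1]$;
* coarse-graining emergence of a micro→macro surjection $g$:
  $\log_2 \bar F(\tilde X)/\bar F(X) > 0$, with a per-transition incongruity
  census (micro-informative transitions whose macro projection is
  misinformative);
* for two-element systems, the 16-atom ΦID double-redundancy lattice solved
  per transition by Möbius inversion of a union-event (shared-exclusions)
  temporal redundancy; the top atom `{12}->{12}` is the causal-decoupling /
  temporal-synergy component, `{12}->{1}`-type atoms the downward-causation
  components;
* random-walker TPMs of weighted graphs, macro-node renormalization over a
  node partition, per-edge local excess entropy and within/between-community
  censuses.

## Worked example

The bundled example is a four-node Boolean network whose element pairs
`{X1,X2}` and `{X3,X4}` are aggregated by logical-AND gates into a
two-element macro system. (Its TPMs are a documented *synthetic stand-in*
generated from explicit rules — see `?figure1_standin_system` — because the
published example matrices are available only as a figure image.)

```r
library(flicker)
ex <- figure1_example()   # micro system, AND mapping, macro system

effectiveness(ex$micro)            # 0.2602
effectiveness(ex$macro)            # 0.4598
emergence_score(ex$micro, ex$mapping)
#> [1] 0.8217
```

The macro model resolves a larger share of its own future uncertainty than
the micro model (score > 0: causal emergence). Locally, that advantage
flickers:

```r
incongruity_census(ex$micro, ex$mapping)
#> Cross-scale incongruity census (256 realizable micro transitions, prior: uniform)
#>       informative_informative    informative_misinformative
#>                            84                            11
#>    misinformative_informative misinformative_misinformative
#>                             6                            91
#>              neutral_involved
#>                            64
#> informative micro -> misinformative macro: 11.58%
```

11.58% of micro-informative transitions project onto *misinformative*
macro transitions. The ΦID view of the macro pair shows the same duality
for integrated emergence:

```r
r <- expected_phiid(ex$macro, prior = "stationary")
causal_decoupling(r)
#> [1] 0.0407    # bits: positive expected temporal synergy
negative_atom_census(ex$macro, "{12}->{12}", prior = "stationary")
#> [1] 0.5       # half of the 16 transitions have locally negative synergy
```

Per-step traces along a sampled walk make the flicker visible
(`cross_scale_series()` flags steps with `e_micro > 0` and `e_macro < 0`;
`phiid_series()` tracks the local causal-decoupling atom):

```r
traj <- sample_walk(ex$micro, 12, seed = 1)
head(cross_scale_series(traj, ex$micro, ex$mapping), 4)
#>   step from   to   e_micro   e_macro     ratio incongruous
#> 1    1 1000 0000 0.8279510 0.7653581 0.9244003       FALSE
#> 2    2 0000 0000 0.8279510 0.7653581 0.9244003       FALSE
#> 3    3 0000 0100 0.6674247 0.7653581 1.1467334       FALSE
#> 4    4 0100 0000 0.8279510 0.7653581 0.9244003       FALSE
```

Network analyses follow the same pattern on graphs:

```r
mg <- modular_graph(c(8, 8, 8), within_weight = 1, between_weight = 0.15, seed = 1)
scale_effectiveness(mg$graph, mg$partition)
community_census(mg$graph, mg$partition)   # misinformative edges sit between communities
```

A thin command-line wrapper with `ei`, `emerge`, `phiid`, `net`, `walk` and
`gen` subcommands lives at
`system.file("cli", "flicker.R", package = "flicker")`.

## Acceptance script

`scripts/acceptance.R` recomputes the worked example's four headline
quantities from scratch against the installed package — the emergence
score, the expected causal-decoupling atom, the incongruity-census
percentage, and the negative-synergy-census percentage — and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/flickering-emergence.Rmd` documents the model and its
assumptions, the priors and tolerances, the macro-construction and
redundancy-function choices, what the synthetic generators do and do not
emulate, and known limitations.
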