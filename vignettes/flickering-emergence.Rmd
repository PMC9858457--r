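---
title: "Local information dynamics and flickering emergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local information dynamics and flickering emergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flicker)
```

## The model

`flicker` works on finite, discrete-time Markov chains given as labelled,
row-stochastic transition probability matrices (TPMs): entry $(i, j)$ is
$P(X_t = j \mid X_{t-1} = i)$. Everything the package computes derives from
the one-step joint distribution $P(x_{t-1}, x_t)$ that a TPM induces once a
prior over past states is fixed. Two assumptions are therefore built in:

* **Markovianity.** The infinite-history excess entropy is represented by
  its one-step restriction $E(X) = I(X_{t-1}; X_t)$. Systems with longer
  memory are modelled only through their one-step statistics.
* **Exact distributions.** All quantities are evaluated from the given TPM
  and prior; nothing is estimated from finite samples. Plug-in entropy
  estimation is deliberately out of scope, and the random-walk analyses
  localize *model* quantities along a trajectory rather than re-estimating
  them from its empirical frequencies.

On top of the expected measures, every quantity is *localized*: the local
(pointwise) mutual information of one transition,
$e(x) = \log_2 \frac{P(x_{t-1}, x_t)}{P(x_{t-1})\,P(x_t)}$, may be negative
even though its expectation cannot. A negative value ("misinformation")
marks a transition the chain makes *despite* its own temporal statistics.
Flickering emergence is the observation that emergence measures built from
temporal mutual information inherit this sign freedom transition by
transition.

Two emergence lenses are implemented:

1. **Coarse-graining (causal) emergence.** Effective information
   $F(X)$ is the excess entropy under a uniform ("maximum-entropy",
   intervention-like) prior on past states; effectiveness is
   $\bar F = F / \log_2 N$. A surjection $g$ from micro states onto macro
   states is emergent when $\log_2 \bar F(\tilde X)/\bar F(X) > 0$
   (`emergence_score()`). Locally, `incongruity_census()` tabulates
   transitions informative at the micro scale whose projection under $g$ is
   misinformative at the macro scale.
2. **Integrated (PhiID) emergence.** For a two-element system the excess
   entropy decomposes additively over the sixteen source→target antichain
   pairs of the double-redundancy lattice. The lattice is seeded by a
   localizable double-redundancy function and solved by Möbius inversion
   (`local_phiid()`); the top atom `{12}->{12}` is the causal-decoupling
   (temporal synergy) component. Its local value flickers in sign along
   trajectories even when its expectation is positive (`phiid_series()`).

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| prior over past states | most functions | uniform for effective-information-style and network analyses; stationary for PhiID | effectiveness is defined under the maximum-entropy prior, and the cross-scale censuses are compared against it; the PhiID literature does not force a max-entropy prior, so the self-consistent stationary distribution is the default there and uniform is selectable everywhere |
| sign tolerance `tol` | censuses, series | 1e-10 (bits) | the sources define informative/misinformative by strict sign only; values within 1e-10 of zero are classed "neutral" and excluded from incongruity fractions rather than attributed a sign they do not robustly have |
| row-sum tolerance | `tpm()` | 1e-6 | absorbs decimal round-off of text-serialized matrices; larger deviations are treated as data errors, not renormalized silently |
| `within_group_weighting` | `macro_tpm()`, `macro_node_graph()` | uniform over the preimage | the macro construction is not pinned down by the sources; conditioning uniformly within each macro state is the maximum-entropy choice consistent with the interventionist reading of effective information. A stationary-weighted option exists, and results record the mode used |
| `noise` | `boolean_network()` | 0.1 in the worked example | a per-element flip probability of 0.1 keeps deterministic logic visibly dominant while giving every transition positive probability, the regime in which local sign structure is non-trivial |
| `concentration` | `random_tpm()` | 1 | flat Dirichlet: rows uniform on the simplex, no bias toward either the deterministic or the memoryless extreme |

## Numerical choices

* **Log base 2 everywhere;** all information quantities are in bits, and the
  emergence score uses base-2 logs (the criterion's sign is base-invariant).
* **Zero-probability transitions are undefined, not $-\infty$.** A
  transition with zero joint probability raises a classed error
  (`flicker_undefined_transition`) in pointwise functions and is excluded
  from censuses; matrix-valued outputs carry `NA` there. Negative-atom
  censuses keep all $N^2$ formal transitions in the denominator and count
  unrealizable ones as non-negative.
* **Stationary distributions** come from the unit eigenvector of the
  transposed TPM. When the unit eigenvalue is degenerate (reducible chains,
  e.g. the identity), power iteration from the uniform distribution picks a
  canonical fixed point and the result is flagged `unique = FALSE` rather
  than erroring — toy deterministic systems are legitimately reducible.
* **Cross-scale projection** uses the pushforward of the micro joint
  distribution through the mapping, so the macro prior is always the exact
  projection of the micro prior and every realizable micro transition has a
  realizable macro image. Under a uniform micro prior this coincides with
  the uniform-within-preimage macro TPM.
* **Möbius inversion** is evaluated bottom-up in down-set order; the test
  suite cross-checks it against an independent linear solve of the zeta
  matrix.

## Design choices where the design was open

* **The double-redundancy function.** The decomposition literature
  delegates the lattice's bottom to an external redundancy function. The
  package implements the temporal shared-exclusions form: the local mutual
  information between the *union* of the source antichain's realization
  events and the union of the target antichain's events. On the top atom
  this reduces exactly to the transition's local excess entropy, which is
  what makes the decomposition sum correctly. Because this is the one
  under-specified ingredient, `local_phiid()` takes the redundancy function
  as an argument, so alternatives (e.g. a minimum over pairwise local
  informations) can be swapped without touching the lattice or inversion
  code.
* **Effectiveness in bits or unitless.** Reported network effectiveness
  values in the literature are sometimes bit-valued although the ratio is
  unitless; `scale_effectiveness()` therefore returns both $F$ (bits) and
  $\bar F$ (unitless) at both scales, labelled distinctly.
* **"Downward causation".** Whether the term denotes one atom
  (`{12}->{1}`) or the sum over all three joint-source atoms is not fixed;
  `downward_causation()` returns the sum by default and the individual
  atoms with `atoms = TRUE`.
* **Census denominators.** The cross-scale incongruity census runs over
  realizable transitions only (unrealizable ones have no local value); the
  negative-atom census uses all sixteen formal transitions, matching the
  "sixteen possible transitions" convention. Both conventions are
  documented on the respective functions.
* **Community detection is input, not implementation.** Network censuses
  take the partition as data (file or named vector); any detector from
  `igraph` can produce it, and no result depends on which one did.

## The synthetic generators — and what a green test does not establish

`random_tpm()` draws Dirichlet rows; `boolean_network()` composes exact
Bernoulli-product rows around deterministic update rules;
`modular_graph()` plants a block partition with exponential edge weights
(mean `within_weight` inside blocks, `between_weight` across; weight zero
means no edge). All are seed-deterministic and carry their generating
parameters.

The worked example (`figure1_example()`) deserves a caveat it also carries
in its documentation: the published four-node example system's numeric
TPMs exist only as an image, so the bundled files are a **synthetic
stand-in** generated by `figure1_standin_system()` — explicit OR/XOR
group-level rules around AND-aggregated pairs at flip noise 0.1, chosen
once because they robustly exhibit the qualitative phenomena (positive
emergence score, positive expected causal decoupling, non-trivial
incongruity and negative-synergy censuses). Consequently:

* green tests establish that the *machinery* is correct (decompositions
  sum, censuses match brute-force enumeration, identities hold) and that
  the *phenomena* occur on a system built to display them;
* they do **not** establish the published example's numeric values
  (≈0.202 emergence score, ≈0.031 bit expected decoupling, ≈52.73%
  incongruity, 31.25% negative synergy). The stand-in's own values —
  0.8217, 0.0407 bit, 11.58%, 50% — are frozen as regression anchors, not
  as reproductions. A user holding a faithful transcription of the
  published matrices can pass it to `figure1_example()`, which
  cross-validates the macro construction and then yields the genuine
  comparison.

Similarly, `modular_graph()` emulates only the *modularity* of empirical
connectome-style networks, not their degree heterogeneity, geometry or
weight distributions; the replicated finding (misinformative walker edges
concentrate between communities) is a direction of effect, not an effect
size.

## Known limitations

* The PhiID machinery is strictly two-element: `double_lattice(n)` errors
  for `n != 2`. Larger systems can still be coarse-grained to two macro
  elements first, as the worked example does.
* No search over coarse-grainings is provided; the emergence score
  evaluates a *given* mapping.
* Local mutual information is unbounded, so per-transition values admit no
  effectiveness-style normalization; cross-scale comparisons of local
  values are therefore sign-based.
* Walk-based analyses assume every trajectory step is realizable under the
  analysis prior; a prior assigning zero mass to a visited state makes the
  corresponding local value undefined.
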