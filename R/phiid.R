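#' The double-redundancy lattice for a two-element system
#'
#' Enumerates the integrated information decomposition (PhiID) lattice: every
#' atom is a pair of antichains (source at `t - 1`, target at `t`) over the
#' element set, ordered by the product of the single-side redundancy orders
#' (`alpha <= alpha'` iff every member of `alpha'` contains some member of
#' `alpha`). For two elements there are four antichains — `{1}{2}`, `{1}`,
#' `{2}`, `{12}` — and hence sixteen atoms, with bottom `{1}{2}->{1}{2}` and
#' top `{12}->{12}`.
#'
#' Systems with more than two elements are out of scope: the lattice and the
#' localizable double-redundancy function implemented here are the
#' two-element machinery.
#'
#' @param n Number of elements; only `n = 2` is supported.
#' @return Object of class `"double_lattice"`: `atoms` (named list of
#'   `list(source, target)` antichains, each antichain a list of integer
#'   index vectors), `order` (16 x 16 logical matrix of the reflexive
#'   partial order, `order[i, j]` meaning atom i precedes-or-equals atom j),
#'   and `down_sets` (strict predecessors per atom, as index vectors).
#' @export
double_lattice <- function(n = 2) {
  if (n != 2) {
    stop("only the two-element double-redundancy lattice (16 atoms) is supported")
  }
  antichains <- list(
    "{1}{2}" = list(1L, 2L),
    "{1}" = list(1L),
    "{2}" = list(2L),
    "{12}" = list(c(1L, 2L))
  )
  atoms <- list()
  for (s in names(antichains)) {
    for (t_ in names(antichains)) {
      atoms[[paste0(s, "->", t_)]] <- list(
        source = antichains[[s]],
        target = antichains[[t_]],
        source_name = s,
        target_name = t_
      )
    }
  }
  ac_leq <- function(a, b) {
    all(vapply(b, function(B) {
      any(vapply(a, function(A) all(A %in% B), logical(1)))
    }, logical(1)))
  }
  nm <- names(atoms)
  ord <- matrix(FALSE, 16L, 16L, dimnames = list(nm, nm))
  for (i in seq_len(16L)) {
    for (j in seq_len(16L)) {
      ord[i, j] <- ac_leq(atoms[[i]]$source, atoms[[j]]$source) &&
        ac_leq(atoms[[i]]$target, atoms[[j]]$target)
    }
  }
  down <- lapply(seq_len(16L), function(j) setdiff(which(ord[, j]), j))
  names(down) <- nm
  structure(
    list(atoms = atoms, order = ord, down_sets = down, antichains = antichains),
    class = "double_lattice"
  )
}

#' @export
print.double_lattice <- function(x, ...) {
  cat(sprintf("Double-redundancy lattice: %d atoms\n", length(x$atoms)))
  cat(paste(names(x$atoms), collapse = "  "), "\n")
  invisible(x)
}

#' Parse an atom name such as `"{12}->{12}"`
#'
#' @param name Atom name in index notation, e.g. `"{1}{2}->{12}"`.
#' @param lattice A [double_lattice].
#' @return The atom (list with `source` and `target` antichains).
#' @export
parse_atom <- function(name, lattice = double_lattice(2)) {
  atom <- lattice$atoms[[name]]
  if (is.null(atom)) {
    stop(
      "unknown atom '", name, "'; valid atoms: ",
      paste(names(lattice$atoms), collapse = ", ")
    )
  }
  atom
}

check_two_elements <- function(system) {
  if (!inherits(system, "element_system")) {
    stop("`system` must be an element_system")
  }
  if (length(system$element_names) != 2L) {
    stop("PhiID analyses require a two-element system")
  }
  system
}

# Logical vector over product states: TRUE where the state agrees with the
# observed tuple `obs` on at least one member subset of the antichain (the
# union / disjunction of realization events).
union_event <- function(states, antichain, obs) {
  sel <- rep(FALSE, nrow(states))
  for (A in antichain) {
    hit <- rep(TRUE, nrow(states))
    for (el in A) hit <- hit & states[, el] == obs[[el]]
    sel <- sel | hit
  }
  sel
}

#' Localizable temporal double-redundancy (shared-exclusions form)
#'
#' The redundancy function that seeds the PhiID lattice, evaluated on a
#' single transition: the local mutual information between the union
#' (disjunction) of the source antichain's realization events at `t - 1` and
#' the union of the target antichain's events at `t`,
#' `log2 P(U_past & U_fut) / (P(U_past) P(U_fut))`, with probabilities under
#' the joint one-step distribution induced by the prior. On the top atom
#' (singleton unions `{12}->{12}`) this reduces to the plain local excess
#' entropy of the transition. The function is one pluggable ingredient:
#' [local_phiid] accepts any alternative with the same signature.
#'
#' @param system A two-element [element_system].
#' @param source,target Product-state labels at `t - 1` and `t`.
#' @param atom An atom of the [double_lattice] (or its name).
#' @param prior Prior over past product states (see [resolve_prior]).
#' @param jt Optional precomputed [joint_transition] (an optimization used
#'   by the lattice solvers).
#' @return Local redundancy in bits (possibly negative).
#' @export
local_double_redundancy <- function(system, source, target, atom,
                                    prior = "stationary", jt = NULL) {
  system <- check_two_elements(system)
  if (is.character(atom)) atom <- parse_atom(atom)
  if (is.null(jt)) jt <- joint_transition(system$tpm, prior)
  ij <- transition_index(jt, source, target)
  if (jt$joint[ij["i"], ij["j"]] <= 0) undefined_transition(source, target)
  obs_past <- system$states[ij["i"], ]
  obs_fut <- system$states[ij["j"], ]
  sel_past <- union_event(system$states, atom$source, obs_past)
  sel_fut <- union_event(system$states, atom$target, obs_fut)
  p_past <- sum(jt$marginal_past[sel_past])
  p_fut <- sum(jt$marginal_future[sel_fut])
  p_both <- sum(jt$joint[sel_past, sel_fut])
  log2(p_both / (p_past * p_fut))
}

#' Moebius inversion on the double-redundancy lattice
#'
#' Recursively converts cumulative redundancy values on the lattice nodes
#' into the partial ("atom") values:
#' `partial(a) = redundancy(a) - sum of partial over strict predecessors`.
#' Summing the partials over any node's inclusive down-set recovers that
#' node's redundancy, and the total over all sixteen atoms equals the
#' redundancy of the top node.
#'
#' @param lattice A [double_lattice].
#' @param redundancy Named numeric vector of redundancy values, one per atom
#'   (names matching `names(lattice$atoms)`).
#' @return Named numeric vector of partial values in the same order.
#' @export
mobius_invert <- function(lattice, redundancy) {
  nm <- names(lattice$atoms)
  if (!all(nm %in% names(redundancy))) {
    stop("`redundancy` must supply a value for every atom")
  }
  redundancy <- redundancy[nm]
  partial <- stats::setNames(numeric(length(nm)), nm)
  for (j in order(lengths(lattice$down_sets))) {
    partial[j] <- redundancy[j] - sum(partial[lattice$down_sets[[j]]])
  }
  partial
}

#' Local integrated information decomposition of one transition
#'
#' Evaluates the redundancy function on all sixteen atoms for a single
#' transition and solves the lattice by Moebius inversion, decomposing the
#' transition's local excess entropy `e(t)` into sixteen additive local
#' atoms. Individual atoms (and `e(t)` itself) may be negative; a negative
#' causal-decoupling atom on a transition of a system whose expected
#' decoupling is positive is the PhiID form of incongruous dynamics.
#'
#' @inheritParams local_double_redundancy
#' @param lattice The [double_lattice] to solve (default: built fresh).
#' @param redundancy_fn Redundancy function with the signature of
#'   [local_double_redundancy]; swap in alternatives here.
#' @return Object of class `"phiid_result"`: `transition`, `redundancy` and
#'   `partial` (named 16-vectors, bits), `total` (= local excess entropy of
#'   the transition), and `prior`.
#' @export
local_phiid <- function(system, source, target, prior = "stationary",
                        lattice = double_lattice(2),
                        redundancy_fn = local_double_redundancy) {
  system <- check_two_elements(system)
  jt <- joint_transition(system$tpm, prior)
  red <- vapply(
    names(lattice$atoms),
    function(a) {
      redundancy_fn(system, source, target, lattice$atoms[[a]],
        prior = prior, jt = jt
      )
    },
    numeric(1)
  )
  partial <- mobius_invert(lattice, red)
  structure(
    list(
      transition = c(source = source, target = target),
      redundancy = red,
      partial = partial,
      total = unname(red[["{12}->{12}"]]),
      prior = if (is.character(prior)) prior else "custom"
    ),
    class = "phiid_result"
  )
}

#' Expected integrated information decomposition
#'
#' The joint-probability-weighted mean of the local PhiID atoms over all
#' realizable transitions. Because the Moebius inversion is linear, the
#' expected partials solve the lattice of expected redundancies, and their
#' total equals the excess entropy of the system under the chosen prior.
#'
#' @inheritParams local_phiid
#' @return A `"phiid_result"` with `transition = "expected"`.
#' @export
expected_phiid <- function(system, prior = "stationary",
                           lattice = double_lattice(2),
                           redundancy_fn = local_double_redundancy) {
  system <- check_two_elements(system)
  jt <- joint_transition(system$tpm, prior)
  nz <- which(jt$joint > 0, arr.ind = TRUE)
  nm <- names(lattice$atoms)
  red <- stats::setNames(numeric(length(nm)), nm)
  partial <- stats::setNames(numeric(length(nm)), nm)
  for (r in seq_len(nrow(nz))) {
    src <- jt$labels[nz[r, 1L]]
    tgt <- jt$labels[nz[r, 2L]]
    w <- jt$joint[nz[r, 1L], nz[r, 2L]]
    loc <- local_phiid(system, src, tgt,
      prior = prior, lattice = lattice,
      redundancy_fn = redundancy_fn
    )
    red <- red + w * loc$redundancy
    partial <- partial + w * loc$partial
  }
  structure(
    list(
      transition = "expected",
      redundancy = red,
      partial = partial,
      total = unname(red[["{12}->{12}"]]),
      prior = if (is.character(prior)) prior else "custom"
    ),
    class = "phiid_result"
  )
}

#' @export
print.phiid_result <- function(x, ...) {
  what <- if (identical(x$transition, "expected")) {
    "expected over transitions"
  } else {
    paste(x$transition["source"], "->", x$transition["target"])
  }
  cat(sprintf(
    "PhiID decomposition (%s; prior: %s; total %.4f bit)\n",
    what, x$prior, x$total
  ))
  print(round(x$partial, 4))
  invisible(x)
}

#' Causal decoupling and downward causation atoms
#'
#' `causal_decoupling()` extracts the top atom `{12}->{12}` — the synergistic
#' information the whole (and only the whole) discloses about its own future
#' ("temporal synergy"). `downward_causation()` returns the total over the
#' atoms whose source is the joint `{12}` and whose target antichain does not
#' contain `{12}` (`{12}->{1}`, `{12}->{2}`, `{12}->{1}{2}`): synergy in the
#' whole's past informing the futures of simpler parts. Set `atoms = TRUE`
#' for the three individual values, since usage in the literature sometimes
#' means a single such atom.
#'
#' @param r A `"phiid_result"`.
#' @param atoms If `TRUE`, return the named individual downward atoms
#'   instead of their sum.
#' @return Bits (a scalar, or a named 3-vector when `atoms = TRUE`).
#' @export
causal_decoupling <- function(r) {
  stopifnot(inherits(r, "phiid_result"))
  unname(r$partial[["{12}->{12}"]])
}

#' @rdname causal_decoupling
#' @export
downward_causation <- function(r, atoms = FALSE) {
  stopifnot(inherits(r, "phiid_result"))
  dc <- r$partial[c("{12}->{1}", "{12}->{2}", "{12}->{1}{2}")]
  if (atoms) dc else sum(dc)
}

# Joint distribution of one element's (past, future) pair, collapsed from the
# product-state joint.
element_joint <- function(system, jt, element) {
  symbols <- system$alphabets[[element]]
  M <- matrix(0, nrow(system$states), length(symbols),
    dimnames = list(NULL, symbols)
  )
  M[cbind(seq_len(nrow(M)), match(system$states[, element], symbols))] <- 1
  t(M) %*% jt$joint %*% M
}

mi_from_joint <- function(J) {
  denom <- outer(rowSums(J), colSums(J))
  nz <- J > 0
  sum(J[nz] * log2(J[nz] / denom[nz]))
}

#' Heuristic integration Phi (whole minus sum of parts)
#'
#' The classic heuristic for integrated emergence: the excess entropy of the
#' joint system minus the summed excess entropies of its elements' marginal
#' chains (each obtained by collapsing the joint one-step distribution to
#' that element). Zero for fully independent elements; positive when the
#' joint state carries predictive information inaccessible from any single
#' part; negative when redundant information shared between elements swamps
#' the synergy.
#'
#' @param system An [element_system] (any element count >= 2).
#' @param prior Prior over past product states (see [resolve_prior]).
#' @return Phi in bits (sign-free).
#' @export
heuristic_phi <- function(system, prior = "stationary") {
  if (!inherits(system, "element_system")) stop("`system` must be an element_system")
  if (length(system$element_names) < 2L) stop("Phi needs at least two elements")
  jt <- joint_transition(system$tpm, prior)
  marg <- vapply(
    seq_along(system$element_names),
    function(i) mi_from_joint(element_joint(system, jt, i)),
    numeric(1)
  )
  mi_from_joint(jt$joint) - sum(marg)
}

#' Census of transitions with a negative local atom
#'
#' Fraction of the `N^2` formal transitions of a two-element system whose
#' local value of a given atom is below `-tol`. The denominator is all `N^2`
#' transitions (for two Boolean elements, sixteen); transitions unrealizable
#' under the prior have no local value and are counted as non-negative,
#' unless no transition is realizable at all, in which case the census is
#' undefined.
#'
#' @inheritParams local_phiid
#' @param atom Atom name (e.g. `"{12}->{12}"`) or atom object.
#' @param tol Negativity tolerance.
#' @return Fraction in `[0, 1]`, with attribute `counts` =
#'   `c(negative, realizable, total)`.
#' @export
negative_atom_census <- function(system, atom = "{12}->{12}",
                                 prior = "stationary", tol = 1e-10,
                                 lattice = double_lattice(2),
                                 redundancy_fn = local_double_redundancy) {
  system <- check_two_elements(system)
  if (!is.character(atom)) {
    atom <- names(lattice$atoms)[vapply(
      lattice$atoms, identical, logical(1), atom
    )][1L]
  }
  parse_atom(atom, lattice) # validates
  jt <- joint_transition(system$tpm, prior)
  labels <- jt$labels
  n_neg <- 0L
  n_real <- 0L
  for (src in labels) {
    for (tgt in labels) {
      if (jt$joint[src, tgt] <= 0) next
      n_real <- n_real + 1L
      val <- local_phiid(system, src, tgt,
        prior = prior, lattice = lattice,
        redundancy_fn = redundancy_fn
      )$partial[[atom]]
      if (val < -tol) n_neg <- n_neg + 1L
    }
  }
  total <- length(labels)^2
  if (n_real == 0L) {
    return(structure(NA_real_, counts = c(negative = 0L, realizable = 0L, total = total)))
  }
  structure(
    n_neg / total,
    counts = c(negative = n_neg, realizable = n_real, total = total)
  )
}
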