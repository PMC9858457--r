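#' Multi-element discrete system
#'
#' Wraps a [tpm] whose states are tuples over per-element alphabets (a Boolean
#' network, for example, has one binary element per node and `2^k` product
#' states). State labels serialize each tuple as the concatenation of its
#' symbols, enumerated with the first element varying slowest ("0000", "0001",
#' ..., "1111" for four binary elements).
#'
#' @param x A [tpm] over the full product state space.
#' @param element_names Character vector naming the elements.
#' @param alphabets List of character vectors, one finite alphabet per
#'   element. Defaults to binary `c("0", "1")` for every element.
#' @return Object of class `"element_system"` with fields `tpm`,
#'   `element_names`, `alphabets`, and `states` (N x k symbol matrix, one row
#'   per product state in label order).
#' @export
element_system <- function(x, element_names,
                           alphabets = rep(list(c("0", "1")), length(element_names))) {
  x <- as_tpm(x)
  if (length(element_names) < 1L) stop("at least one element is required")
  if (length(alphabets) != length(element_names)) {
    stop("one alphabet per element is required")
  }
  st <- product_states(element_names, alphabets)
  if (nrow(st$states) != n_states(x)) {
    stop(sprintf(
      "TPM has %d states but the product alphabet has %d",
      n_states(x), nrow(st$states)
    ))
  }
  if (!identical(st$labels, state_labels(x))) {
    stop("TPM state labels must equal the product enumeration: ",
      paste(utils::head(st$labels, 8L), collapse = ", "),
      if (length(st$labels) > 8L) ", ..."
    )
  }
  structure(
    list(
      tpm = x,
      element_names = as.character(element_names),
      alphabets = alphabets,
      states = st$states
    ),
    class = "element_system"
  )
}

#' @export
print.element_system <- function(x, ...) {
  cat(sprintf(
    "Discrete system: %d elements (%s), %d product states\n",
    length(x$element_names), paste(x$element_names, collapse = ", "),
    n_states(x$tpm)
  ))
  invisible(x)
}

# Enumerate product states: first element varies slowest, matching the usual
# binary-counting order of serialized labels such as "0110".
product_states <- function(element_names, alphabets) {
  k <- length(alphabets)
  grid <- expand.grid(rev(alphabets),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- as.matrix(grid)[, rev(seq_len(k)), drop = FALSE]
  colnames(grid) <- element_names
  rownames(grid) <- NULL
  list(states = grid, labels = apply(grid, 1L, paste0, collapse = ""))
}

#' Micro-to-macro state mapping
#'
#' A total surjection `g` from the states of a micro-scale TPM onto a smaller
#' macro state space; the object all coarse-graining analyses are driven by.
#'
#' @param map Named character vector: `names(map)` are micro-state labels,
#'   values are macro-state labels.
#' @param macro_labels Ordered macro label set; defaults to the sorted unique
#'   values of `map`. Every macro label must be hit (surjectivity).
#' @param provenance Optional free-form description of how the mapping was
#'   built (e.g. an element partition plus gate names).
#' @return Object of class `"state_mapping"`.
#' @export
state_mapping <- function(map, macro_labels = sort(unique(unname(map))),
                          provenance = NULL) {
  if (is.null(names(map)) || anyNA(names(map)) || any(names(map) == "")) {
    stop("`map` must be named by micro-state label")
  }
  map <- vapply(map, as.character, character(1))
  if (anyDuplicated(names(map))) stop("duplicate micro-state labels in `map`")
  macro_labels <- as.character(macro_labels)
  if (!all(map %in% macro_labels)) {
    stop("`map` contains macro labels missing from `macro_labels`")
  }
  if (!all(macro_labels %in% map)) {
    stop("mapping must be surjective: every macro label needs a preimage")
  }
  structure(
    list(
      map = map,
      micro_labels = names(map),
      macro_labels = macro_labels,
      provenance = provenance
    ),
    class = "state_mapping"
  )
}

#' @export
print.state_mapping <- function(x, ...) {
  cat(sprintf(
    "State mapping: %d micro states -> %d macro states\n",
    length(x$micro_labels), length(x$macro_labels)
  ))
  if (!is.null(x$provenance)) cat("provenance:", format(x$provenance), "\n")
  invisible(x)
}

check_mapping <- function(x, mapping) {
  x <- as_tpm(x)
  if (!inherits(mapping, "state_mapping")) stop("`mapping` must be a state_mapping")
  if (!setequal(mapping$micro_labels, state_labels(x))) {
    stop("mapping is not defined on exactly the micro TPM's states")
  }
  mapping
}

# 0/1 membership matrix, micro states x macro states, in label order.
mapping_matrix <- function(x, mapping) {
  x <- as_tpm(x)
  macro <- mapping$map[state_labels(x)]
  M <- matrix(0, n_states(x), length(mapping$macro_labels),
    dimnames = list(state_labels(x), mapping$macro_labels)
  )
  M[cbind(seq_len(nrow(M)), match(macro, mapping$macro_labels))] <- 1
  M
}

builtin_gates <- list(
  AND = function(bits) as.character(as.integer(all(bits == "1"))),
  OR = function(bits) as.character(as.integer(any(bits == "1"))),
  XOR = function(bits) as.character(sum(bits == "1") %% 2L),
  MAJORITY = function(bits) {
    as.character(as.integer(sum(bits == "1") > length(bits) / 2))
  },
  COPY = function(bits) bits[[1L]]
)

boolean_gate <- function(gate) {
  if (is.function(gate)) return(gate)
  if (!is.character(gate) || !gate %in% names(builtin_gates)) {
    stop(
      "unknown gate '", format(gate), "'; built-ins are ",
      paste(names(builtin_gates), collapse = ", ")
    )
  }
  g <- builtin_gates[[gate]]
  attr(g, "boolean") <- !identical(gate, "COPY")
  g
}

#' Logic-gate coarse-graining of a multi-element system
#'
#' Partitions the elements of a system into groups and collapses each group's
#' joint state through a named aggregation gate (e.g. grouping node pairs with
#' logical AND), producing the induced mapping from micro product states to
#' macro product states. Macro states are enumerated lexicographically over
#' the per-group output alphabets.
#'
#' @param system An [element_system].
#' @param element_partition List of character vectors of element names (or
#'   integer index vectors); must cover all elements disjointly. Group order
#'   determines macro tuple order.
#' @param gates One gate per group (recycled if length 1): a built-in name
#'   (`"AND"`, `"OR"`, `"XOR"`, `"MAJORITY"`, `"COPY"` — the first four
#'   require binary alphabets; `"COPY"` forwards the group's first element) or
#'   a function mapping a character vector of member symbols to one output
#'   symbol.
#' @return A [state_mapping] with gate provenance attached.
#' @export
gate_mapping <- function(system, element_partition, gates = "AND") {
  if (!inherits(system, "element_system")) stop("`system` must be an element_system")
  k <- length(system$element_names)
  idx <- lapply(element_partition, function(g) {
    if (is.character(g)) {
      i <- match(g, system$element_names)
      if (anyNA(i)) stop("unknown element name(s): ", paste(g[is.na(i)], collapse = ", "))
      i
    } else {
      as.integer(g)
    }
  })
  flat <- unlist(idx)
  if (length(flat) != k || anyDuplicated(flat) || !setequal(flat, seq_len(k))) {
    stop("`element_partition` must cover all elements exactly once")
  }
  if (length(gates) == 1L) gates <- rep(list(if (is.list(gates)) gates[[1L]] else gates), length(idx))
  if (length(gates) != length(idx)) stop("need one gate per group")
  gate_fns <- lapply(gates, boolean_gate)
  for (gi in seq_along(idx)) {
    if (isTRUE(attr(gate_fns[[gi]], "boolean"))) {
      alph <- unique(unlist(system$alphabets[idx[[gi]]]))
      if (!all(alph %in% c("0", "1"))) {
        stop("gate ", gi, " is Boolean but its group's alphabet is not {0, 1}")
      }
    }
  }
  micro_labels <- state_labels(system$tpm)
  outputs <- vapply(seq_along(micro_labels), function(s) {
    paste0(
      vapply(seq_along(idx), function(gi) {
        out <- gate_fns[[gi]](system$states[s, idx[[gi]]])
        if (!is.character(out) || length(out) != 1L) {
          stop("gate ", gi, " must return a single character symbol")
        }
        out
      }, character(1)),
      collapse = ""
    )
  }, character(1))
  group_alphabets <- lapply(seq_along(idx), function(gi) {
    sort(unique(vapply(
      seq_along(micro_labels),
      function(s) gate_fns[[gi]](system$states[s, idx[[gi]]]), character(1)
    )))
  })
  macro_labels <- product_states(
    paste0("G", seq_along(idx)), group_alphabets
  )$labels
  macro_labels <- macro_labels[macro_labels %in% outputs] # drop unreachable combos
  state_mapping(
    structure(outputs, names = micro_labels),
    macro_labels = macro_labels,
    provenance = list(
      partition = lapply(idx, function(i) system$element_names[i]),
      gates = vapply(gates, function(g) if (is.character(g)) g else "<function>", character(1))
    )
  )
}

#' Macro-scale TPM induced by a coarse-graining
#'
#' Builds `P(macro_j | macro_i)` from a micro TPM and a [state_mapping] by
#' conditioning on each macro state through a within-preimage weighting:
#' `P(y~ | x~) = sum_{x in g^-1(x~)} w(x | x~) sum_{y in g^-1(y~)} P(y | x)`.
#' The default weighting is uniform over the preimage (maximum entropy within
#' the macro state, the interventionist convention of effective information);
#' `"stationary"` weights micro states by the micro chain's stationary
#' distribution conditioned on the preimage.
#'
#' @param micro A [tpm] or [element_system] at the micro scale.
#' @param mapping A [state_mapping] defined on the micro states.
#' @param weighting `"uniform"`, `"stationary"`, or a numeric vector over
#'   micro states (named or in label order) that is normalized within each
#'   preimage.
#' @return A [tpm] over the macro labels, with attribute `"weighting"`.
#' @export
macro_tpm <- function(micro, mapping, weighting = "uniform") {
  micro <- as_tpm(micro)
  mapping <- check_mapping(micro, mapping)
  M <- mapping_matrix(micro, mapping)
  w <- within_preimage_weights(micro, M, weighting)
  macro <- t(w * M) %*% micro$matrix %*% M
  out <- tpm(macro, labels = mapping$macro_labels)
  attr(out, "weighting") <- if (is.character(weighting)) weighting else "custom"
  out
}

within_preimage_weights <- function(micro, M, weighting) {
  if (is.character(weighting)) {
    weighting <- match.arg(weighting, c("uniform", "stationary"))
    base <- switch(weighting,
      uniform = rep(1, n_states(micro)),
      stationary = as.vector(stationary_distribution(micro))
    )
  } else {
    base <- as.vector(resolve_prior(micro, weighting)) * n_states(micro)
  }
  totals <- as.vector(t(M) %*% base) # mass per macro preimage
  if (any(totals <= 0)) {
    stop("weighting assigns zero total mass to a macro preimage")
  }
  base / as.vector(M %*% totals)
}

# Pushforward of a micro joint transition distribution through a mapping.
push_joint <- function(jt, M, macro_labels) {
  Jm <- t(M) %*% jt$joint %*% M
  dimnames(Jm) <- list(macro_labels, macro_labels)
  structure(
    list(
      joint = Jm,
      prior = rowSums(Jm),
      marginal_past = rowSums(Jm),
      marginal_future = colSums(Jm),
      labels = macro_labels
    ),
    class = "joint_transition"
  )
}

#' Coarse-graining causal-emergence score
#'
#' The log-ratio of macro to micro effectiveness,
#' `log2( effectiveness(macro) / effectiveness(micro) )`; a positive value is
#' the causal-emergence criterion (the macro model resolves a greater share
#' of its own future uncertainty than the micro model does).
#'
#' @inheritParams macro_tpm
#' @param base Base of the logarithm (2, the package default, reports the
#'   score in bits; the sign is base-invariant).
#' @return Numeric score; `+Inf` (with a warning) when the micro
#'   effectiveness is zero, making the ratio undefined.
#' @export
emergence_score <- function(micro, mapping, weighting = "uniform", base = 2) {
  micro <- as_tpm(micro)
  mapping <- check_mapping(micro, mapping)
  if (length(mapping$macro_labels) < 2L) {
    stop("emergence score needs at least two macro states")
  }
  f_micro <- effectiveness(micro)
  f_macro <- effectiveness(macro_tpm(micro, mapping, weighting))
  if (f_micro <= 0) {
    warning("micro effectiveness is zero; emergence score is undefined (+Inf)")
    return(Inf)
  }
  log(f_macro / f_micro, base = base)
}

#' Local excess entropy of one transition at both scales
#'
#' Evaluates a micro transition's local excess entropy together with the
#' local excess entropy of its projected macro transition
#' `(g(source), g(target))`. The macro joint distribution is the pushforward
#' of the micro joint through the mapping, so the macro prior is always the
#' projection of the micro prior and a realizable micro transition always
#' projects onto a realizable macro transition.
#'
#' @inheritParams macro_tpm
#' @param source,target Micro state labels at `t - 1` and `t`.
#' @param prior Prior over micro past states (see [resolve_prior]).
#' @return Named numeric vector `c(e_micro, e_macro)` in bits.
#' @export
local_scale_pair <- function(micro, mapping, source, target, prior = "uniform") {
  micro <- as_tpm(micro)
  mapping <- check_mapping(micro, mapping)
  jt <- joint_transition(micro, prior)
  e_micro <- local_mutual_information(jt, source, target)
  jm <- push_joint(jt, mapping_matrix(micro, mapping), mapping$macro_labels)
  e_macro <- local_mutual_information(
    jm, mapping$map[[source]], mapping$map[[target]]
  )
  c(e_micro = e_micro, e_macro = e_macro)
}

#' Cross-scale incongruity census
#'
#' Classifies every realizable micro transition by the signs of its local
#' excess entropy at the micro scale and at the projected macro scale.
#' Incongruous dynamics — the signature of flickering emergence — occur when
#' a transition informative at the micro scale (`e_micro > tol`) projects
#' onto a misinformative macro transition (`e_macro < -tol`). The headline
#' fraction is the share of informative micro transitions that do so.
#'
#' @inheritParams local_scale_pair
#' @param tol Sign-neutrality tolerance (see [classify_sign]).
#' @return Object of class `"cross_scale_census"`: a list with `transitions`
#'   (data frame of realizable transitions with `e_micro`, `e_macro`, sign
#'   classes and `incongruous` flag), `counts` (the four sign-pair counts
#'   plus neutral-involving count), `headline_fraction`, `n_realizable`,
#'   and the prior mode used.
#' @export
incongruity_census <- function(micro, mapping, prior = "uniform", tol = 1e-10) {
  micro <- as_tpm(micro)
  mapping <- check_mapping(micro, mapping)
  jt <- joint_transition(micro, prior)
  M <- mapping_matrix(micro, mapping)
  jm <- push_joint(jt, M, mapping$macro_labels)

  denom_micro <- outer(jt$marginal_past, jt$marginal_future)
  e_micro_mat <- matrix(NA_real_, nrow(jt$joint), ncol(jt$joint))
  nz <- jt$joint > 0
  e_micro_mat[nz] <- log2(jt$joint[nz] / denom_micro[nz])

  denom_macro <- outer(jm$marginal_past, jm$marginal_future)
  e_macro_mat <- matrix(NA_real_, nrow(jm$joint), ncol(jm$joint))
  nzm <- jm$joint > 0
  e_macro_mat[nzm] <- log2(jm$joint[nzm] / denom_macro[nzm])

  idx <- which(nz, arr.ind = TRUE)
  labels <- state_labels(micro)
  macro_of <- match(mapping$map[labels], mapping$macro_labels)
  df <- data.frame(
    source = labels[idx[, 1L]],
    target = labels[idx[, 2L]],
    macro_source = mapping$map[labels[idx[, 1L]]],
    macro_target = mapping$map[labels[idx[, 2L]]],
    probability = jt$joint[idx],
    e_micro = e_micro_mat[idx],
    e_macro = e_macro_mat[cbind(macro_of[idx[, 1L]], macro_of[idx[, 2L]])],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  df$micro_class <- classify_sign(df$e_micro, tol)
  df$macro_class <- classify_sign(df$e_macro, tol)
  df$incongruous <- df$micro_class == "informative" &
    df$macro_class == "misinformative"

  counts <- c(
    informative_informative = sum(df$micro_class == "informative" & df$macro_class == "informative"),
    informative_misinformative = sum(df$incongruous),
    misinformative_informative = sum(df$micro_class == "misinformative" & df$macro_class == "informative"),
    misinformative_misinformative = sum(df$micro_class == "misinformative" & df$macro_class == "misinformative"),
    neutral_involved = sum(df$micro_class == "neutral" | df$macro_class == "neutral")
  )
  n_inf <- sum(df$micro_class == "informative")
  structure(
    list(
      transitions = df,
      counts = counts,
      n_realizable = nrow(df),
      headline_fraction = if (n_inf > 0) counts[["informative_misinformative"]] / n_inf else NA_real_,
      prior = if (is.character(prior)) prior else "custom",
      tol = tol
    ),
    class = "cross_scale_census"
  )
}

#' @export
print.cross_scale_census <- function(x, ...) {
  cat(sprintf(
    "Cross-scale incongruity census (%d realizable micro transitions, prior: %s)\n",
    x$n_realizable, x$prior
  ))
  print(x$counts)
  if (is.na(x$headline_fraction)) {
    cat("no informative micro transitions; headline fraction undefined\n")
  } else {
    cat(sprintf(
      "informative micro -> misinformative macro: %.2f%%\n",
      100 * x$headline_fraction
    ))
  }
  invisible(x)
}

#' Macro-scale system induced by a gate coarse-graining
#'
#' Convenience wrapper packaging [macro_tpm] as an [element_system] whose
#' elements are the groups of a gate-built mapping, ready for the PhiID
#' analyses (which require an element-resolved macro system).
#'
#' @inheritParams macro_tpm
#' @param element_names Names for the macro elements; defaults to `"Y1"`,
#'   `"Y2"`, ...
#' @return An [element_system] over the macro states.
#' @export
macro_system <- function(micro, mapping, weighting = "uniform",
                         element_names = NULL) {
  mt <- macro_tpm(micro, mapping, weighting)
  width <- unique(nchar(mapping$macro_labels))
  if (length(width) != 1L) {
    stop("macro labels are not fixed-width tuples; cannot infer elements")
  }
  k <- width
  symbols <- lapply(seq_len(k), function(i) {
    sort(unique(substr(mapping$macro_labels, i, i)))
  })
  if (is.null(element_names)) element_names <- paste0("Y", seq_len(k))
  element_system(mt, element_names, symbols)
}
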