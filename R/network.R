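#' Random-walker TPM of a weighted graph
#'
#' Converts a weighted graph into the transition matrix of an unbiased random
#' walker: row `u` is node `u`'s out-edge weights normalized by its
#' out-strength. Undirected edges contribute both directions (walker dynamics
#' are directional). Nodes with zero out-strength (sinks / isolates) are
#' rejected because the walk is undefined there.
#'
#' @param g An `igraph` graph, optionally with an edge `weight` attribute
#'   (unweighted graphs count each edge as weight 1). Vertex `name`
#'   attributes become state labels; unnamed vertices are labelled `"v1"`,
#'   `"v2"`, ...
#' @return A [tpm] over the nodes.
#' @export
walk_tpm <- function(g) {
  A <- graph_adjacency(g)
  s <- rowSums(A)
  if (any(s <= 0)) {
    stop(
      "node(s) with zero out-strength: ",
      paste(rownames(A)[s <= 0], collapse = ", ")
    )
  }
  tpm(A / s, labels = rownames(A))
}

graph_adjacency <- function(g) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph graph")
  attr_name <- if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
  if (!is.null(attr_name) && any(igraph::E(g)$weight < 0)) {
    stop("negative edge weights are not allowed")
  }
  A <- igraph::as_adjacency_matrix(g, attr = attr_name, sparse = FALSE)
  nms <- igraph::vertex_attr(g, "name")
  if (is.null(nms)) nms <- paste0("v", seq_len(nrow(A)))
  dimnames(A) <- list(nms, nms)
  A
}

as_node_partition <- function(partition, labels) {
  if (is.data.frame(partition)) {
    partition <- stats::setNames(
      as.character(partition[[2L]]),
      as.character(partition[[1L]])
    )
  }
  if (is.null(names(partition))) {
    if (length(partition) != length(labels)) {
      stop("unnamed partition must have one community per node")
    }
    names(partition) <- labels
  }
  if (!setequal(names(partition), labels)) {
    stop("partition must cover exactly the graph's nodes")
  }
  stats::setNames(as.character(partition)[match(labels, names(partition))], labels)
}

#' Collapse a graph's communities into macro-nodes
#'
#' Renormalizes a weighted graph over a node partition: each community
#' becomes one macro-node and the macro transition probability `C -> D`
#' aggregates the walker flow of the constituent nodes. The default
#' aggregation averages, uniformly over the nodes of `C`, their total walk
#' probability into `D` (maximum entropy within the macro-node, consistent
#' with [macro_tpm]); `"stationary"` weights constituents by the micro
#' walker's stationary distribution instead. Macro rows are stochastic by
#' construction, so the returned graph's edge weights are directly the
#' macro walker TPM.
#'
#' @param g An `igraph` graph (see [walk_tpm]).
#' @param partition Node partition: named vector `node -> community` or a
#'   two-column data frame.
#' @param aggregation `"uniform"` or `"stationary"`.
#' @return List with `graph` (directed, weighted igraph over communities),
#'   `tpm` (the macro walker [tpm]), and `aggregation`.
#' @export
macro_node_graph <- function(g, partition, aggregation = c("uniform", "stationary")) {
  aggregation <- match.arg(aggregation)
  W <- walk_tpm(g)
  partition <- as_node_partition(partition, state_labels(W))
  mapping <- state_mapping(partition)
  macro <- macro_tpm(W, mapping, weighting = aggregation)
  mg <- igraph::graph_from_adjacency_matrix(
    as.matrix(macro),
    mode = "directed", weighted = TRUE, diag = TRUE
  )
  list(graph = mg, tpm = macro, aggregation = aggregation)
}

#' Per-edge local excess entropy of a random walker
#'
#' Evaluates, for every positive-weight (directed) edge, the local excess
#' entropy of the walker transition it carries; informative edges help
#' predict the walker's next position, misinformative edges actively
#' mislead. Undirected edges yield two directed rows.
#'
#' @param g An `igraph` graph (see [walk_tpm]).
#' @param prior Prior over nodes (see [resolve_prior]); default uniform,
#'   matching the effective-information convention.
#' @return Data frame with columns `from`, `to`, `weight`, `probability`
#'   (walker transition probability), and `e` (bits).
#' @export
edge_local_excess <- function(g, prior = "uniform") {
  A <- graph_adjacency(g)
  W <- tpm(A / rowSums(A), labels = rownames(A))
  E_mat <- local_information_matrix(W, prior)
  idx <- which(A > 0, arr.ind = TRUE)
  data.frame(
    from = rownames(A)[idx[, 1L]],
    to = colnames(A)[idx[, 2L]],
    weight = A[idx],
    probability = as.matrix(W)[idx],
    e = E_mat[idx],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Within/between-community census of informative and misinformative edges
#'
#' Classifies every directed edge of the graph by the sign of its walker
#' local excess entropy and tabulates, per sign class, the proportion of
#' edges falling within a community versus linking two different
#' communities. Also reports the incongruous fraction: the share of
#' informative micro edges whose macro image (the community-to-community
#' walker transition, under the pushforward joint distribution) is
#' misinformative.
#'
#' @inheritParams macro_node_graph
#' @param prior Prior over nodes (see [resolve_prior]).
#' @param tol Sign-neutrality tolerance.
#' @return Object of class `"edge_census"`: `edges` (per-edge data frame
#'   with `e`, `class`, `within`, `e_macro`, `incongruous`), `fractions`
#'   (within/between proportions per sign class), `incongruous_fraction`,
#'   and `counts`.
#' @export
community_census <- function(g, partition, prior = "uniform", tol = 1e-10) {
  A <- graph_adjacency(g)
  W <- tpm(A / rowSums(A), labels = rownames(A))
  partition <- as_node_partition(partition, state_labels(W))
  mapping <- state_mapping(partition)

  jt <- joint_transition(W, prior)
  jm <- push_joint(jt, mapping_matrix(W, mapping), mapping$macro_labels)
  denom <- outer(jm$marginal_past, jm$marginal_future)
  e_macro_mat <- matrix(NA_real_, nrow(jm$joint), ncol(jm$joint),
    dimnames = dimnames(jm$joint)
  )
  nzm <- jm$joint > 0
  e_macro_mat[nzm] <- log2(jm$joint[nzm] / denom[nzm])

  edges <- edge_local_excess(g, prior)
  edges$community_from <- partition[edges$from]
  edges$community_to <- partition[edges$to]
  edges$within <- edges$community_from == edges$community_to
  edges$class <- classify_sign(edges$e, tol)
  edges$e_macro <- e_macro_mat[cbind(edges$community_from, edges$community_to)]
  edges$incongruous <- edges$class == "informative" &
    classify_sign(edges$e_macro, tol) == "misinformative"

  frac <- function(cls) {
    n <- sum(edges$class == cls)
    if (n == 0L) {
      return(c(within = NA_real_, between = NA_real_))
    }
    w <- sum(edges$class == cls & edges$within) / n
    c(within = w, between = 1 - w)
  }
  n_inf <- sum(edges$class == "informative")
  structure(
    list(
      edges = edges,
      fractions = list(
        informative = frac("informative"),
        misinformative = frac("misinformative")
      ),
      incongruous_fraction = if (n_inf > 0) sum(edges$incongruous) / n_inf else NA_real_,
      counts = c(
        edges = nrow(edges),
        informative = n_inf,
        misinformative = sum(edges$class == "misinformative"),
        neutral = sum(edges$class == "neutral")
      ),
      prior = if (is.character(prior)) prior else "custom",
      tol = tol
    ),
    class = "edge_census"
  )
}

#' @export
print.edge_census <- function(x, ...) {
  cat(sprintf(
    "Edge census: %d directed edges (%d informative, %d misinformative, %d neutral)\n",
    x$counts[["edges"]], x$counts[["informative"]],
    x$counts[["misinformative"]], x$counts[["neutral"]]
  ))
  f <- x$fractions
  cat(sprintf(
    "informative: %.1f%% within / %.1f%% between communities\n",
    100 * f$informative[["within"]], 100 * f$informative[["between"]]
  ))
  cat(sprintf(
    "misinformative: %.1f%% within / %.1f%% between communities\n",
    100 * f$misinformative[["within"]], 100 * f$misinformative[["between"]]
  ))
  if (!is.na(x$incongruous_fraction)) {
    cat(sprintf(
      "informative micro edges with misinformative macro image: %.2f%%\n",
      100 * x$incongruous_fraction
    ))
  }
  invisible(x)
}

#' Effective information and effectiveness at both network scales
#'
#' Compares the walker dynamics of the micro graph with those of its
#' macro-node renormalization. Both the raw effective information (bits)
#' and the normalized effectiveness are returned because reported values
#' in the literature sometimes quote one, sometimes the other.
#'
#' @inheritParams macro_node_graph
#' @return Named numeric vector: `micro_F`, `micro_effectiveness`,
#'   `macro_F`, `macro_effectiveness`.
#' @export
scale_effectiveness <- function(g, partition, aggregation = "uniform") {
  W <- walk_tpm(g)
  macro <- macro_node_graph(g, partition, aggregation)$tpm
  if (n_states(macro) < 2L) {
    stop("macro scale has fewer than two macro-nodes; effectiveness undefined")
  }
  c(
    micro_F = effective_information(W),
    micro_effectiveness = effectiveness(W),
    macro_F = effective_information(macro),
    macro_effectiveness = effectiveness(macro)
  )
}
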