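#' Random Dirichlet-row TPM
#'
#' Draws each row of an `n`-state TPM independently from a symmetric
#' Dirichlet distribution. Large concentrations approach uniform rows
#' (effectiveness near 0); small concentrations approach near-deterministic
#' rows (effectiveness near 1).
#'
#' @param n Number of states (>= 2).
#' @param concentration Symmetric Dirichlet concentration parameter (> 0).
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @param labels Optional state labels.
#' @return A [tpm].
#' @export
random_tpm <- function(n, concentration = 1, seed = NULL, labels = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2")
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("`concentration` must be positive")
  }
  draw <- function() {
    g <- matrix(stats::rgamma(n * n, shape = concentration), n, n)
    # guard against an all-zero row at tiny concentrations
    zero <- rowSums(g) == 0
    g[zero, ] <- 1 / n
    g / rowSums(g)
  }
  m <- with_local_seed(seed, draw())
  tpm(m, labels = labels %||% paste0("s", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noisy Boolean network as an element system
#'
#' Builds the product-state TPM of a Boolean network from one deterministic
#' update rule per element plus independent per-element flip noise:
#' `P(next | prev)` is the product over elements of a Bernoulli around each
#' rule's output (probability `1 - noise` of taking the ruled value,
#' `noise` of flipping). `noise = 0` gives the deterministic 0/1 TPM;
#' `noise = 0.5` erases all dynamics (uniform TPM).
#'
#' @param rules Named list of functions, one per element; each receives the
#'   full previous state as a named integer 0/1 vector and must return 0 or
#'   1.
#' @param noise Per-element flip probability in `[0, 0.5]`.
#' @param element_names Element names; defaults to `names(rules)`.
#' @return An [element_system] over `2^k` product states.
#' @export
boolean_network <- function(rules, noise = 0, element_names = names(rules)) {
  k <- length(rules)
  if (k < 1L) stop("at least one update rule is required")
  if (is.null(element_names)) element_names <- paste0("X", seq_len(k))
  if (!is.numeric(noise) || noise < 0 || noise > 0.5) {
    stop("`noise` must lie in [0, 0.5]")
  }
  st <- product_states(element_names, rep(list(c("0", "1")), k))
  n <- nrow(st$states)
  bits <- matrix(as.integer(st$states), n, k,
    dimnames = list(NULL, element_names)
  )
  ruled <- matrix(0L, n, k)
  for (s in seq_len(n)) {
    prev <- stats::setNames(bits[s, ], element_names)
    for (e in seq_len(k)) {
      out <- rules[[e]](prev)
      if (!length(out) == 1L || !out %in% c(0, 1)) {
        stop("rule for element ", element_names[e], " must return 0 or 1")
      }
      ruled[s, e] <- as.integer(out)
    }
  }
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      match_ <- sum(bits[j, ] == ruled[i, ])
      P[i, j] <- (1 - noise)^match_ * noise^(k - match_)
    }
  }
  element_system(
    tpm(P, labels = st$labels),
    element_names = element_names
  )
}

#' Synthetic stand-in for the four-node example system
#'
#' The worked example analysed throughout the package: a four-element
#' Boolean network whose pairs `{X1, X2}` and `{X3, X4}` are coarse-grained
#' by logical-AND gates into a two-element macro system. The published
#' example system's numeric transition matrices are available only as a
#' figure image, so this generator provides a SYNTHETIC stand-in built from
#' explicit update rules chosen (once) to exhibit the same qualitative
#' phenomena: positive coarse-graining emergence, positive expected causal
#' decoupling, and sign-flickering local values. Its printed outputs are
#' properties of this stand-in, not of the published matrices.
#'
#' Dynamics: with `a = X1 AND X2` and `b = X3 AND X4` at `t - 1`, elements
#' `X1, X2` update to `a OR b` and elements `X3, X4` to `a XOR b`, each
#' independently flipped with probability `noise`. Micro rows therefore
#' depend on the past state only through `(a, b)`, which is what makes the
#' AND macro model more effective than the micro model, and the XOR arm
#' gives the macro pair a genuinely synergistic (decoupling-positive)
#' temporal structure.
#'
#' @param noise Per-element flip probability (default 0.1).
#' @return An [element_system] with elements `X1 ... X4`.
#' @export
figure1_standin_system <- function(noise = 0.1) {
  or_rule <- function(s) {
    as.integer((s[["X1"]] & s[["X2"]]) | (s[["X3"]] & s[["X4"]]))
  }
  xor_rule <- function(s) {
    as.integer(xor(s[["X1"]] & s[["X2"]], s[["X3"]] & s[["X4"]]))
  }
  boolean_network(
    rules = list(
      X1 = or_rule, X2 = or_rule,
      X3 = xor_rule, X4 = xor_rule
    ),
    noise = noise,
    element_names = c("X1", "X2", "X3", "X4")
  )
}

#' Load the four-node example system and its AND coarse-graining
#'
#' Assembles the package's worked example: the micro element system, the
#' AND-gate mapping over element pairs `{X1, X2}` and `{X3, X4}`, and the
#' induced two-element macro system. By default the TPMs are read from the
#' bundled synthetic stand-in CSVs (see [figure1_standin_system] for why
#' they are synthetic); users holding a faithful transcription of the
#' published matrices can pass their own files in the same CSV dialect.
#' The macro TPM constructed from the micro TPM by uniform within-preimage
#' conditioning is cross-validated against the supplied macro file; a
#' mismatch raises a warning and is recorded in the result, signalling that
#' micro and macro files are mutually inconsistent under this package's
#' macro construction.
#'
#' @param micro_file Path to a 16 x 16 micro TPM CSV (states `"0000"` ...
#'   `"1111"`); `NULL` for the bundled stand-in.
#' @param macro_file Path to a 4 x 4 macro TPM CSV (states `"00"` ...
#'   `"11"`); `NULL` for the bundled stand-in.
#' @param check_tol Tolerance for the macro cross-validation.
#' @return List with `micro` ([element_system], 4 elements), `mapping`
#'   ([state_mapping]), `macro` ([element_system], 2 elements, built from
#'   the supplied macro TPM), and `macro_consistent` (logical).
#' @export
figure1_example <- function(micro_file = NULL, macro_file = NULL,
                            check_tol = 1e-8) {
  micro_file <- micro_file %||%
    system.file("extdata", "figure1_micro_synthetic.csv", package = "flicker")
  macro_file <- macro_file %||%
    system.file("extdata", "figure1_macro_synthetic.csv", package = "flicker")
  micro_tpm <- read_tpm_csv(micro_file)
  if (n_states(micro_tpm) != 16L) {
    stop("micro TPM must have 16 states (4 binary elements)")
  }
  micro <- element_system(micro_tpm, c("X1", "X2", "X3", "X4"))
  mapping <- gate_mapping(
    micro,
    element_partition = list(c("X1", "X2"), c("X3", "X4")),
    gates = "AND"
  )
  macro_given <- read_tpm_csv(macro_file)
  if (n_states(macro_given) != 4L) {
    stop("macro TPM must have 4 states (2 binary elements)")
  }
  macro_built <- macro_tpm(micro_tpm, mapping, weighting = "uniform")
  consistent <- isTRUE(all.equal(
    as.matrix(macro_built)[mapping$macro_labels, mapping$macro_labels],
    as.matrix(macro_given)[mapping$macro_labels, mapping$macro_labels],
    tolerance = check_tol, check.attributes = FALSE
  ))
  if (!consistent) {
    warning(
      "supplied macro TPM does not match the macro TPM constructed from the ",
      "micro TPM (uniform within-preimage conditioning); cross-validation failed"
    )
  }
  list(
    micro = micro,
    mapping = mapping,
    macro = element_system(macro_given, c("Y1", "Y2")),
    macro_consistent = consistent
  )
}

#' Synthetic modular (planted-partition) weighted graph
#'
#' Generates an undirected weighted graph with planted community structure:
#' every within-block node pair receives an exponential weight with mean
#' `within_weight`, every between-block pair one with mean `between_weight`
#' (a weight of exactly 0, as when `between_weight = 0`, means no edge).
#' With `within_weight > between_weight` the blocks are modular and, as in
#' empirical connectomes, misinformative walker edges concentrate between
#' communities. The planted partition is returned alongside the graph.
#'
#' @param block_sizes Integer vector of community sizes (>= 2 blocks).
#' @param within_weight,between_weight Mean edge weight within / between
#'   blocks (>= 0; modular structure requires `within > between`).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with `graph` (igraph, undirected, weighted), `partition`
#'   (named vector node -> block id), and `spec` (the generating
#'   parameters, for provenance).
#' @export
modular_graph <- function(block_sizes, within_weight = 1,
                          between_weight = 0.1, seed = NULL) {
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) < 2L || any(block_sizes < 1L)) {
    stop("need at least two non-empty blocks")
  }
  if (within_weight < 0 || between_weight < 0) {
    stop("weights must be non-negative")
  }
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  nodes <- paste0("n", seq_len(n))
  build <- function() {
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        mean_w <- if (block[i] == block[j]) within_weight else between_weight
        w <- if (mean_w > 0) stats::rexp(1L, rate = 1 / mean_w) else 0
        W[i, j] <- W[j, i] <- w
      }
    }
    W
  }
  W <- with_local_seed(seed, build())
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  list(
    graph = g,
    partition = stats::setNames(paste0("B", block), nodes),
    spec = list(
      kind = "modular_graph", block_sizes = block_sizes,
      within_weight = within_weight, between_weight = between_weight,
      seed = seed
    )
  )
}
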