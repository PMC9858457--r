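#' Labelled transition probability matrix
#'
#' Constructs a validated, row-stochastic transition probability matrix (TPM)
#' describing a finite, discrete-time Markov chain. Entry `(i, j)` is the
#' conditional probability of moving to state `j` at time `t` given state `i`
#' at time `t - 1`.
#'
#' Rows whose sums deviate from 1 by no more than `renormalize_tol` are
#' silently renormalized (this absorbs decimal round-off in transcribed or
#' text-serialized matrices); larger deviations are an error.
#'
#' @param matrix Square numeric matrix of conditional probabilities.
#' @param labels Character vector of unique state labels, one per row.
#'   Defaults to the matrix rownames, or `"s1" ... "sN"` when unnamed.
#' @param renormalize_tol Maximum tolerated absolute deviation of a row sum
#'   from 1 before renormalization is refused.
#'
#' @return An object of class `"tpm"`.
#' @examples
#' p <- tpm(rbind(c(0.9, 0.1), c(0.2, 0.8)), labels = c("a", "b"))
#' effective_information(p)
#' @export
tpm <- function(matrix, labels = rownames(matrix), renormalize_tol = 1e-6) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix")
  }
  n <- nrow(matrix)
  if (n < 1L) stop("a TPM needs at least one state")
  if (ncol(matrix) != n) {
    stop(sprintf("TPM must be square; got %d x %d", n, ncol(matrix)))
  }
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop(sprintf("%d labels supplied for %d states", length(labels), n))
  }
  if (anyDuplicated(labels)) stop("state labels must be unique")
  if (anyNA(matrix)) stop("TPM entries must not be NA")
  if (any(matrix < 0)) stop("TPM entries must be non-negative")
  rs <- rowSums(matrix)
  off <- abs(rs - 1)
  if (any(off > renormalize_tol)) {
    bad <- which.max(off)
    stop(sprintf(
      "row %d ('%s') sums to %.9g; deviation exceeds tolerance %g",
      bad, labels[bad], rs[bad], renormalize_tol
    ))
  }
  matrix <- matrix / rs
  dimnames(matrix) <- list(labels, labels)
  structure(list(matrix = matrix, labels = labels), class = "tpm")
}

#' @export
as.matrix.tpm <- function(x, ...) x$matrix

#' @export
print.tpm <- function(x, ...) {
  cat(sprintf("Transition probability matrix: %d states\n", n_states(x)))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Number of states and state labels of a TPM
#'
#' @param x A [tpm] (or an object wrapping one, such as an [element_system]).
#' @return `n_states()`: integer count of states; `state_labels()`: character
#'   vector of labels.
#' @export
n_states <- function(x) length(state_labels(x))

#' @rdname n_states
#' @export
state_labels <- function(x) {
  if (inherits(x, "element_system")) x <- x$tpm
  if (!inherits(x, "tpm")) stop("not a tpm")
  x$labels
}

as_tpm <- function(x) {
  if (inherits(x, "element_system")) return(x$tpm)
  if (!inherits(x, "tpm")) stop("expected a `tpm` or `element_system`")
  x
}

#' Stationary distribution of a TPM
#'
#' Solves `pi P = pi` by eigen-decomposition of the transpose. When the unit
#' eigenvalue is degenerate (a reducible or otherwise non-ergodic chain, e.g.
#' the identity), the fixed point reached by power iteration from the uniform
#' distribution is returned instead and the result carries
#' `attr(, "unique") = FALSE`.
#'
#' @param x A [tpm].
#' @param tol Numerical tolerance for identifying unit eigenvalues.
#' @return Named numeric vector summing to 1, with attribute `unique`.
#' @export
stationary_distribution <- function(x, tol = 1e-8) {
  x <- as_tpm(x)
  P <- x$matrix
  n <- nrow(P)
  if (n == 1L) {
    return(structure(c(1), names = x$labels, unique = TRUE))
  }
  ev <- eigen(t(P))
  unit <- which(abs(ev$values - 1) < tol)
  pi_ <- NULL
  unique_ <- length(unit) == 1L
  if (unique_) {
    v <- Re(ev$vectors[, unit])
    if (sum(v) != 0) {
      v <- v / sum(v)
      if (all(v >= -1e-9)) pi_ <- pmax(v, 0) / sum(pmax(v, 0))
    }
  }
  if (is.null(pi_)) {
    # power iteration from uniform: converges to a fixed point for any
    # row-stochastic matrix that has one reachable from the interior
    p <- rep(1 / n, n)
    for (i in seq_len(100000L)) {
      p_new <- as.vector(p %*% P)
      if (max(abs(p_new - p)) < 1e-14) {
        p <- p_new
        break
      }
      p <- p_new
    }
    pi_ <- p / sum(p)
  }
  structure(pi_, names = x$labels, unique = unique_)
}

#' Resolve a prior distribution over the states of a TPM
#'
#' @param x A [tpm].
#' @param prior `"uniform"` (the maximum-entropy prior used by effective
#'   information), `"stationary"`, or a numeric vector of length `n_states(x)`
#'   (optionally named by state label) summing to 1.
#' @return Named numeric probability vector over `state_labels(x)`.
#' @export
resolve_prior <- function(x, prior = c("uniform", "stationary")) {
  x <- as_tpm(x)
  n <- n_states(x)
  if (is.character(prior)) {
    prior <- match.arg(prior)
    p <- switch(prior,
      uniform = rep(1 / n, n),
      stationary = as.vector(stationary_distribution(x))
    )
    return(structure(p, names = x$labels))
  }
  if (!is.numeric(prior) || length(prior) != n) {
    stop("numeric prior must have one probability per state")
  }
  if (!is.null(names(prior))) {
    if (!setequal(names(prior), x$labels)) {
      stop("prior names do not match the TPM state labels")
    }
    prior <- prior[x$labels]
  }
  if (any(prior < -1e-12)) stop("prior probabilities must be non-negative")
  if (abs(sum(prior) - 1) > 1e-9) stop("prior must sum to 1")
  structure(pmax(prior, 0) / sum(pmax(prior, 0)), names = x$labels)
}

#' Joint one-step transition distribution
#'
#' Combines a TPM with a prior over past states into the joint distribution
#' `P(x_{t-1}, x_t)`, together with its past and future marginals. All local
#' and expected information measures are evaluated against this object.
#'
#' @inheritParams resolve_prior
#' @return Object of class `"joint_transition"` with elements `joint` (N x N
#'   matrix summing to 1), `prior`, `marginal_past`, `marginal_future`, and
#'   `labels`.
#' @export
joint_transition <- function(x, prior = "uniform") {
  x <- as_tpm(x)
  p <- resolve_prior(x, prior)
  joint <- p * x$matrix # recycles p down columns: joint[i, j] = p[i] P[j|i]
  structure(
    list(
      joint = joint,
      prior = p,
      marginal_past = p,
      marginal_future = colSums(joint),
      labels = x$labels
    ),
    class = "joint_transition"
  )
}

transition_index <- function(jt, source, target) {
  i <- match(source, jt$labels)
  j <- match(target, jt$labels)
  if (is.na(i)) stop(sprintf("unknown source state '%s'", source))
  if (is.na(j)) stop(sprintf("unknown target state '%s'", target))
  c(i = i, j = j)
}

undefined_transition <- function(source, target) {
  stop(errorCondition(
    sprintf(
      "transition '%s' -> '%s' has zero probability under this prior; local information is undefined",
      source, target
    ),
    class = "flicker_undefined_transition"
  ))
}

#' Shannon entropy of a probability vector (bits)
#'
#' @param p Numeric vector of non-negative probabilities summing to 1
#'   (tolerance 1e-9). Zero entries contribute zero.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (any(p < -1e-12)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Local (pointwise) mutual information of one transition
#'
#' The per-realization term of the mutual information,
#' `i(x; y) = log2 P(x, y) / (P(x) P(y))`, evaluated on a single
#' past/future pair under a [joint_transition]. Unlike its expectation it can
#' be negative: a negative value ("misinformation") marks a transition that
#' would be more probable under independence than under the chain's actual
#' temporal coupling.
#'
#' @param jt A [joint_transition].
#' @param source,target State labels at `t - 1` and `t`.
#' @return Local mutual information in bits.
#' @export
local_mutual_information <- function(jt, source, target) {
  ij <- transition_index(jt, source, target)
  pj <- jt$joint[ij["i"], ij["j"]]
  if (pj <= 0) undefined_transition(source, target)
  unname(log2(pj / (jt$marginal_past[ij["i"]] * jt$marginal_future[ij["j"]])))
}

#' Expected mutual information between past and future (bits)
#'
#' The joint-probability-weighted mean of [local_mutual_information] over all
#' realizable transitions; always non-negative.
#'
#' @param jt A [joint_transition].
#' @return Mutual information in bits.
#' @export
expected_mutual_information <- function(jt) {
  J <- jt$joint
  denom <- outer(jt$marginal_past, jt$marginal_future)
  nz <- J > 0
  sum(J[nz] * log2(J[nz] / denom[nz]))
}

#' Local excess entropy of a transition
#'
#' The local temporal mutual information `e(x) = i(x_{t-1}; x_t)` of a single
#' transition of a Markov chain. Negative exactly when
#' `P(x_t | x_{t-1}) < P(x_t)` under the chosen prior.
#'
#' @inheritParams joint_transition
#' @param source,target State labels at `t - 1` and `t`.
#' @return Local excess entropy in bits (possibly negative).
#' @export
local_excess_entropy <- function(x, source, target, prior = "uniform") {
  local_mutual_information(joint_transition(x, prior), source, target)
}

#' Excess entropy of a Markov chain (bits)
#'
#' The one-step temporal mutual information `E(X) = I(X_{t-1}; X_t)` under a
#' chosen prior on past states (the Markovian restriction of the
#' infinite-history excess entropy).
#'
#' @inheritParams joint_transition
#' @return Excess entropy in bits.
#' @export
excess_entropy <- function(x, prior = "uniform") {
  expected_mutual_information(joint_transition(x, prior))
}

#' Matrix of local excess entropies
#'
#' Evaluates the local excess entropy of every transition under one prior.
#' Transitions with zero joint probability are undefined and returned as `NA`.
#'
#' @inheritParams joint_transition
#' @return N x N numeric matrix (rows: past state, columns: future state).
#' @export
local_information_matrix <- function(x, prior = "uniform") {
  jt <- joint_transition(x, prior)
  denom <- outer(jt$marginal_past, jt$marginal_future)
  out <- matrix(NA_real_, nrow(jt$joint), ncol(jt$joint),
    dimnames = dimnames(jt$joint)
  )
  nz <- jt$joint > 0
  out[nz] <- log2(jt$joint[nz] / denom[nz])
  out
}

#' Effective information and effectiveness
#'
#' Effective information is the excess entropy computed with a
#' maximum-entropy (uniform) distribution imposed on past states — a
#' statistical analogue of intervening on the system. It is bounded by
#' `log2 N`, which permits the normalization to effectiveness in `[0, 1]`:
#' 1 for deterministic bijective dynamics (permutation matrices), 0 when all
#' rows are identical and the past carries no information about the future.
#'
#' @param x A [tpm] or [element_system].
#' @return `effective_information()`: bits; `effectiveness()`: unitless in
#'   `[0, 1]`.
#' @export
effective_information <- function(x) {
  excess_entropy(as_tpm(x), prior = "uniform")
}

#' @rdname effective_information
#' @export
effectiveness <- function(x) {
  x <- as_tpm(x)
  if (n_states(x) < 2L) {
    stop("effectiveness is undefined for a single-state system (log2 N = 0)")
  }
  effective_information(x) / log2(n_states(x))
}

#' Sign classification of local information values
#'
#' @param e Numeric vector of local information values (bits).
#' @param tol Neutrality tolerance: values within `tol` of zero are classed
#'   `"neutral"` and excluded from incongruity fractions.
#' @return Character vector: `"informative"`, `"misinformative"`, or
#'   `"neutral"` (`NA` input stays `NA`).
#' @export
classify_sign <- function(e, tol = 1e-10) {
  out <- rep(NA_character_, length(e))
  out[!is.na(e) & e > tol] <- "informative"
  out[!is.na(e) & e < -tol] <- "misinformative"
  out[!is.na(e) & abs(e) <= tol] <- "neutral"
  out
}
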