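#' Seedable random walk on a TPM
#'
#' Samples a state sequence from a Markov chain, drawing each step from the
#' TPM row of the current state. The seed is applied locally (the caller's
#' RNG state is restored afterwards) so identical `(seed, inputs)` give
#' bit-identical trajectories; R's default Mersenne-Twister generator is
#' used throughout.
#'
#' @param x A [tpm] or [element_system].
#' @param length Number of states in the trajectory (>= 2).
#' @param seed Integer seed; `NULL` leaves the current RNG stream untouched.
#' @param start `"uniform"` (draw the initial state uniformly),
#'   `"stationary"` (draw it from the stationary distribution), or a state
#'   label.
#' @return Object of class `"walk_trajectory"`: `states` (character vector),
#'   `seed`, `start`.
#' @export
sample_walk <- function(x, length, seed = NULL, start = "uniform") {
  x <- as_tpm(x)
  length <- as.integer(length)
  if (length < 2L) stop("a trajectory needs at least two states")
  labels <- state_labels(x)
  P <- as.matrix(x)
  run <- function() {
    cur <- if (identical(start, "uniform")) {
      sample.int(length(labels), 1L)
    } else if (identical(start, "stationary")) {
      sample.int(length(labels), 1L, prob = stationary_distribution(x))
    } else {
      i <- match(start, labels)
      if (is.na(i)) stop(sprintf("start state '%s' is not in the TPM", start))
      i
    }
    states <- integer(length)
    states[1L] <- cur
    for (s in 2L:length) {
      cur <- sample.int(length(labels), 1L, prob = P[cur, ])
      states[s] <- cur
    }
    labels[states]
  }
  states <- with_local_seed(seed, run())
  structure(
    list(states = states, seed = seed, start = start),
    class = "walk_trajectory"
  )
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.walk_trajectory <- function(x, ...) {
  cat(sprintf(
    "Random walk: %d steps (seed: %s, start: %s)\n",
    length(x$states), format(x$seed), format(x$start)
  ))
  cat(paste(utils::head(x$states, 12L), collapse = " "),
    if (length(x$states) > 12L) "...\n" else "\n"
  )
  invisible(x)
}

traj_states <- function(traj) {
  if (inherits(traj, "walk_trajectory")) traj$states else as.character(traj)
}

#' Cross-scale local information series along a trajectory
#'
#' For every step of a random walk on the micro system, evaluates the local
#' excess entropy of the transition at the micro scale and at its projected
#' macro scale, their ratio `e_macro / e_micro`, and the incongruity flag
#' (`e_micro > tol` and `e_macro < -tol`) — the flickering-emergence trace.
#' Local values are model quantities computed from the TPM under the chosen
#' prior, not plug-in estimates from the trajectory's empirical frequencies.
#' The ratio is undefined (`NA`) where `|e_micro| <= tol`.
#'
#' @param traj A [sample_walk] trajectory (or character vector of micro
#'   state labels).
#' @inheritParams incongruity_census
#' @return Data frame with one row per transition: `step`, `from`, `to`,
#'   `e_micro`, `e_macro`, `ratio`, `incongruous`.
#' @export
cross_scale_series <- function(traj, micro, mapping, prior = "uniform",
                               tol = 1e-10) {
  micro <- as_tpm(micro)
  mapping <- check_mapping(micro, mapping)
  states <- traj_states(traj)
  jt <- joint_transition(micro, prior)
  jm <- push_joint(jt, mapping_matrix(micro, mapping), mapping$macro_labels)

  from <- states[-length(states)]
  to <- states[-1L]
  e_micro <- vapply(seq_along(from), function(s) {
    local_mutual_information(jt, from[s], to[s])
  }, numeric(1))
  e_macro <- vapply(seq_along(from), function(s) {
    local_mutual_information(jm, mapping$map[[from[s]]], mapping$map[[to[s]]])
  }, numeric(1))
  ratio <- ifelse(abs(e_micro) > tol, e_macro / e_micro, NA_real_)
  data.frame(
    step = seq_along(from),
    from = from,
    to = to,
    e_micro = e_micro,
    e_macro = e_macro,
    ratio = ratio,
    incongruous = e_micro > tol & e_macro < -tol,
    stringsAsFactors = FALSE
  )
}

#' Local causal-decoupling series along a trajectory
#'
#' Solves the local PhiID lattice for every transition of a walk on a
#' two-element system and reports the causal-decoupling (temporal synergy)
#' atom per step with its sign flag: the PhiID form of flickering emergence,
#' where the system moves through periods of informative and misinformative
#' integrated emergence. Distinct transitions are solved once and cached.
#'
#' @param traj A [sample_walk] trajectory (or character vector of
#'   product-state labels of `system`).
#' @inheritParams local_phiid
#' @param tol Sign-neutrality tolerance.
#' @return Data frame with one row per transition: `step`, `from`, `to`,
#'   `e`, `decoupling`, `misinformative`.
#' @export
phiid_series <- function(traj, system, prior = "stationary", tol = 1e-10) {
  system <- check_two_elements(system)
  states <- traj_states(traj)
  from <- states[-length(states)]
  to <- states[-1L]
  keys <- paste(from, to, sep = "\r")
  cache <- new.env(parent = emptyenv())
  vals <- lapply(unique(keys), function(k) {
    pair <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    r <- local_phiid(system, pair[1L], pair[2L], prior = prior)
    assign(k, c(e = r$total, decoupling = causal_decoupling(r)), envir = cache)
  })
  per <- t(vapply(keys, function(k) get(k, envir = cache), numeric(2)))
  data.frame(
    step = seq_along(from),
    from = from,
    to = to,
    e = per[, "e"],
    decoupling = per[, "decoupling"],
    misinformative = per[, "decoupling"] < -tol,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
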