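# Independent oracles: deliberately different code paths (explicit loops,
# linear solves) from the package implementations they check.

# Direct evaluation of the mutual-information sum over all state pairs.
oracle_mi <- function(P, prior) {
  n <- nrow(P)
  joint <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) joint[i, j] <- prior[i] * P[i, j]
  }
  px <- rowSums(joint)
  py <- colSums(joint)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (joint[i, j] > 0) {
        total <- total + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
      }
    }
  }
  total
}

# Local excess entropy of a single transition, from first principles.
oracle_local_e <- function(P, prior, i, j) {
  joint <- unname(prior[i]) * P[i, j]
  px <- unname(prior[i])
  py <- sum(prior * P[, j])
  log2(joint / (px * py))
}

# Full PhiID atom vector of one transition: union-event redundancies by
# explicit enumeration, Moebius inversion by linear solve against a
# brute-force product order (not the package's recursion).
oracle_phiid_atoms <- function(system, src, tgt, prior_vec) {
  P <- as.matrix(system$tpm)
  labels <- state_labels(system$tpm)
  states <- system$states
  n <- nrow(P)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) J[i, j] <- prior_vec[i] * P[i, j]
  }
  antichains <- list(
    "{1}{2}" = list(1L, 2L), "{1}" = list(1L),
    "{2}" = list(2L), "{12}" = list(c(1L, 2L))
  )
  event <- function(ac, obs) {
    sel <- rep(FALSE, n)
    for (A in ac) {
      sel <- sel | apply(states, 1L, function(r) all(r[A] == obs[A]))
    }
    sel
  }
  is_ <- match(src, labels)
  it_ <- match(tgt, labels)
  nm <- character(0)
  red <- numeric(0)
  src_ac <- list()
  tgt_ac <- list()
  for (s in names(antichains)) {
    for (t2 in names(antichains)) {
      selp <- event(antichains[[s]], states[is_, ])
      self <- event(antichains[[t2]], states[it_, ])
      pp <- sum(rowSums(J)[selp])
      pf <- sum(colSums(J)[self])
      pb <- sum(J[selp, self, drop = FALSE])
      nm <- c(nm, paste0(s, "->", t2))
      red <- c(red, log2(pb / (pp * pf)))
      src_ac <- c(src_ac, antichains[s])
      tgt_ac <- c(tgt_ac, antichains[t2])
    }
  }
  names(red) <- nm
  leq <- function(a, b) {
    all(vapply(b, function(B) {
      any(vapply(a, function(A) all(A %in% B), logical(1)))
    }, logical(1)))
  }
  Z <- matrix(0, 16L, 16L, dimnames = list(nm, nm))
  for (i in seq_len(16L)) {
    for (j in seq_len(16L)) {
      if (leq(src_ac[[i]], src_ac[[j]]) && leq(tgt_ac[[i]], tgt_ac[[j]])) {
        Z[i, j] <- 1
      }
    }
  }
  partial <- solve(t(Z), red) # red = t(Z) %*% partial
  names(partial) <- nm
  list(redundancy = red, partial = partial)
}
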