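# Small systems reused across tests.

two_state_tpm <- function() {
  tpm(rbind(c(0.9, 0.1), c(0.2, 0.8)), labels = c("a", "b"))
}

cycle_tpm <- function(n) {
  m <- matrix(0, n, n)
  m[cbind(seq_len(n), c(seq_len(n)[-1L], 1L))] <- 1
  tpm(m)
}

uniform_tpm <- function(n) {
  tpm(matrix(1 / n, n, n))
}

# Memoryless two-element system (all rows uniform) over product labels.
uniform_system2 <- function() {
  element_system(
    tpm(matrix(0.25, 4, 4), labels = c("00", "01", "10", "11")),
    element_names = c("X1", "X2")
  )
}

# Two independent binary coins, each copying itself deterministically.
independent_coins <- function() {
  element_system(tpm(diag(4), labels = c("00", "01", "10", "11")),
    element_names = c("X1", "X2")
  )
}

# Product chain of two independent copies of a given 2-state chain.
product_chain <- function(p1) {
  labels <- c("00", "01", "10", "11")
  P <- matrix(0, 4, 4, dimnames = list(labels, labels))
  bit <- function(lab, k) as.integer(substr(lab, k, k)) + 1L
  for (x in labels) {
    for (y in labels) {
      P[x, y] <- p1[bit(x, 1), bit(y, 1)] * p1[bit(x, 2), bit(y, 2)]
    }
  }
  element_system(tpm(P, labels = labels), element_names = c("X1", "X2"))
}

random_two_element_system <- function(seed, concentration = 1) {
  element_system(
    random_tpm(4,
      concentration = concentration, seed = seed,
      labels = c("00", "01", "10", "11")
    ),
    element_names = c("X1", "X2")
  )
}
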