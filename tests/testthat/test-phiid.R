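test_that("the double lattice has 16 atoms with the product partial order", {
  lat <- double_lattice(2)
  expect_length(lat$atoms, 16L) # 4 antichains squared
  expect_length(lat$antichains, 4L)
  # bottom has no strict predecessors; top precedes nothing and covers all
  expect_length(lat$down_sets[["{1}{2}->{1}{2}"]], 0L)
  expect_length(lat$down_sets[["{12}->{12}"]], 15L)
  # brute-force re-derivation of the order from the definition
  ac_leq <- function(a, b) {
    all(vapply(b, function(B) {
      any(vapply(a, function(A) all(A %in% B), logical(1)))
    }, logical(1)))
  }
  for (i in names(lat$atoms)) {
    for (j in names(lat$atoms)) {
      expect_equal(
        lat$order[i, j],
        ac_leq(lat$atoms[[i]]$source, lat$atoms[[j]]$source) &&
          ac_leq(lat$atoms[[i]]$target, lat$atoms[[j]]$target),
        label = paste(i, "vs", j)
      )
    }
  }
  # reflexive, antisymmetric
  expect_true(all(diag(lat$order)))
  expect_true(all(!(lat$order & t(lat$order)) | diag(16) == 1))
  expect_error(double_lattice(3), "two-element")
})

test_that("Moebius inversion round-trips arbitrary redundancy assignments", {
  lat <- double_lattice(2)
  nm <- names(lat$atoms)
  # zero in, zero out
  expect_equal(
    unname(mobius_invert(lat, stats::setNames(numeric(16), nm))),
    numeric(16)
  )
  # constant: everything lands on the unique bottom
  const <- mobius_invert(lat, stats::setNames(rep(0.7, 16), nm))
  expect_equal(unname(const[["{1}{2}->{1}{2}"]]), 0.7)
  expect_equal(sum(abs(const[setdiff(nm, "{1}{2}->{1}{2}")])), 0)
  # random values: inclusive down-set sums reproduce the input exactly
  set.seed(99)
  for (rep_ in 1:10) {
    red <- stats::setNames(stats::rnorm(16), nm)
    partial <- mobius_invert(lat, red)
    for (j in nm) {
      inclusive <- c(lat$down_sets[[j]], match(j, nm))
      expect_equal(sum(partial[inclusive]), red[[j]], tolerance = 1e-10)
    }
  }
})

test_that("the top atom's redundancy is the transition's local excess entropy", {
  for (seed in 1:6) {
    sys <- random_two_element_system(seed)
    jt <- joint_transition(sys$tpm, "stationary")
    for (tr in list(c("00", "11"), c("01", "10"), c("11", "11"))) {
      expect_equal(
        local_double_redundancy(sys, tr[1], tr[2], "{12}->{12}", prior = "stationary"),
        local_mutual_information(jt, tr[1], tr[2]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("union-event redundancies take analytic values on canonical systems", {
  # two independent uniform coins with identity dynamics: {1}->{1} = 1 bit
  coins <- independent_coins()
  for (tr in c("00", "01", "10", "11")) {
    expect_equal(
      local_double_redundancy(coins, tr, tr, "{1}->{1}", prior = "uniform"),
      1,
      tolerance = 1e-12
    )
  }
  # memoryless dynamics: every atom of every transition carries nothing
  unif <- uniform_system2()
  lat <- double_lattice(2)
  for (a in names(lat$atoms)) {
    expect_equal(
      local_double_redundancy(unif, "01", "10", a, prior = "uniform"),
      0,
      tolerance = 1e-12
    )
  }
  expect_error(
    local_double_redundancy(coins, "00", "11", "{12}->{12}", prior = "uniform"),
    class = "flicker_undefined_transition"
  )
})

test_that("local PhiID decomposes local excess entropy over 16 atoms", {
  for (seed in c(1, 8, 23)) {
    sys <- random_two_element_system(seed)
    for (prior in c("stationary", "uniform")) {
      jt <- joint_transition(sys$tpm, prior)
      pv <- as.vector(jt$prior)
      for (src in state_labels(sys$tpm)) {
        for (tgt in state_labels(sys$tpm)) {
          if (jt$joint[src, tgt] <= 0) next
          r <- local_phiid(sys, src, tgt, prior = prior)
          # completeness: atoms re-sum to e(t)
          expect_equal(sum(r$partial), r$total, tolerance = 1e-9)
          expect_equal(r$total, local_mutual_information(jt, src, tgt),
            tolerance = 1e-12
          )
          # full independent oracle: enumeration + linear-solve inversion
          orc <- oracle_phiid_atoms(sys, src, tgt, pv)
          expect_equal(r$redundancy, orc$redundancy, tolerance = 1e-10)
          expect_equal(r$partial, orc$partial, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("expected PhiID atoms average to the excess entropy", {
  for (seed in c(4, 17)) {
    sys <- random_two_element_system(seed)
    for (prior in c("stationary", "uniform")) {
      r <- expected_phiid(sys, prior = prior)
      expect_equal(r$total, excess_entropy(sys$tpm, prior), tolerance = 1e-9)
      expect_equal(sum(r$partial), r$total, tolerance = 1e-9)
    }
  }
  # memoryless system: all expected atoms vanish
  unif <- uniform_system2()
  expect_equal(sum(abs(expected_phiid(unif, prior = "uniform")$partial)), 0,
    tolerance = 1e-12
  )
})

test_that("element relabelling 1<->2 permutes atoms by the lattice automorphism", {
  sys <- random_two_element_system(31)
  # swap the elements: relabel each state "ab" -> "ba"
  labels <- state_labels(sys$tpm)
  swapped <- paste0(substr(labels, 2, 2), substr(labels, 1, 1))
  P <- as.matrix(sys$tpm)
  Psw <- P[match(labels, swapped), match(labels, swapped)]
  dimnames(Psw) <- list(labels, labels)
  sys_sw <- element_system(tpm(Psw, labels), c("X1", "X2"))
  swap_atom <- function(a) {
    chartr("12", "21", a) |>
      gsub(pattern = "\\{21\\}", replacement = "{12}") |>
      gsub(pattern = "^\\{2\\}\\{1\\}", replacement = "{1}{2}") |>
      gsub(pattern = ">\\{2\\}\\{1\\}", replacement = ">{1}{2}")
  }
  src <- "01"
  tgt <- "11"
  r <- local_phiid(sys, src, tgt, prior = "uniform")
  r_sw <- local_phiid(
    sys_sw,
    paste0(substr(src, 2, 2), substr(src, 1, 1)),
    paste0(substr(tgt, 2, 2), substr(tgt, 1, 1)),
    prior = "uniform"
  )
  for (a in names(r$partial)) {
    expect_equal(r$partial[[a]], r_sw$partial[[swap_atom(a)]],
      tolerance = 1e-10, label = a
    )
  }
})

test_that("causal decoupling and downward causation partition correctly", {
  sys <- random_two_element_system(12)
  r <- local_phiid(sys, "00", "11", prior = "stationary")
  expect_equal(causal_decoupling(r), r$partial[["{12}->{12}"]])
  dc <- downward_causation(r, atoms = TRUE)
  expect_named(dc, c("{12}->{1}", "{12}->{2}", "{12}->{1}{2}"))
  expect_equal(downward_causation(r), sum(dc))
  rest <- setdiff(names(r$partial), c("{12}->{12}", names(dc)))
  expect_equal(
    causal_decoupling(r) + downward_causation(r) + sum(r$partial[rest]),
    r$total,
    tolerance = 1e-10
  )
})

test_that("heuristic Phi is zero for independent parts and signed as theory predicts", {
  # independent product chain: whole reduces exactly to parts
  sys <- product_chain(rbind(c(0.7, 0.3), c(0.4, 0.6)))
  expect_equal(heuristic_phi(sys, prior = "uniform"), 0, tolerance = 1e-10)
  # both elements follow XOR of the previous pair: purely synergistic
  xor_rule <- function(s) as.integer(xor(s[["X1"]], s[["X2"]]))
  xor_sys <- boolean_network(list(X1 = xor_rule, X2 = xor_rule), noise = 0.1)
  expect_gt(heuristic_phi(xor_sys, prior = "uniform"), 0)
  # perfectly correlated copy chains: redundancy swamps synergy
  copy_sys <- element_system(tpm(diag(4), c("00", "01", "10", "11")), c("X1", "X2"))
  corr_prior <- c(0.5, 0, 0, 0.5)
  expect_equal(heuristic_phi(copy_sys, prior = corr_prior), -1, tolerance = 1e-10)
})

test_that("negative-atom census counts over all formal transitions", {
  # memoryless system: nothing is negative
  unif <- uniform_system2()
  expect_equal(as.numeric(negative_atom_census(unif, prior = "uniform")), 0)
  # stand-in macro system: census agrees with an independent recount
  ex <- figure1_example()
  cen <- negative_atom_census(ex$macro, "{12}->{12}", prior = "stationary")
  pv <- as.vector(resolve_prior(ex$macro$tpm, "stationary"))
  jt <- joint_transition(ex$macro$tpm, "stationary")
  n_neg <- 0L
  for (src in state_labels(ex$macro$tpm)) {
    for (tgt in state_labels(ex$macro$tpm)) {
      if (jt$joint[src, tgt] <= 0) next
      val <- oracle_phiid_atoms(ex$macro, src, tgt, pv)$partial[["{12}->{12}"]]
      if (val < -1e-10) n_neg <- n_neg + 1L
    }
  }
  expect_equal(as.numeric(cen), n_neg / 16)
  counts <- attr(cen, "counts")
  expect_equal(counts[["total"]], 16L)
  expect_equal(counts[["negative"]], n_neg)
})
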