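test_that("gate mappings implement the logic-gate truth tables", {
  sys4 <- figure1_standin_system()
  map <- gate_mapping(sys4, list(c("X1", "X2"), c("X3", "X4")), "AND")
  expect_length(map$micro_labels, 16L)
  expect_length(map$macro_labels, 4L)
  expect_equal(unname(map$map[["1100"]]), "10")
  expect_equal(unname(map$map[["1111"]]), "11")
  expect_equal(unname(map$map[["0111"]]), "01")
  # singleton partition with COPY gates is the identity mapping
  sys2 <- independent_coins()
  id_map <- gate_mapping(sys2, list("X1", "X2"), "COPY")
  expect_equal(unname(id_map$map), names(id_map$map))
  # one XOR group folds 4 states onto 2
  xor_map <- gate_mapping(sys2, list(c("X1", "X2")), "XOR")
  expect_equal(unname(xor_map$map[c("00", "01", "10", "11")]), c("0", "1", "1", "0"))
  expect_error(
    gate_mapping(sys2, list("X1"), "AND"),
    "cover all elements"
  )
})

test_that("gate mapping rejects non-Boolean alphabets for Boolean gates", {
  tri <- element_system(
    tpm(matrix(1 / 3, 3, 3), labels = c("a", "b", "c")),
    element_names = "E1", alphabets = list(c("a", "b", "c"))
  )
  expect_error(gate_mapping(tri, list("E1"), "AND"), "not \\{0, 1\\}")
  expect_s3_class(gate_mapping(tri, list("E1"), "COPY"), "state_mapping")
})

test_that("macro TPM construction conditions uniformly within preimages", {
  # identity mapping reproduces the micro TPM
  x <- random_tpm(4, seed = 3, labels = c("00", "01", "10", "11"))
  idm <- state_mapping(stats::setNames(state_labels(x), state_labels(x)))
  expect_equal(as.matrix(macro_tpm(x, idm)), as.matrix(x), tolerance = 1e-12)
  # total aggregation gives the trivial 1x1 chain
  allm <- state_mapping(stats::setNames(rep("m", 4), state_labels(x)))
  expect_equal(as.matrix(macro_tpm(x, allm)), matrix(1, 1, 1, dimnames = list("m", "m")))
  # two independent identical chains under AND: enumerate the preimages by hand
  p1 <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  sys <- product_chain(p1)
  andm <- gate_mapping(sys, list(c("X1", "X2")), "AND")
  got <- as.matrix(macro_tpm(sys, andm))
  to1 <- function(x_lab) { # P(macro 1 | micro state) = P(next state "11")
    b <- as.integer(c(substr(x_lab, 1, 1), substr(x_lab, 2, 2))) + 1L
    p1[b[1], 2] * p1[b[2], 2]
  }
  exp_row0 <- mean(vapply(c("00", "01", "10"), to1, numeric(1)))
  exp_row1 <- to1("11")
  expect_equal(got["0", "1"], exp_row0, tolerance = 1e-12)
  expect_equal(got["0", "0"], 1 - exp_row0, tolerance = 1e-12)
  expect_equal(got["1", "1"], exp_row1, tolerance = 1e-12)
})

test_that("stationary within-preimage weighting changes the construction as specified", {
  x <- random_tpm(6, seed = 4, labels = paste0("s", 1:6))
  map <- state_mapping(stats::setNames(
    c("A", "A", "A", "B", "B", "B"), state_labels(x)
  ))
  uni <- macro_tpm(x, map, weighting = "uniform")
  sta <- macro_tpm(x, map, weighting = "stationary")
  # both stochastic, but different constructions on a generic chain
  expect_equal(rowSums(as.matrix(sta)), rowSums(as.matrix(uni)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(as.matrix(sta), as.matrix(uni), tolerance = 1e-6)))
  # hand check one entry: weights = stationary mass conditioned on the preimage
  pi_ <- stationary_distribution(x)
  pre_a <- names(map$map)[map$map == "A"]
  w <- pi_[pre_a] / sum(pi_[pre_a])
  P <- as.matrix(x)
  col_b <- names(map$map)[map$map == "B"]
  expect_equal(
    as.matrix(sta)["A", "B"],
    sum(w * rowSums(P[pre_a, col_b, drop = FALSE])),
    tolerance = 1e-12
  )
})

test_that("emergence score is zero at the identity, bounded by effectiveness limits, and sign-consistent", {
  x <- random_tpm(8, seed = 11)
  idm <- state_mapping(stats::setNames(state_labels(x), state_labels(x)))
  expect_identical(emergence_score(x, idm), 0)
  # a permutation micro system already has effectiveness 1: no macro can beat it
  perm <- cycle_tpm(4)
  half <- state_mapping(stats::setNames(
    c("A", "A", "B", "B"), state_labels(perm)
  ))
  expect_lte(emergence_score(perm, half), 0)
  # Eq.-12-style sign agreement across random mappings
  for (seed in 1:8) {
    x <- random_tpm(6, seed = seed)
    set.seed(seed + 100)
    groups <- c("u", "u", "v", "v", "w", "w")[sample(6)]
    mapping <- state_mapping(stats::setNames(groups, state_labels(x)))
    sc <- emergence_score(x, mapping)
    expect_equal(
      sc > 0,
      effectiveness(macro_tpm(x, mapping)) > effectiveness(x)
    )
  }
})

test_that("local scale pairs project through the pushforward joint", {
  # identity mapping: the two scales coincide transition by transition
  x <- random_tpm(4, seed = 5)
  idm <- state_mapping(stats::setNames(state_labels(x), state_labels(x)))
  for (s in state_labels(x)) {
    pair <- local_scale_pair(x, idm, s, state_labels(x)[1L], prior = "uniform")
    expect_equal(pair[["e_micro"]], pair[["e_macro"]], tolerance = 1e-12)
  }
  # uniform micro dynamics: both scales neutral
  u <- uniform_tpm(4)
  m2 <- state_mapping(stats::setNames(c("A", "A", "B", "B"), state_labels(u)))
  pair <- local_scale_pair(u, m2, "s1", "s3")
  expect_equal(unname(pair), c(0, 0), tolerance = 1e-12)
  # projection consistency: macro marginals equal the pushforward of micro ones
  x <- random_tpm(6, seed = 9)
  mapping <- state_mapping(stats::setNames(
    c("A", "A", "B", "B", "C", "C"), state_labels(x)
  ))
  jt <- joint_transition(x, "uniform")
  agg <- function(v) vapply(
    c("A", "B", "C"),
    function(m) sum(v[mapping$map[state_labels(x)] == m]), numeric(1)
  )
  pair <- local_scale_pair(x, mapping, "s1", "s2")
  e_macro_by_hand <- {
    Jm <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    for (i in seq_len(6)) {
      for (j in seq_len(6)) {
        Jm[mapping$map[[state_labels(x)[i]]], mapping$map[[state_labels(x)[j]]]] <-
          Jm[mapping$map[[state_labels(x)[i]]], mapping$map[[state_labels(x)[j]]]] +
          jt$joint[i, j]
      }
    }
    log2(Jm["A", "A"] / (sum(Jm["A", ]) * sum(Jm[, "A"])))
  }
  expect_equal(pair[["e_macro"]], e_macro_by_hand, tolerance = 1e-12)
  expect_equal(sum(agg(jt$marginal_past)), 1, tolerance = 1e-10)
})

test_that("incongruity census matches a brute-force enumeration", {
  for (seed in c(2, 13)) {
    x <- random_tpm(6, seed = seed, labels = paste0("s", 1:6))
    mapping <- state_mapping(stats::setNames(
      c("A", "A", "A", "B", "B", "C"), state_labels(x)
    ))
    cen <- incongruity_census(x, mapping, prior = "uniform")
    # independent double loop over all transitions
    jt <- joint_transition(x, "uniform")
    n_inf <- 0L
    n_incong <- 0L
    n_real <- 0L
    combos <- c(ii = 0L, im = 0L, mi = 0L, mm = 0L, neutral = 0L)
    for (i in 1:6) {
      for (j in 1:6) {
        if (jt$joint[i, j] <= 0) next
        n_real <- n_real + 1L
        em <- oracle_local_e(as.matrix(x), jt$prior, i, j)
        pair <- local_scale_pair(x, mapping, paste0("s", i), paste0("s", j))
        ema <- pair[["e_macro"]]
        cm <- if (em > 1e-10) "i" else if (em < -1e-10) "m" else "n"
        ca <- if (ema > 1e-10) "i" else if (ema < -1e-10) "m" else "n"
        if (cm == "i") n_inf <- n_inf + 1L
        if (cm == "i" && ca == "m") n_incong <- n_incong + 1L
        key <- paste0(cm, ca)
        if (cm == "n" || ca == "n") {
          combos["neutral"] <- combos["neutral"] + 1L
        } else {
          combos[key] <- combos[key] + 1L
        }
      }
    }
    expect_equal(cen$n_realizable, n_real)
    expect_equal(unname(cen$counts), unname(combos))
    expect_equal(cen$headline_fraction, n_incong / n_inf, tolerance = 1e-12)
    # census completeness: sign-pair counts plus neutral cover all realizable
    expect_equal(sum(cen$counts), cen$n_realizable)
  }
})

test_that("identity coarse-graining yields zero incongruity on any chain", {
  x <- random_tpm(5, seed = 21)
  idm <- state_mapping(stats::setNames(state_labels(x), state_labels(x)))
  cen <- incongruity_census(x, idm)
  expect_equal(cen$counts[["informative_misinformative"]], 0L)
  expect_equal(cen$headline_fraction, 0)
})

test_that("the worked example displays incongruous cross-scale dynamics", {
  ex <- figure1_example()
  expect_gt(emergence_score(ex$micro, ex$mapping), 0)
  cen <- incongruity_census(ex$micro, ex$mapping, prior = "uniform")
  # informative micro transitions exist that project to misinformative macro
  expect_gt(cen$counts[["informative_misinformative"]], 0L)
  expect_gt(cen$headline_fraction, 0)
  expect_lt(cen$headline_fraction, 1)
})
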