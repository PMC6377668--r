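test_that("mutual-positive graph requires positivity in both directions", {
  S <- init_reputation(4)
  g <- mutual_positive_graph(S)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 0)

  S[1, 2] <- 0.5
  S[2, 1] <- -0.2
  expect_equal(igraph::ecount(mutual_positive_graph(S)), 0)

  S[2, 1] <- 0.3
  g <- mutual_positive_graph(S)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.4)   # mean of the two directions
})

test_that("community counting agrees with connected components on clique unions", {
  g2 <- mutual_positive_graph(clique_matrix(c(5, 5)))
  expect_equal(count_communities(g2)$n_communities, 2)
  g1 <- mutual_positive_graph(clique_matrix(10))
  expect_equal(count_communities(g1)$n_communities, 1)
  g0 <- mutual_positive_graph(init_reputation(6))
  expect_equal(count_communities(g0)$n_communities, 6)

  set.seed(20)
  for (rep in 1:10) {
    sizes <- sample(1:6, sample(2:5, 1), replace = TRUE)
    g <- mutual_positive_graph(clique_matrix(sizes))
    expect_equal(count_communities(g)$n_communities,
                 igraph::components(g)$no)
  }
})

test_that("community counting does not perturb the caller's RNG stream", {
  set.seed(21)
  a <- runif(1)
  set.seed(21)
  invisible(count_communities(mutual_positive_graph(clique_matrix(c(3, 4)))))
  expect_identical(runif(1), a)
})

test_that("cooperation rate is the fraction of C actions", {
  expect_equal(cooperation_rate(rep("D", 5)), 0)
  expect_equal(cooperation_rate(rep("C", 5)), 1)
  expect_equal(cooperation_rate(c(rep("C", 3), rep("D", 7))), 0.3)
  expect_error(cooperation_rate(character()), "empty")
})

test_that("outgoing positive connections count positive off-diagonal entries", {
  S <- init_reputation(4)
  expect_equal(outgoing_positive_connections(S, 1), 0)
  S[2, c(1, 3, 4)] <- c(0.2, -0.3, 0.7)
  expect_equal(outgoing_positive_connections(S, 2), 2)
  expect_equal(outgoing_positive_connections(S), c(0L, 2L, 0L, 0L))
})

test_that("exponential decay regression recovers noiseless parameters exactly", {
  x <- 0:9
  fit <- fit_exponential_decay(x, 10 * exp(-x / 5))
  expect_equal(fit$tau, 5, tolerance = 1e-6)
  expect_equal(fit$amplitude, 10, tolerance = 1e-5)
  expect_equal(fit$offset, 0, tolerance = 1e-5)

  for (tau in c(0.5, 2, 17)) {
    y <- 1.5 + 4 * exp(-seq(0, 3 * tau, length.out = 12) / tau)
    fit <- fit_exponential_decay(seq(0, 3 * tau, length.out = 12), y)
    expect_equal(fit$tau, tau, tolerance = 1e-5)
  }

  # growth is a negative amplitude
  fit <- fit_exponential_decay(x, 5 - 3 * exp(-x / 4))
  expect_equal(fit$tau, 4, tolerance = 1e-5)
  expect_lt(fit$amplitude, 0)

  expect_error(fit_exponential_decay(x, rep(2, 10)), "degenerate")
  expect_error(fit_exponential_decay(c(0, 1), c(1, 2)), "3 distinct")
})

test_that("decay regression recovers tau within 10% under observation noise", {
  set.seed(22)
  x <- seq(0, 12, length.out = 50)
  rel_err <- replicate(20, {
    y <- 2 + 8 * exp(-x / 3) + rnorm(50, sd = 0.05)
    abs(fit_exponential_decay(x, y)$tau - 3) / 3
  })
  expect_lt(median(rel_err), 0.1)
  expect_lt(max(rel_err), 0.25)
})

test_that("Rapoport index follows (b - c) / (b + c)", {
  expect_equal(rapoport_index(1, 1), 0)
  expect_equal(rapoport_index(2, 1), 1 / 3)
  expect_equal(rapoport_index(8, 1), 7 / 9)
  expect_equal(rapoport_index(4, 1), 3 / 5)
  ks <- vapply(1:8, rapoport_index, numeric(1), c = 1)
  expect_true(all(diff(ks) > 0))   # strictly increasing in b
  expect_error(rapoport_index(1, 2), "b >= c")
})

test_that("majority-state classification uses strict plurality", {
  expect_equal(classify_majority_state(c(FRIEND = 60, HEIDER = 30,
                                         DEFECTOR = 10)), "FRIEND_MAJ")
  expect_equal(classify_majority_state(c(FRIEND = 40, HEIDER = 40,
                                         DEFECTOR = 20)), "MIXED")
  expect_equal(classify_majority_state(c(FRIEND = 0, HEIDER = 0,
                                         DEFECTOR = 100)), "DEFECTOR_MAJ")
  tr <- data.frame(n_heider = c(5, 2), n_friend = c(2, 2), n_enemy = 0,
                   n_incomplete = 0, n_defector = c(1, 2))
  expect_equal(majority_states(tr), c("HEIDER_MAJ", "MIXED"))
})

test_that("transition matrix estimation counts and normalizes correctly", {
  P <- estimate_transition_matrix(c("A", "A", "B", "B"))
  expect_equal(P["A", "A"], 0.5)
  expect_equal(P["A", "B"], 0.5)
  expect_equal(P["B", "B"], 1)
  P2 <- estimate_transition_matrix(c("A", "B", "A", "B", "A"))
  expect_equal(P2["A", "B"], 1)
  expect_equal(P2["B", "A"], 1)
  expect_error(estimate_transition_matrix("A"), "at least 2")

  # defined rows are stochastic; unvisited rows are NA
  P3 <- estimate_transition_matrix(c("A", "B", "B"), state_space = c("A", "B", "C"))
  expect_equal(rowSums(P3)[c("A", "B")], c(A = 1, B = 1))
  expect_true(all(is.na(P3["C", ])))
})

test_that("transition MLE converges to the generating chain", {
  set.seed(23)
  n <- 10000
  states <- character(n)
  states[1] <- "A"
  for (t in 2:n) {
    states[t] <- if (states[t - 1] == "A") {
      if (runif(1) < 0.1) "B" else "A"
    } else {
      if (runif(1) < 0.3) "A" else "B"
    }
  }
  P <- estimate_transition_matrix(states)
  expect_lt(abs(P["A", "B"] - 0.1), 0.02)
  expect_lt(abs(P["B", "A"] - 0.3), 0.04)
})

test_that("fission-fusion cycle counter tracks ordered phase traversals", {
  expect_equal(count_cycles(c("DEFECTOR_MAJ", "FRIEND_MAJ", "HEIDER_MAJ",
                              "DEFECTOR_MAJ"))$cycles, 1)
  expect_equal(count_cycles(c("DEFECTOR_MAJ", "FRIEND_MAJ", "DEFECTOR_MAJ",
                              "FRIEND_MAJ", "DEFECTOR_MAJ"))$cycles, 0)
  seq8 <- c("DEFECTOR_MAJ", "FRIEND_MAJ", "MIXED", "HEIDER_MAJ",
            "DEFECTOR_MAJ", "FRIEND_MAJ", "HEIDER_MAJ", "DEFECTOR_MAJ")
  out <- count_cycles(seq8)
  expect_equal(out$cycles, 2)
  expect_equal(out$per_1000, 2000 / 8)
  # the closing defection phase opens the next cycle
  expect_equal(count_cycles(rep(c("DEFECTOR_MAJ", "FRIEND_MAJ",
                                  "HEIDER_MAJ"), 3))$cycles, 2)
  expect_error(count_cycles(character()), "non-empty")
})
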