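test_that("reputation matrix initializes to the identity", {
  expect_identical(init_reputation(3), diag(3))
  expect_identical(init_reputation(2), diag(2))
  expect_error(init_reputation(1), "n")
  expect_error(init_reputation(0), "n")
})

test_that("relationship score reproduces the worked single-opinion cases", {
  S <- init_reputation(3)
  S[1, 2] <- 0.1
  # a single own-relationship entry is passed through unchanged
  expect_equal(relationship_score(S, 1, 2, "HEIDER"), 0.1)
  expect_equal(relationship_score(S, 1, 2, "FRIEND"), 0.1)
  expect_equal(relationship_score(S, 1, 2, "ENEMY"), 0.1)
  expect_equal(relationship_score(S, 1, 2, "INCOMPLETE_HEIDER"), 0.1)

  # an enemy of an enemy is a friend: (-1) * (-1) = +1 for Heider agents only
  S2 <- init_reputation(3)
  S2[1, 3] <- -1   # x dislikes C
  S2[3, 2] <- -1   # C dislikes y
  expect_equal(relationship_score(S2, 1, 2, "HEIDER"), 1)
  expect_equal(relationship_score(S2, 1, 2, "FRIEND"), 0)
  expect_equal(relationship_score(S2, 1, 2, "INCOMPLETE_HEIDER"), 0)
  expect_equal(relationship_score(S2, 1, 2, "ENEMY"), 1)

  expect_error(relationship_score(S, 1, 1, "HEIDER"), "self-interaction")
  expect_error(relationship_score(S, 1, 2, "DEFECTOR"), "defectors")
})

test_that("relationship score matches the four-heuristic enumeration oracle", {
  set.seed(42)
  for (n in 3:5) {
    for (rep in 1:10) {
      S <- random_reputation(n)
      for (strat in c("HEIDER", "FRIEND", "ENEMY", "INCOMPLETE_HEIDER")) {
        for (x in seq_len(n)) {
          for (y in seq_len(n)[-x]) {
            expect_equal(relationship_score(S, x, y, strat),
                         oracle_score(S, x, y, strat),
                         tolerance = 1e-12,
                         label = sprintf("%s x=%d y=%d", strat, x, y))
          }
        }
      }
    }
  }
})

test_that("Heider and friend-focused scores coincide on non-negative matrices", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    S <- matrix(runif(n * n), n, n)
    diag(S) <- 1
    for (x in seq_len(n)) {
      for (y in seq_len(n)[-x]) {
        expect_equal(relationship_score(S, x, y, "HEIDER"),
                     relationship_score(S, x, y, "FRIEND"))
      }
    }
  }
})

test_that("logistic decision function reproduces the printed probabilities", {
  expect_equal(decision_probability(0), 0.5)
  expect_equal(round(decision_probability(0.1, 0.2), 2), 0.62)
  expect_equal(round(decision_probability(0.5, 0.2), 2), 0.92)
  expect_equal(decision_probability(0.1, 0.2), 0.6224593, tolerance = 1e-6)
  expect_equal(decision_probability(-0.1, 0.2), 1 - decision_probability(0.1, 0.2))
  expect_error(decision_probability(0.1, 0), "temperature")
  expect_error(decision_probability(0.1, -1), "temperature")
})

test_that("cooperate/defect probabilities are complementary for any score", {
  rs <- seq(-30, 30, length.out = 101)
  expect_equal(decision_probability(rs) + decision_probability(-rs),
               rep(1, length(rs)))
})

test_that("relationship updating follows the action-pair rules and clips", {
  S <- init_reputation(3)
  S1 <- update_relationships(S, 1, 2, "C", "C", r = 0.3)
  expect_equal(S1[1, 2], 0.3)
  expect_equal(S1[2, 1], 0.3)

  # a defecting agent leaves its own opinion of a cooperator untouched
  S2 <- update_relationships(S, 1, 2, "D", "C", r = 0.3)
  expect_equal(S2[1, 2], 0)
  expect_equal(S2[2, 1], -0.3)

  S3 <- update_relationships(S, 1, 2, "D", "D", r = 0.3)
  expect_equal(S3[1, 2], -0.3)
  expect_equal(S3[2, 1], -0.3)

  S[1, 2] <- 0.9
  S4 <- update_relationships(S, 1, 2, "C", "C", r = 0.3)
  expect_equal(S4[1, 2], 1)      # clipped at the upper bound

  # defectors never update their own row; partners still judge them
  S5 <- update_relationships(init_reputation(3), 1, 2, "D", "C", r = 0.3,
                             x_strategy = "DEFECTOR")
  expect_equal(S5[1, 2], 0)
  expect_equal(S5[2, 1], -0.3)
  S6 <- update_relationships(init_reputation(3), 1, 2, "D", "D", r = 0.3,
                             x_strategy = "DEFECTOR")
  expect_equal(S6[1, 2], 0)
  expect_equal(S6[2, 1], -0.3)

  expect_error(update_relationships(S, 2, 2, "C", "C", 0.3),
               "self-interaction")
})

test_that("memory limit keeps the k most extreme relationships", {
  S <- init_reputation(4)
  S[1, 2:4] <- c(0.9, -0.8, 0.1)
  expect_equal(apply_memory_limit(S, 1, k = 3), S)
  S2 <- apply_memory_limit(S, 1, k = 2)
  expect_equal(S2[1, ], c(1, 0.9, -0.8, 0))
  expect_equal(S2[2:4, ], S[2:4, ])        # other rows untouched
  S3 <- apply_memory_limit(S, 1, k = 1)
  expect_equal(S3[1, ], c(1, 0.9, 0, 0))
  expect_error(apply_memory_limit(S, 1, k = 0), "k")
  expect_error(apply_memory_limit(S, 1, k = 4), "k")
})

test_that("memory limit breaks exact-magnitude ties uniformly at random", {
  S <- init_reputation(4)
  S[1, 2:4] <- c(0.5, -0.5, 0.5)
  set.seed(31)
  trials <- 3000
  forgotten <- integer(3)
  for (t in seq_len(trials)) {
    out <- apply_memory_limit(S, 1, k = 2)
    zeroed <- which(out[1, 2:4] == 0)
    expect_length(zeroed, 1)
    forgotten[zeroed] <- forgotten[zeroed] + 1L
  }
  expect_true(all(abs(forgotten / trials - 1 / 3) < 0.05))
})

test_that("memory limit is idempotent away from ties", {
  set.seed(11)
  for (rep in 1:10) {
    S <- random_reputation(6, prob_zero = 0)
    once <- apply_memory_limit(S, 2, k = 3)
    expect_identical(apply_memory_limit(once, 2, k = 3), once)
  }
})

test_that("bounds and unit diagonal survive arbitrary operation sequences", {
  set.seed(13)
  S <- init_reputation(6)
  strategies <- c("HEIDER", "FRIEND", "ENEMY", "INCOMPLETE_HEIDER",
                  "DEFECTOR", "HEIDER")
  for (step in 1:300) {
    pair <- sample(6, 2)
    acts <- sample(c("C", "D"), 2, replace = TRUE)
    S <- update_relationships(S, pair[1], pair[2], acts[1], acts[2], r = 0.3,
                              x_strategy = strategies[pair[1]],
                              y_strategy = strategies[pair[2]])
    if (step %% 7 == 0) S <- apply_memory_limit(S, sample(6, 1), k = 3)
    expect_valid_reputation(S)
  }
})
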