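# Brute-force oracle for the relationship score: enumerate the four
# case-labelled balance heuristics (friend-of-friend, enemy-of-friend,
# friend-of-enemy, enemy-of-enemy) and sum only the cases a strategy is
# allowed to use, plus the own-opinion term that every scoring strategy
# carries through its self-trust weight of 1.
oracle_score <- function(S, x, y, strategy) {
  allowed <- switch(strategy,
    HEIDER = c("pp", "pn", "np", "nn"),
    FRIEND = c("pp", "pn"),
    ENEMY = c("np", "nn"),
    INCOMPLETE_HEIDER = c("pp", "pn", "np"),
    stop("no oracle for ", strategy))
  rs <- S[x, y]
  for (i in seq_len(nrow(S))) {
    if (i == x || i == y) next
    sxi <- S[x, i]
    siy <- S[i, y]
    if (sxi == 0 || siy == 0) next
    case <- paste0(if (sxi > 0) "p" else "n", if (siy > 0) "p" else "n")
    if (case %in% allowed) rs <- rs + sxi * siy
  }
  rs
}

# random signed reputation matrix with unit diagonal
random_reputation <- function(n, prob_zero = 0.2) {
  S <- matrix(runif(n * n, -1, 1), n, n)
  S[runif(n * n) < prob_zero] <- 0
  diag(S) <- 1
  S
}

# block-diagonal matrix of mutually positive cliques (weight w)
clique_matrix <- function(sizes, w = 0.5) {
  n <- sum(sizes)
  S <- diag(n)
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  for (b in seq_along(sizes)) {
    idx <- starts[b]:stops[b]
    S[idx, idx] <- w
    diag(S)[idx] <- 1
  }
  diag(S) <- 1
  S
}

expect_valid_reputation <- function(S) {
  expect_true(all(diag(S) == 1))
  off <- S[row(S) != col(S)]
  expect_true(all(off >= -1 & off <= 1))
}

three_strategy_config <- function(iterations, seed, k = NULL, n = 100L) {
  sim_config(composition = c(HEIDER = 0L, FRIEND = 0L, DEFECTOR = n),
             iterations = iterations, r = 0.3, b = 4, c = 1, i = 10L,
             u = 0.01, k = k, seed = seed, evolve = TRUE,
             strategy_pool = c("HEIDER", "FRIEND", "DEFECTOR"))
}
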