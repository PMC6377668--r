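#' Initialize a reputation matrix
#'
#' Creates the n-by-n signed reputation matrix in its initial state: the
#' identity matrix. Entry `S[x, y]` is agent x's relationship with (opinion
#' of) agent y, bounded to `[-1, 1]`. The diagonal — each agent's
#' relationship with itself — is fixed at 1 throughout a simulation: an
#' agent trusts no opinion more than its own.
#'
#' @param n Number of agents; at least 2.
#' @return An `n x n` numeric matrix, identity at initialization.
#' @examples
#' init_reputation(3)
#' @export
init_reputation <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != round(n)) {
    stop("population size `n` must be a single integer >= 2")
  }
  diag(nrow = as.integer(n))
}

check_reputation <- function(S) {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S)) {
    stop("`S` must be a square numeric matrix")
  }
  invisible(S)
}

check_agent <- function(S, x, arg = "x") {
  n <- nrow(S)
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x > n ||
      x != round(x)) {
    stop("agent id `", arg, "` must be a single integer in 1..", n)
  }
  invisible(as.integer(x))
}

#' Relationship score of one agent toward another
#'
#' Aggregates gossip about partner `y`: every other agent i contributes its
#' opinion `S[i, y]`, weighted by the focal agent's relationship `S[x, i]`
#' with the opinion holder. How the weight is formed depends on the
#' strategy:
#'
#' * `HEIDER`: weight is the signed relationship itself (all four balance
#'   heuristics).
#' * `FRIEND`: negative relationships are zeroed — only friends are
#'   consulted.
#' * `ENEMY`: positive relationships are zeroed, except the agent's own
#'   opinion (`i == x`), which always carries weight 1.
#' * `INCOMPLETE_HEIDER`: as `HEIDER`, but a product of two negative values
#'   ("an enemy of an enemy is a friend") is suppressed to 0.
#'
#' The partner's self-opinion (`i == y`, which is fixed at 1) is excluded
#' for every strategy, so the focal agent's own opinion `S[x, y]` enters the
#' sum exactly once, through the `i == x` term (self-trust `S[x, x] = 1`).
#' After a single mutual cooperation from a neutral start the score
#' therefore equals the relationship increment r.
#'
#' @param S Reputation matrix.
#' @param x,y Focal agent and partner (1-based ids, `x != y`).
#' @param strategy One of [agent_strategies()] except `"DEFECTOR"`.
#' @param normalize If `TRUE`, divide the score by `n - 1` (exploration
#'   switch; default `FALSE`, the raw weighted sum).
#' @return The scalar relationship score rs.
#' @examples
#' S <- init_reputation(3)
#' S[1, 2] <- 0.1
#' relationship_score(S, 1, 2, "HEIDER")  # 0.1: own opinion only
#' @export
relationship_score <- function(S, x, y, strategy, normalize = FALSE) {
  check_reputation(S)
  x <- check_agent(S, x, "x")
  y <- check_agent(S, y, "y")
  if (x == y) stop("self-interaction: `x` and `y` must differ")
  code <- strategy_code(strategy)
  if (code == 4L) stop("defectors do not compute relationship scores")
  rs <- cpp_relationship_score(S, x - 1L, y - 1L, code)
  if (isTRUE(normalize)) rs <- rs / (nrow(S) - 1)
  rs
}

#' Logistic cooperate/defect decision function
#'
#' Maps a relationship score to the probability of playing C:
#' `p(C) = 1 / (1 + exp(-rs / temperature))`, with `p(D) = 1 - p(C)`.
#' A neutral score gives p = 0.5; at the default temperature 0.2 a score of
#' 0.1 gives p ~ 0.62 and a score of 0.5 gives p ~ 0.92.
#'
#' @param rs Relationship score(s); vectorized.
#' @param temperature Logistic scale parameter, > 0. Default 0.2.
#' @return Probability (or vector of probabilities) of cooperating.
#' @examples
#' decision_probability(0)            # 0.5
#' decision_probability(0.1)          # ~0.62
#' @export
decision_probability <- function(rs, temperature = 0.2) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number")
  }
  1 / (1 + exp(-rs / temperature))
}

#' Update a relationship pair after one interaction
#'
#' Applies the relationship-updating rules to the directed pair
#' `(S[x, y], S[y, x])` given the two actions:
#'
#' * `(C, C)`: both relationships increase by `r`.
#' * one cooperates, the other defects: the cooperator downgrades the
#'   defector by `r`; the defector's opinion of the cooperator is left
#'   unchanged (this avoids anti-correlated flip-flopping of the dyad).
#' * `(D, D)`: both decrease by `r`.
#'
#' Results are clipped to `[-1, 1]`; the diagonal is untouched. An agent
#' playing the `DEFECTOR` strategy never updates its own row (its partners
#' still update their opinion of it).
#'
#' @param S Reputation matrix.
#' @param x,y Agent ids, `x != y`.
#' @param a_x,a_y Actions, `"C"` or `"D"`.
#' @param r Relationship increment, > 0.
#' @param x_strategy,y_strategy Strategy labels, used only to suppress
#'   updates of a defector's own row. Default `"HEIDER"`.
#' @return The updated reputation matrix.
#' @examples
#' S <- init_reputation(3)
#' update_relationships(S, 1, 2, "C", "C", r = 0.3)[1:2, 1:2]
#' @export
update_relationships <- function(S, x, y, a_x, a_y, r,
                                 x_strategy = "HEIDER",
                                 y_strategy = "HEIDER") {
  check_reputation(S)
  x <- check_agent(S, x, "x")
  y <- check_agent(S, y, "y")
  if (x == y) stop("self-interaction: `x` and `y` must differ")
  if (!a_x %in% c("C", "D") || !a_y %in% c("C", "D")) {
    stop('actions must be "C" or "D"')
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    stop("`r` must be a single positive number")
  }
  clip <- function(v) pmin(1, pmax(-1, v))
  if (strategy_code(x_strategy) != 4L) {
    if (a_y == "D") S[x, y] <- clip(S[x, y] - r)
    else if (a_x == "C") S[x, y] <- clip(S[x, y] + r)
  }
  if (strategy_code(y_strategy) != 4L) {
    if (a_x == "D") S[y, x] <- clip(S[y, x] - r)
    else if (a_y == "C") S[y, x] <- clip(S[y, x] + r)
  }
  S
}

#' Apply the memory constraint to one agent's relationship row
#'
#' An agent can only store `k` relationships: the `k` off-diagonal entries
#' of its row with the largest absolute value ("best friends and worst
#' enemies") are retained and all others are forgotten, i.e. reset to the
#' neutral value 0 — a forgotten relationship is indistinguishable from
#' never having met. Exact-magnitude ties at the retention boundary are
#' resolved uniformly at random (draws come from R's global RNG, so runs
#' are reproducible under `set.seed()`).
#'
#' @param S Reputation matrix.
#' @param x Agent whose row is constrained.
#' @param k Memory capacity, between 1 and `n - 1`; `k = n - 1` is
#'   unlimited memory and leaves the row unchanged.
#' @return The reputation matrix with row `x` constrained.
#' @examples
#' S <- init_reputation(4)
#' S[1, 2:4] <- c(0.9, -0.8, 0.1)
#' apply_memory_limit(S, 1, k = 2)[1, ]
#' @export
apply_memory_limit <- function(S, x, k) {
  check_reputation(S)
  x <- check_agent(S, x, "x")
  n <- nrow(S)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n - 1 ||
      k != round(k)) {
    stop("memory capacity `k` must be an integer in 1..n-1")
  }
  cpp_forget_row(S, x - 1L, as.integer(k))
}
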