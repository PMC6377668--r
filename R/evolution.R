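#' Prisoner's Dilemma payoff increments for one interaction
#'
#' Playing C costs the actor `c` and delivers benefit `b` to the partner;
#' playing D is costless and benefits no one. Mutual defection therefore
#' yields (0, 0) and mutual cooperation (b - c, b - c).
#'
#' @param a_x,a_y Actions of the two agents, `"C"` or `"D"`.
#' @param b,c Benefit and cost, `c < b`, both non-negative.
#' @return Numeric vector `c(x = ..., y = ...)` of payoff increments.
#' @examples
#' accrue_payoff("C", "C", b = 4, c = 1)  # +3 each
#' accrue_payoff("D", "C", b = 4, c = 1)  # +4 / -1
#' @export
accrue_payoff <- function(a_x, a_y, b, c) {
  if (!a_x %in% c("C", "D") || !a_y %in% c("C", "D")) {
    stop('actions must be "C" or "D"')
  }
  if (b < 0 || c < 0) stop("`b` and `c` must be non-negative")
  c(x = b * (a_y == "C") - c * (a_x == "C"),
    y = b * (a_x == "C") - c * (a_y == "C"))
}

#' Strategy-adoption probabilities of the Moran process
#'
#' Under the frequency-dependent Moran process with exponential fitness,
#' the (non-mutating) focal agent adopts strategy X with probability
#' `sum_{j in X} exp(pi_j) / sum_all exp(pi_j)` — it copies a random agent
#' chosen proportionally to `exp(payoff)`, possibly re-adopting its own
#' strategy. Payoffs are shifted by their maximum before exponentiation,
#' which leaves the ratios unchanged and avoids overflow for large
#' accumulated payoffs.
#'
#' @param payoffs Per-agent accumulated payoffs of the last generation.
#' @param strategies Per-agent strategy labels.
#' @return Named numeric vector of adoption probabilities, summing to 1,
#'   over the strategies present.
#' @examples
#' adoption_probabilities(c(log(3), 0), c("HEIDER", "DEFECTOR"))
#' @export
adoption_probabilities <- function(payoffs, strategies) {
  if (length(payoffs) != length(strategies) || length(payoffs) == 0) {
    stop("`payoffs` and `strategies` must be non-empty and equal length")
  }
  w <- exp(payoffs - max(payoffs))
  tot <- tapply(w, factor(strategies), sum)
  p <- as.numeric(tot) / sum(w)
  names(p) <- names(tot)
  p[order(names(p))]
}

#' One Moran strategy-update step
#'
#' One agent is chosen uniformly at random to adapt its strategy. With
#' probability `u` it mutates: it adopts one of the strategies in `pool`
#' with equal probability. With probability `1 - u` it adopts the strategy
#' of an agent drawn proportionally to the exponential of its accumulated
#' payoff (see [adoption_probabilities()]).
#'
#' @param strategies Character vector of per-agent strategy labels.
#' @param payoffs Per-agent accumulated payoffs of the last generation.
#' @param u Mutation probability in `[0, 1]`.
#' @param pool Strategies available to mutation; non-empty.
#' @return The updated strategy vector.
#' @export
moran_update <- function(strategies, payoffs, u, pool) {
  n <- length(strategies)
  if (length(payoffs) != n || n == 0) {
    stop("`strategies` and `payoffs` must be non-empty and equal length")
  }
  if (u < 0 || u > 1) stop("`u` must lie in [0, 1]")
  if (length(pool) == 0) stop("mutation `pool` must be non-empty")
  focal <- sample.int(n, 1L)
  if (u > 0 && runif(1) < u) {
    strategies[focal] <- pool[sample.int(length(pool), 1L)]
  } else {
    w <- exp(payoffs - max(payoffs))
    model <- sample.int(n, 1L, prob = w)
    strategies[focal] <- strategies[model]
  }
  strategies
}
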