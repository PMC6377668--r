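#' Agent strategy labels
#'
#' The five decision strategies an agent can follow when deciding whether to
#' cooperate with a randomly assigned partner:
#'
#' * `"HEIDER"` — weighs every third-party opinion by the (signed)
#'   relationship with the opinion holder, i.e. applies all four
#'   structural-balance heuristics (friend of a friend is a friend, enemy of
#'   a friend is an enemy, friend of an enemy is an enemy, enemy of an enemy
#'   is a friend).
#' * `"FRIEND"` — friend-focused: only consults agents it has a positive
#'   relationship with (negative weights are zeroed), i.e. applies only the
#'   two friendship heuristics.
#' * `"ENEMY"` — enemy-focused: only consults agents it has a negative
#'   relationship with, plus its own direct experience.
#' * `"INCOMPLETE_HEIDER"` — as `"HEIDER"` but the "enemy of an enemy is a
#'   friend" product is suppressed.
#' * `"DEFECTOR"` — always defects; performs no relationship scoring and
#'   never updates its own opinions.
#'
#' @return Character vector of the five strategy labels.
#' @examples
#' agent_strategies()
#' @export
agent_strategies <- function() {
  c("HEIDER", "FRIEND", "ENEMY", "INCOMPLETE_HEIDER", "DEFECTOR")
}

# integer codes shared with src/core.cpp (HEIDER = 0 ... DEFECTOR = 4)
strategy_code <- function(strategy) {
  code <- match(strategy, agent_strategies())
  if (anyNA(code)) {
    stop("unknown strategy label(s): ",
         paste(unique(strategy[is.na(code)]), collapse = ", "),
         "; valid labels are ", paste(agent_strategies(), collapse = ", "))
  }
  as.integer(code - 1L)
}
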