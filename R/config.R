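#' Simulation configuration
#'
#' Bundles every free parameter of a simulation run. The defaults are the
#' settings used throughout the main analyses: relationship increment
#' 0.3, logistic temperature 0.2, Prisoner's Dilemma benefit 4 and cost 1,
#' interaction frequency of 10 pairing iterations per Moran generation,
#' and unlimited memory (`k` equal to n - 1).
#'
#' @param composition Named integer vector of agent counts per strategy,
#'   e.g. `c(HEIDER = 20)` or `c(HEIDER = 0, FRIEND = 0, DEFECTOR = 100)`.
#'   Names must be a subset of [agent_strategies()]. Zero entries are
#'   allowed; their names still define the mutation pool default.
#' @param iterations Total number of pairing iterations to run.
#' @param r Relationship increment per interaction (default 0.3).
#' @param b,c Prisoner's Dilemma benefit and cost (defaults 4 and 1);
#'   `c < b` is required when evolution is enabled.
#' @param i Interaction frequency: iterations per Moran generation.
#' @param u Mutation probability per Moran update, in `[0, 1]`. Default 0.
#' @param k Memory capacity (relationships stored per agent); default
#'   `n - 1`, i.e. unlimited.
#' @param temperature Logistic scale of the decision function (default 0.2).
#' @param evolve Whether the Moran strategy-update step runs every `i`
#'   iterations. Defaults to `TRUE` when more than one strategy is named in
#'   `composition` and `u > 0`.
#' @param strategy_pool Strategies available to mutation; defaults to the
#'   names of `composition`.
#' @param seed RNG seed; `NULL` leaves the current RNG state untouched.
#' @param record_every Measurement stride in iterations; defaults to `i`
#'   when evolving (one record per generation), otherwise to roughly 100
#'   records over the run.
#' @param record_communities If `TRUE`, count mutual-positive-network
#'   communities at every record point (slower).
#' @param normalize_rs Divide relationship scores by `n - 1` (exploration
#'   switch, default `FALSE`).
#' @param reset_on_adoption If `TRUE` (default), an agent that changes
#'   strategy in a Moran update has its relationship row and column reset
#'   to the initial neutral state — the death-birth reading of the Moran
#'   process, in which the new strategy carrier starts with no relationship
#'   history. Set to `FALSE` to let relationships persist across adoption
#'   (the social-learning reading; with persistence, defection states
#'   become near-absorbing and the fission-fusion cycling largely
#'   disappears).
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' sim_config(composition = c(HEIDER = 20), iterations = 1000, seed = 1)
#' @export
sim_config <- function(composition, iterations, r = 0.3, b = 4, c = 1,
                       i = 10, u = 0, k = NULL, temperature = 0.2,
                       evolve = NULL, strategy_pool = NULL, seed = NULL,
                       record_every = NULL, record_communities = FALSE,
                       normalize_rs = FALSE, reset_on_adoption = TRUE) {
  if (is.null(names(composition)) || any(names(composition) == "")) {
    stop("`composition` must be a fully named vector of agent counts")
  }
  strategy_code(names(composition))  # validates labels
  if (any(composition < 0) || any(composition != round(composition))) {
    stop("`composition` counts must be non-negative integers")
  }
  n <- as.integer(sum(composition))
  if (n < 2) stop("population size (sum of `composition`) must be >= 2")
  if (!is.numeric(iterations) || iterations < 1) {
    stop("`iterations` must be a positive integer")
  }
  if (r <= 0) stop("`r` must be positive")
  if (temperature <= 0) stop("`temperature` must be positive")
  if (u < 0 || u > 1) stop("`u` must lie in [0, 1]")
  if (b < 0 || c < 0) stop("`b` and `c` must be non-negative")
  if (i < 1 || i != round(i)) stop("`i` must be a positive integer")
  if (is.null(k)) k <- n - 1L
  if (k < 1 || k > n - 1) stop("`k` must lie in 1..n-1")
  if (is.null(evolve)) evolve <- u > 0 && length(composition) > 1L
  if (evolve && c >= b) stop("evolution requires c < b")
  if (is.null(strategy_pool)) strategy_pool <- names(composition)
  strategy_code(strategy_pool)
  if (length(strategy_pool) < 1L) stop("`strategy_pool` must be non-empty")
  if (is.null(record_every)) {
    record_every <- if (evolve) i else max(1L, as.integer(iterations %/% 100))
  }
  structure(list(
    n = n, composition = composition, iterations = as.integer(iterations),
    r = r, b = b, c = c, i = as.integer(i), u = u, k = as.integer(k),
    temperature = temperature, evolve = isTRUE(evolve),
    strategy_pool = strategy_pool, seed = seed,
    record_every = as.integer(record_every),
    record_communities = isTRUE(record_communities),
    normalize_rs = isTRUE(normalize_rs),
    reset_on_adoption = isTRUE(reset_on_adoption)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  comp <- paste(sprintf("%s=%d", names(x$composition), x$composition),
                collapse = ", ")
  cat("Simulation configuration\n")
  cat("  population:  n =", x$n, "(", comp, ")\n")
  cat("  dynamics:    r =", x$r, ", temperature =", x$temperature,
      ", k =", x$k, "\n")
  cat("  PD payoffs:  b =", x$b, ", c =", x$c, "\n")
  cat("  evolution:  ", if (x$evolve) {
    paste0("on (i = ", x$i, ", u = ", x$u, ", pool = ",
           paste(x$strategy_pool, collapse = "/"), ")")
  } else "off", "\n")
  cat("  run length: ", x$iterations, "iterations, record every",
      x$record_every, "\n")
  if (!is.null(x$seed)) cat("  seed:       ", x$seed, "\n")
  invisible(x)
}
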