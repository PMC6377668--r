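#' Random pairing of agents
#'
#' Draws a uniformly random perfect matching of the population. For odd
#' `n`, one uniformly chosen agent sits the iteration out (attached as
#' attribute `"idle"`).
#'
#' @param n Population size, >= 2.
#' @return A two-column integer matrix of disjoint pairs (1-based ids).
#' @examples
#' set.seed(1)
#' random_pairing(4)
#' @export
random_pairing <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 ||
      n != round(n)) {
    stop("population size `n` must be a single integer >= 2")
  }
  perm <- sample.int(n)
  npairs <- n %/% 2
  pairs <- matrix(perm[seq_len(2 * npairs)], ncol = 2, byrow = TRUE)
  colnames(pairs) <- c("x", "y")
  if (n %% 2 == 1L) attr(pairs, "idle") <- perm[n]
  pairs
}

#' Initial simulation state
#'
#' @param config A [sim_config()].
#' @return A list with the identity reputation matrix `S`, the strategy
#'   assignment, zeroed payoffs and an iteration counter.
#' @export
sim_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  strategies <- rep(names(config$composition), config$composition)
  list(S = init_reputation(config$n), strategies = strategies,
       payoffs = numeric(config$n), iteration = 0L)
}

#' Run one iteration of the interaction loop
#'
#' Executes the three stages once — random matching, simultaneous action
#' choice from the iteration-start snapshot of the reputation matrix, and
#' relationship updating — followed by the memory constraint on every
#' agent's row. Defectors always play D. Payoffs accrue into
#' `state$payoffs`.
#'
#' @param state A simulation state, see [sim_state()].
#' @param config A [sim_config()].
#' @return The updated state; elements `coop` and `actions` hold the C-count
#'   and action count of this iteration.
#' @export
run_iteration <- function(state, config) {
  stopifnot(inherits(config, "sim_config"))
  res <- cpp_iterate(state$S, strategy_code(state$strategies), state$payoffs,
                     1L, config$r, config$temperature, config$k, config$b,
                     config$c, config$normalize_rs)
  state$S <- res$S
  state$payoffs <- res$payoffs
  state$iteration <- state$iteration + 1L
  state$coop <- res$n_coop
  state$actions <- res$n_actions
  state
}

#' Run a full simulation
#'
#' Executes `config$iterations` pairing iterations. When evolution is
#' enabled, a Moran strategy update (see [moran_update()]) runs every
#' `config$i` iterations, after which payoffs reset — fitness reflects only
#' the current generation. Measurements are taken every
#' `config$record_every` iterations: strategy counts, the cooperation rate
#' of the elapsed window, mean payoff per strategy, mean outgoing-positive
#' connection count per strategy and (optionally) the Louvain community
#' count of the mutual-positive network.
#'
#' With a `seed` in the configuration, the returned trajectory is
#' bit-reproducible.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: list with `trajectory` (one
#'   data-frame row per record), final reputation matrix `S`, final
#'   `strategies`, and the `config`.
#' @examples
#' cfg <- sim_config(composition = c(HEIDER = 10), iterations = 2000,
#'                   seed = 42)
#' res <- run_simulation(cfg)
#' tail(res$trajectory, 2)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- sim_state(config)
  scode <- strategy_code(state$strategies)
  labels <- agent_strategies()

  if (config$evolve) {
    gens <- config$iterations %/% config$i
    stride <- max(1L, config$record_every %/% config$i)
    n_rec <- gens %/% stride
    block_iter <- config$i
  } else {
    gens <- config$iterations %/% config$record_every
    stride <- 1L
    n_rec <- gens
    block_iter <- config$record_every
  }
  rec <- make_recorder(n_rec, labels)
  S <- state$S
  payoffs <- state$payoffs
  ridx <- 0L

  for (g in seq_len(gens)) {
    res <- cpp_iterate(S, scode, payoffs, block_iter, config$r,
                       config$temperature, config$k, config$b, config$c,
                       config$normalize_rs)
    S <- res$S
    payoffs <- res$payoffs
    if (g %% stride == 0L) {
      ridx <- ridx + 1L
      rec <- record_row(rec, ridx, g, g * block_iter, scode, payoffs,
                        res$n_coop, res$n_actions, S, config, labels)
    }
    if (config$evolve) {
      new_labels <- moran_update(labels[scode + 1L], payoffs, config$u,
                                 config$strategy_pool)
      new_scode <- strategy_code(new_labels)
      if (config$reset_on_adoption) {
        changed <- which(new_scode != scode)
        for (a in changed) {
          S[a, -a] <- 0
          S[-a, a] <- 0
        }
      }
      scode <- new_scode
      payoffs <- numeric(config$n)
    }
  }

  trajectory <- finish_recorder(rec, ridx, labels)
  structure(list(trajectory = trajectory, S = S,
                 strategies = labels[scode + 1L], config = config),
            class = "sim_result")
}

# pre-allocated trajectory storage -------------------------------------------

make_recorder <- function(n_rec, labels) {
  k <- length(labels)
  list(core = matrix(NA_real_, nrow = n_rec, ncol = 4L + k),
       payoff = matrix(NA_real_, nrow = n_rec, ncol = k),
       outpos = matrix(NA_real_, nrow = n_rec, ncol = k))
}

record_row <- function(rec, ridx, gen, iter, scode, payoffs, n_coop,
                       n_actions, S, config, labels) {
  k <- length(labels)
  counts <- tabulate(scode + 1L, nbins = k)
  coop_rate <- if (n_actions > 0) n_coop / n_actions else NA_real_
  ncomm <- NA_real_
  if (config$record_communities) {
    ncomm <- count_communities(mutual_positive_graph(S))$n_communities
  }
  rec$core[ridx, ] <- c(gen, iter, coop_rate, ncomm, counts)
  outdeg <- outgoing_positive_connections(S)
  for (j in seq_len(k)) {
    members <- scode == (j - 1L)
    if (any(members)) {
      rec$payoff[ridx, j] <- mean(payoffs[members])
      rec$outpos[ridx, j] <- mean(outdeg[members])
    }
  }
  rec
}

finish_recorder <- function(rec, ridx, labels) {
  keep <- seq_len(ridx)
  lab <- tolower(sub("INCOMPLETE_HEIDER", "incomplete", labels))
  out <- as.data.frame(rec$core[keep, , drop = FALSE])
  names(out) <- c("generation", "iteration", "coop_rate", "n_communities",
                  paste0("n_", lab))
  pay <- as.data.frame(rec$payoff[keep, , drop = FALSE])
  names(pay) <- paste0("payoff_", lab)
  op <- as.data.frame(rec$outpos[keep, , drop = FALSE])
  names(op) <- paste0("outpos_", lab)
  cbind(out, pay, op)
}

#' @export
print.sim_result <- function(x, ...) {
  counts <- table(factor(x$strategies, levels = agent_strategies()))
  cat("Simulation result:", x$config$iterations, "iterations, n =",
      x$config$n, "\n")
  cat("  final composition:",
      paste(sprintf("%s=%d", names(counts)[counts > 0], counts[counts > 0]),
            collapse = ", "), "\n")
  tr <- x$trajectory
  if (nrow(tr)) {
    cat("  records:", nrow(tr), "; final window cooperation rate:",
        round(tr$coop_rate[nrow(tr)], 3), "\n")
  }
  invisible(x)
}
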