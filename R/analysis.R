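#' Mutual-positive cooperation network
#'
#' Builds the undirected graph whose edges connect agent pairs with a
#' positive relationship in both directions — pairs with a high likelihood
#' of mutual cooperation. Edge weight is the mean of the two directed
#' relationship values. Every agent is present as a node, so agents with no
#' mutual-positive ties appear as isolates.
#'
#' @param S Reputation matrix.
#' @param threshold Strict lower bound for "positive"; default 0, so a
#'   forgotten (neutral) relationship is not a link.
#' @return An [igraph][igraph::graph_from_adjacency_matrix] undirected
#'   weighted graph with `n` nodes.
#' @export
mutual_positive_graph <- function(S, threshold = 0) {
  check_reputation(S)
  A <- (S > threshold) & (t(S) > threshold)
  diag(A) <- FALSE
  W <- ifelse(A, (S + t(S)) / 2, 0)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Count communities by Louvain modularity maximization
#'
#' Runs the Louvain method (resolution 1) on an undirected graph under a
#' fixed internal seed, so repeated calls on the same graph agree and do
#' not disturb the simulation RNG stream. Isolated nodes form singleton
#' communities.
#'
#' @param graph Undirected graph, typically from [mutual_positive_graph()].
#' @return List with `labels` (per-node community id) and `n_communities`.
#' @examples
#' g <- mutual_positive_graph(init_reputation(4))
#' count_communities(g)$n_communities  # 4 isolates -> 4 singletons
#' @export
count_communities <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object")
  labels <- with_preserved_seed(20190215L, {
    igraph::membership(igraph::cluster_louvain(graph))
  })
  list(labels = as.integer(labels),
       n_communities = length(unique(as.integer(labels))))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream (analysis calls must not perturb a running simulation's draws).
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Cooperation rate of an action window
#'
#' @param actions Character vector of `"C"`/`"D"` actions (or logical,
#'   `TRUE` = C).
#' @return Fraction of C actions, in `[0, 1]`.
#' @export
cooperation_rate <- function(actions) {
  if (length(actions) == 0) stop("cooperation rate undefined: empty window")
  if (is.logical(actions)) return(mean(actions))
  if (!all(actions %in% c("C", "D"))) stop('actions must be "C" or "D"')
  mean(actions == "C")
}

#' Outgoing positive connections
#'
#' Number of positive off-diagonal entries in an agent's relationship row —
#' how many agents it currently holds a positive opinion of.
#'
#' @param S Reputation matrix.
#' @param x Optional agent id; if `NULL`, returns the count for every
#'   agent.
#' @return Integer count or vector of counts.
#' @export
outgoing_positive_connections <- function(S, x = NULL) {
  check_reputation(S)
  counts <- as.integer(rowSums(S > 0) - (diag(S) > 0))
  if (is.null(x)) return(counts)
  x <- check_agent(S, x, "x")
  counts[x]
}

#' Exponential decay regression
#'
#' Fits `y = offset + amplitude * exp(-x / tau)` by nonlinear least squares
#' (Levenberg-Marquardt), or the pure form `y = amplitude * exp(-x / tau)`
#' when `model_form = "pure"`. Growth is captured by a negative amplitude.
#' Starting values come from a log-linear regression of the de-offset
#' response.
#'
#' @param xs Predictor values (at least 3 distinct).
#' @param ys Responses, same length.
#' @param model_form `"offset"` (default) or `"pure"`.
#' @return Object of class `decay_fit`: list with `tau`, `amplitude`,
#'   `offset`, `model_form` and the underlying `fit`.
#' @examples
#' x <- 0:9
#' fit_exponential_decay(x, 10 * exp(-x / 5))$tau  # 5
#' @export
fit_exponential_decay <- function(xs, ys, model_form = c("offset", "pure")) {
  model_form <- match.arg(model_form)
  if (length(xs) != length(ys)) stop("`xs` and `ys` must have equal length")
  if (length(unique(xs)) < 3) stop("need at least 3 distinct predictor values")
  if (isTRUE(all.equal(var(ys), 0))) {
    stop("degenerate input: constant response has no decay scale")
  }
  dat <- data.frame(x = as.numeric(xs), y = as.numeric(ys))
  off0 <- if (model_form == "offset") min(dat$y) else 0
  amp0 <- dat$y[which.min(dat$x)] - off0
  if (amp0 == 0) amp0 <- diff(range(dat$y))
  z <- pmax(abs(dat$y - off0), 1e-9) # log-linear slope for a tau start
  sl <- coef(lm(log(z) ~ dat$x))[2]
  tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else diff(range(dat$x)) / 2
  tau0 <- max(tau0, 1e-3)
  fit <- tryCatch({
    if (model_form == "offset") {
      minpack.lm::nlsLM(y ~ offset + amplitude * exp(-x / tau), data = dat,
                        start = list(offset = off0, amplitude = amp0,
                                     tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ amplitude * exp(-x / tau), data = dat,
                        start = list(amplitude = amp0, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) {
    stop("exponential decay fit failed to converge: ", conditionMessage(e),
         " (n = ", nrow(dat), ", y range = ",
         paste(signif(range(dat$y), 4), collapse = ".."), ")")
  })
  est <- coef(fit)
  if (!is.finite(est[["tau"]]) || est[["tau"]] <= 0) {
    stop("exponential decay fit degenerate: tau = ", est[["tau"]])
  }
  structure(list(tau = unname(est[["tau"]]),
                 amplitude = unname(est[["amplitude"]]),
                 offset = if (model_form == "offset") {
                   unname(est[["offset"]])
                 } else 0,
                 model_form = model_form, fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit (", x$model_form, " form): tau = ",
      signif(x$tau, 4), ", amplitude = ", signif(x$amplitude, 4),
      ", offset = ", signif(x$offset, 4), "\n", sep = "")
  invisible(x)
}

#' Rapoport index of cooperation
#'
#' Normalized measure of how conducive a Prisoner's Dilemma is to
#' cooperation: `K = (R - P) / (T - S)` with reward `R = b - c`, punishment
#' `P = 0`, temptation `T = b` and sucker's payoff `S = -c`, giving
#' `K = (b - c) / (b + c)`. `b = c` is the degenerate boundary, `K = 0`.
#'
#' @param b Benefit of receiving cooperation, > 0.
#' @param c Cost of cooperating, `0 <= c <= b`.
#' @return The index K in `[0, 1)`.
#' @examples
#' rapoport_index(4, 1)  # 3/5
#' @export
rapoport_index <- function(b, c) {
  if (b <= 0 || c < 0) stop("need b > 0 and c >= 0")
  if (b < c) stop("invalid Prisoner's Dilemma: requires b >= c")
  (b - c) / (b + c)
}

#' Majority (plurality) state of a strategy composition
#'
#' @param counts Named vector of agent counts per strategy.
#' @return `"<STRATEGY>_MAJ"` for the strategy holding a strict plurality,
#'   or `"MIXED"` on a tie for the top count.
#' @examples
#' classify_majority_state(c(FRIEND = 60, HEIDER = 30, DEFECTOR = 10))
#' @export
classify_majority_state <- function(counts) {
  if (is.null(names(counts)) || length(counts) == 0) {
    stop("`counts` must be a named vector")
  }
  top <- max(counts)
  leaders <- names(counts)[counts == top]
  if (length(leaders) > 1L) "MIXED" else paste0(leaders, "_MAJ")
}

#' Majority-state sequence of a simulation trajectory
#'
#' Classifies the plurality strategy of every recorded generation.
#'
#' @param trajectory Trajectory data frame from [run_simulation()] (or a
#'   `sim_result`).
#' @return Character vector of majority-state labels, one per record.
#' @export
majority_states <- function(trajectory) {
  if (inherits(trajectory, "sim_result")) trajectory <- trajectory$trajectory
  cols <- c(HEIDER = "n_heider", FRIEND = "n_friend", ENEMY = "n_enemy",
            INCOMPLETE_HEIDER = "n_incomplete", DEFECTOR = "n_defector")
  cols <- cols[cols %in% names(trajectory)]
  counts <- as.matrix(trajectory[, cols, drop = FALSE])
  colnames(counts) <- names(cols)
  apply(counts, 1L, classify_majority_state)
}

#' Maximum-likelihood transition matrix of a state sequence
#'
#' Estimates first-order Markov transition probabilities by transition
#' counting: entry (a, b) is the number of observed a to b transitions
#' divided by the number of visits to a with a successor. States never
#' visited (with a successor) get an `NA` row.
#'
#' @param states Character vector of states, length >= 2.
#' @param state_space Optional vector fixing the row/column order; defaults
#'   to the sorted unique states.
#' @return Row-stochastic matrix with `NA` rows for unvisited states.
#' @examples
#' estimate_transition_matrix(c("A", "A", "B", "B"))
#' @export
estimate_transition_matrix <- function(states, state_space = NULL) {
  if (length(states) < 2) stop("need at least 2 states to estimate transitions")
  if (is.null(state_space)) state_space <- sort(unique(states))
  from <- factor(states[-length(states)], levels = state_space)
  to <- factor(states[-1L], levels = state_space)
  counts <- table(from, to)
  P <- unclass(counts / rowSums(counts))  # rows with 0 visits become NaN
  P[is.nan(P)] <- NA_real_
  dimnames(P) <- list(from = state_space, to = state_space)
  P
}

#' Count fission-fusion cycles in a majority-state sequence
#'
#' A completed cycle is an ordered traversal of the three phases defection
#' dominance, friend-focused community building, Heider-driven
#' polarization: `DEFECTOR_MAJ -> FRIEND_MAJ -> HEIDER_MAJ ->
#' DEFECTOR_MAJ`. A `MIXED` (or any other) generation is transparent: it
#' neither advances nor resets the phase tracker. A `DEFECTOR_MAJ` state
#' always (re)starts the tracker, so the closing defection phase of one
#' cycle opens the next.
#'
#' @param states Character vector of majority-state labels, non-empty.
#' @return List with `cycles` (completed count), `n_generations`, and
#'   `per_1000` (cycles per 1000 generations).
#' @examples
#' count_cycles(c("DEFECTOR_MAJ", "FRIEND_MAJ", "HEIDER_MAJ",
#'                "DEFECTOR_MAJ"))$cycles  # 1
#' @export
count_cycles <- function(states) {
  if (length(states) == 0) stop("`states` must be non-empty")
  cycles <- 0L
  phase <- 0L  # 0 none, 1 D seen, 2 D,F seen, 3 D,F,H seen
  for (s in states) {
    if (s == "DEFECTOR_MAJ") {
      if (phase == 3L) cycles <- cycles + 1L
      phase <- 1L
    } else if (s == "FRIEND_MAJ") {
      if (phase == 1L) phase <- 2L
    } else if (s == "HEIDER_MAJ") {
      if (phase == 2L) phase <- 3L
    }
  }
  list(cycles = cycles, n_generations = length(states),
       per_1000 = 1000 * cycles / length(states))
}
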