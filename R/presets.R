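# Preset experiments. Each preset reproduces one of the study's experiment
# families at either full size or a documented desk scale, writes its
# summaries and a JSON manifest of every parameter and seed, and returns the
# summaries invisibly for programmatic use.

preset_names <- function() {
  c("polarization", "evolution", "paramspace", "pairwise", "memory")
}

#' Run a preset experiment
#'
#' Available presets:
#'
#' * `"polarization"`: non-evolutionary runs measuring community structure —
#'   pure-Heider populations (fraction ending in one vs. two communities)
#'   and a gradient of 0-5 Heider agents embedded in friend-focused
#'   populations, with an exponential-decay fit of mean community count
#'   against the number of Heider agents.
#' * `"evolution"`: the three-strategy Moran run (n = 100, i = 10, b = 4,
#'   c = 1, r = 0.3, u = 0.01) starting from all defectors; outputs the
#'   trajectory, majority-state sequence, transition matrices and
#'   fission-fusion cycle count.
#' * `"paramspace"`: sweep over interaction frequency i and benefit b (and
#'   mutation rate u at full scale), with Rapoport indices.
#' * `"pairwise"`: the three pairwise competitions (Heider vs. defector,
#'   friend vs. defector, Heider vs. friend) from 50/50 starts.
#' * `"memory"`: memory-capacity effects — mean cooperative connections
#'   versus capacity k in non-evolutionary populations, and cycle
#'   frequency at constrained vs. full memory under selection.
#'
#' Desk scale reduces run lengths and replicate counts (factors recorded in
#' the manifest) so a preset completes in minutes on one CPU; full scale
#' uses the original experiment sizes.
#'
#' @param name One of `preset_names()`.
#' @param scale `"desk"` (default) or `"full"`.
#' @param seed Base integer seed; every run's seed is derived from it.
#' @param out_dir Output directory; defaults to a fresh directory under
#'   `tempdir()`.
#' @return Invisibly, a list of the preset's summary objects plus `dir`.
#' @export
run_preset <- function(name, scale = c("desk", "full"), seed = 1,
                       out_dir = NULL) {
  scale <- match.arg(scale)
  if (!name %in% preset_names()) {
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "))
  }
  if (is.null(out_dir)) {
    out_dir <- file.path(tempdir(),
                         paste0("heidercoop-", name, "-", scale, "-", seed))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(name,
    polarization = preset_polarization(scale, seed, out_dir),
    evolution = preset_evolution(scale, seed, out_dir),
    paramspace = preset_paramspace(scale, seed, out_dir),
    pairwise = preset_pairwise(scale, seed, out_dir),
    memory = preset_memory(scale, seed, out_dir)
  )
  out$dir <- out_dir
  invisible(out)
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

preset_polarization <- function(scale, seed, out_dir) {
  p <- if (scale == "desk") {
    list(pure_sizes = c(10L, 20L, 40L), grad_sizes = c(20L, 40L),
         reps = 20L, iterations = 1e5)
  } else {
    list(pure_sizes = c(10L, 20L, 40L, 60L, 120L),
         grad_sizes = c(10L, 20L, 40L, 60L, 120L),
         reps = 50L, iterations = 1e5)
  }
  counter <- 0L
  pure <- do.call(rbind, lapply(p$pure_sizes, function(nsz) {
    do.call(rbind, lapply(seq_len(p$reps), function(rep_i) {
      counter <<- counter + 1L
      run_seed <- seed + counter
      res <- run_simulation(sim_config(
        composition = c(HEIDER = nsz), iterations = p$iterations,
        r = 0.3, seed = run_seed))
      cbind(data.frame(size = nsz, replicate = rep_i, seed = run_seed),
            summarize_run(res))
    }))
  }))
  gradient <- do.call(rbind, lapply(p$grad_sizes, function(nsz) {
    do.call(rbind, lapply(0:5, function(h) {
      do.call(rbind, lapply(seq_len(p$reps), function(rep_i) {
        counter <<- counter + 1L
        run_seed <- seed + counter
        res <- run_simulation(sim_config(
          composition = c(HEIDER = h, FRIEND = nsz - h),
          iterations = p$iterations, r = 0.3, seed = run_seed))
        cbind(data.frame(size = nsz, n_heider_agents = h, replicate = rep_i,
                         seed = run_seed),
              summarize_run(res))
      }))
    }))
  }))
  decay <- community_decay_fit(gradient)
  write.csv(pure, file.path(out_dir, "pure_summary.csv"), row.names = FALSE)
  write.csv(gradient, file.path(out_dir, "gradient_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(tau = decay$tau, amplitude = decay$amplitude, offset = decay$offset,
         model_form = decay$model_form),
    file.path(out_dir, "decay_fit.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, c(list(preset = "polarization", scale = scale,
                                 seed = seed, r = 0.3,
                                 seed_rule = "seed + run counter"), p))
  list(pure = pure, gradient = gradient, decay_fit = decay)
}

#' Fit the community-count decay against the number of Heider agents
#'
#' Averages the Louvain community count per (population size, Heider count)
#' cell, pools the cell means across sizes per Heider count and fits the
#' pure exponential-decay form `A * exp(-x / tau)` — the "declines by a
#' factor of tau" parameterization. An additive-offset variant absorbs the
#' flattening of the community count near its polarized floor into the
#' offset and yields a tau describing only the initial drop; the pure form
#' describes the overall multiplicative decline. The offset form is used
#' as a fallback if the pure fit does not converge.
#'
#' @param gradient Data frame with columns `size`, `n_heider_agents` and
#'   `n_communities` (as produced by the polarization preset).
#' @return A `decay_fit`, see [fit_exponential_decay()].
#' @export
community_decay_fit <- function(gradient) {
  cell <- aggregate_sweep(gradient, by = c("size", "n_heider_agents"),
                          value = "n_communities")
  pooled <- aggregate_sweep(cell, by = "n_heider_agents", value = "mean")
  tryCatch(
    fit_exponential_decay(pooled$n_heider_agents, pooled$mean, "pure"),
    error = function(e) {
      fit_exponential_decay(pooled$n_heider_agents, pooled$mean, "offset")
    })
}

evolution_config <- function(iterations, seed, k = NULL, n = 100L) {
  sim_config(composition = c(HEIDER = 0L, FRIEND = 0L, DEFECTOR = n),
             iterations = iterations, r = 0.3, b = 4, c = 1, i = 10L,
             u = 0.01, k = k, seed = seed,
             evolve = TRUE,
             strategy_pool = c("HEIDER", "FRIEND", "DEFECTOR"))
}

preset_evolution <- function(scale, seed, out_dir) {
  iterations <- if (scale == "desk") 4e4 else 4e5
  res <- run_simulation(evolution_config(iterations, seed))
  states <- majority_states(res)
  tmat <- estimate_transition_matrix(states)
  condensed <- states[states != "MIXED"]
  tmat_condensed <- if (length(condensed) >= 2) {
    estimate_transition_matrix(condensed)
  } else NULL
  cyc <- count_cycles(states)
  write_sim_result(res, out_dir)
  writeLines(states, file.path(out_dir, "majority_states.txt"))
  jsonlite::write_json(
    list(cycles = cyc, transition_matrix = as.data.frame(tmat),
         transition_matrix_no_mixed = if (!is.null(tmat_condensed)) {
           as.data.frame(tmat_condensed)
         }),
    file.path(out_dir, "markov.json"), digits = NA)
  write_manifest(out_dir, list(preset = "evolution", scale = scale,
                               seed = seed, n = 100, i = 10, b = 4, c = 1,
                               r = 0.3, u = 0.01, iterations = iterations))
  list(result = res, states = states, transition_matrix = tmat,
       transition_matrix_no_mixed = tmat_condensed, cycles = cyc)
}

preset_paramspace <- function(scale, seed, out_dir) {
  p <- if (scale == "desk") {
    list(u = 0.01, i = c(1L, 4L, 16L), b = c(2, 4, 8), reps = 1L,
         iter_factor = 5e3)
  } else {
    list(u = c(0.01, 0.001), i = 1:32, b = 1:8, reps = 1L, iter_factor = 5e5)
  }
  counter <- 0L
  rows <- list()
  for (i_val in p$i) {
    sw <- run_sweep(
      base = list(composition = c(HEIDER = 0L, FRIEND = 0L, DEFECTOR = 100L),
                  iterations = i_val * p$iter_factor, r = 0.3, c = 1,
                  i = i_val, evolve = TRUE,
                  strategy_pool = c("HEIDER", "FRIEND", "DEFECTOR")),
      grid = list(u = p$u, b = p$b), replicates = p$reps,
      base_seed = seed + counter)
    counter <- counter + nrow(sw)
    rows[[length(rows) + 1L]] <- cbind(data.frame(i = i_val), sw)
  }
  summary <- do.call(rbind, rows)
  summary$rapoport_K <- vapply(summary$b, rapoport_index, numeric(1), c = 1)
  write.csv(summary, file.path(out_dir, "paramspace_summary.csv"),
            row.names = FALSE)
  write_manifest(out_dir, c(list(preset = "paramspace", scale = scale,
                                 seed = seed, n = 100, c = 1, r = 0.3), p))
  list(summary = summary)
}

preset_pairwise <- function(scale, seed, out_dir) {
  iterations <- if (scale == "desk") 4e4 else 1e6
  combos <- list(
    heider_vs_defector = c(HEIDER = 50L, DEFECTOR = 50L),
    friend_vs_defector = c(FRIEND = 50L, DEFECTOR = 50L),
    heider_vs_friend = c(HEIDER = 50L, FRIEND = 50L)
  )
  results <- list()
  rows <- list()
  for (j in seq_along(combos)) {
    cfg <- sim_config(composition = combos[[j]], iterations = iterations,
                      r = 0.3, b = 4, c = 1, i = 10L, u = 0.01,
                      seed = seed + j, evolve = TRUE)
    res <- run_simulation(cfg)
    results[[names(combos)[j]]] <- res
    tr <- res$trajectory
    tail_rows <- tr[seq.int(ceiling(nrow(tr) / 2), nrow(tr)), ]
    rows[[j]] <- cbind(data.frame(combo = names(combos)[j], seed = seed + j,
                                  mean_tail_coop = mean(tail_rows$coop_rate),
                                  mean_tail_heider = mean(tail_rows$n_heider),
                                  mean_tail_friend = mean(tail_rows$n_friend),
                                  mean_tail_defector =
                                    mean(tail_rows$n_defector)),
                       summarize_run(res))
    write.csv(tr, file.path(out_dir,
                            paste0("trajectory_", names(combos)[j], ".csv")),
              row.names = FALSE)
  }
  summary <- do.call(rbind, rows)
  write.csv(summary, file.path(out_dir, "pairwise_summary.csv"),
            row.names = FALSE)
  write_manifest(out_dir, list(preset = "pairwise", scale = scale,
                               seed = seed, n = 100, i = 10, b = 4, c = 1,
                               r = 0.3, u = 0.01, iterations = iterations))
  list(summary = summary, results = results)
}

preset_memory <- function(scale, seed, out_dir) {
  p <- if (scale == "desk") {
    list(net_size = 40L, net_heider = 2L, k_frac = c(0.1, 0.5, 0.9),
         net_reps = 3L, net_iterations = 3e4,
         evo_k = c(33L, 99L), evo_iterations = 1e5)
  } else {
    list(net_size = c(20L, 40L, 60L, 120L), net_heider = 1:5,
         k_frac = c(0.1, 0.3, 0.5, 0.7, 0.9), net_reps = 20L,
         net_iterations = 1e5,
         evo_k = c(33L, 66L, 99L), evo_iterations = 1e5)
  }
  counter <- 0L
  network <- do.call(rbind, lapply(p$net_size, function(nsz) {
    do.call(rbind, lapply(p$net_heider, function(h) {
      do.call(rbind, lapply(p$k_frac, function(kf) {
        k <- max(1L, min(nsz - 1L, as.integer(round(kf * nsz))))
        do.call(rbind, lapply(seq_len(p$net_reps), function(rep_i) {
          counter <<- counter + 1L
          run_seed <- seed + counter
          res <- run_simulation(sim_config(
            composition = c(HEIDER = h, FRIEND = nsz - h),
            iterations = p$net_iterations, r = 0.3, k = k, seed = run_seed))
          cbind(data.frame(size = nsz, n_heider_agents = h, k_frac = kf,
                           k = k, replicate = rep_i, seed = run_seed),
                summarize_run(res))
        }))
      }))
    }))
  }))
  cycles <- do.call(rbind, lapply(seq_along(p$evo_k), function(j) {
    k <- p$evo_k[j]
    res <- run_simulation(evolution_config(p$evo_iterations,
                                           seed + 10000L + j, k = k))
    cyc <- count_cycles(majority_states(res))
    data.frame(k = k, seed = seed + 10000L + j, cycles = cyc$cycles,
               n_generations = cyc$n_generations, per_1000 = cyc$per_1000)
  }))
  write.csv(network, file.path(out_dir, "memory_network_summary.csv"),
            row.names = FALSE)
  write.csv(cycles, file.path(out_dir, "memory_cycles.csv"),
            row.names = FALSE)
  write_manifest(out_dir, c(list(preset = "memory", scale = scale,
                                 seed = seed, r = 0.3,
                                 evo = list(n = 100, i = 10, b = 4, c = 1,
                                            u = 0.01)), p))
  list(network = network, cycles = cycles)
}
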