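#' Summarize a finished simulation run
#'
#' One-row summary used by sweeps and presets: final strategy proportions,
#' the cooperation rate averaged over the last fraction of records, the
#' Louvain community count of the final mutual-positive network and its
#' mean degree (cooperative connections per agent).
#'
#' @param result A `sim_result`.
#' @param tail_frac Fraction of trailing records to average the
#'   cooperation rate over (default 0.25).
#' @return A one-row data frame.
#' @export
summarize_run <- function(result, tail_frac = 0.25) {
  stopifnot(inherits(result, "sim_result"))
  tr <- result$trajectory
  n <- result$config$n
  tail_rows <- tr[seq.int(max(1L, ceiling(nrow(tr) * (1 - tail_frac))),
                          nrow(tr)), , drop = FALSE]
  counts <- table(factor(result$strategies, levels = agent_strategies()))
  g <- mutual_positive_graph(result$S)
  data.frame(
    n = n,
    prop_heider = as.numeric(counts[["HEIDER"]]) / n,
    prop_friend = as.numeric(counts[["FRIEND"]]) / n,
    prop_enemy = as.numeric(counts[["ENEMY"]]) / n,
    prop_incomplete = as.numeric(counts[["INCOMPLETE_HEIDER"]]) / n,
    prop_defector = as.numeric(counts[["DEFECTOR"]]) / n,
    coop_rate = mean(tail_rows$coop_rate, na.rm = TRUE),
    n_communities = count_communities(g)$n_communities,
    mean_pos_degree = mean(igraph::degree(g))
  )
}

#' Run a seeded parameter sweep
#'
#' Expands a grid of [sim_config()] parameters, runs `replicates`
#' simulations per cell with deterministic per-run seeds (`base_seed` plus
#' a running counter, so cells never share a seed), and returns one summary
#' row per run. Failed cells are kept as rows with an `error` message so
#' partial sweeps are not lost.
#'
#' @param base Named list of arguments for [sim_config()] shared by all
#'   cells (must include `composition` and `iterations`).
#' @param grid Named list of parameter value vectors to cross; names must
#'   be [sim_config()] arguments.
#' @param replicates Runs per grid cell.
#' @param base_seed Integer seed from which every run's seed is derived.
#' @param out_dir Optional directory; when given, the summary is written to
#'   `sweep_summary.csv` there.
#' @return Data frame: grid columns, `replicate`, `seed`, the
#'   [summarize_run()] columns and `error` (`NA` on success).
#' @examples
#' run_sweep(base = list(composition = c(HEIDER = 6), iterations = 500),
#'           grid = list(r = c(0.1, 0.3)), replicates = 2, base_seed = 7)
#' @export
run_sweep <- function(base, grid = list(), replicates = 1, base_seed = 1,
                      out_dir = NULL) {
  if (length(grid) > 0 && is.null(names(grid))) {
    stop("`grid` must be a named list of parameter values")
  }
  bad <- setdiff(names(grid), names(formals(sim_config)))
  if (length(bad)) {
    stop("unknown grid parameter(s): ", paste(bad, collapse = ", "))
  }
  cells <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
           else data.frame(.dummy = 1)
  rows <- list()
  counter <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- as.list(cells[ci, , drop = FALSE])
    cell$.dummy <- NULL
    for (rep_i in seq_len(replicates)) {
      counter <- counter + 1L
      run_seed <- as.integer(base_seed) + counter
      args <- modifyList(base, cell)
      args$seed <- run_seed
      row <- tryCatch({
        res <- run_simulation(do.call(sim_config, args))
        cbind(summarize_run(res), error = NA_character_)
      }, error = function(e) {
        data.frame(n = NA, prop_heider = NA, prop_friend = NA,
                   prop_enemy = NA, prop_incomplete = NA, prop_defector = NA,
                   coop_rate = NA, n_communities = NA, mean_pos_degree = NA,
                   error = conditionMessage(e))
      })
      meta <- data.frame(replicate = rep_i, seed = run_seed)
      if (length(cell)) meta <- cbind(as.data.frame(cell), meta)
      rows[[counter]] <- cbind(meta, row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "sweep_summary.csv"), row.names = FALSE)
  }
  out
}

#' Aggregate sweep rows to per-cell means and standard errors
#'
#' @param summary Data frame from [run_sweep()].
#' @param by Character vector of grid column names to aggregate over.
#' @param value Summary column to aggregate (default `"coop_rate"`).
#' @return Data frame with per-cell `mean`, `sem` and `n_reps`.
#' @export
aggregate_sweep <- function(summary, by, value = "coop_rate") {
  if (!all(by %in% names(summary)) || !value %in% names(summary)) {
    stop("`by`/`value` columns not present in the sweep summary")
  }
  split_idx <- interaction(summary[, by, drop = FALSE], drop = TRUE)
  parts <- lapply(split(summary, split_idx), function(d) {
    v <- d[[value]]
    cbind(d[1L, by, drop = FALSE],
          data.frame(mean = mean(v, na.rm = TRUE),
                     sem = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))),
                     n_reps = sum(!is.na(v))))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
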