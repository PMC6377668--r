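# Plain-text output formats: square-matrix CSV, signed edge lists, GraphML,
# trajectory CSV and a JSON echo of the configuration.

#' Write / read a reputation matrix as square CSV
#'
#' @param S Reputation matrix.
#' @param path Output file.
#' @return `path`, invisibly (writer); the matrix (reader).
#' @export
write_reputation_csv <- function(S, path) {
  check_reputation(S)
  write.csv(as.data.frame(S), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reputation_csv
#' @export
read_reputation_csv <- function(path) {
  S <- as.matrix(read.csv(path))
  dimnames(S) <- NULL
  check_reputation(S)
}

#' Write a signed adjacency as an edge list
#'
#' Writes every non-zero off-diagonal directed relationship as a
#' `source,target,weight` row with 0-based agent ids.
#'
#' @param S Reputation matrix.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(S, path) {
  check_reputation(S)
  idx <- which(S != 0 & row(S) != col(S), arr.ind = TRUE)
  df <- data.frame(source = idx[, 1] - 1L, target = idx[, 2] - 1L,
                   weight = S[idx])
  df <- df[order(df$source, df$target), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the mutual-positive network as GraphML
#'
#' @param S Reputation matrix (converted via [mutual_positive_graph()]) or
#'   an igraph graph.
#' @param path Output `.graphml` file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(S, path) {
  g <- if (igraph::is_igraph(S)) S else mutual_positive_graph(S)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a simulation result to a directory
#'
#' Writes `trajectory.csv`, the final reputation matrix (`matrix.csv`), the
#' final signed edge list (`edges.csv`), the mutual-positive network
#' (`network.graphml`) and a JSON echo of the configuration
#' (`config.json`).
#'
#' @param result A `sim_result` from [run_simulation()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(result, dir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$trajectory, file.path(dir, "trajectory.csv"),
            row.names = FALSE)
  write_reputation_csv(result$S, file.path(dir, "matrix.csv"))
  write_edge_list(result$S, file.path(dir, "edges.csv"))
  write_graphml(result$S, file.path(dir, "network.graphml"))
  cfg <- result$config
  cfg$composition <- as.list(cfg$composition)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
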