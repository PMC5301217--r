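#' Weighted functional-connectivity graph
#'
#' Constructs a weighted, undirected graph over labelled nodes (typically
#' EEG channels). Edge weights are correlation-valued: symmetric, zero on
#' the diagonal, and bounded in \[-1, 1\]. The graph carries its sign
#' regime: `"signed"` weights keep the sign of the correlation (used for
#' energy analysis, where the sign encodes agreement between instantaneous
#' amplitudes and long-epoch connectivity), `"absolute"` weights are
#' magnitudes (used for modular weight statistics).
#'
#' @param weights numeric square matrix of edge weights. Row/column names,
#'   if present, are used as node labels unless `node_labels` is given.
#' @param node_labels character vector of node names, one per row of
#'   `weights`.
#' @param weight_mode `"signed"` or `"absolute"`.
#' @return an object of class `weighted_graph` with elements `labels`,
#'   `weights` and `weight_mode`.
#' @examples
#' w <- matrix(c(0, .5, .5, 0), 2, 2)
#' g <- weighted_graph(w, c("Fz", "Oz"), "signed")
#' @export
weighted_graph <- function(weights,
                           node_labels = rownames(weights),
                           weight_mode = c("signed", "absolute")) {
  weight_mode <- match.arg(weight_mode)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("weights must be a square matrix, got ", nrow(weights), " x ",
         ncol(weights))
  if (is.null(node_labels))
    node_labels <- paste0("n", seq_len(nrow(weights)))
  node_labels <- as.character(node_labels)
  if (length(node_labels) != nrow(weights))
    stop("node_labels length (", length(node_labels),
         ") must equal matrix dimension (", nrow(weights), ")")
  if (anyDuplicated(node_labels))
    stop("node labels must be unique")
  if (any(!is.finite(weights)))
    stop("weights must be finite")
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2   # remove representational asymmetry
  if (any(abs(diag(weights)) > 1e-12))
    stop("diagonal weights must be zero")
  diag(weights) <- 0
  if (max(abs(weights)) > 1 + 1e-9)
    stop("weights must lie in [-1, 1] (correlation-valued)")
  weights[weights > 1] <- 1
  weights[weights < -1] <- -1
  if (weight_mode == "absolute" && any(weights < 0))
    stop("absolute-mode graph has negative weights")
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(labels = node_labels, weights = weights,
                 weight_mode = weight_mode),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("<weighted_graph> ", length(x$labels), " nodes, ",
      sum(x$weights[upper.tri(x$weights)] != 0), " non-zero edges, ",
      x$weight_mode, " weights\n", sep = "")
  invisible(x)
}

n_nodes <- function(graph) length(graph$labels)

#' Module partition of graph nodes
#'
#' Assigns disjoint subsets of node labels to named modules (scalp regions
#' such as frontal or occipital electrode groups). Nodes may be left
#' unassigned; partitions are user-supplied on physiological grounds, never
#' inferred from the data.
#'
#' @param assignments named list; each element a character vector of node
#'   labels for one module.
#' @return object of class `module_partition`.
#' @examples
#' module_partition(list(front = c("F3", "Fz"), back = c("O1", "O2")))
#' @export
module_partition <- function(assignments) {
  if (!is.list(assignments))
    stop("assignments must be a named list of label vectors")
  if (length(assignments) &&
      (is.null(names(assignments)) || any(!nzchar(names(assignments)))))
    stop("assignments must be a fully named list of label vectors")
  if (anyDuplicated(names(assignments)))
    stop("module names must be unique")
  assignments <- lapply(assignments, as.character)
  if (any(lengths(assignments) == 0))
    stop("each module must be non-empty")
  all_labels <- unlist(assignments, use.names = FALSE)
  if (anyDuplicated(all_labels))
    stop("module node sets must be pairwise disjoint; duplicated: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  structure(list(assignments = assignments), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", length(x$assignments), " modules: ",
      paste(sprintf("%s(%d)", names(x$assignments), lengths(x$assignments)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

module_names <- function(partition) names(partition$assignments)

# Logical mask of a module's nodes over the graph's label order; errors on
# unknown module or labels absent from the graph.
module_mask <- function(graph, partition, module) {
  if (!module %in% names(partition$assignments))
    stop("unknown module: ", module)
  labs <- partition$assignments[[module]]
  missing <- setdiff(labs, graph$labels)
  if (length(missing))
    stop("module '", module, "' names nodes absent from the graph: ",
         paste(missing, collapse = ", "))
  graph$labels %in% labs
}

#' Time-indexed graph signal
#'
#' A multichannel signal aligned to a graph's node labels: one row per node,
#' one column per time sample, with the sampling rate and the time of the
#' first sample relative to stimulus onset.
#'
#' @param samples numeric matrix, nodes x time (microvolts). Row names, if
#'   present, are used as node labels unless `node_labels` is given.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param t0 time of the first column in seconds relative to stimulus onset.
#' @param node_labels character vector of node names.
#' @return object of class `graph_signal_series`.
#' @export
graph_signal_series <- function(samples, sampling_rate, t0 = 0,
                                node_labels = rownames(samples)) {
  samples <- as.matrix(samples)
  if (is.null(node_labels))
    stop("node labels required (rownames or node_labels=)")
  node_labels <- as.character(node_labels)
  if (length(node_labels) != nrow(samples))
    stop("node_labels length must equal row count")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  if (any(!is.finite(samples)))
    stop("samples must be finite")
  rownames(samples) <- node_labels
  structure(list(labels = node_labels, samples = samples,
                 sampling_rate = sampling_rate, t0 = t0),
            class = "graph_signal_series")
}

#' @export
print.graph_signal_series <- function(x, ...) {
  cat("<graph_signal_series> ", nrow(x$samples), " nodes x ",
      ncol(x$samples), " samples @ ", x$sampling_rate, " Hz, t0 = ",
      x$t0 * 1000, " ms\n", sep = "")
  invisible(x)
}

# sample times in seconds relative to stimulus onset (0-based columns)
series_times <- function(series)
  series$t0 + (seq_len(ncol(series$samples)) - 1) / series$sampling_rate

#' Write / read a labelled dense weight matrix as TSV
#'
#' Round-trips a graph's weight matrix through a plain-text table with a
#' header row and a leading label column.
#'
#' @param graph a `weighted_graph`.
#' @param path file path.
#' @rdname graph_tsv
#' @export
write_graph_tsv <- function(graph, path) {
  df <- data.frame(label = graph$labels, graph$weights,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param weight_mode sign regime of the stored weights.
#' @rdname graph_tsv
#' @export
read_graph_tsv <- function(path, weight_mode = c("signed", "absolute")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(df[[1]])
  w <- as.matrix(df[, -1, drop = FALSE])
  weighted_graph(w, labs, match.arg(weight_mode))
}
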