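#' Dirichlet energy of a graph signal
#'
#' The Dirichlet energy of node amplitudes `f` over a weighted graph is the
#' sum over unordered node pairs \{i, j\} of `w_ij * (f_i - f_j)^2`, each
#' edge counted once. It is an inverse smoothness measure: large when
#' strongly connected nodes carry dissimilar amplitudes. With signed
#' correlation weights the energy can be negative; a large negative value
#' indicates instantaneous amplitudes in agreement with the long-epoch
#' connectivity (anticorrelated channels far apart, correlated channels
#' close together).
#'
#' @param graph a [weighted_graph()].
#' @param amplitudes numeric vector of node amplitudes, one per node. If
#'   named, it is matched to the graph's labels.
#' @return scalar energy.
#' @examples
#' g <- weighted_graph(matrix(c(0, -1, -1, 0), 2), c("a", "b"))
#' dirichlet_energy(g, c(1, -1))  # -1 * (1 - (-1))^2 = -4
#' @export
dirichlet_energy <- function(graph, amplitudes) {
  f <- conform_amplitudes(graph, amplitudes)
  d <- outer(f, f, "-")
  sum(graph$weights * d * d) / 2
}

# validate/reorder an amplitude vector against the graph's node order
conform_amplitudes <- function(graph, amplitudes) {
  f <- amplitudes
  if (!is.null(names(f))) {
    if (!setequal(names(f), graph$labels))
      stop("amplitude names do not match graph labels")
    f <- f[graph$labels]
  }
  if (length(f) != n_nodes(graph))
    stop("amplitude vector has length ", length(f),
         " but graph has ", n_nodes(graph), " nodes")
  if (any(!is.finite(f)))
    stop("amplitudes must be finite")
  as.numeric(f)
}

#' Node gradient
#'
#' Local smoothness measure at one node: the sum over all other nodes j of
#' `w_ij * (f_i - f_j)^2`, i.e. the energy carried by the node's incident
#' edges. Summed over all nodes it double-counts every edge, so the total
#' equals twice the Dirichlet energy.
#'
#' @inheritParams dirichlet_energy
#' @param node a node label.
#' @return scalar gradient at `node`.
#' @export
node_gradient <- function(graph, amplitudes, node) {
  f <- conform_amplitudes(graph, amplitudes)
  i <- match(node, graph$labels)
  if (is.na(i)) stop("unknown node label: ", node)
  d <- f[i] - f
  sum(graph$weights[i, ] * d * d)
}

#' Time-averaged node-gradient profile
#'
#' Mean over time samples of the per-node gradient, used to screen
#' electrodes when composing modules (outlier channels show gradients far
#' from the rest of the array).
#'
#' @param series a [graph_signal_series()] sharing the graph's labels.
#' @param graph a [weighted_graph()].
#' @return data.frame with columns `node`, `gradient`.
#' @export
node_gradient_profile <- function(series, graph) {
  if (!setequal(series$labels, graph$labels))
    stop("series and graph node labels differ")
  x <- series$samples[graph$labels, , drop = FALSE]
  ns <- ncol(x)
  if (ns == 0) stop("empty sample range")
  acc <- numeric(n_nodes(graph))
  for (tt in seq_len(ns)) {
    f <- x[, tt]
    d <- outer(f, f, "-")
    acc <- acc + rowSums(graph$weights * d * d)
  }
  data.frame(node = graph$labels, gradient = acc / ns,
             stringsAsFactors = FALSE)
}

#' Total modular weight
#'
#' Sum of absolute edge weights over all edges adjacent to a module — edges
#' with at least one endpoint inside it — each edge counted once. A module
#' is taken with all its adjacent edges, so this measures how strongly the
#' module's activity is coupled both internally and to the rest of the
#' network; the modulus is used because only correlation strength matters
#' here. This is the level-1 statistic of the two-level analysis. Note the
#' convention differs from [mde()], which restricts to within-module edges.
#'
#' @inheritParams dirichlet_energy
#' @param partition a [module_partition()].
#' @param module module name.
#' @return non-negative scalar.
#' @export
total_modular_weight <- function(graph, partition, module) {
  m <- module_mask(graph, partition, module)
  a <- abs(graph$weights)
  sum(a[m, m]) / 2 + sum(a[m, !m, drop = FALSE])
}

#' Modular Dirichlet Energy (MDE)
#'
#' Dirichlet-energy components restricted to edges with both endpoints in
#' one module; equivalently the Dirichlet energy of the module-induced
#' subgraph. Cross-module components are deliberately excluded — they are
#' measured by [bmde()] — so that the decomposition of the total energy
#' into modular parts is disjoint.
#'
#' @inheritParams total_modular_weight
#' @return scalar energy.
#' @export
mde <- function(graph, amplitudes, partition, module) {
  f <- conform_amplitudes(graph, amplitudes)
  m <- module_mask(graph, partition, module)
  fm <- f[m]
  d <- outer(fm, fm, "-")
  sum(graph$weights[m, m] * d * d) / 2
}

#' Between-Module Dirichlet Energy (BMDE)
#'
#' Energy components on edges joining two disjoint modules (one endpoint in
#' each); probes the interaction between the module pair specifically. Zero
#' when no edges connect the modules; symmetric in its module arguments.
#'
#' @inheritParams total_modular_weight
#' @param moduleA,moduleB distinct module names.
#' @return scalar energy.
#' @export
bmde <- function(graph, amplitudes, partition, moduleA, moduleB) {
  if (identical(moduleA, moduleB))
    stop("bmde requires two distinct modules, got '", moduleA, "' twice")
  f <- conform_amplitudes(graph, amplitudes)
  a <- module_mask(graph, partition, moduleA)
  b <- module_mask(graph, partition, moduleB)
  d <- outer(f[a], f[b], "-")
  sum(graph$weights[a, b, drop = FALSE] * d * d)
}

#' Full energy decomposition over a partition
#'
#' Splits the total Dirichlet energy into per-module MDE, per-pair BMDE,
#' and a residual carried by edges touching unassigned nodes. The pieces
#' sum back to the total exactly (to numerical tolerance), because every
#' unordered node pair falls in exactly one of the three classes.
#'
#' @inheritParams total_modular_weight
#' @return object of class `energy_decomposition`: list with `total`,
#'   `within` (named numeric per module), `between` (named numeric per
#'   module pair, names `"A:B"`), `residual`.
#' @export
decompose_energy <- function(graph, amplitudes, partition) {
  f <- conform_amplitudes(graph, amplitudes)
  total <- dirichlet_energy(graph, f)
  mods <- module_names(partition)
  within <- vapply(mods, function(m) mde(graph, f, partition, m),
                   numeric(1))
  between <- numeric(0)
  if (length(mods) >= 2) {
    prs <- utils::combn(mods, 2)
    between <- apply(prs, 2, function(p)
      bmde(graph, f, partition, p[1], p[2]))
    names(between) <- apply(prs, 2, paste, collapse = ":")
  }
  assigned <- graph$labels %in% unlist(partition$assignments,
                                       use.names = FALSE)
  u <- !assigned
  d <- outer(f, f, "-")
  comp <- graph$weights * d * d
  residual <- sum(comp[u, u]) / 2 + sum(comp[assigned, u, drop = FALSE])
  structure(list(total = total, within = within, between = between,
                 residual = residual),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat("<energy_decomposition> total =", format(x$total), "\n")
  if (length(x$within))
    cat("  within: ", paste(sprintf("%s=%.4g", names(x$within), x$within),
                            collapse = ", "), "\n", sep = "")
  if (length(x$between))
    cat("  between:", paste(sprintf("%s=%.4g", names(x$between), x$between),
                            collapse = ", "), "\n")
  cat("  residual =", format(x$residual), "\n")
  invisible(x)
}

#' Windowed modular energies over a signal series
#'
#' Tiles the series with non-overlapping windows of `window_ms` and, for
#' each requested target (a module name for MDE, a pair of module names for
#' BMDE), sums the per-sample energy over the samples of each window.
#' Trailing samples that do not fill a complete window are dropped.
#'
#' @param series a [graph_signal_series()].
#' @param graph a [weighted_graph()] sharing the series' labels.
#' @param partition a [module_partition()].
#' @param window_ms window length in milliseconds; must convert to an
#'   integer number (>= 1) of samples at the series' sampling rate.
#' @param targets list whose elements are either a single module name
#'   (MDE) or a character vector of two module names (BMDE).
#' @return object of class `energy_trace`: list with `window_starts`
#'   (0-based first sample index of each window), `window_len` (samples),
#'   `sampling_rate`, `t0`, and `values`, a targets x windows matrix with
#'   target labels (`"mod"` or `"modA:modB"`) as row names.
#' @export
windowed_energy <- function(series, graph, partition, window_ms, targets) {
  if (!setequal(series$labels, graph$labels))
    stop("series and graph node labels differ")
  wlen_exact <- window_ms / 1000 * series$sampling_rate
  wlen <- round(wlen_exact)
  if (wlen < 1 || abs(wlen_exact - wlen) > 1e-8)
    stop("window of ", window_ms, " ms is not a whole number of samples (>= 1) at ",
         series$sampling_rate, " Hz")
  ns <- ncol(series$samples)
  if (wlen > ns)
    stop("window (", wlen, " samples) longer than series (", ns, " samples)")
  nw <- ns %/% wlen
  if (!is.list(targets)) targets <- as.list(targets)
  labels <- vapply(targets, function(tg) {
    if (length(tg) == 1) as.character(tg)
    else if (length(tg) == 2) paste(tg, collapse = ":")
    else stop("each target must be one module or a pair of modules")
  }, character(1))
  x <- series$samples[graph$labels, , drop = FALSE]
  # per-sample energies for all targets, then aggregate into windows
  per_sample <- matrix(0, length(targets), ns)
  for (tt in seq_len(ns)) {
    f <- x[, tt]
    per_sample[, tt] <- vapply(targets, function(tg) {
      if (length(tg) == 1) mde(graph, f, partition, tg)
      else bmde(graph, f, partition, tg[1], tg[2])
    }, numeric(1))
  }
  vals <- matrix(0, length(targets), nw,
                 dimnames = list(labels, NULL))
  starts <- (seq_len(nw) - 1) * wlen
  for (k in seq_len(nw))
    vals[, k] <- rowSums(per_sample[, starts[k] + seq_len(wlen),
                                    drop = FALSE])
  structure(list(window_starts = starts, window_len = wlen,
                 sampling_rate = series$sampling_rate, t0 = series$t0,
                 values = vals),
            class = "energy_trace")
}

#' @export
print.energy_trace <- function(x, ...) {
  cat("<energy_trace> ", nrow(x$values), " target(s) x ",
      ncol(x$values), " windows of ", x$window_len, " samples (",
      x$window_len / x$sampling_rate * 1000, " ms)\n", sep = "")
  invisible(x)
}

#' Tidy view of an energy trace
#'
#' @param x an `energy_trace`.
#' @param ... unused.
#' @return data.frame with columns `target`, `window`, `window_start_ms`,
#'   `window_end_ms`, `value`. Times are stimulus-relative.
#' @export
as.data.frame.energy_trace <- function(x, ...) {
  nw <- ncol(x$values)
  start_ms <- (x$t0 + x$window_starts / x$sampling_rate) * 1000
  end_ms <- start_ms + x$window_len / x$sampling_rate * 1000
  data.frame(
    target = rep(rownames(x$values), times = nw),
    window = rep(seq_len(nw), each = nrow(x$values)),
    window_start_ms = rep(start_ms, each = nrow(x$values)),
    window_end_ms = rep(end_ms, each = nrow(x$values)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE)
}

#' Export an energy trace as tidy TSV
#'
#' @param trace an `energy_trace`.
#' @param path file path.
#' @export
write_energy_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
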