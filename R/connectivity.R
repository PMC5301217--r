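#' Connectivity specification
#'
#' Fixes how a functional-connectivity graph is built from a period's
#' signals: Pearson correlation of the pairwise channel time courses
#' (amplitude-sensitive, unlike phase-based measures), under a declared
#' sign regime.
#'
#' @param period period label carried through to outputs.
#' @param weight_mode `"signed"` or `"absolute"`.
#' @return object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(period = "encoding",
                              weight_mode = c("signed", "absolute")) {
  structure(list(measure = "pearson", period = period,
                 weight_mode = match.arg(weight_mode)),
            class = "connectivity_spec")
}

#' Correlation graph of a signal series
#'
#' Builds a fully weighted functional-connectivity graph: the weight of
#' edge \{i, j\} is the Pearson correlation of channels i and j over the
#' series' samples (absolute value under the `"absolute"` regime), with a
#' zero diagonal. No thresholding or sparsification is applied. Channels
#' with zero variance get weight 0 on all incident edges, with a warning,
#' rather than aborting the subject.
#'
#' @param series a [graph_signal_series()] with >= 3 samples and >= 2
#'   channels.
#' @param spec a [connectivity_spec()], or a weight-mode string.
#' @return a [weighted_graph()].
#' @export
correlation_graph <- function(series, spec = connectivity_spec()) {
  if (is.character(spec)) spec <- connectivity_spec(weight_mode = spec)
  x <- t(series$samples)               # samples x channels
  if (ncol(x) < 2) stop("need >= 2 channels")
  if (nrow(x) < 3)
    stop("need >= 3 time samples for a stable correlation, got ", nrow(x))
  sds <- apply(x, 2, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(flat)) {
    warning("zero-variance channel(s): ",
            paste(colnames(x)[flat], collapse = ", "),
            "; incident edge weights set to 0")
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 0
  if (spec$weight_mode == "absolute") r <- abs(r)
  weighted_graph(r, series$labels, spec$weight_mode)
}

#' Period graphs in both sign regimes
#'
#' Extracts each requested period from an ERP, zero-centres the channel
#' space, and returns the signed and absolute correlation graphs from a
#' single correlation computation (the absolute graph is the elementwise
#' modulus of the signed one), guaranteeing that the level-1 weight
#' statistics and level-2 energies see consistent connectivity. The
#' centred period series is returned alongside for graph-signal use.
#'
#' @param erp a `subject_condition_erp`.
#' @param periods named list of period bounds in ms (or period names).
#' @return named list (per period) of lists with elements `signed`,
#'   `absolute` (both [weighted_graph()]) and `series` (the centred
#'   [graph_signal_series()]).
#' @export
build_period_graphs <- function(erp, periods = period_bounds_default) {
  out <- lapply(names(periods), function(pname) {
    ser <- extract_period(erp, periods[[pname]])
    ser <- channel_space_center(ser)
    signed <- correlation_graph(ser, connectivity_spec(pname, "signed"))
    absolute <- weighted_graph(abs(signed$weights), signed$labels,
                               "absolute")
    list(signed = signed, absolute = absolute, series = ser)
  })
  names(out) <- names(periods)
  out
}
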