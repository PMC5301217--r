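#' Single-trial multichannel epoch
#'
#' One stimulus-locked trial: a channels x time matrix in microvolts with
#' its sampling rate, the time of the first sample relative to stimulus
#' onset, and bookkeeping fields (subject, condition, trial index, whether
#' the behavioural response was correct).
#'
#' @param samples numeric matrix, channels x time (microvolts), with
#'   channel labels as row names (or via `channels`).
#' @param sampling_rate Hz.
#' @param t0 seconds relative to stimulus onset (-0.2 for a 200 ms
#'   pre-stimulus baseline).
#' @param subject subject identifier.
#' @param condition condition label.
#' @param trial trial index within subject x condition.
#' @param correct logical; was the behavioural response correct.
#' @param channels channel labels.
#' @return object of class `trial_epoch`.
#' @export
trial_epoch <- function(samples, sampling_rate, t0 = -0.2,
                        subject = NA_character_, condition = NA_character_,
                        trial = NA_integer_, correct = TRUE,
                        channels = rownames(samples)) {
  samples <- as.matrix(samples)
  if (is.null(channels))
    stop("channel labels required (rownames or channels=)")
  if (length(channels) != nrow(samples))
    stop("channels length must equal row count")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (any(!is.finite(samples)))
    stop("samples must be finite")
  rownames(samples) <- as.character(channels)
  structure(list(samples = samples, sampling_rate = sampling_rate, t0 = t0,
                 subject = as.character(subject),
                 condition = as.character(condition),
                 trial = as.integer(trial), correct = isTRUE(correct)),
            class = "trial_epoch")
}

#' @export
print.trial_epoch <- function(x, ...) {
  cat("<trial_epoch> subj ", x$subject, ", cond ", x$condition, ", trial ",
      x$trial, ": ", nrow(x$samples), " ch x ", ncol(x$samples),
      " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

# subtract the across-channel mean from every channel, per time sample
center_channel_space <- function(x) {
  sweep(x, 2, colMeans(x))
}

#' Average re-reference
#'
#' Re-references every channel to the instantaneous average over channels:
#' for each time sample the channel mean is subtracted from all channels,
#' so every output column sums to zero. Idempotent.
#'
#' @param epoch a [trial_epoch()] (or any object with a channels x time
#'   `samples` matrix).
#' @return the epoch with re-referenced samples.
#' @export
average_rereference <- function(epoch) {
  x <- epoch$samples
  if (nrow(x) < 2)
    stop("average re-reference needs >= 2 channels")
  epoch$samples <- center_channel_space(x)
  epoch
}

#' Artifact-based trial rejection
#'
#' Screens trials against amplitude-artifact rules and drops incorrect
#' responses. A trial is rejected, with the first matching reason, when:
#' the behavioural response was incorrect (`"incorrect"`); any channel's
#' peak-to-peak range exceeds `fluct_max` (`"fluctuation"`); any channel's
#' largest absolute sample-to-sample step exceeds `transient_max`
#' (`"transient"`); or any designated electro-oculogram channel's
#' peak-to-peak range exceeds `eog_max` (`"eog"`).
#'
#' @param trials list of [trial_epoch()].
#' @param fluct_max peak-to-peak voltage-fluctuation limit, microvolts.
#' @param transient_max sample-to-sample transient limit, microvolts.
#' @param eog_max EOG peak-to-peak limit, microvolts.
#' @param eog_channels labels of EOG channels (screened only if present).
#' @return list with `kept` (surviving trials) and `log` (data.frame
#'   subject, condition, trial, reason — one row per rejection). Errors if
#'   no trial survives, flagging the subject x condition as unusable.
#' @export
reject_trials <- function(trials, fluct_max = 200, transient_max = 100,
                          eog_max = 70, eog_channels = character()) {
  stopifnot(fluct_max > 0, transient_max > 0, eog_max > 0)
  row_p2p <- function(x) {
    # C-level row max/min; much faster than apply(x, 1, range)
    hi <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
    lo <- x[cbind(seq_len(nrow(x)), max.col(-x, ties.method = "first"))]
    stats::setNames(hi - lo, rownames(x))
  }
  reasons <- vapply(trials, function(tr) {
    x <- tr$samples
    if (!tr$correct) return("incorrect")
    p2p <- row_p2p(x)
    if (any(p2p > fluct_max)) return("fluctuation")
    if (ncol(x) > 1 &&
        max(abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE])) >
        transient_max)
      return("transient")
    eog <- intersect(eog_channels, rownames(x))
    if (length(eog) &&
        any(p2p[eog] > eog_max)) return("eog")
    ""
  }, character(1))
  rejected <- reasons != ""
  log <- data.frame(
    subject = vapply(trials[rejected], `[[`, character(1), "subject"),
    condition = vapply(trials[rejected], `[[`, character(1), "condition"),
    trial = vapply(trials[rejected], `[[`, integer(1), "trial"),
    reason = reasons[rejected],
    stringsAsFactors = FALSE)
  kept <- trials[!rejected]
  if (!length(kept))
    stop("no trials survive artifact rejection; subject x condition unusable")
  list(kept = kept, log = log)
}

#' Noisy-channel detection
#'
#' Flags channels whose mean absolute amplitude across the kept trials
#' exceeds a limit. Two modes: `"absolute"` flags channels above
#' `amp_threshold` microvolts (default 30); `"sd"` flags channels more than
#' 2 standard deviations above the mean amplitude of the rest of the
#' array (leave-one-out, so a single loud channel cannot mask itself).
#'
#' @param trials list of [trial_epoch()] sharing a channel set.
#' @param amp_threshold microvolts (absolute mode).
#' @param method `"absolute"` or `"sd"`.
#' @return character vector of channel labels to drop (possibly empty);
#'   errors if every channel is flagged.
#' @export
reject_channels <- function(trials, amp_threshold = 30,
                            method = c("absolute", "sd")) {
  method <- match.arg(method)
  stopifnot(amp_threshold > 0)
  amp <- Reduce(`+`, lapply(trials, function(tr) rowMeans(abs(tr$samples)))) /
    length(trials)
  flagged <- if (method == "absolute") {
    amp > amp_threshold
  } else {
    vapply(seq_along(amp), function(i)
      amp[i] > mean(amp[-i]) + 2 * stats::sd(amp[-i]), logical(1))
  }
  if (all(flagged))
    stop("all channels flagged as noisy")
  names(amp)[flagged]
}

#' Drop channels from every trial
#'
#' @param trials list of [trial_epoch()].
#' @param channels labels to remove.
#' @return trials with the channels removed.
#' @export
drop_channels <- function(trials, channels) {
  if (!length(channels)) return(trials)
  lapply(trials, function(tr) {
    keep <- !(rownames(tr$samples) %in% channels)
    if (!any(keep)) stop("dropping all channels")
    tr$samples <- tr$samples[keep, , drop = FALSE]
    tr
  })
}

#' Trial-averaged ERP
#'
#' Sample-wise mean over the (artifact-screened, correct) trials of one
#' subject x condition, yielding the event-related potential on which
#' graphs and energies are computed.
#'
#' @param trials non-empty list of [trial_epoch()] with identical channel
#'   sets and timing.
#' @param rejected_channels labels removed upstream, recorded for audit.
#' @return object of class `subject_condition_erp`: samples (channels x
#'   time), sampling_rate, t0, subject, condition, n_trials_used,
#'   rejected_channels.
#' @export
average_erp <- function(trials, rejected_channels = character()) {
  if (!length(trials)) stop("average_erp needs >= 1 trial")
  ref <- trials[[1]]
  acc <- Reduce(`+`, lapply(trials, `[[`, "samples"))
  structure(list(samples = acc / length(trials),
                 sampling_rate = ref$sampling_rate, t0 = ref$t0,
                 subject = ref$subject, condition = ref$condition,
                 n_trials_used = length(trials),
                 rejected_channels = rejected_channels),
            class = "subject_condition_erp")
}

#' @export
print.subject_condition_erp <- function(x, ...) {
  cat("<subject_condition_erp> subj ", x$subject, ", cond ", x$condition,
      ": ", nrow(x$samples), " ch x ", ncol(x$samples), " samples, mean of ",
      x$n_trials_used, " trials\n", sep = "")
  invisible(x)
}

#' Zero-centre the channel space
#'
#' Subtracts the across-channel mean at every time sample, so the node
#' amplitudes fed to energy computations are zero-averaged over the scalp.
#' Identical transform to [average_rereference()]; kept as a separately
#' named step because it is applied at the graph-signal stage of the
#' pipeline, after ERP averaging.
#'
#' @param x a `subject_condition_erp` or [graph_signal_series()].
#' @return the object with centred samples.
#' @export
channel_space_center <- function(x) {
  if (nrow(x$samples) < 2)
    stop("channel-space centering needs >= 2 channels")
  x$samples <- center_channel_space(x$samples)
  x
}

band_edges_default <- list(broadband = c(0.01, 40), theta = c(4, 8),
                           alpha = c(8, 13), beta = c(13, 30))

#' Zero-phase band-pass filter
#'
#' Filters every channel with a zero-phase (two-pass, forward-backward)
#' Butterworth band-pass. The broadband setting (0.01–40 Hz) is realised
#' as a cascade of a second-order high-pass and an `order`-th order
#' low-pass, which is numerically better behaved than a direct band-pass
#' with a near-zero lower edge; the narrow bands use a single band-pass.
#' Filter settings are recorded in the result's `filter` field.
#'
#' @param erp a `subject_condition_erp` (or any object with `samples` and
#'   `sampling_rate`).
#' @param band one of `"broadband"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param edges optional numeric length-2 override of the band edges (Hz).
#' @param order Butterworth order for the band-pass / low-pass stage.
#' @return the input with filtered samples and a `filter` metadata list.
#' @export
band_filter <- function(erp, band = c("broadband", "theta", "alpha", "beta"),
                        edges = NULL, order = 4) {
  band <- match.arg(band)
  if (is.null(edges)) edges <- band_edges_default[[band]]
  stopifnot(length(edges) == 2, edges[1] < edges[2])
  nyq <- erp$sampling_rate / 2
  if (edges[2] >= nyq)
    stop("upper band edge (", edges[2], " Hz) must be below Nyquist (",
         nyq, " Hz)")
  x <- erp$samples
  filt_rows <- function(x, flt) t(apply(x, 1, function(r)
    signal::filtfilt(flt, r)))
  if (band == "broadband") {
    hp <- signal::butter(2, edges[1] / nyq, type = "high")
    lp <- signal::butter(order, edges[2] / nyq, type = "low")
    y <- filt_rows(filt_rows(x, hp), lp)
  } else {
    bp <- signal::butter(order, edges / nyq, type = "pass")
    y <- filt_rows(x, bp)
  }
  dimnames(y) <- dimnames(x)
  erp$samples <- y
  erp$filter <- list(band = band, edges_hz = edges, order = order,
                     type = "butterworth zero-phase (filtfilt)")
  erp
}

period_bounds_default <- list(encoding = c(0, 200), maintenance = c(200, 1000))

#' Extract a task period as a graph signal
#'
#' Selects the samples of a stimulus-relative half-open interval
#' \[start, end) from an ERP. The default periods are encoding (0–200 ms)
#' and maintenance (200–1000 ms); at 250 Hz these hold 50 and 200 samples
#' and share no sample.
#'
#' @param erp a `subject_condition_erp`.
#' @param period `"encoding"`, `"maintenance"`, or a numeric length-2
#'   interval in milliseconds.
#' @return a [graph_signal_series()] whose `t0` is the interval start.
#' @export
extract_period <- function(erp, period = "encoding") {
  bounds <- if (is.character(period)) {
    if (!period %in% names(period_bounds_default))
      stop("unknown period: ", period)
    period_bounds_default[[period]]
  } else {
    stopifnot(is.numeric(period), length(period) == 2)
    period
  }
  rate <- erp$sampling_rate
  ns <- ncol(erp$samples)
  # 0-based index of the first sample at/after each bound
  i0 <- (bounds[1] / 1000 - erp$t0) * rate
  i1 <- (bounds[2] / 1000 - erp$t0) * rate
  i0 <- round(i0); i1 <- round(i1)
  if (i0 < 0 || i1 > ns || i1 <= i0)
    stop("period [", bounds[1], ", ", bounds[2],
         ") ms lies outside the epoch")
  graph_signal_series(erp$samples[, (i0 + 1):i1, drop = FALSE],
                      sampling_rate = rate, t0 = bounds[1] / 1000,
                      node_labels = rownames(erp$samples))
}
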