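#' Write a trial dataset as a directory of TSV matrices plus a manifest
#'
#' Each trial becomes one TSV file (first column `channel`, remaining
#' columns the time samples) and `manifest.tsv` records subject,
#' condition, trial index, correctness, sampling rate, epoch start and
#' file name.
#'
#' @param dataset a `trial_dataset` (or list with `trials`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- dataset$trials
  man <- data.frame(
    subject = vapply(trials, `[[`, character(1), "subject"),
    condition = vapply(trials, `[[`, character(1), "condition"),
    trial = vapply(trials, `[[`, integer(1), "trial"),
    correct = vapply(trials, `[[`, logical(1), "correct"),
    sampling_rate = vapply(trials, `[[`, numeric(1), "sampling_rate"),
    t0 = vapply(trials, `[[`, numeric(1), "t0"),
    file = sprintf("trial_%05d.tsv", seq_along(trials)),
    stringsAsFactors = FALSE)
  for (i in seq_along(trials)) {
    df <- data.frame(channel = rownames(trials[[i]]$samples),
                     trials[[i]]$samples, check.names = FALSE)
    utils::write.table(df, file.path(dir, man$file[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a trial dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.tsv` and per-trial TSVs.
#' @return a `trial_dataset` (without a generating config).
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("no manifest.tsv under ", dir)
  man <- utils::read.table(man_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(man)), function(i) {
    df <- utils::read.table(file.path(dir, man$file[i]), sep = "\t",
                            header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    x <- as.matrix(df[, -1, drop = FALSE])
    dimnames(x) <- list(as.character(df[[1]]), NULL)
    trial_epoch(x, man$sampling_rate[i], t0 = man$t0[i],
                subject = man$subject[i], condition = man$condition[i],
                trial = man$trial[i], correct = man$correct[i])
  })
  structure(list(trials = trials, config = NULL), class = "trial_dataset")
}

#' Read / write a study configuration file
#'
#' One structured-text (YAML) file covering the montage, module
#' membership, contrasts, periods, window length, FDR level, band and
#' artifact thresholds. Fields absent from the file fall back to the
#' package defaults.
#'
#' @param path file path.
#' @rdname study_config
#' @return `read_study_config()`: list with `design` (a [study_design()])
#'   and `thresholds` (list of artifact limits).
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modules <- if (!is.null(cfg$modules))
    module_partition(lapply(cfg$modules, as.character))
  else default_modules()
  contrasts <- if (!is.null(cfg$contrasts))
    lapply(cfg$contrasts, as.character)
  else list(L = c("Shape.L", "Bind.L"), R = c("Shape.R", "Bind.R"))
  periods <- if (!is.null(cfg$periods))
    lapply(cfg$periods, as.numeric)
  else period_bounds_default
  design <- study_design(
    contrasts = contrasts, modules = modules, periods = periods,
    window_ms = cfg$window_ms %||% 20,
    q = cfg$q %||% 0.05,
    band = cfg$band %||% "none")
  thresholds <- list(
    fluct_max = cfg$fluct_max %||% 200,
    transient_max = cfg$transient_max %||% 100,
    eog_max = cfg$eog_max %||% 70,
    eog_channels = as.character(cfg$eog_channels %||% character(0)),
    channel_amp_threshold = cfg$channel_amp_threshold %||% 30)
  list(design = design, thresholds = thresholds, montage = cfg$montage)
}

#' @param design a [study_design()].
#' @param thresholds optional list of artifact limits.
#' @param montage optional channel-label vector.
#' @rdname study_config
#' @export
write_study_config <- function(path, design, thresholds = list(),
                               montage = NULL) {
  cfg <- list(
    montage = montage,
    modules = design$modules$assignments,
    contrasts = design$contrasts,
    periods = design$periods,
    window_ms = design$window_ms,
    q = design$q,
    band = design$band)
  cfg <- c(cfg, thresholds)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
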