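#' Study design for the two-level analysis
#'
#' Declares what the pipeline tests: which condition pairs to contrast
#' (differences are reported first-listed minus second-listed), over which
#' stimulus-relative periods and node modules, with the short-window
#' length and the FDR level.
#'
#' @param contrasts named list; each element a character vector of two
#'   condition labels, e.g. `list(L = c("Shape.L", "Bind.L"), R =
#'   c("Shape.R", "Bind.R"))` for a per-hemifield Shape-vs-Bind contrast.
#' @param modules a [module_partition()].
#' @param periods named list of ms intervals (default encoding 0-200,
#'   maintenance 200-1000).
#' @param window_ms level-2 window length in ms (default 20).
#' @param q FDR level used throughout (default 0.05).
#' @param band band-pass applied to ERPs before analysis: `"none"`
#'   (default; epochs assumed band-limited upstream by the acquisition
#'   filter), or one of [band_filter()]'s bands.
#' @return object of class `study_design`.
#' @export
study_design <- function(contrasts = list(L = c("Shape.L", "Bind.L"),
                                          R = c("Shape.R", "Bind.R")),
                         modules = default_modules(),
                         periods = period_bounds_default,
                         window_ms = 20, q = 0.05, band = "none") {
  if (!is.list(contrasts) || is.null(names(contrasts)))
    stop("contrasts must be a named list of condition pairs")
  for (p in contrasts)
    if (length(p) != 2) stop("each contrast must name exactly 2 conditions")
  stopifnot(inherits(modules, "module_partition"),
            is.list(periods), length(periods) >= 1,
            window_ms > 0, q > 0, q < 1)
  structure(list(contrasts = contrasts, modules = modules,
                 periods = periods, window_ms = window_ms, q = q,
                 band = band),
            class = "study_design")
}

# preprocess one subject x condition cell: re-reference, screen, average
preprocess_cell <- function(trials, band = "none", fluct_max = 200,
                            transient_max = 100, eog_max = 70,
                            eog_channels = character(),
                            channel_amp_threshold = 30) {
  trials <- lapply(trials, average_rereference)
  scr <- reject_trials(trials, fluct_max, transient_max, eog_max,
                       eog_channels)
  bad <- reject_channels(scr$kept, channel_amp_threshold)
  kept <- drop_channels(scr$kept, bad)
  erp <- average_erp(kept, rejected_channels = bad)
  if (!identical(band, "none")) erp <- band_filter(erp, band)
  list(erp = erp, log = scr$log)
}

#' Preprocess a trial dataset into per-subject condition ERPs
#'
#' Groups trials by subject x condition and, per cell: average
#' re-references each trial, rejects artifact/incorrect trials, flags and
#' drops noisy channels, and averages the survivors into an ERP. Cells
#' where no trial survives are dropped with a log entry.
#'
#' @param dataset a `trial_dataset` (or list with `trials`).
#' @param band optional band-pass (see [study_design()]).
#' @param fluct_max,transient_max,eog_max,eog_channels,channel_amp_threshold
#'   artifact thresholds, microvolts (see [reject_trials()],
#'   [reject_channels()]).
#' @return list with `erps` (nested list `erps[[subject]][[condition]]`),
#'   `rejection_log` (data.frame), `failed_cells` (data.frame of unusable
#'   subject x condition cells).
#' @export
preprocess_dataset <- function(dataset, band = "none", fluct_max = 200,
                               transient_max = 100, eog_max = 70,
                               eog_channels = character(),
                               channel_amp_threshold = 30) {
  trials <- dataset$trials
  key <- paste(vapply(trials, `[[`, character(1), "subject"),
               vapply(trials, `[[`, character(1), "condition"), sep = "\r")
  cells <- split(trials, key)
  erps <- list()
  logs <- list()
  failed <- list()
  for (k in names(cells)) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    res <- tryCatch(
      preprocess_cell(cells[[k]], band, fluct_max, transient_max,
                      eog_max, eog_channels, channel_amp_threshold),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1]] <-
        data.frame(subject = parts[1], condition = parts[2],
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    erps[[parts[1]]][[parts[2]]] <- res$erp
    if (nrow(res$log)) logs[[length(logs) + 1]] <- res$log
  }
  list(erps = erps,
       rejection_log = if (length(logs)) do.call(rbind, logs) else
         data.frame(subject = character(0), condition = character(0),
                    trial = integer(0), reason = character(0)),
       failed_cells = if (length(failed)) do.call(rbind, failed) else
         data.frame(subject = character(0), condition = character(0),
                    reason = character(0)))
}

# period graphs per subject x condition, memoised by the callers
compute_graphs <- function(erps, design) {
  lapply(erps, function(by_cond)
    lapply(by_cond, function(erp)
      build_period_graphs(erp, design$periods)))
}

# subjects having both conditions of a contrast (complete-case)
contrast_subjects <- function(erps, pair) {
  names(erps)[vapply(erps, function(bc) all(pair %in% names(bc)),
                     logical(1))]
}

#' Level-1 analysis: total modular weights
#'
#' For every (contrast, period, module) cell, computes the per-subject
#' total modular weight on the absolute-weight period graph for both
#' conditions of the contrast, takes the within-subject difference
#' (first-listed minus second-listed condition), and runs a paired t-test
#' across subjects, with an advisory KS normality screen. Subjects missing
#' either condition are excluded (complete-case).
#'
#' @param erps nested list `erps[[subject]][[condition]]` of
#'   `subject_condition_erp`.
#' @param design a [study_design()].
#' @param graphs optional precomputed [build_period_graphs()] results
#'   (internal memoisation).
#' @return data.frame with one row per hypothesis: `id`, `contrast`,
#'   `period`, `module`, `n`, `mean_diff`, `t`, `p`, `ks_p`, `note`;
#'   attribute `differences` holds the per-subject difference vectors,
#'   attribute `excluded` the dropped subjects per contrast.
#' @export
run_level1 <- function(erps, design, graphs = NULL) {
  if (is.null(graphs)) graphs <- compute_graphs(erps, design)
  mods <- module_names(design$modules)
  rows <- list()
  diffs <- list()
  excluded <- list()
  for (cname in names(design$contrasts)) {
    pair <- design$contrasts[[cname]]
    subs <- contrast_subjects(erps, pair)
    excluded[[cname]] <- setdiff(names(erps), subs)
    if (length(subs) < 3)
      stop("contrast ", cname, " has fewer than 3 complete subjects")
    for (pname in names(design$periods)) {
      for (m in mods) {
        d <- vapply(subs, function(s) {
          gA <- graphs[[s]][[pair[1]]][[pname]]$absolute
          gB <- graphs[[s]][[pair[2]]][[pname]]$absolute
          total_modular_weight(gA, design$modules, m) -
            total_modular_weight(gB, design$modules, m)
        }, numeric(1))
        id <- paste(m, pname, cname, sep = ".")
        tt <- tryCatch(paired_t_test(d), error = function(e) e)
        if (inherits(tt, "error")) {
          rows[[id]] <- data.frame(
            id = id, contrast = cname, period = pname, module = m,
            n = length(d), mean_diff = mean(d), t = NA_real_, p = NA_real_,
            ks_p = NA_real_, note = conditionMessage(tt),
            stringsAsFactors = FALSE)
        } else {
          ks <- ks_normality(d)
          rows[[id]] <- data.frame(
            id = id, contrast = cname, period = pname, module = m,
            n = tt$n, mean_diff = tt$mean_diff, t = tt$t, p = tt$p,
            ks_p = ks$p, note = "", stringsAsFactors = FALSE)
        }
        diffs[[id]] <- d
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "differences") <- diffs
  attr(out, "excluded") <- excluded
  out
}

#' Level-2 analysis: windowed MDE/BMDE under level-1 gating
#'
#' For each level-1 discovery (module, period, contrast), computes per
#' subject the windowed modular Dirichlet energy of that module over the
#' period, on the signed-weight graph of each condition with that
#' condition's own signals, and paired-tests the per-window
#' Shape-minus-Bind-style differences across subjects. When both modules
#' of a pair are discovered for the same period and contrast, the
#' between-module energy of the pair is tested per window as well, probing
#' the modules' interaction specifically.
#'
#' @param erps nested ERP list as in [run_level1()].
#' @param design a [study_design()].
#' @param level1_discoveries the level-1 table restricted to discoveries
#'   (rows of [run_level1()] output).
#' @param graphs optional precomputed graphs.
#' @return data.frame with one row per (target, window): `id`, `parent`,
#'   `type` ("MDE"/"BMDE"), `target`, `period`, `contrast`, `window`,
#'   `window_start_ms`, `window_end_ms`, `n`, `mean_diff`, `t`, `p`,
#'   `note`. Attribute `traces` holds the across-subject mean energy per
#'   condition and window (data.frame). Empty (zero-row) when no level-1
#'   discovery is supplied.
#' @export
run_level2 <- function(erps, design, level1_discoveries, graphs = NULL) {
  empty <- data.frame(id = character(0), parent = character(0),
                      type = character(0), target = character(0),
                      period = character(0), contrast = character(0),
                      window = integer(0), window_start_ms = numeric(0),
                      window_end_ms = numeric(0), n = integer(0),
                      mean_diff = numeric(0), t = numeric(0), p = numeric(0),
                      note = character(0), stringsAsFactors = FALSE)
  if (is.null(level1_discoveries) || nrow(level1_discoveries) == 0) {
    attr(empty, "traces") <- data.frame(target = character(0),
                                        condition = character(0),
                                        window = integer(0),
                                        value = numeric(0))
    return(empty)
  }
  if (is.null(graphs)) graphs <- compute_graphs(erps, design)
  disc <- level1_discoveries
  # targets: one MDE per discovery; one BMDE per discovered module pair
  # sharing period and contrast, parented on the smaller-p member
  targets <- lapply(seq_len(nrow(disc)), function(i)
    list(type = "MDE", modules = disc$module[i], period = disc$period[i],
         contrast = disc$contrast[i], parent = disc$id[i]))
  groups <- split(seq_len(nrow(disc)), paste(disc$period, disc$contrast))
  for (g in groups) {
    if (length(g) < 2) next
    prs <- utils::combn(g, 2)
    for (j in seq_len(ncol(prs))) {
      i1 <- prs[1, j]; i2 <- prs[2, j]
      parent <- if (disc$p[i1] <= disc$p[i2]) disc$id[i1] else disc$id[i2]
      targets[[length(targets) + 1]] <-
        list(type = "BMDE", modules = c(disc$module[i1], disc$module[i2]),
             period = disc$period[i1], contrast = disc$contrast[i1],
             parent = parent)
    }
  }
  rows <- list()
  traces <- list()
  for (tg in targets) {
    pair <- design$contrasts[[tg$contrast]]
    subs <- contrast_subjects(erps, pair)
    wtarget <- if (tg$type == "MDE") list(tg$modules) else list(tg$modules)
    per_cond <- lapply(pair, function(cond) {
      t(vapply(subs, function(s) {
        pg <- graphs[[s]][[cond]][[tg$period]]
        tr <- windowed_energy(pg$series, pg$signed, design$modules,
                              design$window_ms, wtarget)
        tr$values[1, ]
      }, numeric(win_count(design, tg$period))))
    })
    d <- per_cond[[1]] - per_cond[[2]]      # subjects x windows
    nw <- ncol(d)
    bounds <- design$periods[[tg$period]]
    label <- paste(tg$modules, collapse = ":")
    for (k in seq_len(nw)) {
      tt <- tryCatch(paired_t_test(d[, k]), error = function(e) e)
      err <- inherits(tt, "error")
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0(tg$type, ".", label, ".", tg$period, ".", tg$contrast,
                    ".w", k),
        parent = tg$parent, type = tg$type, target = label,
        period = tg$period, contrast = tg$contrast, window = k,
        window_start_ms = bounds[1] + (k - 1) * design$window_ms,
        window_end_ms = bounds[1] + k * design$window_ms,
        n = nrow(d),
        mean_diff = mean(d[, k]),
        t = if (err) NA_real_ else tt$t,
        p = if (err) NA_real_ else tt$p,
        note = if (err) conditionMessage(tt) else "",
        stringsAsFactors = FALSE)
    }
    for (ci in seq_along(pair))
      traces[[length(traces) + 1]] <- data.frame(
        target = label, period = tg$period, contrast = tg$contrast,
        condition = pair[ci], window = seq_len(nw),
        value = colMeans(per_cond[[ci]]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "traces") <- unique(do.call(rbind, traces))
  out
}

win_count <- function(design, period) {
  b <- design$periods[[period]]
  floor((b[2] - b[1]) / design$window_ms)
}

#' Run the full two-level analysis
#'
#' End-to-end pipeline: preprocess trials into per-subject condition ERPs,
#' build signed/absolute period graphs from one correlation computation,
#' test total modular weights at level 1 (absolute weights), gate with
#' Benjamini-Hochberg at level `q`, test windowed MDE/BMDE at level 2
#' (signed weights) under the discovered parents, apply the hierarchical
#' FDR over the whole tree, and assemble a report. The analysis path is
#' deterministic given its inputs.
#'
#' @param dataset a `trial_dataset` (e.g. from [generate_dataset()]) or a
#'   preprocessed list as returned by [preprocess_dataset()].
#' @param design a [study_design()].
#' @param ... preprocessing thresholds passed to [preprocess_dataset()].
#' @return object of class `analysis_report`: list with `level1`,
#'   `level2` (decision-annotated tables), `traces` (per-condition mean
#'   energy curves), `tree` (the [hypothesis_tree()] with decisions),
#'   `rejection_log`, `failed_cells`, `excluded_subjects`, `design`,
#'   `provenance`.
#' @export
run_full_analysis <- function(dataset, design = study_design(), ...) {
  pre <- if (!is.null(dataset$erps)) dataset
         else preprocess_dataset(dataset, band = design$band, ...)
  erps <- pre$erps
  graphs <- compute_graphs(erps, design)
  l1 <- run_level1(erps, design, graphs)
  testable <- !is.na(l1$p)
  gate <- rep(FALSE, nrow(l1))
  gate[testable] <- bh_stepup(l1$p[testable], design$q)
  l2 <- run_level2(erps, design, l1[gate, , drop = FALSE], graphs)
  nodes <- data.frame(id = l1$id[testable],
                      level = rep(1, sum(testable)),
                      parent = rep(NA_character_, sum(testable)),
                      label = l1$id[testable], p = l1$p[testable],
                      stringsAsFactors = FALSE)
  if (nrow(l2)) {
    ok2 <- !is.na(l2$p)
    nodes <- rbind(nodes,
                   data.frame(id = l2$id[ok2], level = 2,
                              parent = l2$parent[ok2], label = l2$id[ok2],
                              p = l2$p[ok2], stringsAsFactors = FALSE))
  }
  tree <- if (nrow(nodes)) hierarchical_fdr(hypothesis_tree(nodes, q = design$q))
          else hypothesis_tree(nodes, q = design$q)
  l1$decision <- decision_for(tree, l1$id)
  l1$decision[!testable] <- "not_tested"
  if (nrow(l2)) {
    l2$decision <- decision_for(tree, l2$id)
    l2$decision[is.na(l2$p)] <- "not_tested"
  } else {
    l2$decision <- character(0)
  }
  seed <- if (!is.null(dataset$config)) dataset$config$seed else NA_integer_
  structure(list(
    level1 = l1, level2 = l2, traces = attr(l2, "traces"), tree = tree,
    rejection_log = pre$rejection_log, failed_cells = pre$failed_cells,
    excluded_subjects = attr(l1, "excluded"), design = design,
    provenance = list(
      package = "mdenergy",
      package_version = as.character(utils::packageVersion("mdenergy")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      q = design$q, window_ms = design$window_ms, band = design$band,
      dataset_seed = seed)),
    class = "analysis_report")
}

decision_for <- function(tree, ids) {
  d <- tree$decision[match(ids, tree$id)]
  d[is.na(d)] <- "not_tested"
  d
}

#' @export
print.analysis_report <- function(x, ...) {
  n1 <- sum(x$level1$decision == "rejected")
  n2 <- if (nrow(x$level2)) sum(x$level2$decision == "rejected") else 0
  cat("<analysis_report> ", nrow(x$level1), " level-1 hypotheses (",
      n1, " discovered); ", nrow(x$level2), " level-2 tests (",
      n2, " discovered) at q = ", x$design$q, "\n", sep = "")
  if (n1 == 0)
    cat("  no level-1 discoveries: level-2 analysis gated off\n")
  invisible(x)
}

#' Write an analysis report to a directory of plain-text tables
#'
#' Emits `level1.tsv` (one row per level-1 hypothesis), `level2.tsv`
#' (tidy per-window results), `level2_wide.tsv` (windows as rows, targets
#' as columns, cells `p` with `*` marking discoveries), `traces.tsv`
#' (per-condition mean energy curves), `tree.tsv`, `rejections.tsv` and
#' `provenance.yaml`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(report$level1, "level1.tsv")
  w(report$level2, "level2.tsv")
  if (nrow(report$level2)) {
    for (per in unique(report$level2$period)) {
      l2 <- report$level2[report$level2$period == per, , drop = FALSE]
      l2$cell <- paste0(formatC(l2$p, digits = 4, format = "f"),
                        ifelse(l2$decision == "rejected", "*", ""))
      key <- paste0(l2$type, "-", l2$target, ".", l2$contrast)
      lab <- paste0(l2$window_start_ms, "-", l2$window_end_ms)
      wide <- data.frame(time_ms = lab[!duplicated(l2$window)],
                         stringsAsFactors = FALSE)
      for (kk in unique(key))
        wide[[kk]] <- l2$cell[key == kk][order(l2$window[key == kk])]
      w(wide, paste0("level2_wide_", per, ".tsv"))
    }
  }
  if (!is.null(report$traces)) w(report$traces, "traces.tsv")
  w(as.data.frame(report$tree), "tree.tsv")
  w(report$rejection_log, "rejections.tsv")
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
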