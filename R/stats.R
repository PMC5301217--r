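#' Paired t-test on per-subject condition differences
#'
#' One-sample t-test with mean 0 on the vector of per-subject differences
#' (condition A minus condition B): `t = mean(d) / (sd(d) / sqrt(n))` with
#' the n-1-denominator standard deviation, two-sided p from the Student t
#' distribution with n-1 degrees of freedom.
#'
#' @param differences numeric vector of per-subject paired differences,
#'   length >= 3, finite, with nonzero variance.
#' @return list with `t`, `df`, `p`, `n`, `mean_diff`.
#' @examples
#' paired_t_test(c(1, 2, 3))  # t = 3.4641..., p = 0.0742...
#' @export
paired_t_test <- function(differences) {
  d <- as.numeric(differences)
  n <- length(d)
  if (n < 3) stop("paired t-test needs >= 3 differences, got ", n)
  if (any(!is.finite(d))) stop("differences must be finite")
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences: paired t-test degenerate")
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), df = n - 1),
       n = n, mean_diff = mean(d))
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the standardised differences against the standard
#' normal, used as an advisory check of the paired t-test's normality
#' assumption; it never blocks the t-tests. Because the mean and standard
#' deviation are estimated from the same data, the nominal p-value is
#' conservative (the check is a screen, not a calibrated test); `note`
#' records this caveat.
#'
#' @param differences numeric vector, length >= 3.
#' @param alpha screening level (default 0.05).
#' @return list with `statistic`, `p`, `normal` (TRUE = no significant
#'   deviation at `alpha`), `note`.
#' @export
ks_normality <- function(differences, alpha = 0.05) {
  d <- as.numeric(differences)
  if (length(d) < 3) stop("needs >= 3 values")
  z <- (d - mean(d)) / stats::sd(d)
  k <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(k$statistic), p = k$p.value,
       normal = k$p.value > alpha,
       note = paste("mean/sd estimated from the data;",
                    "nominal p approximate/conservative"))
}

#' Benjamini-Hochberg step-up rejection set
#'
#' Standard BH step-up at level `q` over one hypothesis family: sort the
#' p-values ascending, find the largest k with `p(k) <= k q / m`, reject
#' hypotheses 1..k (ties at the boundary are all rejected). Implemented
#' via the BH adjusted p-values, whose `<= q` set is exactly the step-up
#' rejection set.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q FDR level.
#' @return logical vector, TRUE where rejected.
#' @export
bh_stepup <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (!length(p)) return(logical(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Two-level hypothesis tree
#'
#' Assembles level-1 (parent) and level-2 (child) hypotheses into the tree
#' consumed by [hierarchical_fdr()]. Level-1 nodes have no parent; each
#' level-2 node names exactly one level-1 parent.
#'
#' @param nodes data.frame with columns `id`, `level` (1 or 2), `parent`
#'   (NA for level 1), `label`, `p`.
#' @param q FDR level used throughout the procedure.
#' @return object of class `hypothesis_tree` (a data.frame with attribute
#'   `q`), with `decision` initialised to `"not_tested"`.
#' @export
hypothesis_tree <- function(nodes, q = 0.05) {
  req <- c("id", "level", "parent", "label", "p")
  if (!all(req %in% names(nodes)))
    stop("nodes must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (!all(nodes$level %in% c(1, 2))) stop("levels must be 1 or 2")
  l1 <- nodes$id[nodes$level == 1]
  l2 <- nodes[nodes$level == 2, ]
  if (any(is.na(l2$parent) | !(l2$parent %in% l1)))
    stop("orphan level-2 node(s): every child needs an existing level-1 parent")
  if (any(!is.na(nodes$parent[nodes$level == 1])))
    stop("level-1 nodes must have no parent")
  nodes$decision <- rep("not_tested", nrow(nodes))
  nodes$family_size <- rep(NA_integer_, nrow(nodes))
  structure(nodes, q = q, class = c("hypothesis_tree", "data.frame"))
}

#' Hierarchical false-discovery-rate procedure
#'
#' Two-level FDR control with parent gating: the level-1 family is tested
#' with Benjamini-Hochberg at level `q`; then, for each rejected parent,
#' that parent's children form one family tested with BH at level `q`.
#' Children of non-rejected parents are never tested (`"not_tested"`).
#' Family sizes are recorded per node for audit.
#'
#' The fuller tree-wide adjustment of hierarchical FDR theory (a universal
#' multiplier on the nominal level) is available via
#' `method = "yekutieli"`, which tests each family at `q / 2` as a
#' conservative two-level bound; the default `"strict"` applies BH at the
#' fixed `q` in every family.
#'
#' @param tree a [hypothesis_tree()] (or its `nodes` data.frame).
#' @param q FDR level; defaults to the tree's.
#' @param method `"strict"` (default) or `"yekutieli"`.
#' @return the tree with `decision` filled in: `"rejected"`,
#'   `"not_rejected"`, or `"not_tested"`.
#' @export
hierarchical_fdr <- function(tree, q = NULL,
                             method = c("strict", "yekutieli")) {
  method <- match.arg(method)
  if (!inherits(tree, "hypothesis_tree"))
    tree <- hypothesis_tree(tree, q = if (is.null(q)) 0.05 else q)
  if (is.null(q)) q <- attr(tree, "q")
  q_eff <- if (method == "yekutieli") q / 2 else q
  l1 <- which(tree$level == 1)
  if (!length(l1)) stop("no level-1 hypotheses")
  if (any(is.na(tree$p[l1]))) stop("level-1 nodes must carry p-values")
  rej1 <- bh_stepup(tree$p[l1], q_eff)
  tree$decision[l1] <- ifelse(rej1, "rejected", "not_rejected")
  tree$family_size[l1] <- length(l1)
  for (pid in tree$id[l1][rej1]) {
    kids <- which(tree$level == 2 & tree$parent == pid)
    if (!length(kids)) next
    if (any(is.na(tree$p[kids])))
      stop("children of rejected parent '", pid, "' lack p-values")
    rej2 <- bh_stepup(tree$p[kids], q_eff)
    tree$decision[kids] <- ifelse(rej2, "rejected", "not_rejected")
    tree$family_size[kids] <- length(kids)
  }
  tree
}

#' @export
print.hypothesis_tree <- function(x, ...) {
  cat("<hypothesis_tree> q = ", attr(x, "q"), "; ",
      sum(x$level == 1), " level-1 and ", sum(x$level == 2),
      " level-2 hypotheses; ",
      sum(x$decision == "rejected"), " rejected\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
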