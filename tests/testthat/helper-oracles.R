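# Independent brute-force oracles and small random fixtures. Every oracle
# enumerates node pairs explicitly and stays independent of the package's
# vectorised implementations.

random_weights <- function(n, mode = "signed") {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- stats::runif(1, -1, 1)
    if (mode == "absolute") v <- abs(v)
    w[i, j] <- w[j, i] <- v
  }
  w
}

random_graph <- function(n, mode = "signed", labels = letters[seq_len(n)]) {
  weighted_graph(random_weights(n, mode), labels, mode)
}

oracle_de <- function(w, f) {
  s <- 0
  n <- length(f)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + w[i, j] * (f[i] - f[j])^2
  s
}

oracle_node_grad <- function(w, f, i) {
  s <- 0
  for (j in seq_along(f)) if (j != i) s <- s + w[i, j] * (f[i] - f[j])^2
  s
}

oracle_mde <- function(w, f, idx) {
  s <- 0
  idx <- sort(idx)
  if (length(idx) < 2) return(0)
  for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
    i <- idx[a]; j <- idx[b]
    s <- s + w[i, j] * (f[i] - f[j])^2
  }
  s
}

oracle_bmde <- function(w, f, idxA, idxB) {
  s <- 0
  for (i in idxA) for (j in idxB) s <- s + w[i, j] * (f[i] - f[j])^2
  s
}

oracle_tmw <- function(w, idxm) {
  s <- 0
  n <- nrow(w)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (i %in% idxm || j %in% idxm) s <- s + abs(w[i, j])
  s
}

# literal BH step-up: largest k with p_(k) <= k q / m
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

rel_err <- function(a, b) abs(a - b) / max(1, abs(a), abs(b))

# small ERP-like container for preprocessing tests
toy_epoch <- function(x, subject = "S1", condition = "A", trial = 1L,
                      correct = TRUE, rate = 250, t0 = -0.2) {
  if (is.null(rownames(x)))
    rownames(x) <- paste0("ch", seq_len(nrow(x)))
  trial_epoch(x, rate, t0 = t0, subject = subject, condition = condition,
              trial = trial, correct = correct)
}
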