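test_that("weighted_graph validates its invariants", {
  w <- matrix(c(0, .5, .5, 0), 2, 2)
  g <- weighted_graph(w, c("a", "b"))
  expect_identical(g$labels, c("a", "b"))
  expect_error(weighted_graph(matrix(0, 2, 3)), "square")
  expect_error(weighted_graph(matrix(c(0, 1, .5, 0), 2, 2)), "symmetric")
  expect_error(weighted_graph(matrix(c(1, 0, 0, 1), 2, 2)), "diagonal")
  expect_error(weighted_graph(matrix(c(0, 2, 2, 0), 2, 2)), "\\[-1, 1\\]")
  expect_error(weighted_graph(matrix(c(0, -.5, -.5, 0), 2, 2),
                              weight_mode = "absolute"), "negative")
})

test_that("dirichlet energy matches closed forms and sign semantics", {
  g <- random_graph(5)
  expect_equal(dirichlet_energy(g, rep(3.7, 5)), 0)
  g2 <- weighted_graph(matrix(c(0, -1, -1, 0), 2, 2), c("a", "b"))
  expect_equal(dirichlet_energy(g2, c(1, -1)), -4)
  g3 <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2), c("a", "b"))
  expect_equal(dirichlet_energy(g3, c(1, -1)), 4)
  expect_error(dirichlet_energy(g, 1:3), "length")
  expect_error(dirichlet_energy(g, c(1, 2, NA, 4, 5)), "finite")
})

test_that("energies agree with the brute-force pair enumeration oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    g <- random_graph(n)
    f <- stats::rnorm(n)
    expect_lt(rel_err(dirichlet_energy(g, f), oracle_de(g$weights, f)),
              1e-12)
    for (i in seq_len(n))
      expect_lt(rel_err(node_gradient(g, f, g$labels[i]),
                        oracle_node_grad(g$weights, f, i)), 1e-12)
  }
})

test_that("node gradient doubling identity and edge cases", {
  g2 <- weighted_graph(matrix(c(0, -1, -1, 0), 2, 2), c("a", "b"))
  expect_equal(node_gradient(g2, c(1, -1), "a"), -4)
  expect_equal(node_gradient(g2, c(1, -1), "b"), -4)
  set.seed(12)
  for (rep in 1:10) {
    g <- random_graph(sample(3:8, 1))
    f <- stats::rnorm(n_nodes <- length(g$labels))
    grads <- vapply(g$labels, function(l) node_gradient(g, f, l), numeric(1))
    expect_equal(sum(grads), 2 * dirichlet_energy(g, f))
  }
  # isolated node: all incident weights zero
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.5
  g <- weighted_graph(w, c("a", "b", "c"))
  expect_equal(node_gradient(g, c(1, 2, 3), "c"), 0)
  expect_error(node_gradient(g, 1:3, "zz"), "unknown node")
})

test_that("node gradient profile averages per-sample gradients", {
  set.seed(13)
  g <- random_graph(4)
  x <- matrix(stats::rnorm(40), 4, 10, dimnames = list(g$labels, NULL))
  ser <- graph_signal_series(x, 250)
  prof <- node_gradient_profile(ser, g)
  manual <- rowMeans(vapply(1:10, function(tt)
    vapply(seq_len(4), function(i) oracle_node_grad(g$weights, x[, tt], i),
           numeric(1)), numeric(4)))
  expect_equal(prof$gradient, unname(manual), tolerance = 1e-12)
  # single-sample series reduces to the plain node gradient
  ser1 <- graph_signal_series(x[, 1, drop = FALSE], 250)
  p1 <- node_gradient_profile(ser1, g)
  expect_equal(p1$gradient,
               vapply(g$labels, function(l) node_gradient(g, x[, 1], l),
                      numeric(1), USE.NAMES = FALSE))
  # constant-in-time series likewise
  serc <- graph_signal_series(x[, c(2, 2, 2)], 250)
  expect_equal(node_gradient_profile(serc, g)$gradient, p1$gradient * 0 +
               vapply(g$labels, function(l) node_gradient(g, x[, 2], l),
                      numeric(1), USE.NAMES = FALSE))
})

test_that("total modular weight uses the adjacent-edge convention", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- -0.3
  w[2, 3] <- w[3, 2] <- 0.8
  g <- weighted_graph(w, c("a", "b", "c"))
  part <- module_partition(list(m = c("a", "b")))
  expect_equal(total_modular_weight(g, part, "m"), 0.5 + 0.3 + 0.8)
  # whole-graph module: sum of all |w|
  part_all <- module_partition(list(all = c("a", "b", "c")))
  expect_equal(total_modular_weight(g, part_all, "all"), 1.6)
  # all-zero graph
  g0 <- weighted_graph(matrix(0, 3, 3), c("a", "b", "c"))
  expect_equal(total_modular_weight(g0, part, "m"), 0)
  expect_error(total_modular_weight(g, part, "nope"), "unknown module")
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    g <- random_graph(n)
    k <- sample(1:(n - 1), 1)
    idx <- sort(sample(n, k))
    p <- module_partition(list(m = g$labels[idx]))
    expect_lt(rel_err(total_modular_weight(g, p, "m"),
                      oracle_tmw(g$weights, idx)), 1e-12)
  }
})

test_that("MDE restricts to within-module edges", {
  set.seed(15)
  g <- random_graph(6)
  f <- stats::rnorm(6)
  part <- module_partition(list(m1 = g$labels[1:3], m2 = g$labels[4:6]))
  expect_lt(rel_err(mde(g, f, part, "m1"), oracle_mde(g$weights, f, 1:3)),
            1e-12)
  expect_lt(rel_err(mde(g, f, part, "m2"), oracle_mde(g$weights, f, 4:6)),
            1e-12)
  # singleton module has no internal edges
  ps <- module_partition(list(s = g$labels[2]))
  expect_equal(mde(g, f, ps, "s"), 0)
  # whole-graph module equals the total energy
  pa <- module_partition(list(all = g$labels))
  expect_equal(mde(g, f, pa, "all"), dirichlet_energy(g, f))
})

test_that("BMDE sums cross edges, is symmetric, zero when disconnected", {
  set.seed(16)
  g <- random_graph(6)
  f <- stats::rnorm(6)
  part <- module_partition(list(m1 = g$labels[1:3], m2 = g$labels[4:6]))
  expect_lt(rel_err(bmde(g, f, part, "m1", "m2"),
                    oracle_bmde(g$weights, f, 1:3, 4:6)), 1e-12)
  expect_equal(bmde(g, f, part, "m1", "m2"), bmde(g, f, part, "m2", "m1"))
  expect_error(bmde(g, f, part, "m1", "m1"), "distinct")
  # no cross edges: block-diagonal weights
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- .7; w[3, 4] <- w[4, 3] <- -.4
  gd <- weighted_graph(w, letters[1:4])
  pd <- module_partition(list(A = c("a", "b"), B = c("c", "d")))
  expect_equal(bmde(gd, stats::rnorm(4), pd, "A", "B"), 0)
})

test_that("energy decomposition closes exactly", {
  set.seed(17)
  g <- random_graph(8)
  f <- stats::rnorm(8)
  part <- module_partition(list(m1 = g$labels[1:3], m2 = g$labels[4:5],
                                m3 = g$labels[6:7]))  # one node unassigned
  dec <- decompose_energy(g, f, part)
  expect_lt(rel_err(dec$total,
                    sum(dec$within) + sum(dec$between) + dec$residual),
            1e-9)
  # single module covering everything
  pa <- module_partition(list(all = g$labels))
  da <- decompose_energy(g, f, pa)
  expect_equal(unname(da$within["all"]), da$total)
  expect_equal(da$residual, 0)
  expect_length(da$between, 0)
  # empty partition: everything is residual
  de <- decompose_energy(g, f, module_partition(list()))
  expect_equal(de$residual, de$total)
})

test_that("energies are invariant to negation and scale as c^2", {
  set.seed(18)
  for (rep in 1:10) {
    g <- random_graph(6)
    f <- stats::rnorm(6)
    part <- module_partition(list(a = g$labels[1:2], b = g$labels[3:5]))
    cc <- stats::runif(1, 0.1, 3)
    expect_equal(dirichlet_energy(g, -f), dirichlet_energy(g, f))
    expect_equal(mde(g, -f, part, "b"), mde(g, f, part, "b"))
    expect_equal(dirichlet_energy(g, cc * f),
                 cc^2 * dirichlet_energy(g, f))
    expect_equal(bmde(g, cc * f, part, "a", "b"),
                 cc^2 * bmde(g, f, part, "a", "b"))
  }
})

test_that("absolute-weight energies are non-negative", {
  set.seed(19)
  for (rep in 1:10) {
    g <- random_graph(6, mode = "absolute")
    f <- stats::rnorm(6)
    part <- module_partition(list(a = g$labels[1:3], b = g$labels[4:6]))
    expect_gte(dirichlet_energy(g, f), 0)
    expect_gte(mde(g, f, part, "a"), 0)
    expect_gte(bmde(g, f, part, "a", "b"), 0)
    expect_gte(node_gradient(g, f, g$labels[1]), 0)
  }
})

test_that("windowed energy tiles the series and is linear in time", {
  set.seed(20)
  g <- random_graph(6)
  part <- module_partition(list(a = g$labels[1:3], b = g$labels[4:6]))
  x <- matrix(stats::rnorm(6 * 50), 6, 50, dimnames = list(g$labels, NULL))
  ser <- graph_signal_series(x, 250, t0 = 0)
  tr <- windowed_energy(ser, g, part, 20, list("a", "b", c("a", "b")))
  expect_equal(ncol(tr$values), 10)
  expect_equal(tr$window_len, 5)
  expect_identical(rownames(tr$values), c("a", "b", "a:b"))
  # windows are non-overlapping and chronological
  expect_equal(tr$window_starts, seq(0, 45, by = 5))
  expect_true(all(is.finite(tr$values)))
  # per-window value equals brute-force per-sample loop
  for (k in c(1, 4, 10)) {
    cols <- (k - 1) * 5 + 1:5
    expect_equal(unname(tr$values["a", k]),
                 sum(vapply(cols, function(tt)
                   oracle_mde(g$weights, x[, tt], 1:3), numeric(1))),
                 tolerance = 1e-12)
    expect_equal(unname(tr$values["a:b", k]),
                 sum(vapply(cols, function(tt)
                   oracle_bmde(g$weights, x[, tt], 1:3, 4:6), numeric(1))),
                 tolerance = 1e-12)
  }
  # one window spanning the series = sum of all per-sample energies
  tr1 <- windowed_energy(ser, g, part, 200, list("a"))
  expect_equal(ncol(tr1$values), 1)
  expect_equal(unname(tr1$values["a", 1]), sum(vapply(1:50, function(tt)
    oracle_mde(g$weights, x[, tt], 1:3), numeric(1))))
  # trailing partial windows dropped: 48 samples at 20 ms -> 9 windows
  ser48 <- graph_signal_series(x[, 1:48], 250, t0 = 0)
  expect_equal(ncol(windowed_energy(ser48, g, part, 20, list("a"))$values), 9)
  expect_error(windowed_energy(ser48, g, part, 1000, list("a")), "longer")
  expect_error(windowed_energy(ser, g, part, 3, list("a")),
               "whole number")
})

test_that("graph and energy-trace TSV round trips preserve values", {
  set.seed(21)
  g <- random_graph(5)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, p1)
  g2 <- read_graph_tsv(p1)
  expect_equal(g2$weights, g$weights, tolerance = 1e-9)
  expect_identical(g2$labels, g$labels)
  part <- module_partition(list(a = g$labels[1:2], b = g$labels[3:5]))
  x <- matrix(stats::rnorm(5 * 20), 5, 20, dimnames = list(g$labels, NULL))
  tr <- windowed_energy(graph_signal_series(x, 250, t0 = 0), g, part, 20,
                        list("a", c("a", "b")))
  df <- as.data.frame(tr)
  expect_identical(names(df), c("target", "window", "window_start_ms",
                                "window_end_ms", "value"))
  expect_equal(df$value[df$target == "a" & df$window == 2],
               unname(tr$values["a", 2]))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_energy_trace(tr, p2)
  back <- read.delim(p2)
  expect_equal(nrow(back), 2 * 4)
  expect_equal(back$value, df$value, tolerance = 1e-9)
})
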