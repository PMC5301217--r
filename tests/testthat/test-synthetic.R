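test_that("generation is byte-reproducible from the seed", {
  cfg <- synthetic_config(n_subjects = 2, n_trials = 3, noise_sd = 10,
                          seed = 101)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$trials, d2$trials)
  d3 <- generate_dataset(synthetic_config(n_subjects = 2, n_trials = 3,
                                          noise_sd = 10, seed = 102))
  expect_false(identical(d1$trials[[1]]$samples, d3$trials[[1]]$samples))
})

test_that("config validation rejects infeasible settings", {
  expect_error(synthetic_config(seed = NULL), "seed is mandatory")
  expect_error(synthetic_config(baseline_rho = 1, seed = 1),
               "attainable bound")
  expect_error(synthetic_config(baseline_rho = -0.1, seed = 1),
               "attainable bound")
  expect_error(synthetic_config(
    coupling = list(list(module = "occipital", rho = 1.2)), seed = 1),
    "attainable bound")
  expect_error(synthetic_config(
    effects = list(list(module = "occipital", condition = "Shape.R",
                        interval_ms = c(900, 1300), amplitude = 2)),
    seed = 1), "inside the epoch")
  expect_error(synthetic_config(
    effects = list(list(module = "nope", condition = "Shape.R",
                        interval_ms = c(0, 100), amplitude = 2)),
    seed = 1), "unknown module")
})

test_that("within-module coupling calibrates to the target correlation", {
  # rho = 0: 95% of channel pairs within +/- 0.1 of zero at 200+ samples
  cfg0 <- synthetic_config(n_subjects = 1, n_trials = 1,
                           conditions = c("A", "B"), baseline_rho = 0,
                           noise_sd = 10, seed = 201)
  x <- generate_dataset(cfg0)$trials[[1]]$samples
  r <- stats::cor(t(x))
  off <- abs(r[upper.tri(r)])
  expect_gte(mean(off < 0.1 + 1e-12), 0.90)
  # rho = 0.8 within frontal: mean within-module correlation in [0.7, 0.9]
  cfg8 <- synthetic_config(
    n_subjects = 1, n_trials = 50, conditions = c("A", "B"),
    baseline_rho = 0,
    coupling = list(list(module = "frontal", rho = 0.8)),
    noise_sd = 10, seed = 202)
  ds <- generate_dataset(cfg8)
  fr <- default_modules()$assignments$frontal
  trials_A <- Filter(function(tr) tr$condition == "A", ds$trials)
  rs <- vapply(trials_A, function(tr) {
    r <- stats::cor(t(tr$samples[fr, ]))
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_gt(mean(rs), 0.7)
  expect_lt(mean(rs), 0.9)
  # convergence: correlation closer to target with more samples
  devs <- vapply(c(300, 1200), function(ms) {
    cfg <- synthetic_config(n_subjects = 1, n_trials = 30,
                            conditions = c("A",  "B"), baseline_rho = 0,
                            epoch_ms = c(0, ms),
                            coupling = list(list(module = "frontal",
                                                 rho = 0.6)),
                            noise_sd = 10, seed = 203)
    ds <- generate_dataset(cfg)
    rs <- vapply(Filter(function(tr) tr$condition == "A", ds$trials),
                 function(tr) {
                   r <- stats::cor(t(tr$samples[fr, ]))
                   mean(r[upper.tri(r)])
                 }, numeric(1))
    abs(mean(rs) - 0.6)
  }, numeric(1))
  expect_lt(devs[2], devs[1] + 0.02)
})

test_that("null datasets make the conditions exchangeable", {
  # pooled per-trial channel means compared across conditions by
  # two-sample KS: should fail to reject at the 5% level ~95% of the time
  set.seed(301)
  pvals <- vapply(1:100, function(i) {
    cfg <- synthetic_config(n_subjects = 2, n_trials = 6,
                            conditions = c("A", "B"),
                            coupling = list(list(module = "occipital",
                                                 condition = "A",
                                                 rho = 0.9)),
                            noise_sd = 10, seed = 4000 + i)
    ds <- plant_null_dataset(cfg)
    m <- vapply(ds$trials, function(tr) mean(tr$samples), numeric(1))
    condA <- vapply(ds$trials, function(tr) tr$condition == "A", logical(1))
    suppressWarnings(stats::ks.test(m[condA], m[!condA])$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)
})

test_that("null generation strips condition-specific structure only", {
  cfg <- synthetic_config(
    n_subjects = 1, n_trials = 2,
    coupling = list(
      list(module = "frontal", rho = 0.7),                  # shared: kept
      list(module = "occipital", condition = "Bind.R", rho = 0.1)),
    effects = list(list(module = "occipital", condition = "Shape.R",
                        interval_ms = c(100, 140), amplitude = 5)),
    noise_sd = 10, seed = 77)
  ds <- plant_null_dataset(cfg)
  expect_length(ds$config$effects, 0)
  expect_length(ds$config$coupling, 1)
  expect_identical(ds$config$coupling[[1]]$module, "frontal")
})

test_that("degenerate all-zero signals surface as downstream errors", {
  cfg <- synthetic_config(n_subjects = 3, n_trials = 2,
                          conditions = c("A", "B"), baseline_rho = 0,
                          noise_sd = 0, subject_gain_sd = 0, seed = 5)
  ds <- generate_dataset(cfg)
  expect_true(all(vapply(ds$trials, function(tr) all(tr$samples == 0),
                         logical(1))))
  design <- study_design(contrasts = list(AB = c("A", "B")))
  rep <- suppressWarnings(run_full_analysis(ds, design))
  expect_true(all(is.na(rep$level1$p)))
  expect_true(all(grepl("zero-variance", rep$level1$note)))
  expect_true(all(rep$level1$decision == "not_tested"))
})

test_that("planted effects vanish outside their window", {
  # mean condition difference outside the bump interval is zero in
  # expectation: t-test over per-seed differences should not reject
  set.seed(302)
  outside <- vapply(1:40, function(i) {
    cfg <- synthetic_config(
      n_subjects = 1, n_trials = 6, conditions = c("A", "B"),
      effects = list(list(module = "occipital", condition = "A",
                          interval_ms = c(100, 140), amplitude = 6)),
      noise_sd = 10, seed = 6000 + i)
    ds <- generate_dataset(cfg)
    occ <- default_modules()$assignments$occipital
    t_ms <- seq(-200, 1000 - 4, by = 4)
    sel <- t_ms >= 300 & t_ms < 700   # far from the planted interval
    mA <- Reduce(`+`, lapply(Filter(function(tr) tr$condition == "A",
                                    ds$trials),
                             function(tr) tr$samples[occ, sel])) / 6
    mB <- Reduce(`+`, lapply(Filter(function(tr) tr$condition == "B",
                                    ds$trials),
                             function(tr) tr$samples[occ, sel])) / 6
    mean(mA - mB)
  }, numeric(1))
  expect_gt(stats::t.test(outside)$p.value, 0.05)
  # inside the window the bump is a graded (zero-mean) deflection across
  # the module's channels: the across-channel spread of the condition
  # difference is far larger inside the window than outside
  spread <- vapply(1:20, function(i) {
    cfg <- synthetic_config(
      n_subjects = 1, n_trials = 6, conditions = c("A", "B"),
      effects = list(list(module = "occipital", condition = "A",
                          interval_ms = c(100, 140), amplitude = 6)),
      noise_sd = 10, seed = 7000 + i)
    ds <- generate_dataset(cfg)
    occ <- default_modules()$assignments$occipital
    t_ms <- seq(-200, 1000 - 4, by = 4)
    diff_at <- function(sel) {
      mA <- Reduce(`+`, lapply(Filter(function(tr) tr$condition == "A",
                                      ds$trials),
                               function(tr) tr$samples[occ, sel])) / 6
      mB <- Reduce(`+`, lapply(Filter(function(tr) tr$condition == "B",
                                      ds$trials),
                               function(tr) tr$samples[occ, sel])) / 6
      mean(apply(mA - mB, 2, stats::sd))   # per-sample channel spread
    }
    diff_at(t_ms >= 100 & t_ms < 140) - diff_at(t_ms >= 300 & t_ms < 340)
  }, numeric(1))
  expect_lt(stats::t.test(spread)$p.value, 0.001)
  expect_gt(mean(spread), 0)
})

test_that("recovery scoring recognises hits, misses and amplitude order", {
  # strong planted scenario: recovered at both levels
  rep_strong <- run_full_analysis(generate_dataset(planted_config(seed = 11)))
  sc <- recovery_score(rep_strong, planted_config(seed = 11))
  amp_row <- sc[sc$type == "amplitude", ]
  expect_true(all(sc$level1_discovered))
  expect_true(amp_row$level2_hit)
  expect_identical(amp_row$planted_windows, "6,7")
  # zero-amplitude "effect" in an otherwise null dataset: no discovery
  cfg0 <- synthetic_config(
    n_subjects = 10, n_trials = 4,
    effects = list(list(module = "occipital", condition = "Shape.R",
                        interval_ms = c(100, 140), amplitude = 0)),
    noise_sd = 10, seed = 303)
  rep0 <- run_full_analysis(generate_dataset(cfg0))
  sc0 <- recovery_score(rep0, cfg0)
  expect_false(sc0$level1_discovered[sc0$type == "amplitude"])
  expect_false(isTRUE(sc0$level2_hit[sc0$type == "amplitude"]))
  # recovery rate non-decreasing along an amplitude ladder
  rate <- vapply(c(0, 6), function(A) {
    hits <- vapply(1:10, function(i) {
      cfg <- planted_config(seed = 9000 + i, amplitude = A)
      repA <- run_full_analysis(generate_dataset(cfg))
      scA <- recovery_score(repA, cfg)
      isTRUE(scA$level2_hit[scA$type == "amplitude"])
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gte(rate[2], rate[1])
  expect_gte(rate[2], 0.8)
})
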