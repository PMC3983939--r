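test_that("sample summaries use the median and report outliers without removing them", {
  s <- quiet_stats(records_from_ratios(c(1, 2, 3)))
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)

  # a single bright-red outlier drags the mean, not the median
  s2 <- quiet_stats(records_from_ratios(c(1, 1, 1, 1, 100)))
  expect_equal(s2$median, 1)
  expect_equal(s2$mean, 20.8)
  expect_identical(s2$n, 5L)
  expect_equal(s2$outlier_fraction, 0.2)

  expect_warning(summarize_sample(records_from_ratios(1:10), min_n = 300),
                 "transfected cells")
  expect_error(summarize_sample(records_from_ratios(numeric(0))),
               "no transfected cells")
})

test_that("control-arm median and mean agree under the null", {
  p <- scene_params(image_shape = c(600L, 600L), n_cells = 250L, seed = 2L)
  ex <- generate_experiment(p, 2, 2, seed = 2)
  res <- suppressWarnings(
    kd_from_experiment(ex$test, ex$control, ex$untransfected,
                       min_n = 10, n_boot = 100))
  ctl <- res$control
  expect_gt(ctl$n, 200)
  expect_lt(abs(ctl$median - ctl$mean) / ctl$median, 0.10)
})

test_that("delta is the scalar that self-normalises the scramble pair", {
  same <- quiet_stats(records_from_ratios(c(0.8, 1.0, 1.2, 1.4)))
  d <- estimate_delta(same, same)
  expect_identical(d$delta, 1)

  st <- quiet_stats(records_from_ratios(c(1.0, 1.25, 1.5)))   # median 1.25
  sc <- quiet_stats(records_from_ratios(c(0.8, 1.0, 1.2)))    # median 1.0
  expect_equal(estimate_delta(st, sc)$delta, 0.8)

  # self-normalisation: KD of the scramble pair with its own delta is 100%
  kd <- compute_kd_index(st, sc, estimate_delta(st, sc), n_boot = 50)
  expect_identical(kd$kd_percent, 100)
})

test_that("delta recovers the generator's GFP bias from a scramble pair", {
  p <- scene_params(image_shape = c(600L, 600L), n_cells = 200L,
                    knockdown_efficiency = 0, shrna_gfp_bias = 0.7,
                    seed = 8L)
  ex <- generate_experiment(p, 2, 2, seed = 8)
  bg <- estimate_background(ex$untransfected)
  arm <- function(fields) {
    recs <- do.call(rbind, lapply(fields, function(f) {
      thr <- compute_dna_threshold(f$dna, segmentation_config())
      rois <- filter_nuclei(segment_nuclei(f$dna, thr),
                            segmentation_config())
      measure_cells(f, rois, bg)
    }))
    quiet_stats(gate_transfectants(recs, gate_config(), bg))
  }
  d <- estimate_delta(arm(ex$test), arm(ex$control))
  expect_lt(abs(d$delta - 0.7), 0.05)
})

test_that("KD index follows its defining arithmetic and error rules", {
  mk <- function(ratios) quiet_stats(records_from_ratios(ratios))
  same <- mk(c(0.5, 1, 1.5))
  expect_equal(compute_kd_index(same, same, 1, n_boot = 50)$kd_percent, 100)
  expect_equal(compute_kd_index(mk(c(0, 0, 0)), same, 1,
                                n_boot = 50)$kd_percent, 0)

  test_s <- mk(c(0.1, 0.2, 0.3)); ctl <- mk(c(0.7, 0.8, 0.9))
  kd <- compute_kd_index(test_s, ctl, 0.9, n_boot = 50)
  expect_equal(kd$kd_percent, 100 * (0.2 / 0.8) * 0.9)  # 22.5

  # three-plasmid mode forces delta to 1 even when one is supplied
  kd3 <- compute_kd_index(test_s, ctl, 0.9, mode = "three_plasmid",
                          n_boot = 50)
  expect_identical(kd3$delta, 1)
  expect_equal(kd3$kd_percent, 25)

  expect_error(compute_kd_index(test_s, mk(c(0, 0, 0)), 1),
               "control median")
})

test_that("bootstrap CI brackets the estimate, is seeded, and covers the null", {
  set.seed(77)
  mk <- function(n, mu) quiet_stats(records_from_ratios(rlnorm(n, mu, 0.5)))
  a <- mk(400, 0); b <- mk(400, 0)
  kd1 <- compute_kd_index(a, b, seed = 42, n_boot = 500)
  kd2 <- compute_kd_index(a, b, seed = 42, n_boot = 500)
  expect_identical(kd1$bootstrap, kd2$bootstrap)
  expect_lte(kd1$ci_low, kd1$kd_percent)
  expect_gte(kd1$ci_high, kd1$kd_percent)

  # coverage of the true KD (= 100) across simulated repetitions,
  # binomial 99% band around 0.95 at 60 draws: >= 51 hits
  hits <- 0L
  for (i in 1:60) {
    kd <- compute_kd_index(mk(150, 0), mk(150, 0), n_boot = 300, seed = i)
    if (kd$ci_low <= 100 && kd$ci_high >= 100) hits <- hits + 1L
  }
  expect_gte(hits, 51L)
})

test_that("KD is invariant to rescaling one channel in both arms", {
  set.seed(12)
  r1 <- rlnorm(200, 0, 0.4); r2 <- rlnorm(200, -1, 0.4)
  base <- compute_kd_index(quiet_stats(records_from_ratios(r2)),
                           quiet_stats(records_from_ratios(r1)),
                           n_boot = 50, seed = 3)
  scaled <- compute_kd_index(quiet_stats(records_from_ratios(r2 * 5)),
                             quiet_stats(records_from_ratios(r1 * 5)),
                             n_boot = 50, seed = 3)
  expect_equal(scaled$kd_percent, base$kd_percent)
})

test_that("median-based KD resists injected bright-red outliers", {
  set.seed(13)
  ctl <- rlnorm(400, 0, 0.3)
  tst <- 0.1 * rlnorm(400, 0, 0.3)
  kd_of <- function(test_r, stat) {
    100 * stat(test_r) / stat(ctl)
  }
  contaminated <- c(tst, 10 * sample(tst, 20))  # +5% at 10x ratio
  shift_median <- abs(kd_of(contaminated, median) - kd_of(tst, median))
  shift_mean <- abs(kd_of(contaminated, mean) - kd_of(tst, mean))
  expect_lt(shift_median, shift_mean / 3)
})

test_that("linearity QC returns exact and near-perfect correlations", {
  rec <- records_from_ratios(seq(0.5, 2, length.out = 10))
  rec$mean_green <- 1:10; rec$mean_red <- 2 * (1:10)
  qc <- linearity_qc(rec)
  expect_equal(qc$r, 1)
  expect_equal(qc$slope, 2)
  expect_equal(qc$intercept, 0)

  degenerate <- rec; degenerate$mean_green <- 5
  expect_error(linearity_qc(degenerate), "degenerate")
  expect_error(linearity_qc(rec[1:2, ]), ">= 3 transfected")
})

test_that("repeat-level aggregation mirrors bar-graph reporting", {
  mk <- function(seed) {
    set.seed(seed)
    compute_kd_index(quiet_stats(records_from_ratios(rlnorm(80, -2, 0.3))),
                     quiet_stats(records_from_ratios(rlnorm(80, 0, 0.3))),
                     n_boot = 50, seed = seed)
  }
  agg <- aggregate_kd(list(mk(1), mk(2), mk(3)))
  expect_identical(agg$n_experiments, 3L)
  expect_equal(agg$kd_mean, mean(agg$kd_values))
  expect_gt(agg$kd_sd, 0)
})

test_that("kd_result methods expose the estimate coherently", {
  set.seed(21)
  kd <- compute_kd_index(
    quiet_stats(records_from_ratios(rlnorm(100, -1, 0.3))),
    quiet_stats(records_from_ratios(rlnorm(100, 0, 0.3))),
    n_boot = 200)
  expect_output(print(kd), "Knockdown index")
  expect_named(coef(kd), c("kd_percent", "delta", "m_test", "m_control"))
  ci <- confint(kd)
  expect_identical(unname(ci[1, ]), c(kd$ci_low, kd$ci_high))
  ci90 <- confint(kd, level = 0.90)
  expect_gte(ci90[1], ci[1]); expect_lte(ci90[2], ci[2])
  h <- rg_histogram(kd$test, breaks = 10)
  expect_identical(sum(h$count), kd$test$n)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(kd))
})
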