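#' Summarise R/G ratios of a gated sample
#'
#' Computes the per-sample summary of red/green ratios over transfected
#' cells: n, median (the statistic the KD index is built on), mean, and
#' standard deviation. The distribution of ratios under active knockdown
#' is strongly non-Gaussian — a minority of RNAi-insensitive cells shows
#' unusually bright red — so the median, not the mean, represents the
#' population; the mean and an outlier fraction (share of ratios above
#' median + 3 IQR) are reported to make that skew visible. Ratios above
#' the fence are reported, never removed.
#'
#' @param records Gated cell records (see [gate_transfectants()]).
#' @param min_n Minimum recommended number of transfected cells; a warning
#'   (not an error) is emitted below it. Default 300, the protocol's usual
#'   per-sample cell count.
#' @return A `sample_stats`: n, median, mean, sd, outlier_fraction, and the
#'   ratio vector itself (`ratios`) for resampling.
#' @export
summarize_sample <- function(records, min_n = 300) {
  ratios <- records$rg_ratio[which(records$transfected)]
  ratios <- ratios[is.finite(ratios)]
  n <- length(ratios)
  if (n == 0L)
    stop("no transfected cells to summarise", call. = FALSE)
  if (n < min_n)
    warning("only ", n, " transfected cells (< ", min_n,
            " recommended); the median may be unstable", call. = FALSE)
  med <- stats::median(ratios)
  fence <- med + 3 * stats::IQR(ratios)
  structure(list(n = n, median = med, mean = mean(ratios),
                 sd = if (n > 1) stats::sd(ratios) else 0,
                 outlier_fraction = mean(ratios > fence),
                 ratios = ratios),
            class = "sample_stats")
}

#' @export
print.sample_stats <- function(x, ...) {
  cat("<sample_stats> n = ", x$n, ", median = ", signif(x$median, 4),
      ", mean = ", signif(x$mean, 4), ", sd = ", signif(x$sd, 4),
      ", outliers > median+3*IQR: ", sprintf("%.1f%%",
                                             100 * x$outlier_fraction),
      "\n", sep = "")
  invisible(x)
}

#' Estimate the EGFP-expression correction coefficient delta
#'
#' Inserting a hairpin into the shRNA expression plasmid can change its
#' EGFP output relative to the empty vector, which rescales every R/G
#' ratio in the test arm and would bias the KD index. Delta is determined
#' with a scrambled-target reporter (no genuine knockdown): it is the
#' unique scalar that makes the scrambled experiment's own KD index read
#' exactly 100%,
#' \deqn{\delta = m_{scramble,control} / m_{scramble,test}.}
#' When hairpin insertion leaves EGFP expression unchanged, delta is
#' nearly 1.
#'
#' @param scramble_test `sample_stats` of the scrambled-target reporter
#'   co-transfected with the hairpin-bearing plasmid.
#' @param scramble_control `sample_stats` of the scrambled-target reporter
#'   with the empty vector.
#' @return A `delta_estimate`: delta, the two medians, and sample sizes.
#' @export
estimate_delta <- function(scramble_test, scramble_control) {
  stopifnot(inherits(scramble_test, "sample_stats"),
            inherits(scramble_control, "sample_stats"))
  if (scramble_test$median <= 0 || scramble_control$median <= 0)
    stop("delta requires positive scramble medians", call. = FALSE)
  structure(list(delta = scramble_control$median / scramble_test$median,
                 m_scramble_test = scramble_test$median,
                 m_scramble_control = scramble_control$median,
                 n_test = scramble_test$n, n_control = scramble_control$n,
                 scramble_test = scramble_test,
                 scramble_control = scramble_control),
            class = "delta_estimate")
}

#' @export
print.delta_estimate <- function(x, ...) {
  cat("<delta_estimate> delta = ", signif(x$delta, 4),
      "  (m_scramble_control ", signif(x$m_scramble_control, 4),
      " / m_scramble_test ", signif(x$m_scramble_test, 4),
      "; n = ", x$n_test, "/", x$n_control, ")\n", sep = "")
  invisible(x)
}

#' Knockdown index from two sample summaries
#'
#' The KD index compares the median R/G ratio of the test arm (candidate
#' shRNA co-transfected with its cognate reporter) with the control arm
#' (empty vector plus the same reporter):
#' \deqn{KD = 100 \cdot (m_{test} / m_{control}) \cdot \delta}
#' in percent: 0% is the strongest knockdown (no remaining target), 100%
#' is no knockdown. In three-plasmid mode (shRNA, green reference and red
#' reporter on separate plasmids) delta is fixed at 1. KD above 100% is
#' reported as-is, never clipped.
#'
#' A percentile bootstrap confidence interval is obtained by resampling
#' cells within each arm (and within the scramble arms when a
#' `delta_estimate` carrying ratio vectors is supplied).
#'
#' @param test,control `sample_stats` of the two arms.
#' @param delta A `delta_estimate`, a positive scalar, or 1 (default).
#'   Forced to 1 in three-plasmid mode.
#' @param mode `"two_plasmid"` (default) or `"three_plasmid"`.
#' @param conf_level CI level (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @return A `kd_result`.
#' @export
compute_kd_index <- function(test, control, delta = 1,
                             mode = c("two_plasmid", "three_plasmid"),
                             conf_level = 0.95, n_boot = 2000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(test, "sample_stats"), inherits(control, "sample_stats"))
  if (control$median <= 0)
    stop("control median must be > 0", call. = FALSE)
  if (mode == "three_plasmid") delta <- 1
  delta_est <- if (inherits(delta, "delta_estimate")) delta else NULL
  dval <- if (is.null(delta_est)) {
    stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
    as.numeric(delta)
  } else delta_est$delta

  # with an estimated delta, keep the ratio in product form so the
  # scramble pair's own KD is exactly 100% (no intermediate rounding)
  kd <- if (is.null(delta_est)) {
    100 * (test$median / control$median) * dval
  } else {
    100 * (test$median * delta_est$m_scramble_control) /
      (control$median * delta_est$m_scramble_test)
  }

  boot <- .kd_bootstrap(test, control, delta_est, dval, n_boot, seed)
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  structure(list(kd_percent = kd, delta = dval,
                 m_test = test$median, m_control = control$median,
                 n_test = test$n, n_control = control$n,
                 ci_low = min(ci[1], kd), ci_high = max(ci[2], kd),
                 conf_level = conf_level, n_boot = n_boot, mode = mode,
                 bootstrap = boot, test = test, control = control,
                 delta_estimate = delta_est),
            class = "kd_result")
}

.kd_bootstrap <- function(test, control, delta_est, dval, n_boot, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  rt <- test$ratios; rc <- control$ratios
  st <- if (!is.null(delta_est)) delta_est$scramble_test$ratios
  sc <- if (!is.null(delta_est)) delta_est$scramble_control$ratios
  vapply(seq_len(n_boot), function(i) {
    mt <- stats::median(sample(rt, replace = TRUE))
    mc <- stats::median(sample(rc, replace = TRUE))
    if (is.null(delta_est)) {
      100 * (mt / mc) * dval
    } else {
      100 * (mt * stats::median(sample(sc, replace = TRUE))) /
        (mc * stats::median(sample(st, replace = TRUE)))
    }
  }, numeric(1))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' @export
print.kd_result <- function(x, ...) {
  cat("Knockdown index (", sub("_", "-", x$mode), " mode)\n", sep = "")
  cat(sprintf("  KD = %.1f%%  [%d%% CI %.1f-%.1f, %d bootstrap reps]\n",
              x$kd_percent, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_boot))
  cat(sprintf("  m_test = %.4g (n = %d), m_control = %.4g (n = %d), delta = %.3f\n",
              x$m_test, x$n_test, x$m_control, x$n_control, x$delta))
  invisible(x)
}

#' @export
summary.kd_result <- function(object, ...) {
  print(object)
  cat("  0% = complete knockdown of the reporter, 100% = none.\n")
  if (!is.null(object$delta_estimate)) {
    cat("  delta from scramble pair: ")
    print(object$delta_estimate)
  }
  cat("  test arm:    "); print(object$test)
  cat("  control arm: "); print(object$control)
  invisible(object)
}

#' @export
coef.kd_result <- function(object, ...) {
  c(kd_percent = object$kd_percent, delta = object$delta,
    m_test = object$m_test, m_control = object$m_control)
}

#' @export
confint.kd_result <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && abs(level - object$conf_level) > 1e-12) {
    alpha <- (1 - level) / 2
    ci <- stats::quantile(object$bootstrap, c(alpha, 1 - alpha),
                          names = FALSE)
  } else {
    ci <- c(object$ci_low, object$ci_high)
    level <- object$conf_level
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("kd_percent",
                                sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                           1 - (1 - level) / 2))))
  out
}

#' Histogram of the two arms' R/G ratios
#'
#' Mirrors the paired R/G histograms used to read knockdown by eye: the
#' test arm's distribution collapses toward zero under effective RNAi
#' while the control arm stays broad.
#'
#' @param x A `kd_result`.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further graphical parameters.
#' @export
plot.kd_result <- function(x, breaks = 30, ...) {
  rt <- x$test$ratios; rc <- x$control$ratios
  brk <- seq(0, max(rt, rc) * 1.02 + 1e-9, length.out = breaks + 1)
  hc <- graphics::hist(rc, breaks = brk, plot = FALSE)
  ht <- graphics::hist(rt, breaks = brk, plot = FALSE)
  ylim <- c(0, max(hc$counts, ht$counts))
  graphics::plot(hc, col = grDevices::adjustcolor("grey40", 0.5),
                 border = NA, ylim = ylim, xlab = "R/G ratio",
                 main = sprintf("KD = %.1f%%", x$kd_percent), ...)
  graphics::plot(ht, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, add = TRUE)
  graphics::abline(v = c(x$m_control, x$m_test), lty = 2,
                   col = c("grey20", "firebrick"))
  graphics::legend("topright", c("control", "test"),
                   fill = grDevices::adjustcolor(c("grey40", "firebrick"),
                                                 0.5), bty = "n")
  invisible(x)
}

#' R/G histogram table for one arm
#'
#' @param stats A `sample_stats`.
#' @param breaks Number of bins (default 30) or a vector of bin edges.
#' @return data.frame with bin_low, bin_high, count.
#' @export
rg_histogram <- function(stats, breaks = 30) {
  stopifnot(inherits(stats, "sample_stats"))
  h <- graphics::hist(stats$ratios, breaks = breaks, plot = FALSE)
  data.frame(bin_low = utils::head(h$breaks, -1),
             bin_high = utils::tail(h$breaks, -1), count = h$counts)
}

#' Linearity quality control of the green-red coupling
#'
#' In a control arm the green reference and red reporter are produced from
#' expression cassettes with identical promoter and polyadenylation
#' signals, so per-cell red intensity should be linear in green intensity
#' over the full expression range. A poor correlation invalidates the use
#' of per-cell R/G ratios.
#'
#' @param records Gated cell records; transfected rows are used (>= 3
#'   required).
#' @return list with `r` (Pearson), `slope`, `intercept`, `n`.
#' @export
linearity_qc <- function(records) {
  sel <- which(records$transfected)
  g <- records$mean_green[sel]; r <- records$mean_red[sel]
  if (length(g) < 3L)
    stop("linearity QC needs >= 3 transfected cells", call. = FALSE)
  if (stats::sd(g) == 0 || stats::sd(r) == 0)
    stop("degenerate input: zero variance in a channel", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, g), r)
  list(r = stats::cor(g, r), slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = length(g))
}

#' End-to-end knockdown index from microscope fields
#'
#' Composes the full analysis: DNA threshold, nuclear segmentation,
#' size/shape filtering, background estimation from the untransfected
#' sample, per-cell measurement, green-channel gating, pooling of cells
#' across fields within each arm, sample summaries, optional delta
#' estimation from a scrambled-target pair, and the KD index with
#' bootstrap CI.
#'
#' @param test_fields,control_fields `field_image_set` or lists of them:
#'   the two arms.
#' @param untransfected_field A `field_image_set` (or list) with no
#'   transfected cells, for background estimation and gating.
#' @param seg_config A [segmentation_config()].
#' @param gate A [gate_config()].
#' @param scramble_test_fields,scramble_control_fields Optional scrambled-
#'   target arms for delta estimation (two-plasmid mode).
#' @param mode `"two_plasmid"` or `"three_plasmid"` (forces delta = 1).
#' @param min_n Warning threshold for per-arm transfected cell counts.
#' @param n_boot,conf_level,seed Bootstrap parameters.
#' @return A `kd_result` with the per-arm QC attached as attribute
#'   `"qc"` (linearity of the control arm, counts per stage).
#' @export
kd_from_experiment <- function(test_fields, control_fields,
                               untransfected_field,
                               seg_config = segmentation_config(),
                               gate = gate_config(),
                               scramble_test_fields = NULL,
                               scramble_control_fields = NULL,
                               mode = c("two_plasmid", "three_plasmid"),
                               min_n = 300, n_boot = 2000,
                               conf_level = 0.95, seed = 1) {
  mode <- match.arg(mode)
  as_list <- function(x)
    if (inherits(x, "field_image_set")) list(x) else x
  bg <- estimate_background(as_list(untransfected_field), seg_config)

  arm_records <- function(fields) {
    recs <- lapply(as_list(fields), function(f) {
      thr <- compute_dna_threshold(f$dna, seg_config)
      rois <- filter_nuclei(segment_nuclei(f$dna, thr), seg_config)
      measure_cells(f, rois, bg)
    })
    gate_transfectants(do.call(rbind, recs), gate, bg)
  }

  test_rec <- arm_records(test_fields)
  control_rec <- arm_records(control_fields)
  test_stats <- summarize_sample(test_rec, min_n)
  control_stats <- summarize_sample(control_rec, min_n)

  delta <- 1
  if (mode == "two_plasmid" && !is.null(scramble_test_fields)) {
    if (is.null(scramble_control_fields))
      stop("scramble_test_fields given without scramble_control_fields",
           call. = FALSE)
    delta <- estimate_delta(
      summarize_sample(arm_records(scramble_test_fields), min_n),
      summarize_sample(arm_records(scramble_control_fields), min_n))
  }

  res <- compute_kd_index(test_stats, control_stats, delta, mode,
                          conf_level = conf_level, n_boot = n_boot,
                          seed = seed)
  attr(res, "qc") <- list(
    linearity_control = linearity_qc(control_rec),
    gfp_threshold = attr(control_rec, "gfp_threshold"),
    n_cells = c(test = nrow(test_rec), control = nrow(control_rec)),
    n_transfected = c(test = test_stats$n, control = control_stats$n),
    background = bg)
  res
}

#' Aggregate KD indexes over repeated experiments
#'
#' Independent experiment repeats are summarised as mean and standard
#' deviation of their KD indexes, the form used for bar-graph reporting
#' across 2-3 repeats per target.
#'
#' @param kd_results List of `kd_result` objects for the same target.
#' @return list with kd_mean, kd_sd, n_experiments, kd_values.
#' @export
aggregate_kd <- function(kd_results) {
  stopifnot(length(kd_results) >= 1,
            all(vapply(kd_results, inherits, logical(1), "kd_result")))
  v <- vapply(kd_results, function(x) x$kd_percent, numeric(1))
  list(kd_mean = mean(v),
       kd_sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       n_experiments = length(v), kd_values = v)
}
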