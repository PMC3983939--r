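make_uniform_field <- function(green = 100, red = 50, bg_dna = 2000,
                               n = 6, sample_id = "fx") {
  img <- matrix(0, 120, 120)
  ctr <- expand.grid(r = c(30, 60, 90), c = c(40, 80))[seq_len(n), ]
  for (i in seq_len(n)) img <- add_disc(img, ctr$r[i], ctr$c[i], 7, bg_dna)
  field_image_set(img, matrix(green, 120, 120), matrix(red, 120, 120),
                  sample_id = sample_id, pixel_size = 0.1)
}

fake_bg <- function(green_bg, red_bg, green_sd = 1, red_sd = 1) {
  structure(list(green_bg = green_bg, red_bg = red_bg,
                 green_sd = green_sd, red_sd = red_sd, n_rois = 10L,
                 source = "untr"), class = "background_estimate")
}

test_that("background estimation recovers a constant offset exactly", {
  p <- scene_params(image_shape = c(256L, 256L), n_cells = 30L,
                    transfected_fraction = 0, background_level = 100,
                    read_noise_sd = 0, shot_noise = FALSE, seed = 4L)
  f <- generate_scene(p, "control", sample_id = "untr")$field
  bg <- estimate_background(f)
  expect_identical(bg$green_bg, 100)
  expect_identical(bg$red_bg, 100)
  expect_gte(bg$n_rois, 25L)
})

test_that("background is the mean of per-nucleus means pooled over fields", {
  # two uniform-channel fields; per-ROI means are the channel constants,
  # so pooling {10,...} and {30,...} nuclei averages their values
  f1 <- make_uniform_field(green = 10, red = 5, n = 2, sample_id = "u1")
  f2 <- make_uniform_field(green = 30, red = 15, n = 1, sample_id = "u2")
  bg <- estimate_background(list(f1, f2))
  expect_equal(bg$green_bg, mean(c(10, 10, 30)))
  expect_equal(bg$red_bg, mean(c(5, 5, 15)))
  expect_identical(bg$n_rois, 3L)

  blank <- field_image_set(matrix(0, 50, 50), matrix(0, 50, 50),
                           matrix(0, 50, 50), pixel_size = 0.1)
  expect_error(estimate_background(blank), "background estimation failed")
})

test_that("noisy background estimate is close to the generator offset", {
  p <- scene_params(image_shape = c(256L, 256L), n_cells = 30L,
                    transfected_fraction = 0, background_level = 100,
                    read_noise_sd = 5, shot_noise = FALSE, seed = 11L)
  f <- generate_scene(p, "control", sample_id = "untr")$field
  bg <- estimate_background(f)
  sc <- generate_scene(p, "control")
  npix <- sum(sc$truth$area_um2) / p$pixel_size^2
  expect_lt(abs(bg$green_bg - 100), 5 / sqrt(npix) * 10)
})

test_that("cell measurement subtracts background and clamps at zero", {
  f <- make_uniform_field(green = 100, red = 10)
  thr <- 500
  rois <- segment_nuclei(f$dna, thr)
  rec <- measure_cells(f, rois, fake_bg(green_bg = 20, red_bg = 30))
  expect_equal(rec$mean_green, rep(80, nrow(rec)))
  expect_equal(rec$mean_red, rep(0, nrow(rec)))  # dimmer than background
  expect_true(all(is.na(rec$transfected)))
})

test_that("noise-free measured ratios equal the generator truth", {
  p <- scene_params(image_shape = c(400L, 400L), n_cells = 60L,
                    knockdown_efficiency = 0.6, outlier_fraction = 0,
                    read_noise_sd = 0, shot_noise = FALSE, seed = 9L)
  sc <- generate_scene(p, "test")
  bgf <- scene_params(image_shape = c(256L, 256L), n_cells = 25L,
                      transfected_fraction = 0, read_noise_sd = 0,
                      shot_noise = FALSE, seed = 10L)
  bg <- estimate_background(generate_scene(bgf, "control")$field)
  thr <- compute_dna_threshold(sc$field$dna, segmentation_config())
  rois <- filter_nuclei(segment_nuclei(sc$field$dna, thr),
                        segmentation_config())
  rec <- gate_transfectants(measure_cells(sc$field, rois, bg),
                            gate_config(gfp_threshold = 1,
                                        gfp_threshold_mode = "preset"))
  ratios <- rec$rg_ratio[rec$transfected]
  expect_gt(length(ratios), 10)
  expect_equal(ratios, rep(0.4, length(ratios)), tolerance = 1e-9)
})

test_that("gating uses a strict threshold and is monotone in it", {
  rec <- data.frame(field = "f", label = 1:4, mean_green = c(0, 5, 10, 20),
                    mean_red = 1, transfected = NA, rg_ratio = NA_real_)
  g0 <- gate_transfectants(rec, gate_config(0, "preset"))
  expect_identical(g0$transfected, c(FALSE, TRUE, TRUE, TRUE))
  g10 <- gate_transfectants(rec, gate_config(10, "preset"))
  expect_identical(g10$transfected, c(FALSE, FALSE, FALSE, TRUE))  # == is out
  expect_true(all(is.na(g10$rg_ratio[!g10$transfected])))

  thresholds <- c(0, 4, 9, 15, 25)
  n_in <- vapply(thresholds, function(t)
    sum(gate_transfectants(rec, gate_config(t, "preset"))$transfected),
    numeric(1))
  expect_true(all(diff(n_in) <= 0))
})

test_that("control-derived gating separates transfectants near-perfectly", {
  p <- scene_params(image_shape = c(512L, 512L), n_cells = 150L,
                    transfected_fraction = 0.5, seed = 5L)
  ex <- generate_experiment(p, 1, 1, seed = 5)
  bg <- estimate_background(ex$untransfected)
  f <- ex$control[[1]]
  thr <- compute_dna_threshold(f$dna, segmentation_config())
  rois <- filter_nuclei(segment_nuclei(f$dna, thr), segmentation_config())
  rec <- gate_transfectants(measure_cells(f, rois, bg), gate_config(), bg)
  truth <- ex$truth_control
  # match measured cells to ground truth by nearest centroid
  idx <- vapply(seq_len(nrow(rec)), function(i) {
    j <- rec$label[i] == rois$table$label
    which.min((truth$centroid_row - rois$table$centroid_row[j])^2 +
                (truth$centroid_col - rois$table$centroid_col[j])^2)
  }, integer(1))
  truth_flag <- truth$transfected[idx]
  sens <- sum(rec$transfected & truth_flag) / sum(truth_flag)
  spec <- sum(!rec$transfected & !truth_flag) / sum(!truth_flag)
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("ratios are invariant to common channel scaling and label order", {
  f <- make_uniform_field(green = 200, red = 120)
  rois <- segment_nuclei(f$dna, 500)
  bg <- fake_bg(50, 30)
  rec <- measure_cells(f, rois, bg)
  f2 <- field_image_set(f$dna$pixels, f$green$pixels * 3, f$red$pixels * 3,
                        pixel_size = 0.1)
  rec2 <- measure_cells(f2, rois, fake_bg(150, 90))
  expect_equal(rec2$mean_green, 3 * rec$mean_green)
  g <- gate_transfectants(rec, gate_config(1, "preset"))
  g2 <- gate_transfectants(rec2, gate_config(1, "preset"))
  expect_equal(g2$rg_ratio, g$rg_ratio)
})

test_that("immunofluorescence levels normalise to the untransfected mean", {
  rec <- records_from_ratios(c(1, 0, 0.5))
  rec$mean_red <- c(80, 0, 40)
  out <- relative_protein_level(rec, untransfected_mean = 80)
  expect_equal(out$levels_percent, c(100, 0, 50))
  expect_error(relative_protein_level(rec, 0), "must be > 0")

  # knockdown to 0.2x control expression recovers a ~20% median
  set.seed(31)
  sim <- records_from_ratios(rep(1, 200))
  sim$mean_red <- rlnorm(200, log(0.2 * 500), 0.4)
  out <- relative_protein_level(sim, untransfected_mean = 500)
  expect_lt(abs(out$median_percent - 20), 3)
})
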