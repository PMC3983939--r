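#' Parameters of a synthetic microscope scene
#'
#' Defines the statistical structure of a simulated field of fixed,
#' DNA-stained cells co-transfected with a green reference and a red
#' target-reporter plasmid:
#' \itemize{
#'   \item per-cell expression E is log-normal, spanning decades, as
#'     reporter expression does in transiently transfected cells;
#'   \item in transfected cells the noise-free green output is
#'     `green_gain * E * f` and red output `red_gain * E * (1 - k)`, so
#'     control cells (k = 0, f = 1) fall exactly on a line through the
#'     origin — the linear green-red coupling the ratio method relies on;
#'   \item a fraction of transfected cells is RNAi-insensitive (k treated
#'     as 0), reproducing the minority of unusually bright red outliers;
#'   \item untransfected cells carry DNA stain only; nuclear DNA staining
#'     is centre-bright with a ~40% falloff toward the rim, so an
#'     intensity threshold erodes dim rims rather than deleting whole
#'     dim nuclei;
#'   \item `shrna_gfp_bias` f models reduced EGFP output of
#'     hairpin-bearing plasmids, the bias the delta coefficient corrects;
#'   \item nuclei are non-overlapping, randomly rotated ellipses with
#'     areas uniform in `nucleus_area_range`;
#'   \item noise: optional Poisson shot noise on signal, Gaussian read
#'     noise, constant per-channel offset, 16-bit clipping.
#' }
#'
#' @param image_shape Integer (rows, cols) in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param n_cells Number of nuclei to place.
#' @param transfected_fraction Probability a cell is transfected.
#' @param expression_meanlog,expression_sdlog Log-normal parameters of E
#'   (arbitrary intensity units).
#' @param green_gain,red_gain Intensity per unit E in each channel.
#' @param knockdown_efficiency k in [0,1]: fraction by which red output is
#'   suppressed in the test condition.
#' @param outlier_fraction Probability a transfected cell is
#'   RNAi-insensitive.
#' @param shrna_gfp_bias f: multiplicative factor on green output in the
#'   test condition.
#' @param nucleus_area_range (min, max) nuclear area in um^2.
#' @param nucleus_eccentricity_max Maximum eccentricity of generated
#'   ellipses.
#' @param background_level Constant offset per channel (scalar or length-3
#'   vector ordered dna, green, red).
#' @param read_noise_sd Gaussian read noise SD (intensity units).
#' @param shot_noise Logical: apply Poisson noise to the signal.
#' @param dna_level Mean nuclear DNA-stain intensity.
#' @param dna_sdlog Log-scale SD of per-cell DNA-stain brightness.
#' @param seed Integer seed; scenes are bit-reproducible given
#'   params + condition.
#' @return A validated `scene_params` object.
#' @export
scene_params <- function(image_shape = c(512L, 512L),
                         pixel_size = 0.1,
                         n_cells = 150L,
                         transfected_fraction = 0.5,
                         expression_meanlog = 5,
                         expression_sdlog = 1,
                         green_gain = 1,
                         red_gain = 1,
                         knockdown_efficiency = 0,
                         outlier_fraction = 0.02,
                         shrna_gfp_bias = 1,
                         nucleus_area_range = c(1.3, 2.5),
                         nucleus_eccentricity_max = 0.7,
                         background_level = 100,
                         read_noise_sd = 5,
                         shot_noise = TRUE,
                         dna_level = 3000,
                         dna_sdlog = 0.1,
                         seed = 1L) {
  p <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
            n_cells = as.integer(n_cells),
            transfected_fraction = transfected_fraction,
            expression_meanlog = expression_meanlog,
            expression_sdlog = expression_sdlog,
            green_gain = green_gain, red_gain = red_gain,
            knockdown_efficiency = knockdown_efficiency,
            outlier_fraction = outlier_fraction,
            shrna_gfp_bias = shrna_gfp_bias,
            nucleus_area_range = nucleus_area_range,
            nucleus_eccentricity_max = nucleus_eccentricity_max,
            background_level = background_level,
            read_noise_sd = read_noise_sd,
            shot_noise = isTRUE(shot_noise),
            dna_level = dna_level, dna_sdlog = dna_sdlog,
            seed = as.integer(seed))
  .validate_scene_params(p)
  structure(p, class = "scene_params")
}

.validate_scene_params <- function(p) {
  prob_in_01 <- function(x) is.numeric(x) && length(x) == 1 &&
    is.finite(x) && x >= 0 && x <= 1
  if (length(p$image_shape) != 2L || any(p$image_shape < 8L))
    stop("image_shape must be two integers >= 8", call. = FALSE)
  if (!is.finite(p$pixel_size) || p$pixel_size <= 0)
    stop("pixel_size must be > 0", call. = FALSE)
  if (p$n_cells < 0L) stop("n_cells must be >= 0", call. = FALSE)
  for (f in c("transfected_fraction", "knockdown_efficiency",
              "outlier_fraction"))
    if (!prob_in_01(p[[f]]))
      stop(f, " must be in [0, 1]", call. = FALSE)
  for (f in c("green_gain", "red_gain", "read_noise_sd", "dna_level",
              "shrna_gfp_bias"))
    if (!is.numeric(p[[f]]) || any(p[[f]] < 0) || any(!is.finite(p[[f]])))
      stop(f, " must be finite and >= 0", call. = FALSE)
  if (!(length(p$background_level) %in% c(1L, 3L)) ||
      any(p$background_level < 0))
    stop("background_level must be a scalar or length-3 vector >= 0",
         call. = FALSE)
  ar <- p$nucleus_area_range
  if (length(ar) != 2L || !(ar[1] > 0) || !(ar[1] < ar[2]))
    stop("nucleus_area_range must satisfy 0 < min < max", call. = FALSE)
  if (!(p$nucleus_eccentricity_max >= 0 && p$nucleus_eccentricity_max < 1))
    stop("nucleus_eccentricity_max must be in [0, 1)", call. = FALSE)
  # capacity: each nucleus needs a clearance square around its major axis
  a_max <- sqrt((ar[2] / p$pixel_size^2) /
                  (pi * sqrt(1 - p$nucleus_eccentricity_max^2)))
  margin <- ceiling(a_max) + 2
  usable <- prod(pmax(0, p$image_shape - 2 * margin))
  if (p$n_cells > 0 && p$n_cells * (2 * a_max + 3)^2 > 0.7 * usable)
    stop("image too small to place ", p$n_cells,
         " non-overlapping nuclei; enlarge image_shape or reduce n_cells",
         call. = FALSE)
  invisible(p)
}

#' @export
print.scene_params <- function(x, ...) {
  cat("<scene_params> ", x$image_shape[1], "x", x$image_shape[2], " px @ ",
      x$pixel_size, " um/px, ", x$n_cells, " cells (",
      100 * x$transfected_fraction, "% transfected), k = ",
      x$knockdown_efficiency, ", f = ", x$shrna_gfp_bias,
      ", outliers = ", x$outlier_fraction, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# place n ellipse centres with pairwise clearance; bounded retries
.place_nuclei <- function(shape, a, max_attempts) {
  n <- length(a)
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; attempts <- 0L
  margin <- ceiling(max(a, 0)) + 2
  lo_r <- margin + 1; hi_r <- shape[1] - margin
  lo_c <- margin + 1; hi_c <- shape[2] - margin
  if (n > 0 && (hi_r <= lo_r || hi_c <= lo_c))
    stop("field too crowded: nuclei do not fit inside the image margins",
         call. = FALSE)
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("field too crowded: could not place ", n,
           " non-overlapping nuclei after ", max_attempts, " attempts",
           call. = FALSE)
    r <- stats::runif(1, lo_r, hi_r)
    c_ <- stats::runif(1, lo_c, hi_c)
    i <- placed + 1L
    if (placed > 0L) {
      d <- sqrt((rows[1:placed] - r)^2 + (cols[1:placed] - c_)^2)
      if (any(d <= a[1:placed] + a[i] + 3)) next
    }
    rows[i] <- r; cols[i] <- c_; placed <- i
  }
  cbind(row = rows, col = cols)
}

# pixels (indices into an nr x nc matrix) covered by a rotated ellipse,
# with the squared normalised elliptical radius of each pixel
.ellipse_pixels <- function(r0, c0, a, b, theta, nr, nc) {
  rr <- max(1L, floor(r0 - a)):min(nr, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(nc, ceiling(c0 + a))
  dr <- rep(rr, times = length(cc)) - r0
  dc <- rep(cc, each = length(rr)) - c0
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  rho2 <- (u / a)^2 + (v / b)^2
  inside <- rho2 <= 1
  ridx <- rep(rr, times = length(cc))[inside]
  cidx <- rep(cc, each = length(rr))[inside]
  list(idx = (cidx - 1L) * nr + ridx, rho2 = rho2[inside])
}

#' Generate one synthetic microscope field with ground truth
#'
#' Renders registered DNA / green / red channel images for one field under
#' the statistical model described in [scene_params()], together with a
#' per-cell ground-truth table. The DNA stain is present in every nucleus;
#' green and red signal only in transfected cells. `condition = "control"`
#' forces `knockdown_efficiency = 0` and `shrna_gfp_bias = 1` (empty-vector
#' co-transfection). Deterministic for fixed params + condition.
#'
#' @param params A [scene_params()].
#' @param condition `"test"` or `"control"`.
#' @param sample_id Field identifier.
#' @return list with `field` (a `field_image_set`) and `truth`
#'   (data.frame: cell_id, centroid_row, centroid_col, area_um2,
#'   expression, transfected, outlier, true_mean_green, true_mean_red).
#' @export
generate_scene <- function(params, condition = c("test", "control"),
                           sample_id = NULL) {
  stopifnot(inherits(params, "scene_params"))
  condition <- match.arg(condition)
  if (is.null(sample_id)) sample_id <- paste0("sim_", condition)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)

  k <- if (condition == "test") params$knockdown_efficiency else 0
  f <- if (condition == "test") params$shrna_gfp_bias else 1
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  bg <- rep(params$background_level, length.out = 3)  # dna, green, red
  n <- params$n_cells
  ps <- params$pixel_size

  dna <- matrix(0, nr, nc); green <- matrix(0, nr, nc)
  red <- matrix(0, nr, nc)

  if (n > 0) {
    area_um2 <- stats::runif(n, params$nucleus_area_range[1],
                             params$nucleus_area_range[2])
    ecc <- stats::runif(n, 0, params$nucleus_eccentricity_max)
    theta <- stats::runif(n, 0, pi)
    axis_a <- sqrt((area_um2 / ps^2) / (pi * sqrt(1 - ecc^2)))
    axis_b <- axis_a * sqrt(1 - ecc^2)
    centres <- .place_nuclei(c(nr, nc), axis_a, max(1000L, 200L * n))

    transfected <- stats::runif(n) < params$transfected_fraction
    outlier <- transfected & (stats::runif(n) < params$outlier_fraction)
    expression <- stats::rlnorm(n, params$expression_meanlog,
                                params$expression_sdlog)
    dna_cell <- params$dna_level * stats::rlnorm(n, 0, params$dna_sdlog)

    true_green <- ifelse(transfected, params$green_gain * expression * f, 0)
    true_red <- ifelse(transfected,
                       params$red_gain * expression *
                         ifelse(outlier, 1, 1 - k),
                       0)

    px_count <- integer(n)
    for (i in seq_len(n)) {
      ell <- .ellipse_pixels(centres[i, 1], centres[i, 2],
                             axis_a[i], axis_b[i], theta[i], nr, nc)
      idx <- ell$idx
      px_count[i] <- length(idx)
      # DNA stain is brightest at the nucleus centre and falls ~40%
      # toward the rim (chromatin density / defocus proxy); the expressed
      # fluorophores fill the nucleoplasm uniformly
      dna[idx] <- dna[idx] + dna_cell[i] * (1 - 0.4 * ell$rho2)
      if (transfected[i]) {
        green[idx] <- green[idx] + true_green[i]
        red[idx] <- red[idx] + true_red[i]
      }
    }
    truth <- data.frame(cell_id = seq_len(n),
                        centroid_row = centres[, 1],
                        centroid_col = centres[, 2],
                        area_um2 = px_count * ps^2,
                        expression = expression,
                        transfected = transfected,
                        outlier = outlier,
                        true_mean_green = true_green,
                        true_mean_red = true_red)
  } else {
    truth <- data.frame(cell_id = integer(), centroid_row = numeric(),
                        centroid_col = numeric(), area_um2 = numeric(),
                        expression = numeric(), transfected = logical(),
                        outlier = logical(), true_mean_green = numeric(),
                        true_mean_red = numeric())
  }

  noisy <- params$shot_noise || params$read_noise_sd > 0
  finish <- function(signal, offset) {
    img <- if (params$shot_noise) {
      matrix(stats::rpois(length(signal), signal), nrow(signal))
    } else signal
    img <- img + offset
    if (params$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, params$read_noise_sd)
    if (noisy) img <- round(img)   # integer camera counts
    pmin(pmax(img, 0), 65535)      # 16-bit clipping
  }
  field <- field_image_set(finish(dna, bg[1]), finish(green, bg[2]),
                           finish(red, bg[3]),
                           sample_id = sample_id, condition = condition,
                           pixel_size = ps)
  list(field = field, truth = truth)
}

#' Generate a paired synthetic knockdown experiment
#'
#' Produces test-arm and control-arm fields (plus one untransfected field
#' for background estimation) with independent per-field random substreams
#' derived from one seed. Test fields use the knockdown efficiency and
#' GFP bias in `params`; control fields force k = 0, f = 1.
#'
#' @param params A [scene_params()]; its own `seed` is ignored in favour
#'   of per-field substream seeds.
#' @param n_fields_test,n_fields_control Number of fields per arm (>= 1).
#' @param seed Master seed for the experiment.
#' @return A `synthetic_experiment`: lists `test` and `control` of
#'   `field_image_set`s, `truth_test`/`truth_control` (pooled data.frames
#'   with a `field` column), `untransfected` field, `params`, `seed`.
#' @export
generate_experiment <- function(params, n_fields_test = 1L,
                                n_fields_control = 1L, seed = 1L) {
  stopifnot(inherits(params, "scene_params"),
            n_fields_test >= 1L, n_fields_control >= 1L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L,
                    n_fields_test + n_fields_control + 1L)

  gen_arm <- function(n_fields, condition, seed_offset) {
    fields <- vector("list", n_fields)
    truths <- vector("list", n_fields)
    for (i in seq_len(n_fields)) {
      p_i <- params; p_i$seed <- sub[seed_offset + i]
      class(p_i) <- "scene_params"
      sc <- generate_scene(p_i, condition,
                           sample_id = sprintf("%s_%02d", condition, i))
      fields[[i]] <- sc$field
      sc$truth$field <- sc$field$sample_id
      truths[[i]] <- sc$truth
    }
    list(fields = fields, truth = do.call(rbind, truths))
  }

  test <- gen_arm(n_fields_test, "test", 0L)
  control <- gen_arm(n_fields_control, "control", n_fields_test)

  p_u <- params
  p_u$transfected_fraction <- 0
  p_u$seed <- sub[n_fields_test + n_fields_control + 1L]
  class(p_u) <- "scene_params"
  untransfected <- generate_scene(p_u, "control",
                                  sample_id = "untransfected")$field
  untransfected$condition <- "untransfected"

  structure(list(test = test$fields, control = control$fields,
                 truth_test = test$truth, truth_control = control$truth,
                 untransfected = untransfected,
                 params = params, seed = as.integer(seed)),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> ", length(x$test), " test + ",
      length(x$control), " control fields + 1 untransfected, seed = ",
      x$seed, "\n  k = ", x$params$knockdown_efficiency, ", f = ",
      x$params$shrna_gfp_bias, ", ", x$params$n_cells, " cells/field\n",
      sep = "")
  invisible(x)
}

#' Generator-predicted knockdown index
#'
#' The noise-free median R/G ratio of a simulated test arm is
#' `red_gain (1 - k) / (green_gain f)` (outlier cells do not move the
#' median while their fraction is below one half), and of a control arm
#' `red_gain / green_gain`. The predicted uncorrected KD index is
#' therefore `100 (1 - k) / f` and, after delta correction (delta
#' recovers f), `100 (1 - k)`.
#'
#' @param params A [scene_params()].
#' @return list with kd_corrected_percent, kd_uncorrected_percent,
#'   delta (= f), control_rg (= red_gain / green_gain).
#' @export
predicted_kd <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  k <- params$knockdown_efficiency; f <- params$shrna_gfp_bias
  list(kd_corrected_percent = 100 * (1 - k),
       kd_uncorrected_percent = 100 * (1 - k) / f,
       delta = f,
       control_rg = params$red_gain / params$green_gain)
}
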