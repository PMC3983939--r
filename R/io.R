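# schema version stamped into configs/manifests/results; loaders reject a
# different major version
RATIOKD_SCHEMA <- "1.0"

.check_schema <- function(version, what) {
  if (is.null(version)) return(invisible(TRUE))
  major <- function(v) strsplit(as.character(v), ".", fixed = TRUE)[[1]][1]
  if (major(version) != major(RATIOKD_SCHEMA))
    stop(what, " has schema version ", version, "; this build reads ",
         RATIOKD_SCHEMA, call. = FALSE)
  invisible(TRUE)
}

#' Write a field as a multi-page 16-bit grayscale TIFF
#'
#' Page order: DNA, green, red. Intensities are stored as 16-bit counts;
#' values are clipped to [0, 65535].
#'
#' @param field A `field_image_set`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image_set"))
  pages <- lapply(list(field$dna$pixels, field$green$pixels,
                       field$red$pixels),
                  function(m) pmin(pmax(m, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a field from TIFF
#'
#' Accepts either a 3-page grayscale TIFF (page order DNA, green, red) or,
#' given the path of any one of three single-page files suffixed
#' `_dna` / `_gfp` / `_rfp`, the three-file variant. Intensities are
#' returned as floating-point counts on the original 16-bit scale.
#'
#' @param path TIFF path (for the three-file variant, any of the three).
#' @param pixel_size Micrometres per pixel; overrides any TIFF resolution
#'   tag (configuration wins over metadata).
#' @param sample_id,condition Labels; default from the file name.
#' @return A `field_image_set`.
#' @export
read_field <- function(path, pixel_size = 1, sample_id = NULL,
                       condition = "unspecified") {
  if (is.null(sample_id))
    sample_id <- sub("(_dna|_gfp|_rfp)?\\.tiff?$", "", basename(path))
  base <- sub("(_dna|_gfp|_rfp)?\\.(tiff?)$", "", path)
  ext <- sub(".*\\.(tiff?)$", "\\1", path)
  three <- paste0(base, c("_dna", "_gfp", "_rfp"), ".", ext)
  if (all(file.exists(three)) && grepl("_(dna|gfp|rfp)\\.tiff?$", path)) {
    pages <- lapply(three, function(p) {
      pg <- tiff::readTIFF(p, all = TRUE)
      if (length(pg) != 1L)
        stop("format error: ", p, " must be a single-page grayscale TIFF",
             call. = FALSE)
      pg[[1]]
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 3L)
      stop("format error: expected a 3-page TIFF (DNA, green, red), got ",
           length(pages), " page(s) in ", path, call. = FALSE)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # tolerate stored gray+alpha
    round(p * 65535)
  })
  if (!all(vapply(pages, function(p) identical(dim(p), dim(pages[[1]])),
                  logical(1))))
    stop("format error: channel pages differ in shape", call. = FALSE)
  field_image_set(pages[[1]], pages[[2]], pages[[3]],
                  sample_id = sample_id, condition = condition,
                  pixel_size = pixel_size)
}

#' Write a synthetic experiment to disk
#'
#' Writes one multi-page TIFF and one ground-truth CSV per field, plus a
#' YAML manifest listing fields, conditions, seed and generator
#' parameters.
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entry <- function(f) list(file = paste0(f$sample_id, ".tif"),
                            condition = f$condition)
  fields <- c(experiment$test, experiment$control,
              list(experiment$untransfected))
  for (f in fields) write_field(f, file.path(dir, paste0(f$sample_id, ".tif")))
  utils::write.csv(experiment$truth_test,
                   file.path(dir, "truth_test.csv"), row.names = FALSE)
  utils::write.csv(experiment$truth_control,
                   file.path(dir, "truth_control.csv"), row.names = FALSE)
  manifest <- list(
    schema_version = RATIOKD_SCHEMA,
    seed = experiment$seed,
    pixel_size = experiment$params$pixel_size,
    params = unclass(experiment$params),
    fields = lapply(fields, entry))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Assay configuration bundle
#'
#' Collects the segmentation, gating and ratiometry options in one object
#' that round-trips losslessly through YAML.
#'
#' @param seg A [segmentation_config()].
#' @param gate A [gate_config()].
#' @param pixel_size Default micrometres per pixel for loaded images.
#' @param min_n Per-arm transfected-cell count below which a warning is
#'   emitted.
#' @param n_boot Bootstrap replicates for the KD confidence interval.
#' @param conf_level Bootstrap CI level.
#' @param mode `"two_plasmid"` or `"three_plasmid"`.
#' @param seed Seed for the bootstrap.
#' @return An `assay_config`.
#' @export
assay_config <- function(seg = segmentation_config(), gate = gate_config(),
                         pixel_size = 0.1, min_n = 300, n_boot = 2000,
                         conf_level = 0.95,
                         mode = c("two_plasmid", "three_plasmid"),
                         seed = 1L) {
  mode <- match.arg(mode)
  structure(list(seg = seg, gate = gate, pixel_size = pixel_size,
                 min_n = min_n, n_boot = n_boot, conf_level = conf_level,
                 mode = mode, seed = as.integer(seed)),
            class = "assay_config")
}

#' @rdname assay_config
#' @param config An `assay_config` to serialise.
#' @param path YAML path.
#' @export
write_assay_config <- function(config, path) {
  stopifnot(inherits(config, "assay_config"))
  yaml::write_yaml(list(schema_version = RATIOKD_SCHEMA,
                        seg = unclass(config$seg),
                        gate = unclass(config$gate),
                        pixel_size = config$pixel_size,
                        min_n = config$min_n, n_boot = config$n_boot,
                        conf_level = config$conf_level, mode = config$mode,
                        seed = config$seed),
                   path)
  invisible(path)
}

#' @rdname assay_config
#' @export
read_assay_config <- function(path) {
  y <- yaml::read_yaml(path)
  .check_schema(y$schema_version, "config file")
  assay_config(
    seg = do.call(segmentation_config, y$seg[!vapply(y$seg, is.null,
                                                     logical(1))]),
    gate = do.call(gate_config, y$gate[!vapply(y$gate, is.null,
                                               logical(1))]),
    pixel_size = y$pixel_size, min_n = y$min_n, n_boot = y$n_boot,
    conf_level = y$conf_level, mode = y$mode, seed = y$seed)
}

#' Read a run manifest
#'
#' A run manifest is a YAML file mapping condition labels (`test`,
#' `control`, `untransfected`, optionally `scramble_test` /
#' `scramble_control`) to lists of field TIFF paths (relative to the
#' manifest). Validation — existence of every referenced file and
#' presence of the conditions the mode requires — happens before any
#' image is read.
#'
#' @param path Manifest YAML path.
#' @param mode Analysis mode the manifest must support.
#' @return list of condition -> character vector of absolute paths.
#' @export
read_run_manifest <- function(path, mode = "two_plasmid") {
  y <- yaml::read_yaml(path)
  .check_schema(y$schema_version, "manifest")
  dir <- dirname(normalizePath(path))
  conditions <- y$conditions
  if (is.null(conditions))
    stop("manifest has no 'conditions' mapping", call. = FALSE)
  required <- c("test", "control", "untransfected")
  missing <- setdiff(required, names(conditions))
  if (length(missing))
    stop("manifest is missing required condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  has_scramble <- all(c("scramble_test", "scramble_control") %in%
                        names(conditions))
  out <- lapply(conditions, function(files) {
    paths <- file.path(dir, unlist(files))
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("manifest references missing file(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    paths
  })
  attr(out, "seed") <- y$seed
  attr(out, "has_scramble") <- has_scramble
  out
}

#' Run the full analysis pipeline from a manifest
#'
#' Loads every field referenced by the manifest, runs segmentation,
#' background estimation, measurement, gating and the KD index, and
#' writes a results bundle: per-cell CSVs per arm, sample statistics and
#' the KD result as JSON, R/G histogram CSVs, and QC counts. Identical
#' manifest + config (including seed) reproduce identical outputs.
#'
#' @param manifest Path to a run-manifest YAML (see
#'   [read_run_manifest()]).
#' @param config An `assay_config` or path to a config YAML.
#' @param out_dir Output directory.
#' @return The `kd_result`, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(manifest, config = assay_config(),
                         out_dir = "ratiokd_results") {
  if (is.character(config)) config <- read_assay_config(config)
  stopifnot(inherits(config, "assay_config"))
  m <- read_run_manifest(manifest, config$mode)

  load_arm <- function(cond)
    lapply(m[[cond]], read_field, pixel_size = config$pixel_size,
           condition = cond)
  test <- load_arm("test"); control <- load_arm("control")
  untr <- load_arm("untransfected")
  sct <- if (isTRUE(attr(m, "has_scramble"))) load_arm("scramble_test")
  scc <- if (isTRUE(attr(m, "has_scramble"))) load_arm("scramble_control")

  res <- kd_from_experiment(test, control, untr,
                            seg_config = config$seg, gate = config$gate,
                            scramble_test_fields = sct,
                            scramble_control_fields = scc,
                            mode = config$mode, min_n = config$min_n,
                            n_boot = config$n_boot,
                            conf_level = config$conf_level,
                            seed = config$seed)
  qc <- attr(res, "qc")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_kd_json(res, file.path(out_dir, "kd_result.json"))
  utils::write.csv(rg_histogram(res$test),
                   file.path(out_dir, "histogram_test.csv"),
                   row.names = FALSE)
  utils::write.csv(rg_histogram(res$control),
                   file.path(out_dir, "histogram_control.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Serialise a KD result to JSON
#'
#' @param res A `kd_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_kd_json <- function(res, path) {
  stopifnot(inherits(res, "kd_result"))
  qc <- attr(res, "qc")
  stats_list <- function(s) s[c("n", "median", "mean", "sd",
                                "outlier_fraction")]
  out <- list(
    schema_version = RATIOKD_SCHEMA,
    kd_percent = res$kd_percent, delta = res$delta,
    m_test = res$m_test, m_control = res$m_control,
    n_test = res$n_test, n_control = res$n_control,
    ci_low = res$ci_low, ci_high = res$ci_high,
    conf_level = res$conf_level, n_boot = res$n_boot, mode = res$mode,
    test = stats_list(res$test), control = stats_list(res$control))
  if (!is.null(qc))
    out$qc <- list(linearity_r_control = qc$linearity_control$r,
                   gfp_threshold = qc$gfp_threshold,
                   n_cells = as.list(qc$n_cells),
                   n_transfected = as.list(qc$n_transfected))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
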