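#' Gate configuration for transfectant selection
#'
#' Transfectants are cells whose background-subtracted mean green (EGFP)
#' intensity exceeds a threshold. The threshold is either preset
#' (reproducing any externally chosen value) or derived from the
#' untransfected control as `k_sd` standard deviations of its per-nucleus
#' green means above zero on the background-subtracted scale.
#'
#' @param gfp_threshold Preset threshold (background-subtracted scale).
#' @param gfp_threshold_mode `"from_control_k_sd"` (default) or `"preset"`.
#' @param k_sd SD multiplier for the control-derived threshold (default 3).
#' @return A `gate_config`.
#' @export
gate_config <- function(gfp_threshold = NA_real_,
                        gfp_threshold_mode = c("from_control_k_sd", "preset"),
                        k_sd = 3) {
  gfp_threshold_mode <- match.arg(gfp_threshold_mode)
  if (gfp_threshold_mode == "preset") {
    if (!is.finite(gfp_threshold) || gfp_threshold < 0)
      stop("preset mode requires gfp_threshold >= 0", call. = FALSE)
  }
  if (!is.finite(k_sd) || k_sd < 0) stop("k_sd must be >= 0", call. = FALSE)
  structure(list(gfp_threshold = gfp_threshold,
                 gfp_threshold_mode = gfp_threshold_mode, k_sd = k_sd),
            class = "gate_config")
}

#' Estimate channel backgrounds from untransfected fields
#'
#' Runs the segmentation pipeline on the DNA channel of one or more
#' untransfected fields and averages the per-nucleus mean green and red
#' intensities over all filtered nuclei. The standard deviations of those
#' per-nucleus means are retained for `from_control_k_sd` gating.
#'
#' @param untransfected_fields A `field_image_set` or list of them.
#' @param seg_config A [segmentation_config()].
#' @return A `background_estimate`: green_bg, red_bg, green_sd, red_sd,
#'   n_rois, source.
#' @export
estimate_background <- function(untransfected_fields,
                                seg_config = segmentation_config()) {
  if (inherits(untransfected_fields, "field_image_set"))
    untransfected_fields <- list(untransfected_fields)
  g <- numeric(); r <- numeric(); src <- character()
  for (f in untransfected_fields) {
    rois <- tryCatch({
      thr <- compute_dna_threshold(f$dna, seg_config)
      filter_nuclei(segment_nuclei(f$dna, thr), seg_config)
    }, error = function(e) NULL)  # a field with no foreground adds nothing
    if (is.null(rois) || nrow(rois$table) == 0L) next
    m <- .roi_channel_means(rois, f)
    g <- c(g, m$green); r <- c(r, m$red)
    src <- c(src, f$sample_id)
  }
  if (length(g) == 0L)
    stop("background estimation failed: no nuclei found in untransfected ",
         "field(s)", call. = FALSE)
  structure(list(green_bg = mean(g), red_bg = mean(r),
                 green_sd = stats::sd(g), red_sd = stats::sd(r),
                 n_rois = length(g), source = unique(src)),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat("<background_estimate> green ", signif(x$green_bg, 5), " (sd ",
      signif(x$green_sd, 4), "), red ", signif(x$red_bg, 5), " (sd ",
      signif(x$red_sd, 4), "), n = ", x$n_rois, " nuclei [",
      paste(x$source, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# raw per-ROI mean green/red intensities over the label image
.roi_channel_means <- function(rois, field) {
  lab <- rois$label_image
  if (any(dim(lab) != dim(field$green$pixels)))
    stop("ROI label image does not match field dimensions", call. = FALSE)
  labels <- rois$table$label
  idx <- which(lab > 0 & matrix(lab %in% labels, nrow(lab)))
  l <- lab[idx]
  g <- as.vector(tapply(field$green$pixels[idx], l, mean))
  r <- as.vector(tapply(field$red$pixels[idx], l, mean))
  ord <- match(labels, sort(unique(l)))
  list(green = g[ord], red = r[ord])
}

#' Measure background-subtracted per-cell intensities
#'
#' For each ROI, the mean green and red intensities over the nuclear mask
#' are computed and the channel background is subtracted; negative means
#' clamp to 0 (intensities are physical). The transfection flag and R/G
#' ratio are left unset; see [gate_transfectants()].
#'
#' @param field A `field_image_set`.
#' @param rois `nucleus_rois` derived from this field's DNA channel.
#' @param bg A `background_estimate`.
#' @return data.frame of `cell_record`s: field, label, mean_green,
#'   mean_red, transfected (NA), rg_ratio (NA).
#' @export
measure_cells <- function(field, rois, bg) {
  stopifnot(inherits(field, "field_image_set"),
            inherits(rois, "nucleus_rois"),
            inherits(bg, "background_estimate"))
  if (nrow(rois$table) == 0L)
    return(data.frame(field = character(), label = integer(),
                      mean_green = numeric(), mean_red = numeric(),
                      transfected = logical(), rg_ratio = numeric()))
  m <- .roi_channel_means(rois, field)
  data.frame(field = field$sample_id, label = rois$table$label,
             mean_green = pmax(0, m$green - bg$green_bg),
             mean_red = pmax(0, m$red - bg$red_bg),
             transfected = NA, rg_ratio = NA_real_)
}

#' Gate transfectants on green intensity and compute R/G ratios
#'
#' A cell is a transfectant when its background-subtracted mean green
#' intensity is strictly greater than the gate threshold. The R/G ratio
#' `mean_red / mean_green` is computed for transfectants only; gated-out
#' cells keep `rg_ratio = NA` and are excluded from all downstream
#' statistics.
#'
#' @param records Cell records from [measure_cells()] (rows may be pooled
#'   across fields).
#' @param gate A [gate_config()].
#' @param bg The `background_estimate` the records were measured with;
#'   required in `from_control_k_sd` mode.
#' @return The records with `transfected` and `rg_ratio` filled in; the
#'   applied threshold is attached as attribute `"gfp_threshold"`.
#' @export
gate_transfectants <- function(records, gate = gate_config(), bg = NULL) {
  thr <- if (gate$gfp_threshold_mode == "preset") {
    gate$gfp_threshold
  } else {
    if (is.null(bg))
      stop("from_control_k_sd gating needs the background estimate",
           call. = FALSE)
    gate$k_sd * bg$green_sd
  }
  records$transfected <- records$mean_green > thr
  records$rg_ratio <- ifelse(records$transfected & records$mean_green > 0,
                             records$mean_red / records$mean_green,
                             NA_real_)
  attr(records, "gfp_threshold") <- thr
  records
}

#' Relative endogenous protein level by immunofluorescence
#'
#' Normalises per-cell immunofluorescence intensities (carried in
#' `mean_red`) of transfected cells to the average intensity of
#' untransfected cells, in percent, and reports their median.
#'
#' @param if_records Cell records whose `mean_red` holds the
#'   immunofluorescence channel; only rows with `transfected == TRUE`
#'   are used (all rows if the flag is unset).
#' @param untransfected_mean Mean intensity of untransfected cells (> 0).
#' @return list with `levels_percent` (per-cell) and `median_percent`.
#' @export
relative_protein_level <- function(if_records, untransfected_mean) {
  if (!is.finite(untransfected_mean) || untransfected_mean <= 0)
    stop("untransfected_mean must be > 0", call. = FALSE)
  rec <- if_records
  if (!all(is.na(rec$transfected)))
    rec <- rec[which(rec$transfected), , drop = FALSE]
  lv <- 100 * rec$mean_red / untransfected_mean
  list(levels_percent = lv, median_percent = stats::median(lv))
}

#' Write per-cell records to CSV
#'
#' @param records Cell records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_csv <- function(records, path) {
  utils::write.csv(records[, c("field", "label", "mean_green", "mean_red",
                               "transfected", "rg_ratio")],
                   path, row.names = FALSE)
  invisible(path)
}
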