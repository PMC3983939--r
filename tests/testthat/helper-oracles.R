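# Independent oracles and small builders shared across tests.

# Exhaustive flood-fill connected-component labeling (8-neighbourhood),
# written as a plain BFS over a logical mask. Labels are assigned in
# raster (row-major) order of each component's first pixel, matching the
# contract of segment_nuclei(). Deliberately naive; used only on tiny
# images.
flood_fill_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  current <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    current <- current + 1L
    queue <- list(c(r, c)); lab[r, c] <- current
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- current
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# gated cell-record table straight from ratio values
records_from_ratios <- function(ratios, green = 100) {
  n <- length(ratios)
  data.frame(field = rep("fx", n), label = seq_len(n),
             mean_green = rep(green, length.out = n),
             mean_red = ratios * green,
             transfected = rep(TRUE, n), rg_ratio = ratios)
}

# sample_stats without the n < min_n warning noise
quiet_stats <- function(records, min_n = 1) summarize_sample(records, min_n)

# a small, fast parameter set for image-level tests; dots override defaults
small_params <- function(...) {
  args <- list(image_shape = c(256L, 256L), n_cells = 40L, seed = 1L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_params, args)
}

# disc mask helper for constructed segmentation fixtures
add_disc <- function(img, r0, c0, radius, value) {
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img)))
    if ((r - r0)^2 + (c - c0)^2 <= radius^2) img[r, c] <- value
  img
}
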