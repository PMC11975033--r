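## Region-masked axon quantification: per-section masked intensity sums
## (Qi = sum of Ri * Si), active-pixel region areas, and per-animal
## normalization to innervation fractions.

check_mask <- function(mask) {
  if (!all(mask %in% c(0, 1))) {
    stopf("region mask must be binary (0/1)",
          class = "atlastrace_validation_error")
  }
}

#' Masked signal sum within one region of one section
#'
#' Multiplies the binary region mask by the signal-channel intensities and
#' sums, i.e. sums the pixel intensities inside the masked region. Exact for
#' integer inputs.
#'
#' @param mask Binary matrix (the region mask).
#' @param image Non-negative intensity matrix of the same shape (the signal
#'   channel).
#' @return Scalar masked intensity sum.
#' @export
region_signal <- function(mask, image) {
  if (!identical(dim(mask), dim(image))) {
    stopf("mask and signal image dimensions differ (%s vs %s)",
          paste(dim(mask), collapse = "x"), paste(dim(image), collapse = "x"),
          class = "atlastrace_dimension_error")
  }
  check_mask(mask)
  if (any(image < 0) || any(!is.finite(image))) {
    stopf("signal image must be finite and non-negative",
          class = "atlastrace_validation_error")
  }
  sum(mask * image)
}

#' Region size as active pixels of the binary mask
#'
#' @param mask Binary matrix.
#' @return Count of 1-pixels.
#' @export
region_area <- function(mask) {
  check_mask(mask)
  sum(mask == 1)
}

#' Quantify masked axon signal for every manifest row
#'
#' Reads the per-(section, region) mask TIFF and the paired signal TIFF and
#' computes the masked intensity sum and active-pixel area. Overlapping
#' masks of distinct regions within a section are tolerated but reported
#' with a warning (overlap pixel count).
#'
#' @param manifest Data frame with columns `animal_id`, `section_id`,
#'   `region_id`, `mask_path`, `signal_path` (paths relative to `base_dir`).
#' @param base_dir Directory that manifest paths are relative to.
#' @return Data frame of per-section region signals: `animal_id`,
#'   `section_id`, `region_id`, `raw_sum`, `area_px`.
#' @export
quantify_sections <- function(manifest, base_dir = ".") {
  need <- c("animal_id", "section_id", "region_id", "mask_path", "signal_path")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    stopf("manifest lacks column(s): %s", paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(manifest)), function(r) {
    m <- manifest[r, ]
    mask <- read_image_tiff(file.path(base_dir, m$mask_path))
    sig <- read_image_tiff(file.path(base_dir, m$signal_path))
    data.frame(animal_id = m$animal_id, section_id = m$section_id,
               region_id = m$region_id,
               raw_sum = region_signal(mask, sig),
               area_px = region_area(mask),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ## warn on overlapping masks within a section
  for (sid in unique(manifest$section_id)) {
    sub <- manifest[manifest$section_id == sid, ]
    if (nrow(sub) < 2L) next
    acc <- NULL
    for (r in seq_len(nrow(sub))) {
      mask <- read_image_tiff(file.path(base_dir, sub$mask_path[r]))
      acc <- if (is.null(acc)) mask else acc + mask
    }
    n_over <- sum(acc > 1)
    if (n_over > 0) {
      warnf("section %s: region masks overlap on %d pixel(s)", sid, n_over)
    }
  }
  out
}

#' Aggregate per-section signals and normalize within animals
#'
#' Raw masked sums and areas are first summed across sections per
#' (animal, region); each region's total is then divided by the animal's
#' total across all regions to give the innervation fraction.
#'
#' @param section_signals Data frame with `animal_id`, `region_id`,
#'   `raw_sum`, `area_px` (per section; multiple rows per region allowed).
#' @return Data frame per (animal, region): `raw_sum`, `area_px`,
#'   `norm_fraction`; fractions per animal sum to 1.
#' @export
aggregate_and_normalize <- function(section_signals) {
  need <- c("animal_id", "region_id", "raw_sum", "area_px")
  missing <- setdiff(need, names(section_signals))
  if (length(missing)) {
    stopf("table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  agg <- stats::aggregate(cbind(raw_sum, area_px) ~ animal_id + region_id,
                          data = section_signals, FUN = sum)
  agg <- agg[order(agg$animal_id, agg$region_id), ]
  totals <- tapply(agg$raw_sum, agg$animal_id, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    stopf("animal(s) with zero total signal: %s (fractions undefined)",
          paste(zero, collapse = ", "),
          class = "atlastrace_normalization_error")
  }
  agg$norm_fraction <- agg$raw_sum / as.numeric(totals[as.character(agg$animal_id)])
  rownames(agg) <- NULL
  agg
}

## TIFF wrappers: the tiff package stores values scaled to [0, 1]; images
## are written 16-bit so integer counts up to 65535 round-trip exactly.
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  round(img * 65535)
}

write_image_tiff <- function(img, path) {
  if (max(img) > 65535) {
    stopf("intensity %g exceeds the 16-bit TIFF range", max(img))
  }
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
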