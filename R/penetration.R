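# Drug-field selection and penetration measurement.
#
# Per field: binarize the vessel channel, build the distance map, binarize the
# drug channel, extract spots, read each spot's nearest-vessel distance, and
# average. The field value is the mean over spots; the animal value is the
# mean over its three fields. Fields without vessels or without spots are
# flagged, never silently scored zero.

#' Select high-fluorescence drug fields on a section
#'
#' Windows of the drug-field area are scanned on a regular stride and scored
#' by total drug intensity over non-excluded pixels; windows with more than
#' `max_excluded_frac` excluded pixels are ineligible. The `k` best pairwise
#' non-overlapping windows are returned (raster-order tie-break). Necrosis
#' and staining-artifact regions enter through the exclusion mask.
#'
#' @param section_drug drug-intensity raster of the whole section.
#' @param pixel_pitch_um micrometres per pixel edge.
#' @param exclusion optional exclusion mask (TRUE = excluded).
#' @param field_area_mm2 window area (default 1.09 mm^2, the x100 field).
#' @param k number of fields (default 3).
#' @param stride_px scan stride; default one quarter of the window side.
#' @param max_excluded_frac eligibility cut on excluded-pixel fraction.
#' @return tibble like [find_hotspots()], with `score` = summed intensity and
#'   `excluded_frac` per window.
#' @export
select_drug_fields <- function(section_drug, pixel_pitch_um, exclusion = NULL,
                               field_area_mm2 = 1.09, k = 3L, stride_px = NULL,
                               max_excluded_frac = 0.5) {
  stopifnot(is.matrix(section_drug), pixel_pitch_um > 0, k >= 1)
  side <- max(1L, round(sqrt(field_area_mm2 * 1e6) / pixel_pitch_um))
  if (side > nrow(section_drug) || side > ncol(section_drug)) {
    stop_field_too_small(c(side, side), dim(section_drug))
  }
  if (is.null(stride_px)) stride_px <- max(1L, side %/% 4L)
  excl <- if (is.null(exclusion)) {
    matrix(FALSE, nrow(section_drug), ncol(section_drug))
  } else {
    stopifnot(nrow(exclusion) == nrow(section_drug),
              ncol(exclusion) == ncol(section_drug))
    unclass(exclusion)
  }
  signal <- section_drug
  signal[excl] <- 0

  sum_sig <- integral_image(signal)
  sum_exc <- integral_image(excl * 1)

  origins_r <- seq.int(1L, nrow(section_drug) - side + 1L, by = stride_px)
  origins_c <- seq.int(1L, ncol(section_drug) - side + 1L, by = stride_px)
  grid <- expand.grid(row = origins_r, col = origins_c)
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  score <- window_sum(sum_sig, grid$row, grid$col, side, side)
  excl_frac <- window_sum(sum_exc, grid$row, grid$col, side, side) / side^2
  eligible <- excl_frac <= max_excluded_frac
  if (!any(eligible)) stop_no_valid_field()
  score[!eligible] <- -Inf
  sel <- select_nonoverlapping(grid$row, grid$col, side, side, score, k)
  out <- tibble(
    row = grid$row[sel], col = grid$col[sel],
    window_height_px = side, window_width_px = side,
    score = score[sel], excluded_frac = excl_frac[sel]
  )
  class(out) <- c("perivasc_hotspots", class(out))
  out
}

# summed-area table padded with a zero row/column
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# sum of m over window with origin (r, c) and size h x w, from its padded SAT
window_sum <- function(sat, r, c, h, w) {
  sat[cbind(r + h, c + w)] - sat[cbind(r, c + w)] -
    sat[cbind(r + h, c)] + sat[cbind(r, c)]
}

#' Crop one selected window out of a field
#'
#' @param image a [field_image()].
#' @param window one row of a [select_drug_fields()] / [find_hotspots()] table.
#' @param magnification_tag tag for the cropped field.
#' @return a [field_image()] covering the window.
#' @export
crop_field <- function(image, window, magnification_tag = image$magnification_tag) {
  stopifnot(inherits(image, "field_image"), nrow(window) == 1)
  rr <- window$row:(window$row + window$window_height_px - 1L)
  cc <- window$col:(window$col + window$window_width_px - 1L)
  chans <- lapply(image$channels, function(ch) ch[rr, cc, drop = FALSE])
  field_image(chans,
    magnification_tag = magnification_tag,
    pixel_pitch_um = image$pixel_pitch_um, field_id = image$field_id
  )
}

#' Measure doxorubicin penetration in one field
#'
#' Pipeline: binarize vessels -> distance map -> binarize drug -> extract
#' spots -> per-spot nearest-vessel distance -> mean distance and spot count.
#' Excluded pixels contribute neither spots nor vessels. A field with no
#' vessel pixel or no detected spot is returned flagged (`flag` column), with
#' `mean_penetration_um = NA`; it is not scored zero, which would bias
#' penetration downward.
#'
#' @param field a [field_image()] with `drug` and `vessel` channels (and an
#'   optional `exclusion` channel, nonzero = excluded).
#' @param config a [perivasc_config()].
#' @return one-row tibble: `field_id`, `mean_penetration_um`, `spot_count`,
#'   `vessel_count`, `excluded_frac`, `drug_threshold`, `flag` (NA when the
#'   measurement is valid; otherwise `"no_vessel"` or `"no_spot"`).
#' @export
field_penetration <- function(field, config = perivasc_config()) {
  stopifnot(inherits(field, "field_image"), inherits(config, "perivasc_config"))
  drug <- get_channel(field, "drug")
  excl <- if ("exclusion" %in% names(field$channels)) {
    get_channel(field, "exclusion") > 0
  } else {
    matrix(FALSE, field$height_px, field$width_px)
  }

  vmask <- binarize_channel(field, "vessel",
    method = config$vessel_method,
    fixed_threshold = config$vessel_fixed_threshold, semantics = "vessel"
  )
  vmask_eff <- unclass(vmask) & !excl

  row0 <- tibble(
    field_id = field$field_id %||% NA_character_,
    mean_penetration_um = NA_real_,
    spot_count = 0L,
    vessel_count = count_vessels(vmask_eff, min_size_px = config$min_vessel_size),
    excluded_frac = mean(excl),
    drug_threshold = NA_real_,
    flag = NA_character_
  )
  if (!any(vmask_eff)) {
    row0$flag <- "no_vessel"
    return(row0)
  }
  dmap <- compute_distance_map(vmask_eff, field$pixel_pitch_um)

  dmask <- tryCatch(
    binarize_channel(field, "drug",
      method = config$drug_method,
      fixed_threshold = config$drug_fixed_threshold, semantics = "drug"
    ),
    perivasc_degenerate_histogram = function(e) NULL
  )
  if (is.null(dmask)) { # constant drug channel: nothing above background
    row0$flag <- "no_spot"
    return(row0)
  }
  row0$drug_threshold <- attr(dmask, "threshold")
  spots <- extract_spots(unclass(dmask) & !excl, drug,
                         min_spot_size = config$min_spot_size)
  spots <- spot_distances(spots, dmap)
  row0$spot_count <- nrow(spots)
  if (nrow(spots) == 0) {
    row0$flag <- "no_spot"
    return(row0)
  }
  row0$mean_penetration_um <- mean(spots$nearest_vessel_distance_um)
  row0
}

#' Aggregate three field measurements into an animal measurement
#'
#' @param fields tibble of exactly three unflagged [field_penetration()] rows.
#' @return one-row tibble: `penetration_um` (mean of the 3 field means),
#'   `spot_count_mean`, `n_fields`.
#' @export
animal_penetration <- function(fields) {
  stopifnot(is.data.frame(fields))
  if (nrow(fields) != 3L) {
    stop_insufficient_fields(sprintf("got %d fields", nrow(fields)))
  }
  if (any(!is.na(fields$flag))) {
    stop_insufficient_fields(paste(
      "flagged fields:",
      paste(fields$flag[!is.na(fields$flag)], collapse = ", ")
    ))
  }
  tibble(
    penetration_um = mean(fields$mean_penetration_um),
    spot_count_mean = mean(fields$spot_count),
    n_fields = 3L
  )
}

#' Fraction of tissue exposed to detectable drug, by distance band
#'
#' For each distance band, the fraction of non-excluded pixels whose drug
#' intensity exceeds the detection threshold. Quantifies the observation that
#' tissue in avascular and adjacent regions sees no detectable drug.
#'
#' @param field a [field_image()] with `drug` and `vessel` channels.
#' @param config a [perivasc_config()]; supplies the drug threshold rule and
#'   the distance bands.
#' @return tibble: `band_lo_um`, `band_hi_um`, `n_px`, `exposed_fraction`.
#' @export
exposed_fraction <- function(field, config = perivasc_config()) {
  stopifnot(inherits(field, "field_image"))
  drug <- get_channel(field, "drug")
  excl <- if ("exclusion" %in% names(field$channels)) {
    get_channel(field, "exclusion") > 0
  } else {
    matrix(FALSE, field$height_px, field$width_px)
  }
  vmask <- binarize_channel(field, "vessel",
    method = config$vessel_method,
    fixed_threshold = config$vessel_fixed_threshold, semantics = "vessel"
  )
  vmask_eff <- unclass(vmask) & !excl
  if (!any(vmask_eff)) stop_no_vessel()
  dmap <- compute_distance_map(vmask_eff, field$pixel_pitch_um)

  thr <- switch(config$drug_method,
    nonzero = 0,
    fixed = config$drug_fixed_threshold,
    otsu = tryCatch(otsu_threshold(drug),
                    perivasc_degenerate_histogram = function(e) Inf)
  )
  exposed <- drug > thr

  keep <- !as.vector(excl)
  d <- as.vector(dmap)[keep]
  e <- as.vector(exposed)[keep]
  n_bins <- max(1L, ceiling(config$band_max_um / config$band_width_um))
  bin <- floor(d / config$band_width_um) + 1L
  in_range <- bin <= n_bins
  n_px <- tabulate(bin[in_range], nbins = n_bins)
  n_exp <- tabulate(bin[in_range & e], nbins = n_bins)
  tibble(
    band_lo_um = (seq_len(n_bins) - 1) * config$band_width_um,
    band_hi_um = seq_len(n_bins) * config$band_width_um,
    n_px = n_px,
    exposed_fraction = ifelse(n_px > 0, n_exp / n_px, NA_real_)
  )
}
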