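# Spot extraction: 8-connected components of the drug mask.

#' Label 8-connected components of a mask
#'
#' Diagonal neighbours connect. Labels are 1..n in first-encounter
#' (column-major) order; background is 0.
#'
#' @param mask logical matrix.
#' @return integer matrix with attribute `n_components`.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  .label_components_8(unclass(mask))
}

#' Extract fluorescent spots from a binary drug mask
#'
#' Spots are 8-connected components of the mask with area at least
#' `min_spot_size` pixels. The centroid is the unweighted mean (row, col) of
#' the component's pixels, in continuous 1-based pixel coordinates;
#' `peak_intensity` is the maximum of the intensity raster over the component.
#'
#' @param mask drug `binary_mask` (or logical matrix).
#' @param intensity numeric raster on the same grid (used for peak intensity);
#'   may be `NULL`.
#' @param min_spot_size minimum component area in pixels (>= 1). Default 4 px
#'   suppresses single-pixel noise.
#' @return tibble of class `perivasc_spots` with columns `spot_id`, `row`,
#'   `col`, `area_px`, `peak_intensity`, `nearest_vessel_distance_um` (NA
#'   until [spot_distances()] fills it).
#' @export
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
#' extract_spots(m, min_spot_size = 1)
extract_spots <- function(mask, intensity = NULL, min_spot_size = 4L) {
  stopifnot(is.matrix(mask), is.logical(mask), min_spot_size >= 1)
  if (!is.null(intensity)) {
    stopifnot(is.matrix(intensity),
              nrow(intensity) == nrow(mask), ncol(intensity) == ncol(mask))
  }
  lab <- label_components(mask)
  k <- attr(lab, "n_components")
  if (k == 0L) {
    return(new_spots(tibble(
      spot_id = integer(0), row = numeric(0), col = numeric(0),
      area_px = integer(0), peak_intensity = numeric(0),
      nearest_vessel_distance_um = numeric(0)
    )))
  }
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  area <- tabulate(labs, nbins = k)
  cr <- as.numeric(rowsum(rows, labs)) / area
  cc <- as.numeric(rowsum(cols, labs)) / area
  peak <- if (is.null(intensity)) rep(NA_real_, k) else {
    as.numeric(tapply(intensity[idx], labs, max))
  }
  out <- tibble(
    spot_id = seq_len(k), row = cr, col = cc,
    area_px = as.integer(area), peak_intensity = peak,
    nearest_vessel_distance_um = NA_real_
  )
  out <- out[out$area_px >= min_spot_size, , drop = FALSE]
  out$spot_id <- seq_len(nrow(out))
  new_spots(out)
}

new_spots <- function(x) {
  class(x) <- c("perivasc_spots", class(x))
  x
}

#' Histogram of spot nearest-vessel distances
#'
#' @param object a `perivasc_spots` tibble with distances assigned.
#' @param binwidth histogram bin width in micrometres.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.perivasc_spots <- function(object, binwidth = 10, ...) {
  stopifnot(any(!is.na(object$nearest_vessel_distance_um)))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$nearest_vessel_distance_um)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "firebrick", colour = "white") +
    ggplot2::labs(
      x = "distance to nearest vessel (µm)", y = "spots",
      title = "Perivascular spot distances"
    )
}
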