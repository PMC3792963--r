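# Weidner hotspot microvessel density (MVD).
#
# The section is scanned at low magnification for the areas of most intense
# vascularization ("hotspots"); individual microvessels — any separated single
# endothelial cell or contiguous stained cluster, lumen not required — are
# then counted in three different high-magnification fields, and the animal's
# MVD is the mean of the three counts.

#' Count microvessels in a mask
#'
#' A microvessel is one 8-connected component of the vessel mask with area at
#' least `min_size_px`; a contiguous cluster counts once. Components with any
#' pixel inside the exclusion mask are not counted.
#'
#' @param vessels vessel `binary_mask` (or logical matrix).
#' @param exclusion optional exclusion mask (TRUE = excluded) on the same grid.
#' @param min_size_px minimum countable component area (default 4 px).
#' @return integer vessel count.
#' @export
count_vessels <- function(vessels, exclusion = NULL, min_size_px = 4L) {
  stopifnot(is.matrix(vessels), is.logical(vessels))
  lab <- label_components(vessels)
  k <- attr(lab, "n_components")
  if (k == 0L) return(0L)
  area <- tabulate(lab[lab > 0L], nbins = k)
  ok <- area >= min_size_px
  if (!is.null(exclusion)) {
    stopifnot(nrow(exclusion) == nrow(vessels), ncol(exclusion) == ncol(vessels))
    touched <- unique(lab[as.vector(exclusion) & lab > 0L])
    ok[touched] <- FALSE
  }
  sum(ok)
}

#' Locate vascular hotspots by sliding-window scan
#'
#' Every window position on a regular stride is scored by the microvessel
#' count restricted to the window; the `k` highest-scoring pairwise
#' non-overlapping windows are returned, ties broken by raster order
#' (smallest row, then column).
#'
#' @param vessels vessel mask on the low-magnification grid.
#' @param pixel_pitch_um micrometres per pixel edge of that grid.
#' @param window_area_mm2 area of the counting window (default 0.27 mm^2, the
#'   x200 field).
#' @param k number of hotspot windows (default 3).
#' @param stride_px scan stride; default one quarter of the window side.
#' @param min_size_px passed to [count_vessels()].
#' @return tibble of class `perivasc_hotspots`: `row`, `col` (window origin,
#'   1-based), `window_height_px`, `window_width_px`, `score`, sorted by
#'   non-increasing score.
#' @export
find_hotspots <- function(vessels, pixel_pitch_um, window_area_mm2 = 0.27,
                          k = 3L, stride_px = NULL, min_size_px = 4L) {
  stopifnot(is.matrix(vessels), is.logical(vessels), k >= 1,
            pixel_pitch_um > 0, window_area_mm2 > 0)
  side <- max(1L, round(sqrt(window_area_mm2 * 1e6) / pixel_pitch_um))
  if (side > nrow(vessels) || side > ncol(vessels)) {
    stop_field_too_small(c(side, side), dim(vessels))
  }
  if (is.null(stride_px)) stride_px <- max(1L, side %/% 4L)
  origins_r <- seq.int(1L, nrow(vessels) - side + 1L, by = stride_px)
  origins_c <- seq.int(1L, ncol(vessels) - side + 1L, by = stride_px)
  grid <- expand.grid(row = origins_r, col = origins_c)
  # raster order: row varies fastest within col in expand.grid; reorder to
  # (row, col) lexicographic so the documented tie-break is explicit
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  score <- vapply(seq_len(nrow(grid)), function(i) {
    r <- grid$row[i]; c0 <- grid$col[i]
    count_vessels(vessels[r:(r + side - 1L), c0:(c0 + side - 1L), drop = FALSE],
                  min_size_px = min_size_px)
  }, integer(1))
  sel <- select_nonoverlapping(grid$row, grid$col, side, side, score, k)
  out <- tibble(
    row = grid$row[sel], col = grid$col[sel],
    window_height_px = side, window_width_px = side,
    score = as.numeric(score[sel])
  )
  class(out) <- c("perivasc_hotspots", class(out))
  out
}

# greedy top-k pairwise non-overlapping windows; candidates must already be in
# raster order so that ties resolve to smallest (row, col)
select_nonoverlapping <- function(rows, cols, h, w, score, k) {
  ord <- order(-score, rows, cols)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= k) break
    overlaps <- any(
      rows[i] < rows[chosen] + h & rows[chosen] < rows[i] + h &
      cols[i] < cols[chosen] + w & cols[chosen] < cols[i] + w
    )
    if (!overlaps) chosen <- c(chosen, i)
  }
  chosen
}

#' Microvessel density of one animal
#'
#' @param field_counts exactly three per-field microvessel counts.
#' @return tibble with `count_1..count_3` and `mvd`, their arithmetic mean.
#' @export
#' @examples
#' mvd_for_animal(c(10, 12, 14))$mvd # 12
mvd_for_animal <- function(field_counts) {
  if (length(field_counts) != 3L || anyNA(field_counts)) {
    stop_insufficient_fields(sprintf(
      "got %d vessel counts, need 3", sum(!is.na(field_counts))
    ))
  }
  stopifnot(all(field_counts >= 0))
  tibble(
    count_1 = field_counts[1], count_2 = field_counts[2],
    count_3 = field_counts[3], mvd = mean(field_counts)
  )
}
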