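# Calibrated multi-channel microscope fields.
#
# A field is the unit of measurement: a set of co-registered single-channel
# rasters (drug auto-fluorescence, CD31 vessel stain, optional nuclear stain,
# optional exclusion mask) on one pixel grid, together with the physical
# calibration that converts pixels to micrometres. Magnification only enters
# through its printed field area; pixel pitch is derived from area and grid
# size assuming square pixels.

# printed field areas (mm^2) per magnification tag; these scale as the inverse
# square of magnification within rounding
.field_areas_mm2 <- c(x40 = 6.82, x100 = 1.09, x200 = 0.27)

#' Printed field area for a magnification tag
#'
#' @param magnification_tag one of `"x40"`, `"x100"`, `"x200"`.
#' @return field area in mm^2.
#' @export
#' @examples
#' magnification_area_mm2("x100") # 1.09
magnification_area_mm2 <- function(magnification_tag) {
  magnification_tag <- match.arg(magnification_tag, names(.field_areas_mm2))
  unname(.field_areas_mm2[[magnification_tag]])
}

#' Derive pixel pitch from field area and grid size
#'
#' Assumes square pixels: `pitch = sqrt(area / (width * height))`.
#'
#' @param field_area_mm2 field area in mm^2.
#' @param width_px,height_px grid dimensions in pixels.
#' @return pixel pitch in micrometres per pixel edge.
#' @export
#' @examples
#' derive_pixel_pitch(1.09, 1024, 1024) # ~1.0196 um/px
derive_pixel_pitch <- function(field_area_mm2, width_px, height_px) {
  stopifnot(field_area_mm2 > 0, width_px >= 1, height_px >= 1)
  sqrt(field_area_mm2 * 1e6 / (width_px * height_px))
}

#' Construct a calibrated multi-channel field
#'
#' Channels are numeric matrices indexed `[row, col]` (1-based); all channels
#' must share one grid. Non-drug channels on a different grid are first
#' resampled to the drug channel's grid with [resample_to_grid()], mirroring
#' the overlay step used when a vessel image and a drug image of the same
#' field are captured at different camera settings.
#'
#' Exactly one of `pixel_pitch_um` and `field_area_mm2` may be omitted; the
#' other is derived assuming square pixels. When both are given they must
#' agree within 2%.
#'
#' @param channels named list of numeric matrices; conventional names are
#'   `"drug"`, `"vessel"`, `"nuclear"`, `"exclusion"`.
#' @param magnification_tag `"x40"`, `"x100"` or `"x200"`; supplies the
#'   default field area (6.82, 1.09, 0.27 mm^2) when `field_area_mm2` is
#'   missing.
#' @param pixel_pitch_um micrometres per pixel edge (square pixels).
#' @param field_area_mm2 field area in mm^2.
#' @param field_id optional identifier carried into measurement tables.
#' @return a `field_image` object.
#' @export
#' @examples
#' fi <- field_image(
#'   channels = list(drug = matrix(0, 64, 64), vessel = matrix(0, 64, 64)),
#'   magnification_tag = "x100"
#' )
#' fi$pixel_pitch_um
field_image <- function(channels, magnification_tag = "x100",
                        pixel_pitch_um = NULL, field_area_mm2 = NULL,
                        field_id = NULL) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    abort("`channels` must be a non-empty named list of matrices.")
  }
  magnification_tag <- match.arg(magnification_tag, names(.field_areas_mm2))

  ref <- channels[[1L]]
  if (!is.matrix(ref)) abort("Each channel must be a matrix.")
  nr <- nrow(ref); nc <- ncol(ref)
  # align any stray channel to the reference grid (nearest-neighbour)
  channels <- lapply(channels, function(ch) {
    if (!is.matrix(ch)) abort("Each channel must be a matrix.")
    if (nrow(ch) != nr || ncol(ch) != nc) resample_to_grid(ch, nc, nr) else ch
  })
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (anyNA(ch) || any(!is.finite(ch)) || any(ch < 0)) {
      abort(sprintf("Channel '%s' must be finite and non-negative.", nm))
    }
  }

  if (is.null(field_area_mm2) && is.null(pixel_pitch_um)) {
    field_area_mm2 <- magnification_area_mm2(magnification_tag)
  }
  if (is.null(pixel_pitch_um)) {
    pixel_pitch_um <- derive_pixel_pitch(field_area_mm2, nc, nr)
  }
  if (is.null(field_area_mm2)) {
    field_area_mm2 <- nr * nc * pixel_pitch_um^2 / 1e6
  }
  if (pixel_pitch_um <= 0) abort("`pixel_pitch_um` must be > 0.")
  implied_mm2 <- nr * nc * pixel_pitch_um^2 / 1e6
  if (abs(implied_mm2 - field_area_mm2) / field_area_mm2 > 0.02) {
    abort(sprintf(
      "Pixel pitch implies a field area of %.4f mm^2, which differs from the stated %.4f mm^2 by more than 2%%.",
      implied_mm2, field_area_mm2
    ))
  }

  structure(
    list(
      channels = channels,
      width_px = nc, height_px = nr,
      pixel_pitch_um = pixel_pitch_um,
      magnification_tag = magnification_tag,
      field_area_mm2 = field_area_mm2,
      field_id = field_id
    ),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf(
    "<field_image%s> %d x %d px @ %.4f um/px (%s, %.2f mm^2)\n  channels: %s\n",
    if (is.null(x$field_id)) "" else paste0(" ", x$field_id),
    x$width_px, x$height_px, x$pixel_pitch_um, x$magnification_tag,
    x$field_area_mm2, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Fetch a channel raster, erroring informatively when absent
#'
#' @param image a [field_image()].
#' @param channel channel name.
#' @return the channel matrix.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "field_image"))
  if (!channel %in% names(image$channels)) {
    stop_missing_channel(channel, names(image$channels))
  }
  image$channels[[channel]]
}

#' Nearest-neighbour resampling of a raster to a target grid
#'
#' Source pixel for target pixel `(i, j)` is chosen by index mapping
#' `src = floor((i - 1) * nr_src / nr_tgt) + 1` (and likewise for columns), so
#' exact integer upsampling replicates each source pixel into a block and
#' binary inputs stay binary. Identical target dimensions return the input
#' unchanged.
#'
#' @param raster numeric or logical matrix.
#' @param target_width_px,target_height_px target grid size (>= 1).
#' @return resampled matrix of the same storage mode.
#' @export
resample_to_grid <- function(raster, target_width_px, target_height_px) {
  stopifnot(is.matrix(raster), target_width_px >= 1, target_height_px >= 1)
  nr <- nrow(raster); nc <- ncol(raster)
  if (nr == target_height_px && nc == target_width_px) return(raster)
  ri <- floor((seq_len(target_height_px) - 1) * nr / target_height_px) + 1L
  ci <- floor((seq_len(target_width_px) - 1) * nc / target_width_px) + 1L
  raster[ri, ci, drop = FALSE]
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
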