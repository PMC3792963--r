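# TIFF channel I/O.
#
# Channels travel as single-page 16-bit grayscale TIFF. Intensities are
# stored relative to a fixed full scale of 1024 intensity units, giving a
# quantization step of ~0.016 units — far below any threshold the pipeline
# uses. Exclusion masks are binary TIFFs; any nonzero pixel is excluded.

.tiff_full_scale <- 1024

#' Write an intensity raster as 16-bit grayscale TIFF
#'
#' @param x numeric matrix of non-negative intensities (full scale 1024).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  v <- pmin(pmax(x / .tiff_full_scale, 0), 1)
  ok <- tryCatch(
    tiff::writeTIFF(v, path, bits.per.sample = 16L),
    error = function(e) stop_io_failure(conditionMessage(e))
  )
  invisible(path)
}

#' Read a grayscale TIFF channel back onto the 1024 full scale
#'
#' @param path TIFF path (8- or 16-bit grayscale; the first page of a
#'   multi-page file).
#' @return numeric matrix of intensities.
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop_io_failure(paste("No such image file:", path))
  v <- tryCatch(tiff::readTIFF(path),
                error = function(e) stop_io_failure(conditionMessage(e)))
  if (is.list(v)) v <- v[[1]]
  if (length(dim(v)) == 3) v <- v[, , 1] # collapse any extra plane
  v * .tiff_full_scale
}

#' Read a manifest row's channels into a field
#'
#' @param record one manifest row (`drug_path`, `vessel_path`, optional
#'   `exclusion_path`, `pixel_pitch_um`, `magnification_tag`).
#' @param base_dir directory the manifest's relative paths resolve against.
#' @return a [field_image()].
#' @export
read_manifest_field <- function(record, base_dir = ".") {
  stopifnot(nrow(record) == 1)
  chans <- list(
    drug = read_channel_tiff(file.path(base_dir, record$drug_path)),
    vessel = read_channel_tiff(file.path(base_dir, record$vessel_path))
  )
  if (!is.null(record$exclusion_path) && !is.na(record$exclusion_path)) {
    chans$exclusion <- read_channel_tiff(file.path(base_dir, record$exclusion_path))
  }
  field_image(chans,
    magnification_tag = record$magnification_tag,
    pixel_pitch_um = record$pixel_pitch_um,
    field_id = sprintf("%s_f%d", record$animal_id, record$field)
  )
}
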