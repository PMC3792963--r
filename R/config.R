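# Run configuration: every tunable of the measurement pipeline in one place,
# round-trippable through YAML.

#' Measurement configuration
#'
#' @param vessel_method binarization rule for the vessel channel. Default
#'   `"nonzero"`: CD31 images arrive pre-masked (vessels white on a zero
#'   background), so any non-zero pixel is vessel. Use `"otsu"` or `"fixed"`
#'   for raw stain intensity images.
#' @param drug_method binarization rule for the drug channel. Default
#'   `"otsu"`: drug auto-fluorescence is a raw intensity image with no
#'   calibrated cut.
#' @param vessel_fixed_threshold,drug_fixed_threshold numeric cuts used when
#'   the corresponding method is `"fixed"`.
#' @param min_spot_size minimum drug-spot area in pixels (default 4).
#' @param min_vessel_size minimum countable vessel-component area (default 4).
#' @param mvd_window_area_mm2 vessel-counting window (default 0.27 mm^2, the
#'   x200 field).
#' @param drug_field_area_mm2 drug-field window (default 1.09 mm^2, the x100
#'   field).
#' @param lowmag_area_mm2 low-magnification scan area (default 6.82 mm^2, the
#'   x40 field).
#' @param stride_frac hotspot scan stride as a fraction of the window side
#'   (default 0.25).
#' @param k_fields number of fields per animal (default 3).
#' @param band_width_um,band_max_um distance bands for exposure summaries
#'   (default 25 um bands to 250 um).
#' @param max_excluded_frac a candidate field with more than this fraction of
#'   excluded pixels is ineligible (default 0.5).
#' @param seed integer master seed for any stochastic step.
#' @return a list of class `perivasc_config`.
#' @export
perivasc_config <- function(vessel_method = "nonzero",
                            drug_method = "otsu",
                            vessel_fixed_threshold = NULL,
                            drug_fixed_threshold = NULL,
                            min_spot_size = 4L,
                            min_vessel_size = 4L,
                            mvd_window_area_mm2 = 0.27,
                            drug_field_area_mm2 = 1.09,
                            lowmag_area_mm2 = 6.82,
                            stride_frac = 0.25,
                            k_fields = 3L,
                            band_width_um = 25,
                            band_max_um = 250,
                            max_excluded_frac = 0.5,
                            seed = 1L) {
  cfg <- list(
    vessel_method = match.arg(vessel_method, c("nonzero", "otsu", "fixed")),
    drug_method = match.arg(drug_method, c("nonzero", "otsu", "fixed")),
    vessel_fixed_threshold = vessel_fixed_threshold,
    drug_fixed_threshold = drug_fixed_threshold,
    min_spot_size = as.integer(min_spot_size),
    min_vessel_size = as.integer(min_vessel_size),
    mvd_window_area_mm2 = mvd_window_area_mm2,
    drug_field_area_mm2 = drug_field_area_mm2,
    lowmag_area_mm2 = lowmag_area_mm2,
    stride_frac = stride_frac,
    k_fields = as.integer(k_fields),
    band_width_um = band_width_um,
    band_max_um = band_max_um,
    max_excluded_frac = max_excluded_frac,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$min_spot_size >= 1, cfg$min_vessel_size >= 1,
    cfg$stride_frac > 0, cfg$k_fields >= 1,
    cfg$band_width_um > 0, cfg$band_max_um > 0,
    cfg$max_excluded_frac >= 0, cfg$max_excluded_frac <= 1
  )
  structure(cfg, class = "perivasc_config")
}

#' Read / write a configuration as YAML
#'
#' Configurations re-serialize losslessly: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg a [perivasc_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `perivasc_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "perivasc_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io_failure(paste("No such config file:", path))
  raw <- yaml::read_yaml(path)
  do.call(perivasc_config, raw)
}
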