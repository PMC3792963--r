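# Whole-study simulation: 4 treatment arms x 2 sacrifice time points x
# animals x fields, with deterministic per-field sub-seeds so any single field
# is regenerable in isolation.

#' Default arm parameters
#'
#' Per-arm, per-time-point penetration scale (lambda, um) and expected spot
#' count, parameterized from the reported group summaries of the rabbit VX2
#' study the simulator emulates: arm 1 = intravenous doxorubicin, arm 2 =
#' intraarterial infusion, arm 3 = intraarterial + embolization, arm 4 =
#' doxorubicin/Lipiodol intraarterial + embolization. These are simulator
#' inputs (the conditions being emulated), not pipeline outputs.
#'
#' @return tibble: `group`, `time_point`, `lambda_um`, `spot_rate`.
#' @export
default_arm_params <- function() {
  tibble(
    group = rep(1:4, each = 2),
    time_point = rep(c("10min", "4h"), 4),
    lambda_um = c(12.14, 7.36, 40.54, 32.68, 76.29, 72.37, 38.21, 81.16),
    spot_rate = c(235.75, 75, 2070.5, 1137, 3130.75, 3190, 1912, 3681.5)
  )
}

#' Study design for the simulator
#'
#' @param arm_params tibble like [default_arm_params()] (`group`,
#'   `time_point`, `lambda_um`, `spot_rate`).
#' @param animals_per_cell animals per (group x time point) cell (default 4,
#'   i.e. 8 per group split over two sacrifice times).
#' @param fields_per_animal fields measured per animal (default 3).
#' @param width_px,height_px,pixel_pitch_um field geometry; defaults give the
#'   1.09 mm^2 x100 field at 1024 x 1024.
#' @param spot_rate_scale multiplier on all spot rates; lets a study be run
#'   at reduced spot load (and correspondingly reduced field size) without
#'   touching the penetration scales.
#' @param field_spec_overrides named list of [synthetic_field_spec()]
#'   arguments applied to every field (e.g. vessel density, noise).
#' @param master_seed integer; all per-field seeds derive from it.
#' @return list of class `study_design`.
#' @export
study_design <- function(arm_params = default_arm_params(),
                         animals_per_cell = 4L,
                         fields_per_animal = 3L,
                         width_px = 1024L, height_px = 1024L,
                         pixel_pitch_um = NULL,
                         spot_rate_scale = 1,
                         field_spec_overrides = list(),
                         master_seed = 1L) {
  stopifnot(
    is.data.frame(arm_params),
    all(c("group", "time_point", "lambda_um", "spot_rate") %in% names(arm_params)),
    all(arm_params$lambda_um > 0), all(arm_params$spot_rate >= 0),
    animals_per_cell >= 0, fields_per_animal >= 1, spot_rate_scale > 0
  )
  if (is.null(pixel_pitch_um)) {
    pixel_pitch_um <- derive_pixel_pitch(1.09, width_px, height_px)
  }
  structure(
    list(
      arm_params = as_tibble(arm_params),
      animals_per_cell = as.integer(animals_per_cell),
      fields_per_animal = as.integer(fields_per_animal),
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      pixel_pitch_um = pixel_pitch_um,
      spot_rate_scale = spot_rate_scale,
      field_spec_overrides = field_spec_overrides,
      master_seed = as.integer(master_seed)
    ),
    class = "study_design"
  )
}

empty_manifest_tbl <- function() {
  tibble(
    animal_id = character(0), group = integer(0), time_point = character(0),
    field = integer(0), drug_path = character(0), vessel_path = character(0),
    exclusion_path = character(0), magnification_tag = character(0),
    pixel_pitch_um = numeric(0), field_area_mm2 = numeric(0), seed = integer(0)
  )
}

# Deterministic sub-seed from master seed and (group, time, animal, field)
# indices: a fixed-multiplier integer mix reduced mod 2^31 - 1. Any single
# field is regenerable without generating the rest of the study.
field_seed <- function(master_seed, group, time_idx, animal, field) {
  mix <- (as.numeric(master_seed) %% 2147483647) * 48271 +
    group * 1299709 + time_idx * 15485863 + animal * 104729 + field * 7919
  as.integer(mix %% 2147483647)
}

field_spec_for <- function(design, group, time_idx, animal, field) {
  ap <- design$arm_params
  row <- ap[ap$group == group &
              ap$time_point == unique(ap$time_point)[time_idx], ]
  args <- c(
    list(
      width_px = design$width_px, height_px = design$height_px,
      pixel_pitch_um = design$pixel_pitch_um,
      decay_scale_lambda_um = row$lambda_um,
      spot_rate = row$spot_rate * design$spot_rate_scale,
      seed = field_seed(design$master_seed, group, time_idx, animal, field)
    ),
    design$field_spec_overrides
  )
  do.call(synthetic_field_spec, args[!duplicated(names(args))])
}

#' Generate a whole synthetic study in memory
#'
#' @param design a [study_design()].
#' @return list with `fields` (named list of `generate_field()` results,
#'   keyed `g<group>_t<time>_a<animal>_f<field>`) and `manifest` (tibble:
#'   `animal_id`, `group`, `time_point`, `field`, `key`, `seed`).
#' @export
generate_study_fields <- function(design) {
  stopifnot(inherits(design, "study_design"))
  times <- unique(design$arm_params$time_point)
  rows <- list(); fields <- list()
  for (g in sort(unique(design$arm_params$group))) {
    for (ti in seq_along(times)) {
      for (a in seq_len(design$animals_per_cell)) {
        animal_id <- sprintf("g%d_%s_a%d", g, times[ti], a)
        for (f in seq_len(design$fields_per_animal)) {
          spec <- field_spec_for(design, g, ti, a, f)
          key <- sprintf("%s_f%d", animal_id, f)
          fields[[key]] <- generate_field(spec)
          rows[[key]] <- tibble(
            animal_id = animal_id, group = g, time_point = times[ti],
            field = f, key = key, seed = spec$seed
          )
        }
      }
    }
  }
  list(fields = fields, manifest = bind_rows(rows))
}

#' Generate a synthetic study on disk
#'
#' Writes per-field 16-bit grayscale TIFF channels, exclusion masks where
#' present, a manifest CSV, ground-truth CSVs (per-spot true distances and a
#' per-field summary), and the design as YAML.
#'
#' @param design a [study_design()].
#' @param out_dir output directory (created if needed).
#' @return the manifest tibble, invisibly; written as `manifest.csv`.
#' @export
generate_study <- function(design, out_dir) {
  stopifnot(inherits(design, "study_design"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_io_failure(paste("Cannot create", out_dir))
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)

  times <- unique(design$arm_params$time_point)
  manifest <- list(); gt_spots <- list(); gt_fields <- list()
  for (g in sort(unique(design$arm_params$group))) {
    for (ti in seq_along(times)) {
      for (a in seq_len(design$animals_per_cell)) {
        animal_id <- sprintf("g%d_%s_a%d", g, times[ti], a)
        for (f in seq_len(design$fields_per_animal)) {
          spec <- field_spec_for(design, g, ti, a, f)
          res <- generate_field(spec)
          key <- sprintf("%s_f%d", animal_id, f)
          drug_path <- file.path("images", paste0(key, "_drug.tif"))
          vessel_path <- file.path("images", paste0(key, "_vessel.tif"))
          write_channel_tiff(res$field$channels$drug,
                             file.path(out_dir, drug_path))
          write_channel_tiff(res$field$channels$vessel,
                             file.path(out_dir, vessel_path))
          excl_path <- NA_character_
          if ("exclusion" %in% names(res$field$channels)) {
            excl_path <- file.path("images", paste0(key, "_exclusion.tif"))
            write_channel_tiff(res$field$channels$exclusion,
                               file.path(out_dir, excl_path))
          }
          manifest[[key]] <- tibble(
            animal_id = animal_id, group = g, time_point = times[ti],
            field = f,
            drug_path = drug_path, vessel_path = vessel_path,
            exclusion_path = excl_path,
            magnification_tag = "x100",
            pixel_pitch_um = spec$pixel_pitch_um,
            field_area_mm2 = spec$width_px * spec$height_px *
              spec$pixel_pitch_um^2 / 1e6,
            seed = spec$seed
          )
          ts <- res$truth$spots
          if (nrow(ts)) {
            ts$animal_id <- animal_id; ts$group <- g
            ts$time_point <- times[ti]; ts$field <- f
            gt_spots[[key]] <- ts
          }
          gt_fields[[key]] <- tibble(
            animal_id = animal_id, group = g, time_point = times[ti],
            field = f, n_spots = nrow(ts),
            true_mean_distance_um = if (nrow(ts)) mean(ts$true_distance_um) else NA_real_,
            n_vessels_placed = res$truth$n_vessels_placed,
            n_vessel_components_rendered = res$truth$n_vessel_components_rendered
          )
        }
      }
    }
  }
  manifest <- if (length(manifest)) bind_rows(manifest) else empty_manifest_tbl()
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  spots_tbl <- if (length(gt_spots)) bind_rows(gt_spots) else tibble(
    row = numeric(0), col = numeric(0), sampled_distance_um = numeric(0),
    true_distance_um = numeric(0), animal_id = character(0),
    group = integer(0), time_point = character(0), field = integer(0)
  )
  fields_tbl <- if (length(gt_fields)) bind_rows(gt_fields) else tibble(
    animal_id = character(0), group = integer(0), time_point = character(0),
    field = integer(0), n_spots = integer(0),
    true_mean_distance_um = numeric(0), n_vessels_placed = integer(0),
    n_vessel_components_rendered = integer(0)
  )
  readr::write_csv(spots_tbl, file.path(out_dir, "ground_truth_spots.csv"))
  readr::write_csv(fields_tbl, file.path(out_dir, "ground_truth_fields.csv"))
  yaml::write_yaml(
    list(
      arm_params = as.data.frame(design$arm_params),
      animals_per_cell = design$animals_per_cell,
      fields_per_animal = design$fields_per_animal,
      width_px = design$width_px, height_px = design$height_px,
      pixel_pitch_um = design$pixel_pitch_um,
      spot_rate_scale = design$spot_rate_scale,
      master_seed = design$master_seed
    ),
    file.path(out_dir, "design.yaml")
  )
  invisible(manifest)
}
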