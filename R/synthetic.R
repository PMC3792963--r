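# Forward model for synthetic fluorescence fields.
#
# Emulates the structure the measurement pipeline assumes: microvessels placed
# by an edge-enriched inhomogeneous point process (vascularization is most
# intense at the tumor edge), drug spots placed around perfused vessels at
# distances drawn from a decay law with arm-specific scale lambda, drug
# intensity decaying exponentially with distance, a fraction of vessels with
# no surrounding drug, an optional avascular patch with no vessels and no
# drug, and an optional necrotic region delivered as an exclusion mask.
# Identical spec + seed gives bitwise-identical output.

#' Specification of one synthetic field
#'
#' @param width_px,height_px grid size in pixels.
#' @param pixel_pitch_um micrometres per pixel; default derived from the x100
#'   field area (1.09 mm^2) and the grid size.
#' @param vessel_density_per_mm2 vessel density at the un-enriched edge;
#'   density rises linearly to `edge_enrichment` times this value at the
#'   enriched (right) edge.
#' @param edge_enrichment multiplicative density gradient toward one edge
#'   (1 = spatially uniform).
#' @param vessel_radius_um_mean,vessel_radius_um_sd vessel disk radii
#'   (truncated below at 1 um).
#' @param vessel_margin_px keep vessel centers at least this many pixels from
#'   the grid border (0 = no margin).
#' @param spot_rate expected number of accepted drug spots.
#' @param decay_scale_lambda_um scale of the spot-distance law (um).
#' @param distance_law `"exponential"` (mean lambda) or `"half_normal"`
#'   (scale lambda).
#' @param intensity_decay_tau_um length scale of the intensity decay
#'   `I(d) = I0 * exp(-d / tau)`.
#' @param spot_peak_intensity I0, the intensity of a spot at distance 0.
#' @param spot_radius_px rendered radius of one spot.
#' @param unperfused_vessel_fraction fraction of vessels that spawn no drug.
#' @param avascular_patch `NULL`, or `list(row_frac =, col_frac =,
#'   radius_um =)`: a disk kept free of vessels and spots.
#' @param necrosis_fraction fraction of the field area covered by a necrotic
#'   disk (emitted as the exclusion channel; no vessels or spots inside).
#' @param background_noise_mean,background_noise_sd additive Gaussian
#'   background on the drug channel (clamped at 0).
#' @param shot_noise_frac multiplicative Poisson-like shot term: signal gets
#'   `sqrt(signal) * shot_noise_frac` Gaussian jitter.
#' @param vessel_intensity mean rendered intensity of vessel disks.
#' @param seed integer seed; same spec + seed reproduces the field exactly.
#' @return list of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(width_px = 1024L, height_px = 1024L,
                                 pixel_pitch_um = NULL,
                                 vessel_density_per_mm2 = 20,
                                 edge_enrichment = 3,
                                 vessel_radius_um_mean = 5,
                                 vessel_radius_um_sd = 1.5,
                                 vessel_margin_px = 0L,
                                 spot_rate = 2000,
                                 decay_scale_lambda_um = 40,
                                 distance_law = c("exponential", "half_normal"),
                                 intensity_decay_tau_um = 80,
                                 spot_peak_intensity = 220,
                                 spot_radius_px = 1.2,
                                 unperfused_vessel_fraction = 0.05,
                                 avascular_patch = NULL,
                                 necrosis_fraction = 0,
                                 background_noise_mean = 3,
                                 background_noise_sd = 1.5,
                                 shot_noise_frac = 0.05,
                                 vessel_intensity = 200,
                                 seed = 1L) {
  distance_law <- match.arg(distance_law)
  if (is.null(pixel_pitch_um)) {
    pixel_pitch_um <- derive_pixel_pitch(1.09, width_px, height_px)
  }
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_pitch_um = pixel_pitch_um,
    vessel_density_per_mm2 = vessel_density_per_mm2,
    edge_enrichment = edge_enrichment,
    vessel_radius_um_mean = vessel_radius_um_mean,
    vessel_radius_um_sd = vessel_radius_um_sd,
    vessel_margin_px = as.integer(vessel_margin_px),
    spot_rate = spot_rate,
    decay_scale_lambda_um = decay_scale_lambda_um,
    distance_law = distance_law,
    intensity_decay_tau_um = intensity_decay_tau_um,
    spot_peak_intensity = spot_peak_intensity,
    spot_radius_px = spot_radius_px,
    unperfused_vessel_fraction = unperfused_vessel_fraction,
    avascular_patch = avascular_patch,
    necrosis_fraction = necrosis_fraction,
    background_noise_mean = background_noise_mean,
    background_noise_sd = background_noise_sd,
    shot_noise_frac = shot_noise_frac,
    vessel_intensity = vessel_intensity,
    seed = as.integer(seed)
  )
  stopifnot(
    spec$width_px >= 8, spec$height_px >= 8, spec$pixel_pitch_um > 0,
    spec$vessel_density_per_mm2 > 0, spec$edge_enrichment >= 1,
    spec$vessel_radius_um_mean > 0, spec$spot_rate >= 0,
    spec$decay_scale_lambda_um > 0, spec$intensity_decay_tau_um > 0,
    spec$unperfused_vessel_fraction >= 0, spec$unperfused_vessel_fraction <= 1,
    spec$necrosis_fraction >= 0, spec$necrosis_fraction < 1
  )
  structure(spec, class = "synthetic_field_spec")
}

# render filled disks onto a raster; value per disk, overlaps keep the max
render_disks <- function(nr, nc, pitch, row_um, col_um, radius_um, value) {
  img <- matrix(0, nr, nc)
  for (i in seq_along(row_um)) {
    r_px <- row_um[i] / pitch + 0.5 # continuous position in pixel coords
    c_px <- col_um[i] / pitch + 0.5
    rad_px <- radius_um[i] / pitch
    rr <- max(1L, floor(r_px - rad_px)):min(nr, ceiling(r_px + rad_px))
    cc <- max(1L, floor(c_px - rad_px)):min(nc, ceiling(c_px + rad_px))
    if (!length(rr) || !length(cc)) next
    d2 <- outer((rr - r_px)^2, (cc - c_px)^2, "+")
    inside <- d2 <= rad_px^2
    patch <- img[rr, cc, drop = FALSE]
    patch[inside] <- pmax(patch[inside], value[i])
    img[rr, cc] <- patch
  }
  img
}

in_disk_um <- function(row_um, col_um, center_row_um, center_col_um, radius_um) {
  (row_um - center_row_um)^2 + (col_um - center_col_um)^2 <= radius_um^2
}

#' Generate one synthetic field with ground truth
#'
#' Vessels are placed by thinning a uniform proposal process so that density
#' rises linearly from `vessel_density_per_mm2` at the left edge to
#' `edge_enrichment` times that at the right edge, and rendered as disks.
#' Spots pick a perfused source vessel, a uniform direction, and a distance
#' from the configured law; a spot is rejected (and redrawn) if it falls
#' outside the grid, inside any vessel, inside the avascular patch, or inside
#' the necrotic region. Drug intensity at a spot of true distance `d` is
#' `I0 * exp(-d / tau)`; Gaussian background and a Poisson-like shot term are
#' added on top.
#'
#' @param spec a [synthetic_field_spec()].
#' @return list with elements `field` (a [field_image()] with `drug`,
#'   `vessel` and, when `necrosis_fraction > 0`, `exclusion` channels) and
#'   `truth` (list: `spots` tibble with sampled and true nearest-surface
#'   distances, `vessels` tibble, `n_vessels_placed`,
#'   `n_vessel_components_rendered`, `necrosis_mask`, `spec`).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  withr::with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  nr <- spec$height_px; nc <- spec$width_px; pitch <- spec$pixel_pitch_um
  h_um <- nr * pitch; w_um <- nc * pitch
  area_mm2 <- h_um * w_um / 1e6

  # necrotic disk (exclusion), placed at a random interior location
  necrosis <- matrix(FALSE, nr, nc)
  necro_center <- NULL; necro_radius_um <- 0
  if (spec$necrosis_fraction > 0) {
    necro_radius_um <- sqrt(spec$necrosis_fraction * h_um * w_um / pi)
    necro_center <- c(runif(1, 0.25, 0.75) * h_um, runif(1, 0.25, 0.75) * w_um)
    px_r <- (seq_len(nr) - 0.5) * pitch
    px_c <- (seq_len(nc) - 0.5) * pitch
    necrosis <- outer((px_r - necro_center[1])^2, (px_c - necro_center[2])^2, "+") <=
      necro_radius_um^2
  }
  patch <- spec$avascular_patch

  # --- vessels: inhomogeneous Poisson via thinning -------------------------
  h <- spec$edge_enrichment
  margin_um <- spec$vessel_margin_px * pitch
  n_prop <- rpois(1, spec$vessel_density_per_mm2 * h * area_mm2)
  vr <- runif(n_prop, margin_um, h_um - margin_um)
  vc <- runif(n_prop, margin_um, w_um - margin_um)
  t_frac <- vc / w_um # enrichment toward the right edge
  keep <- runif(n_prop) <= (1 + (h - 1) * t_frac) / h
  if (!is.null(patch)) {
    keep <- keep & !in_disk_um(vr, vc, patch$row_frac * h_um,
                               patch$col_frac * w_um, patch$radius_um)
  }
  if (necro_radius_um > 0) {
    keep <- keep & !in_disk_um(vr, vc, necro_center[1], necro_center[2],
                               necro_radius_um)
  }
  vr <- vr[keep]; vc <- vc[keep]
  n_v <- length(vr)
  if (n_v == 0 && spec$spot_rate > 0) {
    stop_inconsistent_spec(
      "Spec produced zero vessels but a nonzero spot rate; spots need a source vessel."
    )
  }
  radius <- pmax(1, rnorm(n_v, spec$vessel_radius_um_mean, spec$vessel_radius_um_sd))
  perfused <- runif(n_v) >= spec$unperfused_vessel_fraction
  if (n_v > 0 && spec$spot_rate > 0 && !any(perfused)) {
    perfused[sample.int(n_v, 1)] <- TRUE # at least one drug source
  }
  v_int <- pmax(50, rnorm(n_v, spec$vessel_intensity, spec$vessel_intensity * 0.1))

  vessel_channel <- render_disks(nr, nc, pitch, vr, vc, radius, v_int)
  lab <- label_components(vessel_channel > 0)
  n_rendered <- attr(lab, "n_components")

  # --- spots ---------------------------------------------------------------
  n_target <- if (spec$spot_rate > 0) rpois(1, spec$spot_rate) else 0L
  acc_r <- acc_c <- acc_d <- numeric(0)
  attempts <- 0L
  src <- which(perfused)
  while (length(acc_r) < n_target && attempts < 60L) {
    attempts <- attempts + 1L
    m <- max(1000L, 2L * (n_target - length(acc_r)))
    vi <- src[sample.int(length(src), m, replace = TRUE)]
    theta <- runif(m, 0, 2 * pi)
    d <- switch(spec$distance_law,
      exponential = stats::rexp(m, rate = 1 / spec$decay_scale_lambda_um),
      half_normal = abs(rnorm(m, 0, spec$decay_scale_lambda_um))
    )
    sr <- vr[vi] + (radius[vi] + d) * sin(theta)
    sc <- vc[vi] + (radius[vi] + d) * cos(theta)
    ok <- sr > 0 & sr < h_um & sc > 0 & sc < w_um
    if (!is.null(patch)) {
      ok <- ok & !in_disk_um(sr, sc, patch$row_frac * h_um,
                             patch$col_frac * w_um, patch$radius_um)
    }
    if (necro_radius_um > 0) {
      ok <- ok & !in_disk_um(sr, sc, necro_center[1], necro_center[2],
                             necro_radius_um)
    }
    # inside any vessel disk?
    if (any(ok) && n_v > 0) {
      oi <- which(ok)
      d_near <- nearest_surface_um(sr[oi], sc[oi], vr, vc, radius)
      ok[oi] <- d_near > 0
    }
    acc_r <- c(acc_r, sr[ok]); acc_c <- c(acc_c, sc[ok]); acc_d <- c(acc_d, d[ok])
  }
  if (length(acc_r) > n_target) {
    acc_r <- acc_r[seq_len(n_target)]
    acc_c <- acc_c[seq_len(n_target)]
    acc_d <- acc_d[seq_len(n_target)]
  }
  n_s <- length(acc_r)
  true_d <- if (n_s > 0) nearest_surface_um(acc_r, acc_c, vr, vc, radius) else numeric(0)

  # --- drug channel --------------------------------------------------------
  spot_val <- spec$spot_peak_intensity * exp(-true_d / spec$intensity_decay_tau_um)
  drug <- render_disks(nr, nc, pitch, acc_r, acc_c,
                       rep(spec$spot_radius_px * pitch, n_s), spot_val)
  if (spec$shot_noise_frac > 0 && n_s > 0) {
    sig <- drug > 0
    drug[sig] <- drug[sig] +
      sqrt(drug[sig]) * rnorm(sum(sig), 0, spec$shot_noise_frac)
  }
  drug <- drug +
    pmax(0, rnorm(nr * nc, spec$background_noise_mean, spec$background_noise_sd))
  drug[necrosis] <- spec$background_noise_mean # necrotic tissue: background only
  drug <- pmax(drug, 0)

  channels <- list(drug = drug, vessel = vessel_channel)
  if (spec$necrosis_fraction > 0) channels$exclusion <- necrosis * 1

  field <- field_image(channels,
    magnification_tag = "x100", pixel_pitch_um = pitch,
    field_id = sprintf("synthetic_seed%d", spec$seed)
  )
  truth <- list(
    spots = tibble(
      row = acc_r / pitch + 0.5, col = acc_c / pitch + 0.5,
      sampled_distance_um = acc_d, true_distance_um = true_d
    ),
    vessels = tibble(
      row_um = vr, col_um = vc, radius_um = radius, perfused = perfused
    ),
    n_vessels_placed = n_v,
    n_vessel_components_rendered = n_rendered,
    necrosis_mask = necrosis,
    spec = spec
  )
  list(field = field, truth = truth)
}

# distance from points to the nearest vessel surface (disk boundary),
# clamped at 0 for points inside a vessel
nearest_surface_um <- function(pr, pc, vr, vc, radius) {
  if (length(vr) == 0) return(rep(Inf, length(pr)))
  out <- numeric(length(pr))
  chunk <- max(1L, floor(4e6 / length(vr)))
  for (s in seq(1, length(pr), by = chunk)) {
    e <- min(s + chunk - 1, length(pr))
    dd <- sqrt(outer(pr[s:e], vr, "-")^2 + outer(pc[s:e], vc, "-")^2)
    dd <- sweep(dd, 2, radius, "-")
    out[s:e] <- pmax(0, apply(dd, 1, min))
  }
  out
}
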