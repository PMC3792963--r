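# Independent oracles used across tests. Each deliberately re-derives the
# quantity by the most naive route available (brute force, exhaustive scan,
# flood fill) and shares no code with the implementation it checks.

# brute-force distance map: per-pixel minimum over all vessel pixels
oracle_distance_map <- function(mask, pitch) {
  idx <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  best <- matrix(Inf, nr, nc)
  for (v in seq_len(nrow(idx))) {
    d <- sqrt((rows - idx[v, 1])^2 + (cols - idx[v, 2])^2)
    best <- pmin(best, d)
  }
  best * pitch
}

# flood-fill connected-component count (8- or 4-connectivity), queue-based
oracle_flood_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pi <- ((p - 1) %% nr) + 1; pj <- ((p - 1) %/% nr) + 1
      for (o in seq_len(nrow(offs))) {
        qi <- pi + offs[o, 1]; qj <- pj + offs[o, 2]
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] && !seen[qi, qj]) {
          seen[qi, qj] <- TRUE
          queue <- c(queue, qi + (qj - 1) * nr)
        }
      }
    }
  }
  count
}

# component sizes by the same flood fill (for min-size filtering checks)
oracle_component_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  sizes <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      pi <- ((p - 1) %% nr) + 1; pj <- ((p - 1) %/% nr) + 1
      for (o in 1:8) {
        qi <- pi + offs[o, 1]; qj <- pj + offs[o, 2]
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] && !seen[qi, qj]) {
          seen[qi, qj] <- TRUE
          queue <- c(queue, qi + (qj - 1) * nr)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# exhaustive Otsu: maximize between-class variance over all candidate cuts of
# a 256-bin histogram spanning the observed range; returns the intensity cut
oracle_otsu_exhaustive <- function(x, levels = 256) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1), levels),
    nbins = levels
  )
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  total <- sum(counts)
  best_var <- -Inf; best_cut <- rng[1]
  for (t in 1:(levels - 1)) {
    w1 <- sum(counts[1:t]); w2 <- total - w1
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(counts[1:t] * mids[1:t]) / w1
    m2 <- sum(counts[(t + 1):levels] * mids[(t + 1):levels]) / w2
    v <- w1 * w2 * (m1 - m2)^2
    if (v > best_var) { best_var <- v; best_cut <- breaks[t + 1] }
  }
  best_cut
}

# exhaustive sliding-window sum oracle
oracle_window_sums <- function(m, side, rows, cols) {
  vapply(seq_along(rows), function(i) {
    sum(m[rows[i]:(rows[i] + side - 1), cols[i]:(cols[i] + side - 1)])
  }, numeric(1))
}

# exhaustive sliding-window component-count oracle
oracle_window_counts <- function(mask, side, rows, cols, min_size = 1) {
  vapply(seq_along(rows), function(i) {
    sub <- mask[rows[i]:(rows[i] + side - 1), cols[i]:(cols[i] + side - 1)]
    sizes <- oracle_component_sizes(sub)
    sum(sizes >= min_size)
  }, numeric(1))
}

# summary-statistics one-way ANOVA from first principles (independent of the
# package's implementation)
oracle_summary_anova_F <- function(n, m, s) {
  grand <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  (ssb / (length(n) - 1)) / (ssw / (sum(n) - length(n)))
}

# random logical mask helper
random_mask <- function(nr, nc, density, ensure_true = TRUE) {
  m <- matrix(runif(nr * nc) < density, nr, nc)
  if (ensure_true && !any(m)) m[sample(nr, 1), sample(nc, 1)] <- TRUE
  m
}

# small field wrapper for raster-level tests
make_field <- function(drug = NULL, vessel = NULL, exclusion = NULL,
                       pitch = 1, nr = 32, nc = 32) {
  ch <- list()
  if (!is.null(drug)) ch$drug <- drug
  if (!is.null(vessel)) ch$vessel <- vessel
  if (!is.null(exclusion)) ch$exclusion <- exclusion
  if (!length(ch)) ch$drug <- matrix(0, nr, nc)
  field_image(ch, magnification_tag = "x100", pixel_pitch_um = pitch)
}

# validation-scale synthetic spec used by recovery tests: a large sparse
# field (4.1 mm^2 at 0.7 um/px) so spot blobs rarely merge
validation_spec <- function(lambda, seed, spot_rate = 1100, ...) {
  synthetic_field_spec(
    width_px = 2048, height_px = 2048, pixel_pitch_um = 0.7,
    vessel_density_per_mm2 = 50, edge_enrichment = 1.5,
    spot_rate = spot_rate, decay_scale_lambda_um = lambda, seed = seed, ...
  )
}

empty_manifest_for_test <- function() {
  tibble::tibble(
    animal_id = character(0), group = integer(0), time_point = character(0),
    field = integer(0), drug_path = character(0), vessel_path = character(0),
    exclusion_path = character(0), magnification_tag = character(0),
    pixel_pitch_um = numeric(0), field_area_mm2 = numeric(0), seed = integer(0)
  )
}

# calibrated measurement config for synthetic data: fixed detection threshold
# well above the background (mean 3, sd 1.5) and far below spot intensity
calibrated_config <- function(...) {
  perivasc_config(drug_method = "fixed", drug_fixed_threshold = 15, ...)
}
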