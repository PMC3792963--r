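# Structured condition classes. Every error raised by the package carries
# "perivasc_error" plus a specific class so callers can branch on failure mode
# (e.g. skip a field on perivasc_no_vessel rather than abort a whole study).

stop_perivasc <- function(class, message, ...) {
  abort(message, class = c(class, "perivasc_error"), ...)
}

stop_missing_channel <- function(channel, available) {
  stop_perivasc(
    "perivasc_missing_channel",
    sprintf(
      "Channel '%s' not present in field (available: %s).",
      channel, paste(available, collapse = ", ")
    )
  )
}

stop_degenerate_histogram <- function() {
  stop_perivasc(
    "perivasc_degenerate_histogram",
    paste(
      "Otsu thresholding is undefined for a constant-valued channel;",
      "fall back to method = 'nonzero' or 'fixed'."
    )
  )
}

stop_no_vessel <- function() {
  stop_perivasc(
    "perivasc_no_vessel",
    "Vessel mask contains no vessel pixel; distance to nearest vessel is undefined."
  )
}

stop_field_too_small <- function(window, grid) {
  stop_perivasc(
    "perivasc_field_too_small",
    sprintf(
      "Scan window (%d x %d px) does not fit inside the grid (%d x %d px).",
      window[1], window[2], grid[1], grid[2]
    )
  )
}

stop_no_valid_field <- function() {
  stop_perivasc(
    "perivasc_no_valid_field",
    "No candidate window is eligible (all windows > 50% excluded)."
  )
}

stop_insufficient_fields <- function(detail) {
  stop_perivasc(
    "perivasc_insufficient_fields",
    paste0("Exactly 3 usable fields per animal are required: ", detail)
  )
}

stop_insufficient_data <- function(detail) {
  stop_perivasc("perivasc_insufficient_data", detail)
}

stop_unequal_subgroups <- function(na, nb) {
  stop_perivasc(
    "perivasc_unequal_subgroups",
    sprintf(
      "combine_subgroups() pools equal-sized subgroups only (got n = %d and %d).",
      na, nb
    )
  )
}

stop_degenerate_anova <- function() {
  stop_perivasc(
    "perivasc_degenerate_anova",
    "Within-group variance is zero in every group; the F statistic is undefined."
  )
}

stop_inconsistent_spec <- function(detail) {
  stop_perivasc("perivasc_inconsistent_spec", detail)
}

stop_io_failure <- function(detail) {
  stop_perivasc("perivasc_io_failure", detail)
}
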