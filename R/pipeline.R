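# Study-level orchestration: simulate, measure, summarize.
#
# run_simulate() writes a synthetic study to disk; run_measure() executes the
# per-field measurement over a manifest and aggregates to animals and groups;
# run_summarize() turns a per-animal table into the published-table shape
# (group x time point x Total, mean +/- SD per metric) plus ANOVA and LSD
# comparison tables. Fixed manifest + config + seed give byte-identical CSVs.

log_line <- function(lines, stage, event) {
  msg <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, event)
  if (isTRUE(getOption("perivasc.verbose", FALSE))) inform(msg)
  c(lines, msg)
}

#' Simulate a study to disk
#'
#' @param design a [study_design()].
#' @param out_dir output directory.
#' @param config a [perivasc_config()]; written next to the outputs as
#'   `config.yaml` so a later [run_measure()] is fully specified.
#' @return the manifest tibble, invisibly.
#' @export
run_simulate <- function(design, out_dir, config = perivasc_config()) {
  manifest <- generate_study(design, out_dir)
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

#' Measure a study from a manifest
#'
#' For every manifest record: load the channels, measure field penetration
#' and spot count, and count microvessels in the best hotspot window of the
#' field. Per animal, the three field values average into the animal
#' penetration, spot count and MVD. Flagged fields (no vessel, no spot) are
#' excluded from their animal's mean with a warning rather than scored zero;
#' an animal with no usable field is dropped with a warning.
#'
#' @param manifest manifest tibble (from [generate_study()]) or path to a
#'   manifest CSV.
#' @param base_dir directory image paths resolve against; defaults to the
#'   manifest's directory when `manifest` is a path.
#' @param config a [perivasc_config()].
#' @param out_dir when given, writes `fields.csv`, `animals.csv`,
#'   `groups.csv`, `anova.csv`, `comparisons.csv` and `run.log` there.
#' @return list: `fields`, `animals`, `groups`, `anova`, `comparisons`.
#' @export
run_measure <- function(manifest, base_dir = ".", config = perivasc_config(),
                        out_dir = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop_io_failure(paste("No such manifest:", manifest))
    if (missing(base_dir)) base_dir <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  stopifnot(is.data.frame(manifest))
  log <- character(0)

  field_rows <- list()
  if (nrow(manifest) > 0) {
    manifest <- dplyr::arrange(manifest, .data$group, .data$time_point,
                               .data$animal_id, .data$field)
    for (i in seq_len(nrow(manifest))) {
      rec <- manifest[i, ]
      field <- tryCatch(
        read_manifest_field(rec, base_dir = base_dir),
        perivasc_io_failure = function(e) {
          stop_io_failure(sprintf(
            "While reading record %s field %d: %s",
            rec$animal_id, rec$field, conditionMessage(e)
          ))
        }
      )
      meas <- field_penetration(field, config)
      log <- log_line(log, "measure", sprintf(
        "%s field %d: %d spots, threshold %s%s",
        rec$animal_id, rec$field, meas$spot_count,
        format(meas$drug_threshold, digits = 4),
        if (is.na(meas$flag)) "" else paste0(" [flag: ", meas$flag, "]")
      ))
      vmask <- binarize_channel(field, "vessel",
        method = config$vessel_method,
        fixed_threshold = config$vessel_fixed_threshold, semantics = "vessel"
      )
      vmask_eff <- unclass(vmask)
      if ("exclusion" %in% names(field$channels)) {
        vmask_eff <- vmask_eff & !(get_channel(field, "exclusion") > 0)
      }
      # counting window: the standard area, clamped to the field when a
      # scaled-down field is smaller than the standard x200 window
      max_area <- (min(dim(vmask_eff)) * field$pixel_pitch_um)^2 / 1e6
      win_area <- min(config$mvd_window_area_mm2, max_area)
      if (win_area < config$mvd_window_area_mm2) {
        log <- log_line(log, "mvd", sprintf(
          "%s field %d: counting window clamped to %.3f mm2 (field smaller than standard window)",
          rec$animal_id, rec$field, win_area
        ))
      }
      hs <- find_hotspots(vmask_eff, field$pixel_pitch_um,
        window_area_mm2 = win_area, k = 1L,
        stride_px = NULL, min_size_px = config$min_vessel_size
      )
      field_rows[[i]] <- dplyr::bind_cols(
        rec[, c("animal_id", "group", "time_point", "field")],
        meas[, setdiff(names(meas), "field_id")],
        tibble(vessel_count_hotspot = as.integer(hs$score[1]))
      )
    }
  }
  fields <- if (length(field_rows)) bind_rows(field_rows) else empty_fields_tbl()

  animals <- aggregate_animals(fields)
  flagged <- fields[!is.na(fields$flag), ]
  for (i in seq_len(nrow(flagged))) {
    log <- log_line(log, "aggregate", sprintf(
      "%s field %d flagged (%s); excluded from animal mean",
      flagged$animal_id[i], flagged$field[i], flagged$flag[i]
    ))
  }

  summ <- run_summarize(animals)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(fields, file.path(out_dir, "fields.csv"))
    readr::write_csv(animals, file.path(out_dir, "animals.csv"))
    readr::write_csv(summ$groups, file.path(out_dir, "groups.csv"))
    readr::write_csv(summ$anova, file.path(out_dir, "anova.csv"))
    readr::write_csv(summ$comparisons, file.path(out_dir, "comparisons.csv"))
    writeLines(log, file.path(out_dir, "run.log"))
  }
  list(
    fields = fields, animals = animals,
    groups = summ$groups, anova = summ$anova, comparisons = summ$comparisons
  )
}

empty_fields_tbl <- function() {
  tibble(
    animal_id = character(0), group = integer(0), time_point = character(0),
    field = integer(0), mean_penetration_um = numeric(0),
    spot_count = integer(0), vessel_count = integer(0),
    excluded_frac = numeric(0), drug_threshold = numeric(0),
    flag = character(0), vessel_count_hotspot = integer(0)
  )
}

aggregate_animals <- function(fields) {
  if (nrow(fields) == 0) {
    return(tibble(
      animal_id = character(0), group = integer(0), time_point = character(0),
      n_fields = integer(0), penetration_um = numeric(0),
      spot_count_mean = numeric(0), mvd = numeric(0)
    ))
  }
  ok <- fields[is.na(fields$flag), ]
  dropped <- setdiff(unique(fields$animal_id), unique(ok$animal_id))
  if (length(dropped)) {
    warn(paste("Animals with no usable field dropped:",
               paste(dropped, collapse = ", ")))
  }
  if (nrow(ok) < nrow(fields)) {
    warn(sprintf("%d flagged field(s) excluded from animal means.",
                 nrow(fields) - nrow(ok)))
  }
  ok |>
    group_by(.data$animal_id, .data$group, .data$time_point) |>
    summarise(
      n_fields = n(),
      penetration_um = mean(.data$mean_penetration_um),
      spot_count_mean = mean(.data$spot_count),
      mvd = mean(.data$vessel_count_hotspot),
      .groups = "drop"
    ) |>
    arrange(.data$group, .data$time_point, .data$animal_id)
}

#' Summarize a per-animal table into the published-table shape
#'
#' Produces one row per (group, time point) plus a pooled `Total` row per
#' group, each with mean +/- SD of MVD, penetration distance and spot count;
#' and, per time point and for the pooled totals, a one-way ANOVA across
#' groups with all pairwise LSD comparisons for each metric.
#'
#' @param animals per-animal tibble with `group`, `time_point`,
#'   `penetration_um`, `spot_count_mean`, `mvd`.
#' @return list: `groups` (summary table), `anova`, `comparisons`.
#' @export
run_summarize <- function(animals) {
  stopifnot(is.data.frame(animals))
  metrics <- c(mvd = "mvd", penetration_um = "penetration_um",
               spot_count = "spot_count_mean")
  if (nrow(animals) == 0) {
    groups <- tibble(
      group = integer(0), time_point = character(0), n = integer(0),
      mvd_mean = numeric(0), mvd_sd = numeric(0),
      penetration_um_mean = numeric(0), penetration_um_sd = numeric(0),
      spot_count_mean = numeric(0), spot_count_sd = numeric(0)
    )
    an <- tibble(metric = character(0), time_point = character(0),
                 F = numeric(0), df_between = integer(0),
                 df_within = integer(0), p_value = numeric(0))
    cmp <- tibble(metric = character(0), time_point = character(0),
                  group_a = integer(0), group_b = integer(0),
                  estimate = numeric(0), t = numeric(0), df = integer(0),
                  p_value = numeric(0), adjusted = character(0))
    return(list(groups = groups, anova = an, comparisons = cmp))
  }
  animals <- dplyr::arrange(animals, .data$group, .data$time_point)
  times <- sort(unique(animals$time_point))

  cell_summary <- function(df, metric) {
    if (nrow(df) < 2) {
      stop_insufficient_data(sprintf(
        "Cell group %s / %s has n = %d < 2.",
        df$group[1] %||% "?", df$time_point[1] %||% "?", nrow(df)
      ))
    }
    summarize_values(df[[metric]])
  }

  group_rows <- list()
  for (g in sort(unique(animals$group))) {
    per_time <- list()
    for (tp in times) {
      cell <- animals[animals$group == g & animals$time_point == tp, ]
      row <- tibble(group = g, time_point = tp, n = nrow(cell))
      for (mname in names(metrics)) {
        s <- cell_summary(cell, metrics[[mname]])
        row[[paste0(mname, "_mean")]] <- s$mean
        row[[paste0(mname, "_sd")]] <- s$sd
      }
      per_time[[tp]] <- row
    }
    group_rows[[length(group_rows) + 1]] <- bind_rows(per_time)
    if (length(times) == 2) {
      a <- per_time[[times[1]]]; b <- per_time[[times[2]]]
      tot <- tibble(group = g, time_point = "Total", n = a$n + b$n)
      for (mname in names(metrics)) {
        comb <- combine_subgroups(
          tibble(n = a$n, mean = a[[paste0(mname, "_mean")]],
                 sd = a[[paste0(mname, "_sd")]]),
          tibble(n = b$n, mean = b[[paste0(mname, "_mean")]],
                 sd = b[[paste0(mname, "_sd")]])
        )
        tot[[paste0(mname, "_mean")]] <- comb$mean
        tot[[paste0(mname, "_sd")]] <- comb$sd
      }
      group_rows[[length(group_rows) + 1]] <- tot
    }
  }
  groups <- bind_rows(group_rows)

  # ANOVA + LSD per time point (and pooled Total) per metric, raw-data route
  an_rows <- list(); cmp_rows <- list()
  strata <- c(as.list(times), list(times)) # each time point, then pooled
  names(strata) <- c(times, "Total")
  gids <- sort(unique(animals$group))
  if (length(gids) >= 2) {
    for (sn in names(strata)) {
      sub <- animals[animals$time_point %in% strata[[sn]], ]
      for (mname in names(metrics)) {
        vals <- lapply(gids, function(g) sub[[metrics[[mname]]]][sub$group == g])
        fit <- anova_oneway(vals)
        an_rows[[paste(sn, mname)]] <- tibble(
          metric = mname, time_point = sn, F = fit$F,
          df_between = fit$df_between, df_within = fit$df_within,
          p_value = fit$p_value
        )
        summ <- purrr::map_dfr(seq_along(gids), function(i) {
          s <- summarize_values(vals[[i]])
          s$group <- gids[i]
          s
        })
        cmp <- lsd_pairwise(summ, fit)
        cmp$metric <- mname; cmp$time_point <- sn
        cmp_rows[[paste(sn, mname)]] <- cmp
      }
    }
  }
  an <- if (length(an_rows)) bind_rows(an_rows) else
    tibble(metric = character(0), time_point = character(0), F = numeric(0),
           df_between = integer(0), df_within = integer(0), p_value = numeric(0))
  cmp <- if (length(cmp_rows)) {
    dplyr::relocate(bind_rows(cmp_rows), "metric", "time_point")
  } else {
    tibble(metric = character(0), time_point = character(0),
           group_a = integer(0), group_b = integer(0), estimate = numeric(0),
           t = numeric(0), df = integer(0), p_value = numeric(0),
           adjusted = character(0))
  }
  list(groups = groups, anova = an, comparisons = cmp)
}

#' Plot a group summary table
#'
#' Mean +/- SD per group and time point for one metric.
#'
#' @param groups the `groups` tibble from [run_measure()]/[run_summarize()].
#' @param metric `"penetration_um"`, `"spot_count"` or `"mvd"`.
#' @return a ggplot.
#' @export
plot_group_summary <- function(groups, metric = "penetration_um") {
  m <- paste0(metric, "_mean"); s <- paste0(metric, "_sd")
  stopifnot(m %in% names(groups))
  d <- groups[groups$time_point != "Total", ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$group), y = .data[[m]], colour = .data$time_point
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data[[m]] - .data[[s]], ymax = .data[[m]] + .data[[s]]),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(x = "treatment arm", y = metric, colour = "time point")
}
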