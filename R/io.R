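.trial_schema <- c("participant_id", "day", "task", "phase", "trial_index",
                   "stimulus", "reinforced", "avoidance_available",
                   "cost_applies", "expectancy", "distress", "avoided",
                   "press_latency", "us_delivered")
.trial_optional <- c("value", "rating")

#' Write / read long-format trial records
#'
#' Comma-separated, dot-decimal, UTF-8, one row per stimulus presentation.
#' `read_trials()` validates the schema: unknown columns raise an error
#' naming them, missing required columns are reported, and out-of-range
#' ratings (expectancy/distress outside integer 0..10) are reported with
#' their row numbers. A file with a header and no rows yields an empty
#' tibble with a warning. The round-trip is lossless.
#'
#' @param trials Trial tibble (e.g. `generate_cohort(...)$trials`).
#' @param path File path.
#' @return `read_trials()` returns the validated tibble (with the `rating`
#'   alias column restored); `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[intersect(c(.trial_schema, "value"),
                                    names(trials))], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  unknown <- setdiff(names(x), c(.trial_schema, .trial_optional))
  if (length(unknown) > 0) {
    stop("unknown column(s) in trial file: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(.trial_schema, names(x))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(x) == 0) {
    warning("trial file contains a header but no rows")
    return(x)
  }
  for (col in c("expectancy", "distress")) {
    v <- x[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 10 | v != round(v)))
    if (length(bad) > 0) {
      stop(sprintf("%s out of range 0..10 at row(s) %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  bad_ph <- which(!x$phase %in% .phases)
  if (length(bad_ph) > 0) {
    stop("unknown phase at row(s) ",
         paste(utils::head(bad_ph, 10), collapse = ", "))
  }
  x$rating <- x$expectancy
  x
}

#' Write / read the wide questionnaire panel
#'
#' @param panels Panel tibble (one row per participant).
#' @param path File path.
#' @return `read_panels()` returns the tibble; `write_panels()` returns
#'   `path` invisibly.
#' @export
write_panels <- function(panels, path) {
  readr::write_csv(panels, path)
  invisible(path)
}

#' @rdname write_panels
#' @export
read_panels <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"participant_id" %in% names(x)) {
    stop("panel file must contain a participant_id column")
  }
  x
}

#' Write the learning-index table and reduction log
#'
#' One row per participant: the 13 raw indices, their 13 `Z_` columns, the
#' three retention flags and the day order. The reduction log (participants
#' excluded per day) is written alongside as plain text when `log_path` is
#' given.
#'
#' @param index_table An `index_table`.
#' @param path CSV path for the table.
#' @param log_path Optional path for the plain-text reduction log.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(index_table, path, log_path = NULL) {
  readr::write_csv(index_table$indices, path)
  if (!is.null(log_path)) {
    lines <- c("participants excluded per day (failed differential responding):",
               paste0("  ", names(index_table$reduction_log), ": ",
                      index_table$reduction_log))
    if (!is.null(index_table$midway)) {
      lines <- c(lines, sprintf(
        "extinction midway: value %.4f, bracket trials %d-%d",
        index_table$midway$midpoint_value, index_table$midway$bracket[1],
        index_table$midway$bracket[2]))
    }
    writeLines(lines, log_path)
  }
  invisible(path)
}

#' Export / import a task-design trial table
#'
#' @param design A `task_design`.
#' @param path File path.
#' @return `read_schedule()` returns the long schedule tibble.
#' @export
write_schedule <- function(design, path) {
  readr::write_csv(design_trials(design), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Pipeline configuration
#'
#' Bundles every option of the end-to-end pipeline with its documented
#' default: the master seed (all randomness flows from it), cohort size and
#' generator parameter overrides, clustering options (`kmax = 10`,
#' `B = 100` reference iterations), the regression grid families, and the
#' mixture options (quadratic shape, classes 1..6, 100 random starts).
#' Round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n = 655L,
    cohort = list(),          # overrides merged into cohort_params()
    clustering = list(kmax = 10L, B = 100L, n_restarts = 10L,
                      sets = c("primary-5", "primary-7", "secondary")),
    regression = list(families = c("main", "failure", "nle_count",
                                   "nle_weighted", "pairwise")),
    mixture = list(shape = "quadratic", Kmax = 6L, n_starts = 100L),
    out_dir = NULL
  )
  ov <- list(...)
  if (length(ov) > 0) {
    stopifnot(!is.null(names(ov)), all(names(ov) %in% names(cfg)))
    cfg <- utils::modifyList(cfg, ov, keep.null = TRUE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
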