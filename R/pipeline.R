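#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage: simulate a cohort, reduce trials to the learning
#' index table, run the manipulation checks and pairwise index
#' correlations, run the profile cluster analyses, fit the hierarchical
#' prediction grid, and model the weekly follow-up trajectories (shape
#' selection, mixture grid, class assignment, class-index tests). When
#' `config$out_dir` is set, each stage writes its delimited outputs there
#' together with a YAML manifest carrying the seed and package version and
#' a plain-text stage log with participant counts, exclusion counts and
#' convergence flags.
#'
#' @param config A [pipeline_config()].
#' @return List with the stage results: `cohort`, `index_table`,
#'   `descriptives`, `correlations`, `clustering`, `regression`,
#'   `trajectories`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  params <- do.call(cohort_params, config$cohort)
  note("simulate: n = %d, seed = %d", config$n, config$seed)
  cohort <- generate_cohort(config$n, params = params, seed = config$seed)
  idx <- cohort$index_table
  note("reduce: excluded per day: %s",
       paste(names(idx$reduction_log), idx$reduction_log, sep = "=",
             collapse = ", "))

  desc <- manipulation_checks(cohort)
  corr <- list(
    primary = pairwise_index_correlations(idx, "primary-7"),
    secondary = pairwise_index_correlations(idx, "secondary")
  )
  note("describe: %d manipulation-check rows, %d + %d correlation pairs",
       nrow(desc), nrow(corr$primary), nrow(corr$secondary))

  clustering <- lapply(config$clustering$sets, function(s) {
    profile_report(idx, set = s, kmax = config$clustering$kmax,
                   B = config$clustering$B, seed = config$seed,
                   n_restarts = config$clustering$n_restarts)
  })
  names(clustering) <- config$clustering$sets
  note("cluster: chosen k: %s",
       paste(config$clustering$sets,
             vapply(clustering, function(x) x$gap$chosen_k, integer(1)),
             sep = "=", collapse = ", "))

  frame <- analysis_frame(cohort)
  ledger <- run_paper_grid(frame, families = config$regression$families)
  note("predict: %d ledger cells (%d skipped)", nrow(ledger),
       nrow(attr(ledger, "skipped") %||% tibble::tibble()))

  traj <- NULL
  weekly <- cohort$ies_weekly
  if (!is.null(weekly) && length(unique(weekly$participant_id)) >=
        5 * config$mixture$Kmax) {
    shapes <- c("linear", "quadratic", "cubic", "logarithmic")
    singles <- lapply(shapes, function(sh)
      fit_single_growth(weekly, shape = sh, seed = config$seed))
    names(singles) <- shapes
    best_shape <- shapes[which.min(vapply(singles, `[[`, numeric(1),
                                          "BIC"))]
    fits <- fit_gmm_grid(weekly, shape = best_shape,
                         Kmax = config$mixture$Kmax,
                         n_starts = config$mixture$n_starts,
                         seed = config$seed)
    sel <- select_mixture(fits)
    asg <- assign_classes(sel)
    cit <- class_index_tests(asg, idx)
    traj <- list(singles = singles, best_shape = best_shape,
                 selection = attr(sel, "comparison"), fit = sel,
                 assignment = asg, class_index_tests = cit)
    note("trajectories: shape = %s, selected %s with K = %d",
         best_shape, sel$effects, sel$K)
  } else {
    note("trajectories: skipped (failed-exam subgroup too small)")
  }

  out <- list(cohort = cohort, index_table = idx, descriptives = desc,
              correlations = corr, clustering = clustering,
              regression = ledger, trajectories = traj, log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_trials(cohort$trials, p("trials.csv"))
    write_panels(cohort$panels, p("panels.csv"))
    write_index_table(idx, p("indices.csv"), p("reduction_log.txt"))
    readr::write_csv(desc, p("manipulation_checks.csv"))
    readr::write_csv(corr$primary, p("correlations_primary.csv"))
    readr::write_csv(ledger, p("regression_ledger.csv"))
    for (s in names(clustering)) {
      readr::write_csv(clustering[[s]]$gap$table,
                       p(paste0("gap_", gsub("-", "", s), ".csv")))
    }
    if (!is.null(traj)) {
      readr::write_csv(traj$selection, p("trajectory_candidates.csv"))
      readr::write_csv(traj$assignment$assignment,
                       p("trajectory_classes.csv"))
    }
    yaml::write_yaml(
      list(seed = config$seed, n = config$n,
           package = as.character(utils::packageVersion("fearcond"))),
      p("manifest.yml"))
    writeLines(log, p("pipeline_log.txt"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Manipulation checks for a cohort
#'
#' The standard set: Stimulus x Time repeated-measures ANOVAs on first vs.
#' last acquisition and extinction trials (expectancy and distress
#' channels), one-sample and paired t-tests on the avoidance counts
#' (no-cost and, where present, cost phase), and the one-way
#' within-subject ANOVA over the six first-trial generalization ratings.
#' Phase-specific checks use the participants retained for that day.
#'
#' @param cohort A `cohort_dataset`.
#' @return Tidy tibble: `analysis`, `channel`, `effect`, statistic columns
#'   as in [rm_anova_2x2()] / [t_tests()].
#' @export
manipulation_checks <- function(cohort) {
  trials <- cohort$trials
  idx <- cohort$index_table$indices
  rows <- list()

  first_last <- function(phase_, channel) {
    x <- trials[trials$phase == phase_, ]
    col <- if (channel == "expectancy") "rating" else "distress"
    x <- x[order(x$participant_id, x$stimulus, x$trial_index), ]
    g <- dplyr::group_by(x, .data$participant_id, .data$stimulus)
    fl <- dplyr::summarise(
      g, first = .data[[col]][1],
      last = .data[[col]][dplyr::n()], .groups = "drop")
    tidyr::pivot_longer(fl, c("first", "last"), names_to = "time",
                        values_to = "value")
  }

  for (ch in c("expectancy", "distress")) {
    cells <- first_last("ACQUISITION", ch)
    r <- rm_anova_2x2(cells)
    r$analysis <- "acquisition"; r$channel <- ch
    rows[[length(rows) + 1]] <- r

    ext_ids <- idx$participant_id[isTRUE_vec(idx$retained_extinction)]
    cells <- first_last("EXTINCTION", ch)
    cells <- cells[cells$participant_id %in% ext_ids, ]
    if (nrow(cells) > 0) {
      r <- rm_anova_2x2(cells)
      r$analysis <- "extinction"; r$channel <- ch
      rows[[length(rows) + 1]] <- r
    }
  }

  av <- idx[isTRUE_vec(idx$retained_avoidance), ]
  if (nrow(av) >= 2) {
    r <- t_tests(av$AV_CSplus, mode = "one_sample")
    r$analysis <- "avoidance_nocost"; r$channel <- "behaviour"
    r$effect <- "AV_CS+ > 0"
    rows[[length(rows) + 1]] <- r
    r <- t_tests(av$AV_CSplus, av$AV_CSminus, mode = "paired")
    r$analysis <- "avoidance_nocost"; r$channel <- "behaviour"
    r$effect <- "AV_CS+ vs AV_CS-"
    rows[[length(rows) + 1]] <- r
    co <- av[!is.na(av$AV_Cost_CSplus), ]
    if (nrow(co) >= 2 && stats::sd(co$AV_Cost_CSplus) > 0) {
      r <- t_tests(co$AV_Cost_CSplus, mode = "one_sample")
      r$analysis <- "avoidance_cost"; r$channel <- "behaviour"
      r$effect <- "AV_Cost_CS+ > 0"
      rows[[length(rows) + 1]] <- r
    }
  }

  gen_ids <- idx$participant_id[isTRUE_vec(idx$retained_generalization)]
  gp <- trials[trials$phase == "GENERALIZATION" &
                 trials$participant_id %in% gen_ids, ]
  if (nrow(gp) > 0) {
    gp <- gp[order(gp$participant_id, gp$trial_index), ]
    for (ch in c("expectancy", "distress")) {
      col <- if (ch == "expectancy") "rating" else "distress"
      first <- gp[!duplicated(gp[c("participant_id", "stimulus")]), ]
      dat <- tibble::tibble(participant_id = first$participant_id,
                            stimulus = first$stimulus,
                            value = first[[col]])
      r <- rm_anova_oneway(dat)
      r$analysis <- "generalization"; r$channel <- ch
      rows[[length(rows) + 1]] <- r
    }
  }
  dplyr::bind_rows(rows)
}

isTRUE_vec <- function(x) !is.na(x) & x
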