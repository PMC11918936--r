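.clamp_sum <- function(x, range) {
  as.integer(pmin(range[2], pmax(range[1], round(x))))
}

.z_or_zero <- function(x) {
  z <- .zscore(x)
  if (is.null(z)) z <- rep(0, length(x))
  z[is.na(z)] <- 0
  z
}

#' Simulate questionnaire panels and weekly follow-up series
#'
#' Generates the longitudinal questionnaire side of a synthetic cohort:
#' baseline (Part 1) DASS-21 subscale and GAD-7 sums, Part 2/3 follow-ups
#' with planted learning-index effects and index-by-stressor interactions on
#' the Z scale, the disappointing-failure indicator, negative-life-event
#' counts and weighted burden (waves with the event list only), ATS-G and
#' impact-of-event sums for the failed subgroup, and the 10-week weekly
#' impact-of-event series drawn from latent quadratic trajectory classes
#' with random intercepts and slopes.
#'
#' A Part 2/3 outcome on the Z scale is
#' `stability * Z(baseline) + sum(w_j * Z(index_j)) + failure_effect *
#' failed_c + nle_effect * Z(NLE) + interactions + noise`, mapped onto the
#' instrument range by `round()` and clamping. Missing index values
#' contribute 0 (their Z column is zero-filled), so planted weights act on
#' the available cases.
#'
#' @param latents Latents tibble from [draw_latents()], optionally with
#'   `has_cost_phase` / `has_NLE` wave flags (default all `TRUE`).
#' @param index_table An `index_table` from [compute_index_table()] for the
#'   same participants (source of the Z-scored indices that planted effects
#'   act on).
#' @param params Parameter list from [cohort_params()].
#' @return List with `panels` (wide, one row per participant) and
#'   `ies_weekly` (long: `participant_id`, `week` 0..9, `ies`). Uses the
#'   session RNG.
#' @export
simulate_questionnaires <- function(latents, index_table,
                                    params = cohort_params()) {
  n <- nrow(latents)
  idx <- index_table$indices
  stopifnot(nrow(idx) == n)
  P <- params$outcome
  has_nle <- if ("has_NLE" %in% names(latents)) latents$has_NLE else
    rep(TRUE, n)

  part2 <- stats::runif(n) < params$participation$p_part2
  part3 <- part2 & (stats::runif(n) < params$participation$p_part3)
  failed <- part2 & (stats::runif(n) < params$stressor$p_fail)
  failed_c <- as.numeric(failed) - mean(failed[part2])

  nle_count <- rep(NA_integer_, n)
  nle_weighted <- rep(NA_integer_, n)
  take_nle <- part2 & has_nle
  nle_count[take_nle] <- pmin(stats::rpois(sum(take_nle),
                                           params$stressor$nle_mean), 33L)
  nle_weighted[take_nle] <- vapply(nle_count[take_nle], function(k) {
    if (k == 0) 0L else
      sum(sample(params$stressor$nle_impact_range[1]:
                   params$stressor$nle_impact_range[2], k, replace = TRUE))
  }, integer(1))
  z_nle_count <- .z_or_zero(nle_count)
  z_nle_weighted <- .z_or_zero(nle_weighted)

  zcol <- function(name) {
    z <- idx[[paste0("Z_", name)]]
    if (is.null(z)) stop("unknown planted index: ", name)
    z[is.na(z)] <- 0
    z
  }
  planted_sum <- function(instr) {
    w <- P$planted_weights[[instr]]
    out <- numeric(n)
    for (nm in names(w)) out <- out + w[[nm]] * zcol(nm)
    iw <- P$interaction_weights[[instr]]
    for (nm in names(iw)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      mod <- switch(parts[2],
                    failed = failed_c,
                    NLE_count = z_nle_count,
                    NLE_weighted = z_nle_weighted,
                    stop("unknown stressor in interaction: ", nm))
      out <- out + iw[[nm]] * zcol(parts[1]) * mod
    }
    out
  }

  panels <- tibble::tibble(
    participant_id = latents$participant_id,
    has_cost_phase = if ("has_cost_phase" %in% names(latents))
      latents$has_cost_phase else rep(TRUE, n),
    has_NLE = has_nle,
    part2 = part2, part3 = part3,
    failed_disappointed = failed,
    NLE_count = nle_count, NLE_weighted = nle_weighted
  )

  core <- c("DASS_A", "DASS_S", "DASS_D", "GAD7")
  base_z <- matrix(stats::rnorm(n * length(core)), n,
                   dimnames = list(NULL, core))
  for (instr in core) {
    ins <- P$instruments[[instr]]
    panels[[paste0(instr, "_1")]] <-
      .clamp_sum(ins$mean + ins$sd * base_z[, instr], ins$range)
    for (part in 2:3) {
      yz <- P$stability * base_z[, instr] + planted_sum(instr) +
        P$failure_effect * failed_c +
        P$nle_effect * z_nle_count +
        P$sigma_out * stats::rnorm(n)
      y <- .clamp_sum(ins$mean + ins$sd * yz, ins$range)
      take <- if (part == 2) part2 else part3
      y[!take] <- NA_integer_
      panels[[paste0(instr, "_", part)]] <- y
    }
  }

  ats <- P$instruments$ATS_G
  for (part in 2:3) {
    yz <- planted_sum("ATS_G") + P$sigma_out * stats::rnorm(n)
    y <- .clamp_sum(ats$mean + ats$sd * yz, ats$range)
    take <- failed & (if (part == 2) part2 else part3)
    y[!take] <- NA_integer_
    panels[[paste0("ATS_G_", part)]] <- y
  }

  # --- impact-of-event trajectories for the failed subgroup -------------
  ies <- params$ies
  K <- length(ies$proportions)
  logits <- matrix(log(ies$proportions), n, K, byrow = TRUE)
  for (nm in names(ies$class_coupling)) {
    zl <- .z_or_zero(latents[[nm]])
    logits <- logits + outer(zl, ies$class_coupling[[nm]])
  }
  pr <- exp(logits - apply(logits, 1, max))
  pr <- pr / rowSums(pr)
  cls <- vapply(seq_len(n), function(i) sample.int(K, 1, prob = pr[i, ]),
                integer(1))
  u0 <- stats::rnorm(n, 0, ies$random_sd["intercept"])
  u1 <- stats::rnorm(n, 0, ies$random_sd["slope"])
  curve <- function(i, t) {
    b <- ies$coefficients[cls[i], ]
    b[1] + b[2] * t + b[3] * t^2 + u0[i] + u1[i] * t
  }
  panels$ies_class <- ifelse(failed, cls, NA_integer_)
  ies2 <- ies3 <- rep(NA_integer_, n)
  weekly <- vector("list", n)
  for (i in seq_len(n)) {
    if (!failed[i]) next
    ies2[i] <- .clamp_sum(curve(i, 0) + stats::rnorm(1, 0, ies$residual_sd),
                          c(0, 45))
    if (part3[i]) {
      ies3[i] <- .clamp_sum(curve(i, 3) + stats::rnorm(1, 0, ies$residual_sd),
                            c(0, 45))
    }
    wk <- 0:(ies$n_weeks - 1)
    present <- stats::runif(length(wk)) < ies$week_present_p
    if (!any(present)) present[1] <- TRUE
    y <- .clamp_sum(curve(i, wk[present]) +
                      stats::rnorm(sum(present), 0, ies$residual_sd),
                    c(0, 45))
    weekly[[i]] <- tibble::tibble(
      participant_id = latents$participant_id[i],
      week = wk[present], ies = y
    )
  }
  panels$IES_2 <- ies2
  panels$IES_3 <- ies3

  list(panels = panels, ies_weekly = dplyr::bind_rows(weekly))
}

#' Generate a complete synthetic cohort
#'
#' End-to-end generator for a cohort with known ground truth: draws latent
#' learning parameters, simulates the three counterbalanced task days
#' (trial-level expectancy/distress ratings, avoidance presses, outcome
#' delivery), computes the learning-index table, and simulates the
#' questionnaire panels and weekly follow-ups with the planted effects in
#' `params`. A cohort wave without the cost phase and the life-event list
#' (emulating a protocol addition after the first collection year) is
#' assigned at rate `params$p_wave1`.
#'
#' All randomness flows from `seed`; two calls with identical arguments
#' produce identical datasets.
#'
#' @param n Number of participants (>= 1).
#' @param params Parameter list from [cohort_params()].
#' @param design A `task_design`; defaults to `build_task_design(20201001)`,
#'   the package's fixed reference schedule.
#' @param seed Integer seed.
#' @return An object of class `cohort_dataset`: list with `trials` (long
#'   trial records), `panels`, `ies_weekly`, `latents` (ground truth),
#'   `index_table`, `us_categories`, `design`, `seed`, `params`.
#' @export
#' @examples
#' coh <- generate_cohort(8, seed = 7)
#' dplyr::count(coh$trials, phase)
generate_cohort <- function(n, params = cohort_params(), design = NULL,
                            seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive integer")
  }
  n <- as.integer(n)
  if (is.null(design)) design <- build_task_design(20201001)
  set.seed(seed)

  lat <- draw_latents(n, params)
  wave1 <- stats::runif(n) < params$p_wave1
  lat$has_cost_phase <- !wave1
  lat$has_NLE <- !wave1

  cats <- names(params$us_category_probs)
  us_categories <- tibble::tibble(
    participant_id = rep(seq_len(n), each = 3),
    day = rep(1:3, n),
    us_category = sample(cats, 3 * n, replace = TRUE,
                         prob = params$us_category_probs)
  )

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    cb <- counterbalance(i)
    trials[[i]] <- .simulate_participant_trials(
      i, lat[i, ], design, cb, params$v0, lat$has_cost_phase[i]
    )
  }
  trials <- dplyr::bind_rows(trials)
  trials$expectancy <- trials$rating
  trials <- trials[, c("participant_id", "day", "task", "phase",
                       "trial_index", "stimulus", "reinforced",
                       "avoidance_available", "cost_applies", "expectancy",
                       "distress", "avoided", "press_latency",
                       "us_delivered", "value")]
  # the index layer reads the generic `rating` column name
  trials$rating <- trials$expectancy

  index_table <- compute_index_table(trials)
  q <- simulate_questionnaires(lat, index_table, params)

  structure(
    list(trials = trials, panels = q$panels, ies_weekly = q$ies_weekly,
         latents = lat, index_table = index_table,
         us_categories = us_categories, design = design, seed = seed,
         params = params),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>", nrow(x$panels), "participants, seed", x$seed, "\n")
  cat(" ", nrow(x$trials), "trial records;",
      sum(x$panels$failed_disappointed, na.rm = TRUE),
      "in the failed-exam subgroup\n")
  invisible(x)
}
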