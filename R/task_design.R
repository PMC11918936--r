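#' Stimulus roles on the CS- ... CS+ size continuum
#'
#' The six stimulus roles used across the three conditioning tasks: the
#' threat cue (CS+), the safety cue (CS-), and the four generalization
#' stimuli (GS1-GS4) intermediate in size between them. `similarity_rank`
#' places each role on the ordinal CS- to CS+ continuum (CS- = 0,
#' GS1..GS4 = 1..4, CS+ = 5).
#'
#' @return A tibble with columns `label` and `similarity_rank`.
#' @export
#' @examples
#' stimulus_roles()
stimulus_roles <- function() {
  tibble::tibble(
    label = c("CS_MINUS", "GS1", "GS2", "GS3", "GS4", "CS_PLUS"),
    similarity_rank = 0:5
  )
}

.tasks <- c("EXTINCTION_DAY", "AVOIDANCE_DAY", "GENERALIZATION_DAY")
.phases <- c("ACQUISITION", "EXTINCTION", "AVOIDANCE_NOCOST",
             "AVOIDANCE_COST", "GENERALIZATION")

.task_orders <- function() {
  # all 6 permutations of the three tasks, fixed lexicographic order
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) .tasks[p])
}

.trial_tbl <- function(task, phase, stimulus, reinforced) {
  tibble::tibble(
    task = task,
    phase = phase,
    trial_index = seq_along(stimulus),
    stimulus = stimulus,
    reinforced = reinforced,
    avoidance_available = phase %in% c("AVOIDANCE_NOCOST", "AVOIDANCE_COST"),
    cost_applies = phase == "AVOIDANCE_COST"
  )
}

# one acquisition phase: 8 CS+ / 8 CS-, 6 of 8 CS+ reinforced (75%),
# CS+ presentations 1 and 2 always reinforced, remaining 4 placed by the
# seeded shuffle among presentations 3..8
.build_acquisition <- function(gen, task) {
  stim <- .constrained_shuffle(gen, rep(c("CS_PLUS", "CS_MINUS"), each = 8))
  extra <- .minstd_shuffle(gen, 3:8)[1:4]
  reinforced_ord <- c(1L, 2L, sort(extra))
  plus_ord <- cumsum(stim == "CS_PLUS")
  reinforced <- stim == "CS_PLUS" & plus_ord %in% reinforced_ord
  .trial_tbl(task, "ACQUISITION", stim, reinforced)
}

.build_extinction <- function(gen) {
  stim <- .constrained_shuffle(gen, rep(c("CS_PLUS", "CS_MINUS"), each = 12))
  .trial_tbl("EXTINCTION_DAY", "EXTINCTION", stim, FALSE)
}

.build_avoidance <- function(gen, phase) {
  stim <- .constrained_shuffle(gen, rep(c("CS_PLUS", "CS_MINUS"), each = 6))
  # CS+ always reinforced unless avoided in time; delivery is resolved at
  # simulation/recording time, the schedule carries the contingency
  .trial_tbl("AVOIDANCE_DAY", phase, stim, stim == "CS_PLUS")
}

.build_generalization <- function(gen) {
  stim <- .constrained_shuffle(gen, rep(stimulus_roles()$label, each = 2))
  .trial_tbl("GENERALIZATION_DAY", "GENERALIZATION", stim, stim == "CS_PLUS")
}

#' Build the fixed three-day conditioning task design
#'
#' Constructs the complete trial schedule grammar for the three task days.
#' Each day starts with a fear-acquisition phase (8 CS+ / 8 CS- trials, six
#' of the eight CS+ presentations reinforced, i.e. a 75% reinforcement rate)
#' followed by the day's own task: extinction (12 CS+ / 12 CS-, never
#' reinforced), avoidance (a no-cost and a response-cost phase of 6 CS+ /
#' 6 CS- each, CS+ reinforced unless avoided in time), or generalization
#' (2 trials of each of CS+, CS-, GS1-GS4, CS+ reinforced on both).
#'
#' Stimulus orders are drawn once from a dedicated Lehmer stream seeded by
#' `order_seed` under a constrained shuffle (no more than three consecutive
#' presentations of the same stimulus) and are identical for every
#' participant, emulating a trial order randomized once before the study and
#' then fixed.
#'
#' @param order_seed Integer seed for the schedule stream.
#' @return An object of class `task_design`: a list with `schedules` (named
#'   list mapping task to a list of phase tibbles), `order_seed`, and the
#'   timing metadata of a trial (CS duration, rating windows, ITI; recorded
#'   only, never used computationally).
#' @export
#' @examples
#' d <- build_task_design(1)
#' nrow(d$schedules$EXTINCTION_DAY$ACQUISITION)
build_task_design <- function(order_seed) {
  gen <- .minstd_new(order_seed)
  schedules <- list(
    EXTINCTION_DAY = list(
      ACQUISITION = .build_acquisition(gen, "EXTINCTION_DAY"),
      EXTINCTION = .build_extinction(gen)
    ),
    AVOIDANCE_DAY = list(
      ACQUISITION = .build_acquisition(gen, "AVOIDANCE_DAY"),
      AVOIDANCE_NOCOST = .build_avoidance(gen, "AVOIDANCE_NOCOST"),
      AVOIDANCE_COST = .build_avoidance(gen, "AVOIDANCE_COST")
    ),
    GENERALIZATION_DAY = list(
      ACQUISITION = .build_acquisition(gen, "GENERALIZATION_DAY"),
      GENERALIZATION = .build_generalization(gen)
    )
  )
  structure(
    list(
      schedules = schedules,
      order_seed = order_seed,
      timing = list(cs_s = 12, expectancy_window_s = 7,
                    distress_window_s = 5, us_s = 1, iti_s = 2)
    ),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat("<task_design> order_seed =", x$order_seed, "\n")
  for (task in names(x$schedules)) {
    ph <- vapply(x$schedules[[task]], nrow, integer(1))
    cat(" ", task, ":", paste(names(ph), ph, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Counterbalancing assignment for one participant
#'
#' Deterministic cyclic counterbalancing of the task-day order (six
#' permutations of extinction/avoidance/generalization days) and of the
#' shape-to-role mapping (which shape of each day's pair serves as CS+;
#' two options). Cycling over participant ids balances both factors: over
#' any block of 12 consecutive ids each task order occurs twice and each
#' role mapping six times.
#'
#' @param participant_id Integer id, >= 1.
#' @param n_conditions Number of task-order conditions; fixed at 6.
#' @return A list with `task_order` (character vector of the three tasks in
#'   day order), `role_swap` (logical; `TRUE` means the alternate
#'   shape-to-CS+ mapping) and `order_index` (1..6).
#' @export
#' @examples
#' counterbalance(1)$task_order
counterbalance <- function(participant_id, n_conditions = 6L) {
  stopifnot(length(participant_id) == 1, participant_id >= 1,
            n_conditions == 6L)
  id0 <- as.integer(participant_id) - 1L
  order_index <- (id0 %% 6L) + 1L
  role_swap <- ((id0 %/% 6L) %% 2L) == 1L
  list(
    task_order = .task_orders()[[order_index]],
    role_swap = role_swap,
    order_index = order_index
  )
}

#' Counterbalance table for a set of participants
#'
#' @param ids Integer vector of participant ids.
#' @return A tibble with one row per participant: `participant_id`,
#'   `day1`/`day2`/`day3` task assignment and `role_swap`.
#' @export
counterbalance_table <- function(ids) {
  rows <- lapply(ids, function(id) {
    cb <- counterbalance(id)
    tibble::tibble(
      participant_id = id,
      day1 = cb$task_order[1], day2 = cb$task_order[2],
      day3 = cb$task_order[3], role_swap = cb$role_swap
    )
  })
  dplyr::bind_rows(rows)
}

#' Validate a phase schedule against the design invariants
#'
#' Checks a single phase tibble (as produced by [build_task_design()])
#' against the trial-count, reinforcement and flag invariants of its phase.
#' Returns a character vector of human-readable violations (empty when the
#' schedule is valid); each violation names the offending rule and, where
#' applicable, trial indices.
#'
#' @param schedule A phase tibble with columns `phase`, `trial_index`,
#'   `stimulus`, `reinforced`, `avoidance_available`, `cost_applies`.
#' @return Character vector of violation descriptions.
#' @export
validate_schedule <- function(schedule) {
  v <- character(0)
  need <- c("phase", "trial_index", "stimulus", "reinforced",
            "avoidance_available", "cost_applies")
  if (!all(need %in% names(schedule))) {
    return(paste("missing columns:",
                 paste(setdiff(need, names(schedule)), collapse = ", ")))
  }
  phase <- schedule$phase[1]
  n <- nrow(schedule)
  cnt <- function(s) sum(schedule$stimulus == s)
  reinf_plus <- sum(schedule$reinforced & schedule$stimulus == "CS_PLUS")

  bad <- schedule$trial_index[schedule$reinforced &
                                schedule$stimulus != "CS_PLUS"]
  if (length(bad) > 0) {
    v <- c(v, paste0("reinforced non-CS+ trial(s) at trial_index ",
                     paste(bad, collapse = ",")))
  }
  if (!identical(schedule$trial_index, seq_len(n))) {
    v <- c(v, "trial_index is not 1..n within phase")
  }
  avail_expected <- phase %in% c("AVOIDANCE_NOCOST", "AVOIDANCE_COST")
  if (any(schedule$avoidance_available != avail_expected)) {
    v <- c(v, paste0("avoidance_available must be ", avail_expected,
                     " in phase ", phase))
  }
  cost_expected <- phase == "AVOIDANCE_COST"
  if (any(schedule$cost_applies != cost_expected)) {
    v <- c(v, paste0("cost_applies must be ", cost_expected,
                     " in phase ", phase))
  }

  if (phase == "ACQUISITION") {
    if (cnt("CS_PLUS") != 8 || cnt("CS_MINUS") != 8) {
      v <- c(v, paste0("acquisition needs 8 CS+ and 8 CS- trials, got ",
                       cnt("CS_PLUS"), "/", cnt("CS_MINUS")))
    }
    if (reinf_plus != 6) {
      v <- c(v, paste0("acquisition reinforcement count must be 6 of 8 CS+ ",
                       "(75%), got ", reinf_plus))
    }
  } else if (phase == "EXTINCTION") {
    if (cnt("CS_PLUS") != 12 || cnt("CS_MINUS") != 12) {
      v <- c(v, paste0("extinction needs 12 CS+ and 12 CS- trials, got ",
                       cnt("CS_PLUS"), "/", cnt("CS_MINUS")))
    }
    if (any(schedule$reinforced)) {
      v <- c(v, "extinction trials must not be reinforced")
    }
  } else if (phase %in% c("AVOIDANCE_NOCOST", "AVOIDANCE_COST")) {
    if (cnt("CS_PLUS") != 6 || cnt("CS_MINUS") != 6) {
      v <- c(v, paste0(phase, " needs 6 CS+ and 6 CS- trials, got ",
                       cnt("CS_PLUS"), "/", cnt("CS_MINUS")))
    }
    if (reinf_plus != 6) {
      v <- c(v, paste0(phase, " must reinforce all 6 CS+ trials, got ",
                       reinf_plus))
    }
  } else if (phase == "GENERALIZATION") {
    roles <- stimulus_roles()$label
    miss <- roles[vapply(roles, cnt, integer(1)) != 2]
    if (length(miss) > 0) {
      v <- c(v, paste0("generalization needs 2 trials of each role; wrong ",
                       "count for ", paste(miss, collapse = ",")))
    }
    if (reinf_plus != 2) {
      v <- c(v, paste0("generalization must reinforce both CS+ trials, got ",
                       reinf_plus))
    }
  } else {
    v <- c(v, paste0("unknown phase ", phase))
  }
  v
}

#' Validate every phase of a task design
#'
#' @param design A `task_design` object.
#' @return Character vector of violations across all phases (empty if valid).
#' @export
validate_design <- function(design) {
  out <- character(0)
  for (task in names(design$schedules)) {
    for (ph in names(design$schedules[[task]])) {
      vv <- validate_schedule(design$schedules[[task]][[ph]])
      if (length(vv) > 0) out <- c(out, paste0(task, "/", ph, ": ", vv))
    }
  }
  out
}

#' Flatten a task design to one long trial table
#'
#' One row per scheduled trial with columns `day`, `task`, `phase`,
#' `trial_index`, `stimulus`, `reinforced`, `avoidance_available`,
#' `cost_applies`. `day` is the canonical day of the task in the reference
#' order (extinction, avoidance, generalization); per-participant day
#' assignment comes from [counterbalance()]. This is the export format
#' documented in the README; [write_schedule()] / [read_schedule()]
#' round-trip it through delimited text.
#'
#' @param design A `task_design` object.
#' @return A tibble.
#' @export
design_trials <- function(design) {
  out <- dplyr::bind_rows(lapply(design$schedules, dplyr::bind_rows))
  out$day <- match(out$task, .tasks)
  out[, c("day", setdiff(names(out), "day"))]
}
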