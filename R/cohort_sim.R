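# Trial-level generative model: a minimal Rescorla-Wagner / logistic /
# similarity-gradient stack. Associative strength V lives on [0, 1]; a rating
# is round(clamp(10 * V + noise, 0, 10)). The CS- starts from a level
# inflated by (1 - alpha_minus) and decays toward 0 at rate alpha_minus, so a
# safety-learning deficit (small alpha_minus) produces sustained CS-
# responding independently of CS+ acquisition.

.clamp_rating <- function(x) as.integer(pmin(10, pmax(0, round(x))))

.rate <- function(v, eps_sd) {
  .clamp_rating(10 * v + stats::rnorm(length(v), 0, eps_sd))
}

.distress_rate <- function(v, gamma, eps_sd) {
  .clamp_rating(10 * gamma * v + stats::rnorm(length(v), 0, eps_sd))
}

.cs_minus_start <- function(v0, alpha_minus) {
  v0 + (1 - alpha_minus) * (1 - v0)
}

#' Simulate an expectancy-rating series for one schedule
#'
#' Runs the trial-level learning model over one phase schedule for a single
#' participant. CS+ associative strength updates as `V <- V + a * (lambda -
#' V)` with `lambda = 1` when the aversive outcome is delivered on that trial
#' and 0 otherwise; `a` is `alpha_plus` during acquisition and avoidance and
#' `beta_ext` during extinction. The CS- starts from `v0 + (1 -
#' alpha_minus) * (1 - v0)` and decays toward 0 at rate `alpha_minus`.
#' The integer rating on each trial reflects the pre-update strength (the
#' expectancy reported at stimulus onset, before the outcome).
#'
#' @param latents One-row data frame (or list) of latent parameters as in
#'   [draw_latents()].
#' @param schedule A phase tibble from [build_task_design()] (acquisition or
#'   extinction).
#' @param v0 Initial CS+ strength, in `[0, 1]`.
#' @return Tibble with `trial_index`, `stimulus`, `value` (pre-noise V) and
#'   `rating` (integer 0..10). Uses the session RNG for the rating noise.
#' @export
#' @examples
#' d <- build_task_design(1)
#' lat <- list(alpha_plus = 1, alpha_minus = 1, beta_ext = 0.3, eps_sd = 0)
#' set.seed(1)
#' simulate_expectancy_series(lat, d$schedules$EXTINCTION_DAY$ACQUISITION)
simulate_expectancy_series <- function(latents, schedule, v0 = 0.05) {
  if (!is.numeric(v0) || length(v0) != 1 || is.na(v0) || v0 < 0 || v0 > 1) {
    stop("`v0` must be a single number in [0, 1]")
  }
  st <- list(v_plus = v0,
             v_minus = .cs_minus_start(v0, latents$alpha_minus))
  out <- .simulate_learning_phase(latents, schedule, st)
  out$df[c("trial_index", "stimulus", "value", "rating")]
}

# core driver for acquisition/extinction phases (no avoidance option)
.simulate_learning_phase <- function(lat, schedule, state) {
  n <- nrow(schedule)
  value <- numeric(n)
  us <- logical(n)
  ext <- schedule$phase[1] == "EXTINCTION"
  for (i in seq_len(n)) {
    if (schedule$stimulus[i] == "CS_PLUS") {
      value[i] <- state$v_plus
      us[i] <- isTRUE(schedule$reinforced[i])
      a <- if (ext) lat$beta_ext else lat$alpha_plus
      state$v_plus <- state$v_plus + a * (as.numeric(us[i]) - state$v_plus)
    } else {
      value[i] <- state$v_minus
      state$v_minus <- state$v_minus + lat$alpha_minus * (0 - state$v_minus)
    }
  }
  df <- schedule
  df$value <- value
  df$rating <- .rate(value, lat$eps_sd)
  df$us_delivered <- us
  df$avoided <- NA
  df$press_latency <- NA_real_
  list(df = df, state = state)
}

#' Simulate one avoidance decision
#'
#' Bernoulli avoidance with press probability
#' `plogis(pi_avoid + 4 * V - kappa_cost * cost_applies)`; given a press,
#' the latency is uniform on 0..2 s (presses always land inside the
#' effective window).
#'
#' @param latents Latent parameter list/row (`pi_avoid`, `kappa_cost`).
#' @param V Current associative strength of the presented stimulus, in
#'   `[0, 1]`.
#' @param cost_applies Logical; does the response cost a point?
#' @return List with `avoided` (logical) and `press_latency` (seconds, `NA`
#'   when no press).
#' @export
simulate_avoidance <- function(latents, V, cost_applies = FALSE) {
  stopifnot(is.numeric(V), length(V) == 1, V >= 0, V <= 1)
  p <- stats::plogis(latents$pi_avoid + 4 * V -
                       latents$kappa_cost * as.numeric(cost_applies))
  avoided <- stats::runif(1) < p
  list(avoided = avoided,
       press_latency = if (avoided) stats::runif(1, 0, 2) else NA_real_)
}

.avoid_prob <- function(lat, V, cost_applies) {
  stats::plogis(lat$pi_avoid + 4 * V -
                  lat$kappa_cost * as.numeric(cost_applies))
}

.simulate_avoidance_phase <- function(lat, schedule, state) {
  n <- nrow(schedule)
  value <- numeric(n)
  avoided <- logical(n)
  lat_s <- rep(NA_real_, n)
  us <- logical(n)
  for (i in seq_len(n)) {
    plus <- schedule$stimulus[i] == "CS_PLUS"
    v <- if (plus) state$v_plus else state$v_minus
    value[i] <- v
    p <- .avoid_prob(lat, v, schedule$cost_applies[i])
    avoided[i] <- stats::runif(1) < p
    if (avoided[i]) lat_s[i] <- stats::runif(1, 0, 2)
    us[i] <- isTRUE(schedule$reinforced[i]) && !avoided[i]
    if (plus) {
      state$v_plus <- state$v_plus +
        lat$alpha_plus * (as.numeric(us[i]) - state$v_plus)
    } else {
      state$v_minus <- state$v_minus + lat$alpha_minus * (0 - state$v_minus)
    }
  }
  df <- schedule
  df$value <- value
  df$rating <- .rate(value, lat$eps_sd)
  df$us_delivered <- us
  df$avoided <- avoided
  df$press_latency <- lat_s
  list(df = df, state = state)
}

#' Expected first-trial generalization gradient
#'
#' Gaussian similarity gradient over the ordinal CS- .. CS+ continuum:
#' `V(role) = v_minus + (v_plus - v_minus) * exp(-((5 - rank) / sigma_gen)^2)`
#' where `rank` is the role's `similarity_rank` (see [stimulus_roles()]).
#' The expected values are monotone nonincreasing from CS+ down to CS-.
#'
#' @param latents Latent parameter list/row (`sigma_gen`).
#' @param v_plus,v_minus End-point strengths, `v_plus >= v_minus`, both in
#'   `[0, 1]`.
#' @return Tibble with `label`, `similarity_rank` and `value`, ordered
#'   CS-, GS1..GS4, CS+.
#' @export
#' @examples
#' simulate_generalization(list(sigma_gen = 2), 1, 0)
simulate_generalization <- function(latents, v_plus, v_minus) {
  stopifnot(is.numeric(v_plus), is.numeric(v_minus))
  if (v_plus < v_minus) stop("`v_plus` must be >= `v_minus`")
  roles <- stimulus_roles()
  roles$value <- .gen_values(latents$sigma_gen, v_plus, v_minus,
                             roles$similarity_rank)
  roles
}

.gen_values <- function(sigma_gen, v_plus, v_minus, rank) {
  v_minus + (v_plus - v_minus) * exp(-(((5 - rank) / sigma_gen)^2))
}

.simulate_generalization_phase <- function(lat, schedule, state) {
  roles <- stimulus_roles()
  # gradient anchored at the day's post-acquisition strengths; no dynamic
  # update across the 12 trials (the index uses first presentations only)
  vals <- .gen_values(lat$sigma_gen, state$v_plus, state$v_minus,
                      roles$similarity_rank)
  names(vals) <- roles$label
  df <- schedule
  df$value <- unname(vals[schedule$stimulus])
  df$rating <- .rate(df$value, lat$eps_sd)
  df$us_delivered <- schedule$reinforced
  df$avoided <- NA
  df$press_latency <- NA_real_
  list(df = df, state = state)
}

# simulate the three task days for one participant; returns a long tibble
.simulate_participant_trials <- function(id, lat, design, cb, v0, has_cost) {
  out <- vector("list", 8)
  k <- 0
  for (day in 1:3) {
    task <- cb$task_order[day]
    phases <- design$schedules[[task]]
    state <- list(v_plus = v0,
                  v_minus = .cs_minus_start(v0, lat$alpha_minus))
    for (ph in names(phases)) {
      if (ph == "AVOIDANCE_COST" && !has_cost) next
      res <- switch(
        ph,
        ACQUISITION = .simulate_learning_phase(lat, phases[[ph]], state),
        EXTINCTION = .simulate_learning_phase(lat, phases[[ph]], state),
        AVOIDANCE_NOCOST = .simulate_avoidance_phase(lat, phases[[ph]], state),
        AVOIDANCE_COST = .simulate_avoidance_phase(lat, phases[[ph]], state),
        GENERALIZATION = .simulate_generalization_phase(lat, phases[[ph]],
                                                        state)
      )
      state <- res$state
      df <- res$df
      df$distress <- .distress_rate(df$value, lat$gamma_distress, lat$eps_sd)
      df$participant_id <- id
      df$day <- day
      k <- k + 1
      out[[k]] <- df
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}
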