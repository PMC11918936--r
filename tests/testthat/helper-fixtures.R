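# Shared fixtures, all built in code.

# deterministic latents for single-participant simulations
fixed_latents <- function(alpha_plus = 0.4, alpha_minus = 0.5,
                          beta_ext = 0.3, pi_avoid = 0, kappa_cost = 1,
                          sigma_gen = 2, gamma_distress = 0.8, eps_sd = 0) {
  list(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
       beta_ext = beta_ext, pi_avoid = pi_avoid, kappa_cost = kappa_cost,
       sigma_gen = sigma_gen, gamma_distress = gamma_distress,
       eps_sd = eps_sd)
}

# one participant-day of hand-specified trial data in the long format the
# index layer consumes; ratings are recycled over the schedule rows
hand_trials <- function(id, day, task, phase, stimulus, rating,
                        distress = rating, avoided = NA,
                        press_latency = NA_real_) {
  n <- length(stimulus)
  tibble::tibble(
    participant_id = id, day = day, task = task, phase = phase,
    trial_index = seq_len(n), stimulus = stimulus,
    reinforced = FALSE, avoidance_available = FALSE, cost_applies = FALSE,
    rating = rating, distress = distress,
    avoided = avoided, press_latency = press_latency,
    us_delivered = FALSE
  )
}

# alternating acquisition day (8 CS+ / 8 CS-) with given per-stimulus series
hand_acquisition <- function(id, day, task, csp, csm, csp_d = csp,
                             csm_d = csm) {
  stim <- rep(c("CS_PLUS", "CS_MINUS"), 8)
  rating <- integer(16); dis <- integer(16)
  rating[stim == "CS_PLUS"] <- csp; rating[stim == "CS_MINUS"] <- csm
  dis[stim == "CS_PLUS"] <- csp_d; dis[stim == "CS_MINUS"] <- csm_d
  hand_trials(id, day, task, "ACQUISITION", stim, rating, dis)
}

# weekly series with planted quadratic classes
make_weekly <- function(n, seed, coefs, props, sd_int = 2, sd_slope = 0.3,
                        sd_res = 3, weeks = 0:9) {
  set.seed(seed)
  cls <- sample(seq_len(nrow(coefs)), n, TRUE, prob = props)
  rows <- lapply(seq_len(n), function(i) {
    b <- coefs[cls[i], ]
    u0 <- stats::rnorm(1, 0, sd_int); u1 <- stats::rnorm(1, 0, sd_slope)
    tibble::tibble(
      participant_id = i, week = weeks,
      ies = b[1] + b[2] * weeks + b[3] * weeks^2 + u0 + u1 * weeks +
        stats::rnorm(length(weeks), 0, sd_res)
    )
  })
  list(data = dplyr::bind_rows(rows), class = cls)
}

# generator configuration with every planted questionnaire effect removed
null_outcome_params <- function(...) {
  cohort_params(outcome = list(planted_weights = NULL,
                               interaction_weights = NULL,
                               failure_effect = 0, nle_effect = 0), ...)
}

# the well-separated 3-class scenario used in recovery checks
sep3_coefs <- rbind(c(35, -0.5, 0.02), c(25, -2.5, 0.12), c(10, -0.8, 0.05))

# small cohort shared by several test files (generated once per run)
shared_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(200, seed = 11)
    coh
  }
})
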