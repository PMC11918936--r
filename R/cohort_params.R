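#' Default parameters for the synthetic-cohort generator
#'
#' Returns the full parameter list controlling [generate_cohort()]: the
#' population distributions of the latent learning parameters, the
#' questionnaire outcome model (baseline means/sds, stability, planted
#' index weights and index-by-stressor interaction weights on the Z scale),
#' the stressor model (failure probability, negative-life-event count law),
#' the latent impact-of-event trajectory classes, and the participation
#' (dropout) structure. Any element can be overridden through `...` using
#' `utils::modifyList()` semantics, e.g.
#' `cohort_params(outcome = list(planted_weights = list()))`.
#'
#' The defaults emulate a first-year-student cohort measured across an
#' academic year: moderately fast threat learning with a heavy enough slow
#' tail to yield a nontrivial nonlearner fraction, a 40% rate of
#' disappointing exam failure, thin-tailed life-event counts, and three
#' latent coping-trajectory classes following quadratic curves over the ten
#' weekly follow-ups (a persistent-impact, an adjustment, and an
#' early-disengagement shape). See the methods vignette for the rationale
#' behind each value.
#'
#' @param ... Named overrides merged into the default list.
#' @return A named list of parameter groups: `latents`, `v0`, `outcome`,
#'   `stressor`, `ies`, `participation`, `us_category_probs`, `p_wave1`.
#' @export
#' @examples
#' p <- cohort_params(stressor = list(p_fail = 0.5))
#' p$stressor$p_fail
cohort_params <- function(...) {
  defaults <- list(
    # population laws of the per-participant latent learning parameters
    latents = list(
      alpha_plus = c(shape1 = 2.2, shape2 = 1.1),   # Beta; CS+ learning rate
      alpha_minus = c(shape1 = 2.0, shape2 = 1.0),  # Beta; safety learning
      beta_ext = c(shape1 = 1.2, shape2 = 4.0),     # Beta; right-skewed: within
                                                    # one session extinction is
                                                    # mostly incomplete, with a
                                                    # clear impaired tail
      p_nonlearner = 0.12,  # unengaged subpopulation: both learning rates
      nonlearner = c(shape1 = 1.0, shape2 = 8.0),   # redrawn from this Beta
      pi_avoid = c(mean = -2.5, sd = 1.5),          # Normal, logit scale
      kappa_cost = c(shape = 2.0, scale = 0.75),    # Gamma; cost sensitivity
      sigma_gen = c(meanlog = log(2), sdlog = 0.4), # LogNormal; gradient width
      gamma_distress = c(meanlog = log(0.8), sdlog = 0.35), # LogNormal
      eps_sd = c(min = 0.8, max = 1.6),             # Uniform; rating noise
      # opt-in latent coupling: adds couple_avoid_acq * Z(alpha_plus) to
      # pi_avoid, so threat acquisition and avoidance propensity covary
      couple_avoid_acq = 0
    ),
    v0 = 0.05,  # initial CS+ associative strength
    outcome = list(
      # instrument scale: mean/sd of baseline sums, hard range
      instruments = list(
        DASS_A = list(mean = 4.5, sd = 3.5, range = c(0, 21)),
        DASS_S = list(mean = 7.0, sd = 4.0, range = c(0, 21)),
        DASS_D = list(mean = 4.5, sd = 4.0, range = c(0, 21)),
        GAD7   = list(mean = 6.0, sd = 4.5, range = c(0, 21)),
        ATS_G  = list(mean = 12.0, sd = 3.0, range = c(4, 20))
      ),
      stability = 0.6,    # Z-scale autoregressive weight on the baseline
      sigma_out = 0.75,   # Z-scale residual sd of Part 2/3 outcomes
      # planted index -> outcome weights (Z scale), per outcome instrument;
      # defaults mirror a safety-learning-deficit diathesis pattern
      planted_weights = list(
        DASS_S = c(ACQ_CSminus = 0.12),
        DASS_D = c(ACQ_CSminus = 0.10),
        GAD7   = c(AV_CSplus = 0.08),
        ATS_G  = c(ACQ_CSminus = 0.15)
      ),
      # planted index-by-stressor interaction weights; term names are
      # "<index>:failed", "<index>:NLE_count" or "<index>:NLE_weighted"
      interaction_weights = list(
        DASS_S = c("ACQ_CSplus:NLE_count" = 0.10)
      ),
      failure_effect = 0.35,  # Z-scale main effect of disappointing failure
      nle_effect = 0.15       # Z-scale effect per SD of NLE count/burden
    ),
    stressor = list(
      p_fail = 0.40,        # P(failed and disappointed) among Part-2 takers
      nle_mean = 3.5,       # Poisson mean of the life-event count (cap 33)
      nle_impact_range = c(0, 10)
    ),
    ies = list(
      proportions = c(0.25, 0.45, 0.30),
      # per class: intercept, linear, quadratic coefficient over weeks 0..9
      coefficients = rbind(
        persistent    = c(30, -0.4, 0.02),
        adjustment    = c(26, -2.8, 0.14),
        disengagement = c(18, -4.2, 0.30)
      ),
      random_sd = c(intercept = 4, slope = 0.5),
      residual_sd = 3,
      n_weeks = 10,
      # multinomial-logit coupling of class membership to Z-scored latents;
      # one shift per class, emulating higher avoidance propensity and
      # stronger distress gain in the persistent-impact class
      class_coupling = list(
        pi_avoid = c(0.6, 0, -0.6),
        gamma_distress = c(0.5, 0, -0.5)
      ),
      week_present_p = 0.93
    ),
    participation = list(p_part2 = 0.88, p_part3 = 0.92),
    us_category_probs = c(mild = 0.155, moderate = 0.155, severe = 0.69),
    p_wave1 = 1 / 3   # fraction of the cohort without cost phase and NLE list
  )
  ov <- list(...)
  if (length(ov) > 0) {
    stopifnot(!is.null(names(ov)), all(names(ov) %in% names(defaults)))
    defaults <- utils::modifyList(defaults, ov)
  }
  defaults
}

#' Draw per-participant latent learning parameters
#'
#' @param n Number of participants.
#' @param params Parameter list from [cohort_params()].
#' @return Tibble with one row per participant and one column per latent.
#' @export
draw_latents <- function(n, params = cohort_params()) {
  stopifnot(n >= 1)
  L <- params$latents
  nonlearner <- stats::runif(n) < L$p_nonlearner
  alpha_plus <- stats::rbeta(n, L$alpha_plus[1], L$alpha_plus[2])
  alpha_minus <- stats::rbeta(n, L$alpha_minus[1], L$alpha_minus[2])
  alpha_plus[nonlearner] <- stats::rbeta(sum(nonlearner), L$nonlearner[1],
                                         L$nonlearner[2])
  alpha_minus[nonlearner] <- stats::rbeta(sum(nonlearner), L$nonlearner[1],
                                          L$nonlearner[2])
  pi_avoid <- stats::rnorm(n, L$pi_avoid[1], L$pi_avoid[2])
  if (L$couple_avoid_acq != 0 && stats::sd(alpha_plus) > 0) {
    pi_avoid <- pi_avoid +
      L$couple_avoid_acq * as.numeric(scale(alpha_plus))
  }
  tibble::tibble(
    participant_id = seq_len(n),
    nonlearner = nonlearner,
    alpha_plus = alpha_plus,
    alpha_minus = alpha_minus,
    beta_ext = stats::rbeta(n, L$beta_ext[1], L$beta_ext[2]),
    pi_avoid = pi_avoid,
    kappa_cost = stats::rgamma(n, shape = L$kappa_cost[1],
                               scale = L$kappa_cost[2]),
    sigma_gen = stats::rlnorm(n, L$sigma_gen[1], L$sigma_gen[2]),
    gamma_distress = stats::rlnorm(n, L$gamma_distress[1],
                                   L$gamma_distress[2]),
    eps_sd = stats::runif(n, L$eps_sd[1], L$eps_sd[2])
  )
}
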