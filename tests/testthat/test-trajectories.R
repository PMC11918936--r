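test_that("growth bases produce the documented design columns", {
  t <- 0:9
  expect_equal(dim(growth_basis("quadratic")(t)), c(10, 3))
  expect_equal(growth_basis("quadratic")(t)[, 3], t^2)
  expect_equal(growth_basis("cubic")(t)[, 4], t^3)
  expect_equal(growth_basis("logarithmic")(t)[, 2], log(t + 1))
  expect_true(all(is.finite(growth_basis("logarithmic")(0:9))))
})

test_that("a noise-free common curve is recovered exactly", {
  wk <- 0:9
  df <- dplyr::bind_rows(lapply(1:30, function(i) {
    tibble::tibble(participant_id = i, week = wk,
                   ies = 30 - 4 * wk + 0.2 * wk^2)
  }))
  fit <- fit_single_growth(df, "quadratic")
  expect_equal(unname(fit$beta[, 1]), c(30, -4, 0.2), tolerance = 1e-8)
  expect_true(fit$sigma_floor)
})

test_that("the single-class fit matches lme4 maximum likelihood", {
  w <- make_weekly(80, seed = 5, coefs = matrix(c(25, -2.5, 0.12), 1),
                   props = 1, sd_int = 3, sd_slope = 0.5, sd_res = 3)
  fit <- fit_single_growth(w$data, "quadratic")
  lm4 <- lme4::lmer(ies ~ week + I(week^2) + (1 + week | participant_id),
                    data = w$data, REML = FALSE)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(lm4)),
               tolerance = 1e-5)
  expect_equal(unname(fit$beta[, 1]), unname(lme4::fixef(lm4)),
               tolerance = 1e-3)
  expect_true(fit$monotone_ok)
  # K = 1 mixture reduces to the single-class model (nesting identity)
  g1 <- fit_gmm(w$data, "quadratic", "random_intercept_slope", K = 1,
                n_starts = 1)
  expect_equal(g1$log_likelihood, fit$log_likelihood, tolerance = 1e-6)
})

test_that("BIC prefers the quadratic shape on quadratic data", {
  wins <- 0
  for (s in 1:10) {
    w <- make_weekly(60, seed = 700 + s,
                     coefs = matrix(c(25, -3, 0.22), 1), props = 1,
                     sd_int = 3, sd_slope = 0.4, sd_res = 3)
    bics <- vapply(c("linear", "quadratic", "cubic", "logarithmic"),
                   function(sh) fit_single_growth(w$data, sh)$BIC,
                   numeric(1))
    if (names(which.min(bics)) == "quadratic") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("a superfluous cubic term stays nonsignificant", {
  ps <- vapply(1:5, function(s) {
    w <- make_weekly(80, seed = 800 + s,
                     coefs = matrix(c(25, -3, 0.22), 1), props = 1,
                     sd_int = 3, sd_slope = 0.4, sd_res = 3)
    fit <- fit_single_growth(w$data, "cubic")
    fit$wald$p[fit$wald$term == "t3"]
  }, numeric(1))
  expect_gt(stats::median(ps), 0.1)
})

test_that("free-parameter counts back the information criteria", {
  w <- make_weekly(40, seed = 6, coefs = sep3_coefs, props = c(.3, .4, .3))
  for (eff in c("fixed_only", "random_intercept",
                "random_intercept_slope")) {
    fit <- fit_gmm(w$data, "quadratic", eff, K = 2, n_starts = 3, seed = 2)
    qvar <- switch(eff, fixed_only = 0, random_intercept = 1,
                   random_intercept_slope = 3)
    expect_equal(fit$n_par, (2 - 1) + 2 * 3 + qvar + 1)
    expect_equal(fit$BIC, -2 * fit$log_likelihood +
                   fit$n_par * log(fit$n), tolerance = 1e-10)
    expect_equal(fit$AIC, -2 * fit$log_likelihood + 2 * fit$n_par,
                 tolerance = 1e-10)
    expect_true(fit$monotone_ok)
    expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-8))
    expect_equal(sum(fit$pi), 1, tolerance = 1e-8)
  }
})

test_that("three separated classes are recovered at the study scale", {
  w <- make_weekly(216, seed = 9, coefs = sep3_coefs,
                   props = c(.3, .4, .3))
  fits <- lapply(1:4, function(K) {
    fit_gmm(w$data, "quadratic", "random_intercept_slope", K = K,
            n_starts = 8, seed = K)
  })
  sel <- select_mixture(fits)
  expect_equal(sel$K, 3)
  cmp <- attr(sel, "comparison")
  expect_equal(nrow(cmp), 4)
  asg <- assign_classes(sel)
  # planted class 1 has the highest intercept, so labels align directly
  expect_gte(mean(asg$assignment$class == w$class), 0.9)
  expect_gte(mean(asg$assignment$max_posterior), 0.9)
  expect_gt(asg$entropy, 0.8)
  expect_true(all(abs(sort(asg$pi, decreasing = TRUE) -
                        sort(table(w$class) / 216, decreasing = TRUE)) <
                    0.1))
})

test_that("class relabelling and tie-breaking follow the declared rules", {
  fake <- structure(list(
    K = 2L, shape = "quadratic", effects = "fixed_only",
    beta = matrix(c(10, -1, 0.1, 30, -2, 0.2), 3, 2),
    pi = c(0.6, 0.4),
    posterior = rbind(c(0.9, 0.1), c(0.05, 0.95), c(0.5, 0.5)),
    participant_id = 1:3
  ), class = "trajectory_fit")
  asg <- assign_classes(fake)
  # column 2 (intercept 30) becomes class 1
  expect_identical(asg$order, c(2L, 1L))
  expect_identical(asg$assignment$class, c(2L, 1L, 1L))  # tie -> class 1
  expect_equal(asg$assignment$max_posterior[3], 0.5)
})

test_that("mixture selection honours convergence and tie rules", {
  mk <- function(bic, npar, conv) structure(
    list(K = 2L, BIC = bic, AIC = bic, log_likelihood = -1, n_par = npar,
         shape = "quadratic", effects = "fixed_only", converged = conv),
    class = "trajectory_fit")
  fits <- list(mk(100, 5, TRUE), mk(90, 8, FALSE), mk(100, 4, TRUE))
  sel <- select_mixture(fits)
  expect_equal(sel$n_par, 4)  # unconverged 90 skipped; tie -> fewer params
  expect_error(select_mixture(list(mk(10, 2, FALSE))), "converged")
})

test_that("class-index tests match hand-computed statistics", {
  # Kruskal-Wallis oracle on a small 3-group fixture with a forced
  # non-normal index (heavy outliers trip the gate)
  x <- c(1, 1, 2, 2, 50, 2, 3, 3, 4, 60, 5, 5, 6, 7, 80)
  g <- rep(1:3, each = 5)
  idxtbl <- structure(list(indices = tibble::tibble(
    participant_id = 1:15, ACQ_CSplus = x, Z_ACQ_CSplus = x
  )), class = "index_table")
  asg <- tibble::tibble(participant_id = 1:15, class = g,
                        max_posterior = 1)
  out <- class_index_tests(asg, idxtbl, indices = "ACQ_CSplus")
  r <- out$results
  expect_identical(r$method, "kruskal")
  # longhand H statistic with average ranks
  rk <- rank(x)
  n <- 15
  H <- 12 / (n * (n + 1)) *
    sum(tapply(rk, g, function(v) length(v) * mean(v)^2)) - 3 * (n + 1)
  ties <- table(rk)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(r$value, H, tolerance = 1e-12)
  expect_equal(r$effect_size, (H - 3 + 1) / (n - 3), tolerance = 1e-12)
  expect_true("1" %in% rownames(out$posthoc$ACQ_CSplus) ||
                "2" %in% rownames(out$posthoc$ACQ_CSplus))
})

test_that("planted class differences in avoidance are detected", {
  # strong coupling: the persistent class has much higher avoidance
  p <- cohort_params(
    stressor = list(p_fail = 0.9),
    participation = list(p_part2 = 1, p_part3 = 1),
    ies = list(class_coupling = list(pi_avoid = c(2.5, 0, -2.5)))
  )
  coh <- generate_cohort(350, params = p, seed = 19)
  pan <- coh$panels[!is.na(coh$panels$ies_class), ]
  asg <- tibble::tibble(participant_id = pan$participant_id,
                        class = pan$ies_class, max_posterior = 1)
  out <- class_index_tests(asg, coh$index_table,
                           indices = c("AV_CSplus", "AV_CSminus"))
  expect_lt(out$results$p_value[out$results$index == "AV_CSplus"], 0.05)

  # permuted labels are calibrated: no effect on average
  set.seed(77)
  ps <- replicate(10, {
    asg$class <- sample(asg$class)
    class_index_tests(asg, coh$index_table,
                      indices = "AV_CSplus")$results$p_value
  })
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("singleton classes are dropped with a warning", {
  idxtbl <- structure(list(indices = tibble::tibble(
    participant_id = 1:9, ACQ_CSplus = stats::rnorm(9),
    Z_ACQ_CSplus = stats::rnorm(9)
  )), class = "index_table")
  asg <- tibble::tibble(participant_id = 1:9,
                        class = c(rep(1L, 4), rep(2L, 4), 3L),
                        max_posterior = 1)
  expect_warning(out <- class_index_tests(asg, idxtbl, "ACQ_CSplus"),
                 "fewer than 3")
  expect_error(
    suppressWarnings(class_index_tests(
      tibble::tibble(participant_id = 1:9,
                     class = c(rep(1L, 8), 2L), max_posterior = 1),
      idxtbl, "ACQ_CSplus")),
    "at least 2 classes")
})
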