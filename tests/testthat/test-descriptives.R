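make_cells <- function(m) {
  # m: matrix with columns CS_PLUS_first, CS_PLUS_last, CS_MINUS_first,
  # CS_MINUS_last
  tibble::tibble(
    participant_id = rep(seq_len(nrow(m)), 4),
    stimulus = rep(c("CS_PLUS", "CS_PLUS", "CS_MINUS", "CS_MINUS"),
                   each = nrow(m)),
    time = rep(c("first", "last", "first", "last"), each = nrow(m)),
    value = c(m)
  )
}

test_that("parallel change yields a zero interaction", {
  m <- cbind(c(1, 2, 3, 4), c(4, 5, 6, 7), c(0, 1, 2, 3), c(3, 4, 5, 6))
  r <- rm_anova_2x2(make_cells(m))
  inter <- r[r$effect == "Stimulus:Time", ]
  expect_equal(inter$value, 0)
  expect_true(inter$degenerate)
})

test_that("the 2x2 decomposition matches a brute-force aov oracle", {
  set.seed(8)
  m <- matrix(sample(0:10, 16, TRUE), 4)
  colnames(m) <- c("CS_PLUS_first", "CS_PLUS_last", "CS_MINUS_first",
                   "CS_MINUS_last")
  cells <- make_cells(m)
  r <- rm_anova_2x2(cells)
  # oracle: classical within-subject aov with an Error stratum per effect
  df <- cells
  df$stimulus <- factor(df$stimulus); df$time <- factor(df$time)
  df$participant_id <- factor(df$participant_id)
  ao <- summary(stats::aov(
    value ~ stimulus * time +
      Error(participant_id / (stimulus * time)), data = df))
  f_or <- c(
    Stimulus = ao[["Error: participant_id:stimulus"]][[1]]["stimulus",
                                                           "F value"],
    Time = ao[["Error: participant_id:time"]][[1]]["time", "F value"],
    `Stimulus:Time` = ao[["Error: participant_id:stimulus:time"]][[1]][
      "stimulus:time", "F value"]
  )
  for (eff in names(f_or)) {
    expect_equal(r$value[r$effect == eff], unname(f_or[eff]),
                 tolerance = 1e-10, info = eff)
  }
  # partial eta^2 identity for single-df within effects
  expect_equal(r$effect_size, r$value / (r$value + r$df2), tolerance = 1e-12)
  expect_true(all(r$effect_size >= 0 & r$effect_size <= 1))
})

test_that("a simulated acquiring cohort shows the expected interaction", {
  coh <- shared_cohort()
  trials <- coh$trials[coh$trials$phase == "ACQUISITION", ]
  fl <- dplyr::summarise(
    dplyr::group_by(trials, participant_id, stimulus),
    first = rating[trial_index == min(trial_index)][1],
    last = rating[trial_index == max(trial_index)][1], .groups = "drop")
  cells <- tidyr::pivot_longer(fl, c("first", "last"), names_to = "time",
                               values_to = "value")
  r <- rm_anova_2x2(cells)
  inter <- r[r$effect == "Stimulus:Time", ]
  expect_lt(inter$p_value, 0.001)
  expect_gt(inter$effect_size, 0.1)
})

test_that("one-way within-subject ANOVA matches its oracle", {
  d0 <- tibble::tibble(participant_id = rep(1:4, each = 6),
                       stimulus = rep(letters[1:6], 4),
                       value = rep(c(2, 5, 7, 1), each = 6))
  r0 <- rm_anova_oneway(d0)
  expect_equal(r0$value, 0)

  set.seed(12)
  d <- tibble::tibble(participant_id = rep(1:5, each = 6),
                      stimulus = rep(letters[1:6], 5),
                      value = sample(0:10, 30, TRUE))
  r <- rm_anova_oneway(d)
  # brute-force sums of squares
  y <- matrix(d$value, 5, 6, byrow = TRUE)
  grand <- mean(y)
  ss_stim <- 5 * sum((colMeans(y) - grand)^2)
  ss_subj <- 6 * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_stim
  expect_equal(r$value, (ss_stim / 5) / (ss_err / 20), tolerance = 1e-10)
  expect_equal(r$effect_size, ss_stim / ss_tot, tolerance = 1e-12)
  # and against aov
  dd <- d; dd$stimulus <- factor(dd$stimulus)
  dd$participant_id <- factor(dd$participant_id)
  ao <- summary(stats::aov(value ~ stimulus + Error(participant_id),
                           data = dd))
  expect_equal(r$value,
               ao[["Error: Within"]][[1]]["stimulus", "F value"],
               tolerance = 1e-10)
})

test_that("the generalization gradient is monotone in the simulated cohort", {
  coh <- shared_cohort()
  gp <- coh$trials[coh$trials$phase == "GENERALIZATION", ]
  keep <- coh$index_table$indices
  gp <- gp[gp$participant_id %in%
             keep$participant_id[isTRUE_vec(keep$retained_generalization)], ]
  gp <- gp[order(gp$participant_id, gp$trial_index), ]
  first <- gp[!duplicated(gp[c("participant_id", "stimulus")]), ]
  means <- tapply(first$rating, first$stimulus, mean)
  ord <- c("CS_MINUS", "GS1", "GS2", "GS3", "GS4", "CS_PLUS")
  expect_true(all(diff(means[ord]) > 0))
})

test_that("t-tests match closed forms and flag zero variance", {
  r <- t_tests(rep(0, 6))
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))

  x <- c(4, 6, 7, 3, 5, 6); y <- c(3, 4, 6, 3, 3, 4)
  r <- t_tests(x, y, mode = "paired")
  o <- stats::t.test(x, y, paired = TRUE)
  expect_equal(r$value, unname(o$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, o$p.value, tolerance = 1e-12)
  d <- x - y
  expect_equal(r$effect_size, mean(d) / stats::sd(d), tolerance = 1e-12)

  r1 <- t_tests(x)
  o1 <- stats::t.test(x)
  expect_equal(r1$value, unname(o1$statistic), tolerance = 1e-12)
})

test_that("simulated avoidance counts show a large one-sample effect", {
  idx <- shared_cohort()$index_table$indices
  av <- idx$AV_CSplus[!is.na(idx$AV_CSplus)]
  r <- t_tests(av)
  expect_gt(r$effect_size, 0.8)
  expect_lt(r$p_value, 0.001)
})

test_that("Cronbach's alpha matches the brute-force formula", {
  x <- matrix(rep(c(1, 3, 2, 5, 4, 2), 4), ncol = 4)
  expect_equal(cronbach_alpha(x)$value, 1, tolerance = 1e-12)

  set.seed(3)
  m <- matrix(sample(0:3, 24, TRUE), 6, 4)
  a <- cronbach_alpha(m)$value
  oracle <- 4 / 3 * (1 - sum(apply(m, 2, stats::var)) /
                       stats::var(rowSums(m)))
  expect_equal(a, oracle, tolerance = 1e-12)

  set.seed(7)
  ind <- matrix(stats::rnorm(2000 * 4), ncol = 4)  # independent items
  expect_lt(abs(cronbach_alpha(ind)$value), 0.1)

  # perfectly anticorrelated items: the total has zero variance
  expect_true(cronbach_alpha(cbind(c(1, 2, 1, 2), c(2, 1, 2, 1)))$degenerate)
})

test_that("correlations switch method on the normality gate", {
  set.seed(21)
  x <- stats::rnorm(60)
  r <- correlate(x, 2 * x + 3)
  expect_equal(r$value, 1, tolerance = 1e-12)
  expect_identical(r$method, "pearson")

  xt <- stats::rt(60, df = 1)           # heavy-tailed
  r2 <- correlate(xt, exp(xt))          # monotone nonlinear transform
  expect_identical(r2$method, "spearman")
  expect_equal(r2$value, 1, tolerance = 1e-12)

  # 10-pair fixture against cor() oracles under forced policies
  set.seed(9)
  a <- stats::rnorm(10); b <- a + stats::rnorm(10)
  expect_equal(correlate(a, b, policy = "pearson")$value,
               stats::cor(a, b), tolerance = 1e-12)
  expect_equal(correlate(a, b, policy = "spearman")$value,
               stats::cor(a, b, method = "spearman"), tolerance = 1e-12)
  expect_true(correlate(rep(1, 10), a)$degenerate)
})

test_that("pairwise index correlations enumerate all pairs", {
  coh <- shared_cohort()
  pc <- pairwise_index_correlations(coh$index_table, "primary-7")
  expect_equal(nrow(pc), choose(7, 2))
  expect_true(all(abs(pc$value) <= 1, na.rm = TRUE))

  # a duplicated index correlates perfectly with itself
  idx <- coh$index_table$indices
  idx$EXT_Full <- idx$EXT_Early
  pc2 <- pairwise_index_correlations(idx, "primary-7")
  row <- pc2[pc2$index_a == "EXT_Early" & pc2$index_b == "EXT_Full", ]
  expect_equal(row$value, 1, tolerance = 1e-12)

  # opt-in latent coupling of threat learning and avoidance propensity
  # surfaces as a positive acquisition-avoidance correlation
  p <- cohort_params(latents = list(couple_avoid_acq = 1.5))
  coupled <- generate_cohort(400, params = p, seed = 31)
  pc3 <- pairwise_index_correlations(coupled$index_table, "primary-7")
  row <- pc3[pc3$index_a == "ACQ_CSplus" & pc3$index_b == "AV_CSplus", ]
  expect_gt(row$value, 0)
  expect_lt(row$p_value, 0.05)
})
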