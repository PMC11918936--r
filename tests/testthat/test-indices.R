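test_that("differential responding compares the final three trials strictly", {
  csp <- c(0, 1, 3, 5, 7, 8, 9, 10)
  csm <- c(2, 1, 1, 0, 1, 1, 2, 0)
  expect_true(differential_responding(csp, csm))
  expect_false(differential_responding(rep(5, 8), rep(5, 8)))  # ties exclude
  expect_error(differential_responding(csp[-1], csm), "8")
})

test_that("acquisition index is the plain mean of the eight ratings", {
  expect_equal(acquisition_index(c(0, 2, 4, 6, 8, 10, 10, 10)), 6.25)
  expect_equal(acquisition_index(rep(0, 8)), 0)
  expect_error(acquisition_index(1:7), "8 ratings")
})

# independent oracle for the bracketing rule: scan all pairs longhand
midway_oracle <- function(m) {
  mid <- (m[1] + m[12]) / 2
  hits <- which(m[1:11] >= mid & m[2:12] <= mid)
  if (length(hits) > 0) return(as.integer(c(hits[1], hits[1] + 1)))
  d <- abs((m[1:11] + m[2:12]) / 2 - mid)
  t <- which(d == min(d))[1]
  as.integer(c(t, t + 1))
}

test_that("the extinction midway point follows the declared bracketing rule", {
  lin <- seq(10, 2, length.out = 12)
  mw <- extinction_midway(lin)
  expect_equal(mw$midpoint_value, 6)
  expect_identical(mw$bracket, midway_oracle(lin))

  flat <- rep(5, 12)
  mw <- extinction_midway(flat)
  expect_equal(mw$midpoint_value, 5)
  expect_identical(mw$bracket, c(1L, 2L))

  mono <- seq(10, 0, length.out = 12)
  mw <- extinction_midway(mono)
  expect_equal(mw$bracket[2], which(mono <= 5)[1])

  # never crosses downward: fallback pair closest to the midpoint
  rising <- seq(2, 10, length.out = 12)
  mw <- extinction_midway(rising)
  expect_false(mw$crossed)
  expect_identical(mw$bracket, midway_oracle(rising))

  # randomized curves agree with the longhand scan
  set.seed(4)
  for (i in 1:50) {
    m <- round(stats::runif(12, 0, 10), 2)
    expect_identical(extinction_midway(m)$bracket, midway_oracle(m))
  }
  expect_error(extinction_midway(rep(3, 11)), "12")
})

test_that("extinction indices carry the reverse-scored sign convention", {
  r <- c(10, 9, 8, 4, 5, 6, 3, 2, 2, 1, 0, 0)
  mw <- list(bracket = c(4L, 6L))
  expect_equal(ext_early_index(r, mw), mean(c(4, 6)) - 10)  # -5
  expect_equal(ext_full_index(c(10, rep(5, 9), 0, 0)), -10)
  expect_equal(ext_early_index(rep(7, 12), mw), 0)
  expect_equal(ext_full_index(rep(7, 12)), 0)
  expect_equal(ext_early_index(c(2, rep(5, 2), 8, 5, 8, rep(9, 6)), mw), 6)
  # strictly decreasing series: both indices strictly negative
  dec <- seq(10, 0, length.out = 12)
  expect_lt(ext_early_index(dec, extinction_midway(dec)), 0)
  expect_lt(ext_full_index(dec), 0)
})

test_that("avoided trials are counted with an inclusive 2-second boundary", {
  expect_equal(avoidance_index(rep(TRUE, 6), rep(1, 6)), 6)
  expect_equal(avoidance_index(rep(FALSE, 6), rep(NA_real_, 6)), 0)
  expect_equal(
    avoidance_index(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                    c(1.9, 2.0, 2.1, NA, 0.5, NA)),
    3
  )
  expect_error(avoidance_index(rep(TRUE, 5), rep(1, 5)), "6")
})

test_that("the generalization index is range-corrected and guarded", {
  expect_equal(generalization_index(10, 0, c(8, 6, 4, 2)), 2.0)
  expect_equal(generalization_index(10, 10, rep(10, 4)), 4.0)
  expect_true(is.na(generalization_index(0, 0, rep(0, 4))))
  # preregistered variant and its degenerate case
  expect_equal(generalization_index(10, 2, c(8, 6, 4, 2), "prereg"),
               (20 - 8) / 8)
  expect_true(is.na(generalization_index(5, 5, c(1, 2, 3, 4), "prereg")))
})

# ---- whole-table oracle on a hand-built five-participant cohort ----------

build_hand_cohort <- function() {
  # day order for ids 1..5 follows counterbalance(); we give everyone the
  # same canonical day-task layout to keep the arithmetic transparent
  csp <- list(
    c(0, 2, 5, 7, 8, 8, 9, 10),
    c(1, 3, 4, 6, 7, 9, 9, 9),
    c(0, 0, 2, 3, 5, 6, 7, 8),
    c(2, 2, 2, 3, 3, 3, 3, 3),   # weak learner, still passes
    c(5, 5, 5, 5, 5, 5, 5, 5)    # fails differential responding everywhere
  )
  csm <- list(
    c(3, 2, 1, 1, 0, 0, 1, 0),
    c(4, 3, 2, 1, 1, 0, 0, 1),
    c(2, 2, 1, 1, 0, 1, 0, 0),
    c(3, 2, 2, 1, 1, 2, 1, 2),
    c(5, 5, 5, 5, 5, 5, 5, 5)
  )
  ext <- list(
    c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0, 0),
    c(9, 9, 8, 8, 7, 6, 6, 5, 5, 4, 4, 3),
    c(8, 7, 5, 4, 3, 2, 2, 1, 1, 0, 0, 0),
    c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3),
    c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5)
  )
  avoided <- list(
    c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  latency <- list(rep(1, 6), c(1.5, NA, 2.0, NA, 0.5, NA), rep(NA_real_, 6),
                  c(2.1, 1.0, NA, NA, NA, NA), rep(0.5, 6))
  gen_first <- list(  # CS+, CS-, GS1..GS4 first-trial ratings
    c(10, 0, 2, 4, 6, 8),
    c(9, 1, 1, 3, 5, 7),
    c(8, 0, 0, 1, 2, 4),
    c(4, 2, 2, 2, 3, 3),
    c(5, 5, 5, 5, 5, 5)
  )
  rows <- list()
  for (i in 1:5) {
    rows[[length(rows) + 1]] <-
      hand_acquisition(i, 1, "EXTINCTION_DAY", csp[[i]], csm[[i]])
    rows[[length(rows) + 1]] <- hand_trials(
      i, 1, "EXTINCTION_DAY", "EXTINCTION",
      rep(c("CS_PLUS", "CS_MINUS"), 12)[1:24],
      rep(0L, 24), rep(0L, 24))
    ext_rows <- rows[[length(rows)]]
    ext_rows$rating[ext_rows$stimulus == "CS_PLUS"] <- ext[[i]]
    ext_rows$distress[ext_rows$stimulus == "CS_PLUS"] <- ext[[i]]
    rows[[length(rows)]] <- ext_rows
    rows[[length(rows) + 1]] <-
      hand_acquisition(i, 2, "AVOIDANCE_DAY", csp[[i]], csm[[i]])
    av <- hand_trials(i, 2, "AVOIDANCE_DAY", "AVOIDANCE_NOCOST",
                      rep(c("CS_PLUS", "CS_MINUS"), 6), rep(5L, 12))
    av$avoidance_available <- TRUE
    av$avoided <- FALSE
    av$avoided[av$stimulus == "CS_PLUS"] <- avoided[[i]]
    av$press_latency[av$stimulus == "CS_PLUS"] <- latency[[i]]
    rows[[length(rows) + 1]] <- av
    rows[[length(rows) + 1]] <-
      hand_acquisition(i, 3, "GENERALIZATION_DAY", csp[[i]], csm[[i]])
    roles <- c("CS_PLUS", "CS_MINUS", "GS1", "GS2", "GS3", "GS4")
    g <- hand_trials(i, 3, "GENERALIZATION_DAY", "GENERALIZATION",
                     rep(roles, 2), rep(c(gen_first[[i]], gen_first[[i]])),
                     rep(c(gen_first[[i]], gen_first[[i]])))
    rows[[length(rows) + 1]] <- g
  }
  dplyr::bind_rows(rows)
}

test_that("compute_index_table equals a longhand spreadsheet calculation", {
  trials <- build_hand_cohort()
  tab <- compute_index_table(trials)
  idx <- tab$indices

  # participant 5 never discriminates: excluded from all three phase days
  expect_false(idx$retained_extinction[5])
  expect_false(idx$retained_avoidance[5])
  expect_false(idx$retained_generalization[5])
  expect_true(all(is.na(idx[5, c("EXT_Early", "EXT_Full", "AV_CSplus",
                                 "AV_CSminus", "GEN")])))
  expect_equal(unname(tab$reduction_log), rep(1, 3))

  # acquisition indices: plain means, present for everyone (day 1)
  expect_equal(idx$ACQ_CSplus[1], mean(c(0, 2, 5, 7, 8, 8, 9, 10)))
  expect_equal(idx$ACQ_CSplus[5], 5)
  expect_equal(idx$ACQ_CSminus[2], mean(c(4, 3, 2, 1, 1, 0, 0, 1)))

  # group midway over retained participants 1-4
  curves <- rbind(
    c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0, 0),
    c(9, 9, 8, 8, 7, 6, 6, 5, 5, 4, 4, 3),
    c(8, 7, 5, 4, 3, 2, 2, 1, 1, 0, 0, 0),
    c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3)
  )
  gm <- colMeans(curves)
  mid <- (gm[1] + gm[12]) / 2
  br <- midway_oracle(gm)
  expect_equal(tab$midway$midpoint_value, mid)
  expect_identical(tab$midway$bracket, br)
  for (i in 1:4) {
    expect_equal(idx$EXT_Early[i],
                 mean(curves[i, br]) - curves[i, 1], info = i)
    expect_equal(idx$EXT_Full[i],
                 mean(curves[i, 11:12]) - curves[i, 1])
  }

  # avoidance counts with the inclusive boundary (participant 4: 2.1 s miss)
  expect_equal(idx$AV_CSplus[1:4], c(6, 3, 0, 1))
  expect_equal(idx$AV_CSminus[1:4], c(0, 0, 0, 0))

  # generalization: sum(GS) / max of all six first-trial ratings
  expect_equal(idx$GEN[1], (2 + 4 + 6 + 8) / 10)
  expect_equal(idx$GEN[4], (2 + 2 + 3 + 3) / 4)

  # Z columns: mean 0, sd 1 over non-missing values
  for (cl in paste0("Z_", c("ACQ_CSplus", "EXT_Full", "AV_CSplus", "GEN"))) {
    v <- idx[[cl]][!is.na(idx[[cl]])]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(stats::sd(v) - 1), 1e-10)
  }
})

test_that("a day-specific exclusion blanks only that day's indices", {
  trials <- build_hand_cohort()
  # make participant 2 fail the avoidance day only
  sel <- trials$participant_id == 2 & trials$day == 2 &
    trials$phase == "ACQUISITION" & trials$stimulus == "CS_PLUS"
  trials$rating[sel] <- 0L
  tab <- compute_index_table(trials)
  idx <- tab$indices
  expect_false(idx$retained_avoidance[2])
  expect_true(is.na(idx$AV_CSplus[2]))
  expect_true(is.na(idx$AV_CSminus[2]))
  expect_false(is.na(idx$EXT_Full[2]))
  expect_false(is.na(idx$GEN[2]))
  expect_false(is.na(idx$ACQ_CSplus[2]))  # day-1 acquisition always kept
})

test_that("degenerate cohorts keep raw values with a warning", {
  trials <- build_hand_cohort()
  solo <- trials[trials$participant_id == 1, ]
  expect_warning(tab <- compute_index_table(solo), "Z-score undefined")
  expect_equal(tab$indices$Z_ACQ_CSplus, tab$indices$ACQ_CSplus)
  expect_error(compute_index_table(trials[0, ]), "empty")
})

test_that("simulated cohorts keep indices inside their hard ranges", {
  coh <- shared_cohort()
  idx <- coh$index_table$indices
  expect_true(all(idx$GEN >= 0 & idx$GEN <= 4, na.rm = TRUE))
  for (cl in c("AV_CSplus", "AV_CSminus", "AV_Cost_CSplus")) {
    v <- idx[[cl]][!is.na(idx[[cl]])]
    expect_true(all(v %in% 0:6), info = cl)
  }
  for (cl in c("EXT_Early", "EXT_Full")) {
    v <- idx[[cl]][!is.na(idx[[cl]])]
    expect_true(all(v >= -10 & v <= 10), info = cl)
  }
  # exclusion fraction strictly between 0 and 0.5 under default latents
  ex <- coh$index_table$exclusions
  frac <- mean(!ex$retained)
  expect_gt(frac, 0)
  expect_lt(frac, 0.5)
})
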