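#' Differential-responding check for one participant-day
#'
#' A participant shows differential responding during a day's acquisition
#' when the mean US-expectancy over the final three CS+ presentations is
#' strictly higher than over the final three CS- presentations. Participants
#' failing this check on a given day are excluded from that day's
#' phase-specific indices (nonlearner exclusion).
#'
#' @param csplus,csminus Integer ratings of the 8 CS+ and 8 CS- acquisition
#'   presentations, in presentation order.
#' @return `TRUE` iff `mean(csplus[6:8]) > mean(csminus[6:8])` (strict).
#' @export
#' @examples
#' differential_responding(c(0, 2, 5, 7, 8, 8, 9, 10), rep(1, 8))
differential_responding <- function(csplus, csminus) {
  if (length(csplus) != 8 || length(csminus) != 8 ||
      anyNA(csplus) || anyNA(csminus)) {
    stop("differential responding needs 8 complete CS+ and 8 CS- ratings")
  }
  mean(csplus[6:8]) > mean(csminus[6:8])
}

#' Acquisition index: mean response over the day-1 acquisition phase
#'
#' @param ratings The 8 ratings (expectancy or distress) for one stimulus
#'   during the first day's acquisition phase.
#' @return Arithmetic mean of the 8 ratings.
#' @export
acquisition_index <- function(ratings) {
  if (length(ratings) != 8 || anyNA(ratings)) {
    stop("acquisition index needs the 8 ratings of one stimulus on day 1")
  }
  mean(ratings)
}

#' Group-level extinction midway point
#'
#' Locates the point of the group CS+ extinction curve where conditioned
#' responding has halved: the midpoint value is the average of the group
#' means on trials 1 and 12, and the bracket is the first consecutive trial
#' pair `(t, t + 1)` with `mean[t] >= midpoint >= mean[t + 1]` (the first
#' downward crossing). A flat or immediately sub-midpoint curve yields the
#' degenerate bracket `(1, 2)`; a curve that never crosses yields the pair
#' whose average is closest to the midpoint, earliest on ties.
#'
#' @param group_means Numeric vector of 12 group mean CS+ ratings, one per
#'   extinction presentation, computed over retained participants.
#' @return List with `midpoint_value`, `bracket` (length-2 integer vector)
#'   and `crossed` (logical; `FALSE` when the fallback rule was used).
#' @export
extinction_midway <- function(group_means) {
  if (length(group_means) != 12 || anyNA(group_means)) {
    stop("the group extinction curve needs 12 complete trial means")
  }
  mid <- (group_means[1] + group_means[12]) / 2
  for (t in 1:11) {
    if (group_means[t] >= mid && mid >= group_means[t + 1]) {
      return(list(midpoint_value = mid, bracket = c(t, t + 1L),
                  crossed = TRUE))
    }
  }
  pair_mid <- (group_means[1:11] + group_means[2:12]) / 2
  t <- which.min(abs(pair_mid - mid))  # earliest on ties
  list(midpoint_value = mid, bracket = c(t, t + 1L), crossed = FALSE)
}

#' Early extinction index for one participant
#'
#' Average rating on the two trials bracketing the group midway point,
#' minus the rating on the first extinction trial. This is the
#' reverse-scored early decline: positive values mean reduced (or reversed)
#' extinction up to the group midway point, negative values mean decline.
#'
#' @param ratings The participant's 12 CS+ ratings across extinction.
#' @param midway Midway object from [extinction_midway()]. The distress
#'   variant of the index reuses the expectancy-based midway.
#' @return `mean(ratings[bracket]) - ratings[1]`.
#' @export
ext_early_index <- function(ratings, midway) {
  if (length(ratings) != 12) stop("extinction needs 12 CS+ ratings")
  b <- midway$bracket
  if (anyNA(ratings[c(1, b)])) stop("missing rating on trial 1 or bracket")
  mean(ratings[b]) - ratings[1]
}

#' Full extinction index for one participant
#'
#' Average of the last two extinction trials minus the first trial:
#' the reverse-scored whole-phase decline (positive = reduced extinction).
#'
#' @param ratings The participant's 12 CS+ ratings across extinction.
#' @return `mean(ratings[11:12]) - ratings[1]`.
#' @export
ext_full_index <- function(ratings) {
  if (length(ratings) != 12 || anyNA(ratings[c(1, 11, 12)])) {
    stop("extinction needs 12 CS+ ratings with trials 1, 11, 12 present")
  }
  mean(ratings[11:12]) - ratings[1]
}

#' Avoidance index: successfully avoided trials of one stimulus
#'
#' Counts trials on which the spacebar was pressed within the first 2 s
#' (boundary inclusive). Computed per stimulus within the no-cost phase
#' (primary) or for the CS+ within the cost phase (secondary).
#'
#' @param avoided Logical vector of length 6 (press performed).
#' @param press_latency Latencies in seconds (`NA` when no press).
#' @return Integer count in 0..6.
#' @export
#' @examples
#' avoidance_index(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
#'                 c(1.9, 2.0, 2.1, NA, 0.5, NA))  # 3: 2.0 counts, 2.1 not
avoidance_index <- function(avoided, press_latency) {
  if (length(avoided) != 6 || length(press_latency) != 6 || anyNA(avoided)) {
    stop("avoidance index needs 6 complete trials of one stimulus")
  }
  sum(avoided & !is.na(press_latency) & press_latency <= 2.0)
}

#' Generalization index (range-corrected GS responding)
#'
#' Sum of the first-presentation ratings of the four generalization stimuli
#' divided by the maximum first-presentation rating across all six stimuli
#' (range correction). When that maximum is 0 the index is undefined and
#' `NA` is returned (callers flag the participant). Values lie in `[0, 4]`.
#'
#' The abandoned preregistered variant
#' `(sum(GS) - 4 * CS-) / (CS+ - CS-)` is available via
#' `variant = "prereg"`; it is exposed for sensitivity analyses only and is
#' prone to extreme outliers when CS+ responding is low or CS- responding
#' high (undefined when `CS+ == CS-`).
#'
#' @param cs_plus,cs_minus First-presentation ratings of CS+ and CS-.
#' @param gs Numeric vector of the four GS first-presentation ratings
#'   (GS1..GS4).
#' @param variant `"range"` (default) or `"prereg"`.
#' @return The index value, or `NA` when undefined.
#' @export
#' @examples
#' generalization_index(10, 0, c(8, 6, 4, 2))  # 2.0
generalization_index <- function(cs_plus, cs_minus, gs,
                                 variant = c("range", "prereg")) {
  variant <- match.arg(variant)
  if (length(gs) != 4 || anyNA(c(cs_plus, cs_minus, gs))) {
    stop("generalization index needs first-trial ratings of CS+, CS- and GS1..GS4")
  }
  if (variant == "prereg") {
    if (cs_plus == cs_minus) return(NA_real_)
    return((sum(gs) - 4 * cs_minus) / (cs_plus - cs_minus))
  }
  mx <- max(c(cs_plus, cs_minus, gs))
  if (mx == 0) return(NA_real_)
  sum(gs) / mx
}

# ratings of one stimulus in one phase, ordered by presentation
.stim_series <- function(trials, id, phase_, stim, col) {
  x <- trials[trials$participant_id == id & trials$phase == phase_ &
                trials$stimulus == stim, ]
  x <- x[order(x$trial_index), ]
  x[[col]]
}

.zscore <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) return(NULL)
  s <- stats::sd(x[ok])
  if (s == 0) return(NULL)
  (x - mean(x[ok])) / s
}

#' Compute the learning-index table for a cohort
#'
#' Applies the full data-reduction chain to long-format trial data: the
#' per-day differential-responding exclusion, the seven primary indices
#' (day-1 acquisition means for CS+ and CS-, early and full reverse-scored
#' extinction, no-cost CS+ and CS- avoidance counts, range-corrected
#' generalization), the six secondary indices (distress-channel variants of
#' the acquisition/extinction/generalization indices plus the cost-phase
#' CS+ avoidance count), and per-index Z-scaling over non-missing values.
#'
#' Exclusions are day-specific: a participant failing differential
#' responding on, say, the avoidance day gets missing avoidance indices but
#' keeps extinction/generalization indices if those days pass. Acquisition
#' indices always come from day 1, whichever task that day carried. The
#' group extinction midway point is computed from retained participants
#' only (configurable) on the expectancy channel and reused for the
#' distress early-extinction index.
#'
#' @param trials Long-format trial tibble as produced by
#'   [generate_cohort()] or [read_trials()].
#' @param midway_retained_only Compute the group midway over retained
#'   participants only (default `TRUE`).
#' @param gen_variant Generalization index variant, see
#'   [generalization_index()].
#' @return An object of class `index_table`: a list with
#'   * `indices`: tibble, one row per participant, 13 raw index columns,
#'     13 `Z_`-prefixed columns, retention flags and day-order metadata;
#'   * `exclusions`: per participant-day flags with the last-three means;
#'   * `midway`: the group midway object (expectancy channel);
#'   * `reduction_log`: counts of participants excluded per day.
#' @export
compute_index_table <- function(trials, midway_retained_only = TRUE,
                                gen_variant = c("range", "prereg")) {
  gen_variant <- match.arg(gen_variant)
  if (is.null(trials) || nrow(trials) == 0) stop("empty cohort")
  ids <- sort(unique(trials$participant_id))

  # --- per-day exclusion flags ------------------------------------------
  acq <- trials[trials$phase == "ACQUISITION", ]
  excl <- lapply(ids, function(id) {
    di <- acq[acq$participant_id == id, ]
    days <- sort(unique(di$day))
    rows <- lapply(days, function(d) {
      dd <- di[di$day == d, ]
      dd <- dd[order(dd$trial_index), ]
      csp <- dd$rating[dd$stimulus == "CS_PLUS"]
      csm <- dd$rating[dd$stimulus == "CS_MINUS"]
      if (length(csp) != 8 || length(csm) != 8) {
        stop(sprintf("participant %s day %s: incomplete acquisition data",
                     id, d))
      }
      tibble::tibble(
        participant_id = id, day = d, task = dd$task[1],
        mean_last3_csplus = mean(csp[6:8]),
        mean_last3_csminus = mean(csm[6:8]),
        retained = differential_responding(csp, csm)
      )
    })
    dplyr::bind_rows(rows)
  })
  excl <- dplyr::bind_rows(excl)

  ret_flag <- function(id, task) {
    r <- excl$retained[excl$participant_id == id & excl$task == task]
    if (length(r) == 0) NA else r[1]
  }

  # --- group extinction midway (expectancy channel) ---------------------
  ext_ids <- excl$participant_id[excl$task == "EXTINCTION_DAY" &
                                   excl$retained]
  mw_ids <- if (midway_retained_only) ext_ids else
    unique(excl$participant_id[excl$task == "EXTINCTION_DAY"])
  ext <- trials[trials$phase == "EXTINCTION" &
                  trials$stimulus == "CS_PLUS" &
                  trials$participant_id %in% mw_ids, ]
  midway <- NULL
  if (nrow(ext) > 0) {
    gm <- tapply(ext$rating, ext$trial_index, mean)
    if (length(gm) == 12) midway <- extinction_midway(as.numeric(gm))
  }

  # --- per-participant indices ------------------------------------------
  rows <- lapply(ids, function(id) {
    cb_task <- excl[excl$participant_id == id, ]
    cb_task <- cb_task[order(cb_task$day), ]
    ret_ext <- ret_flag(id, "EXTINCTION_DAY")
    ret_av <- ret_flag(id, "AVOIDANCE_DAY")
    ret_gen <- ret_flag(id, "GENERALIZATION_DAY")

    day1 <- trials[trials$participant_id == id & trials$day == 1 &
                     trials$phase == "ACQUISITION", ]
    day1 <- day1[order(day1$trial_index), ]
    a_csp <- day1$rating[day1$stimulus == "CS_PLUS"]
    a_csm <- day1$rating[day1$stimulus == "CS_MINUS"]
    d_csp <- day1$distress[day1$stimulus == "CS_PLUS"]
    d_csm <- day1$distress[day1$stimulus == "CS_MINUS"]

    out <- tibble::tibble(
      participant_id = id,
      retained_extinction = ret_ext,
      retained_avoidance = ret_av,
      retained_generalization = ret_gen,
      day_order = paste(cb_task$task, collapse = ";"),
      ACQ_CSplus = acquisition_index(a_csp),
      ACQ_CSminus = acquisition_index(a_csm),
      ACQ_Distress_CSplus = acquisition_index(d_csp),
      ACQ_Distress_CSminus = acquisition_index(d_csm),
      EXT_Early = NA_real_, EXT_Full = NA_real_,
      EXT_Distress_Early = NA_real_, EXT_Distress_Full = NA_real_,
      AV_CSplus = NA_real_, AV_CSminus = NA_real_,
      AV_Cost_CSplus = NA_real_,
      GEN = NA_real_, GEN_Distress = NA_real_,
      gen_undefined = FALSE
    )

    if (isTRUE(ret_ext) && !is.null(midway)) {
      e_exp <- .stim_series(trials, id, "EXTINCTION", "CS_PLUS", "rating")
      e_dis <- .stim_series(trials, id, "EXTINCTION", "CS_PLUS", "distress")
      if (length(e_exp) == 12) {
        out$EXT_Early <- ext_early_index(e_exp, midway)
        out$EXT_Full <- ext_full_index(e_exp)
        out$EXT_Distress_Early <- ext_early_index(e_dis, midway)
        out$EXT_Distress_Full <- ext_full_index(e_dis)
      }
    }
    if (isTRUE(ret_av)) {
      nc <- trials[trials$participant_id == id &
                     trials$phase == "AVOIDANCE_NOCOST", ]
      for (stim in c("CS_PLUS", "CS_MINUS")) {
        s <- nc[nc$stimulus == stim, ]
        s <- s[order(s$trial_index), ]
        if (nrow(s) == 6) {
          cnt <- avoidance_index(s$avoided, s$press_latency)
          if (stim == "CS_PLUS") out$AV_CSplus <- cnt else
            out$AV_CSminus <- cnt
        }
      }
      co <- trials[trials$participant_id == id &
                     trials$phase == "AVOIDANCE_COST" &
                     trials$stimulus == "CS_PLUS", ]
      if (nrow(co) == 6) {
        out$AV_Cost_CSplus <- avoidance_index(co$avoided, co$press_latency)
      }
    }
    if (isTRUE(ret_gen)) {
      gp <- trials[trials$participant_id == id &
                     trials$phase == "GENERALIZATION", ]
      first <- gp[order(gp$trial_index), ]
      first <- first[!duplicated(first$stimulus), ]
      if (nrow(first) == 6) {
        r <- stats::setNames(first$rating, first$stimulus)
        d <- stats::setNames(first$distress, first$stimulus)
        gs <- c("GS1", "GS2", "GS3", "GS4")
        out$GEN <- generalization_index(r["CS_PLUS"], r["CS_MINUS"], r[gs],
                                        variant = gen_variant)
        out$GEN_Distress <- generalization_index(d["CS_PLUS"], d["CS_MINUS"],
                                                 d[gs], variant = gen_variant)
        out$gen_undefined <- is.na(out$GEN)
      }
    }
    out
  })
  indices <- dplyr::bind_rows(rows)

  idx_cols <- c("ACQ_CSplus", "ACQ_CSminus", "EXT_Early", "EXT_Full",
                "AV_CSplus", "AV_CSminus", "GEN",
                "ACQ_Distress_CSplus", "ACQ_Distress_CSminus",
                "EXT_Distress_Early", "EXT_Distress_Full", "GEN_Distress",
                "AV_Cost_CSplus")
  for (cl in idx_cols) {
    z <- .zscore(indices[[cl]])
    if (is.null(z)) {
      warning(sprintf(
        "index %s: Z-score undefined (fewer than 2 values or zero sd); raw values retained",
        cl))
      z <- indices[[cl]]
    }
    indices[[paste0("Z_", cl)]] <- z
  }

  per_day <- stats::aggregate(retained ~ task, data = excl,
                              FUN = function(r) sum(!r))
  reduction_log <- stats::setNames(per_day$retained, per_day$task)

  structure(
    list(indices = indices, exclusions = excl, midway = midway,
         reduction_log = reduction_log, index_columns = idx_cols),
    class = "index_table"
  )
}

#' @export
print.index_table <- function(x, ...) {
  cat("<index_table>", nrow(x$indices), "participants\n")
  cat(" excluded per day:",
      paste(names(x$reduction_log), x$reduction_log, sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$midway)) {
    cat(" extinction midway: value", round(x$midway$midpoint_value, 3),
        "bracket", paste(x$midway$bracket, collapse = "-"), "\n")
  }
  invisible(x)
}

#' Names of the primary and secondary learning indices
#'
#' @param set `"primary-7"` (all seven), `"primary-5"` (the preregistered
#'   five: extinction, avoidance, generalization), or `"secondary"` (the six
#'   distress/cost indices).
#' @return Character vector of index column names.
#' @export
index_names <- function(set = c("primary-7", "primary-5", "secondary")) {
  set <- match.arg(set)
  switch(set,
    "primary-7" = c("ACQ_CSplus", "ACQ_CSminus", "EXT_Early", "EXT_Full",
                    "AV_CSplus", "AV_CSminus", "GEN"),
    "primary-5" = c("EXT_Early", "EXT_Full", "AV_CSplus", "AV_CSminus",
                    "GEN"),
    "secondary" = c("ACQ_Distress_CSplus", "ACQ_Distress_CSminus",
                    "EXT_Distress_Early", "EXT_Distress_Full",
                    "GEN_Distress", "AV_Cost_CSplus")
  )
}
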