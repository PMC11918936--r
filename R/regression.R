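# Merges the questionnaire panel with the Z-scored index table; the result
# is the analysis frame all regression helpers work on.

#' Merge panels and learning indices into one analysis frame
#'
#' @param cohort A `cohort_dataset`, or a list with `panels` and an
#'   `index_table`.
#' @return Tibble with one row per participant: panel columns plus the
#'   `Z_`-prefixed index columns and retention flags.
#' @export
analysis_frame <- function(cohort) {
  idx <- cohort$index_table$indices
  keep <- c("participant_id", grep("^Z_", names(idx), value = TRUE),
            "retained_extinction", "retained_avoidance",
            "retained_generalization")
  dplyr::left_join(cohort$panels, idx[keep], by = "participant_id")
}

.zs <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

.stressor_col <- function(data, name) {
  switch(name,
    failed = {
      f <- as.numeric(data$failed_disappointed)
      f - mean(f, na.rm = TRUE)
    },
    NLE_count = .zs(data$NLE_count),
    NLE_weighted = .zs(data$NLE_weighted),
    stop("unknown stressor: ", name)
  )
}

.term_col <- function(data, name) {
  if (name %in% c("failed", "NLE_count", "NLE_weighted")) {
    return(.stressor_col(data, name))
  }
  z <- data[[paste0("Z_", name)]]
  if (is.null(z)) stop("unknown term: ", name)
  z
}

.default_baseline <- function(outcome) {
  # ATS-G has no Part-1 administration; anxiety baseline stands in
  if (outcome == "ATS_G") "GAD7" else outcome
}

#' Hierarchical linear regression with baseline covariate
#'
#' Fits the three-step hierarchy used throughout the prediction analyses:
#' (1) outcome on the Part-1 baseline covariate, (2) plus learning-index
#' and stressor main effects, (3) plus interaction terms (products of
#' Z-scored indices and centred/Z-scored stressors; component main effects
#' are always retained). Outcome and baseline are Z-scored over the
#' complete cases, indices enter as their cohort Z-scores, the binary
#' failure indicator is centred and the life-event counts Z-scored, so all
#' coefficients are on the standardized scale. Estimation is ordinary least
#' squares via `stats::lm` with classical standard errors; missing data are
#' handled listwise per model; no multiplicity correction is applied.
#'
#' @param data Analysis frame from [analysis_frame()].
#' @param outcome Instrument name (`"DASS_A"`, `"DASS_S"`, `"DASS_D"`,
#'   `"GAD7"`, `"ATS_G"`).
#' @param part Outcome wave, 2 or 3.
#' @param indices Character vector of learning-index names (main effects).
#' @param interactions Character vector of `"a:b"` terms over indices and
#'   the stressors `failed`, `NLE_count`, `NLE_weighted`.
#' @param stressors Stressor main effects to include in step 2 (defaults to
#'   the stressors appearing in `interactions`).
#' @param baseline Baseline instrument (defaults to the outcome instrument;
#'   `ATS_G` falls back to `GAD7`).
#' @return Object of class `hier_fit`: `coefficients` tibble (final model:
#'   term, estimate, se, t, p), `steps` tibble (step, terms, r_squared,
#'   delta_r_squared), `n`, and the call ingredients.
#' @export
fit_hierarchical <- function(data, outcome, part, indices = character(),
                             interactions = character(),
                             stressors = NULL, baseline = NULL) {
  stopifnot(part %in% 2:3)
  if (is.null(baseline)) baseline <- .default_baseline(outcome)
  ycol <- paste0(outcome, "_", part)
  bcol <- paste0(baseline, "_1")
  if (!ycol %in% names(data)) stop("outcome column not found: ", ycol)
  if (!bcol %in% names(data)) stop("baseline column not found: ", bcol)

  inter_parts <- lapply(interactions, function(s)
    strsplit(s, ":", fixed = TRUE)[[1]])
  if (is.null(stressors)) {
    comp <- unlist(inter_parts)
    stressors <- intersect(unique(comp),
                           c("failed", "NLE_count", "NLE_weighted"))
  }
  main_terms <- unique(c(
    indices,
    setdiff(unlist(inter_parts), c("failed", "NLE_count", "NLE_weighted")),
    stressors
  ))

  mf <- tibble::tibble(.y = .zs(data[[ycol]]), .baseline = .zs(data[[bcol]]))
  for (tm in main_terms) mf[[tm]] <- .term_col(data, tm)
  for (j in seq_along(interactions)) {
    p <- inter_parts[[j]]
    if (length(p) != 2) stop("interaction must have two components: ",
                             interactions[j])
    mf[[interactions[j]]] <- .term_col(data, p[1]) * .term_col(data, p[2])
  }
  ok <- stats::complete.cases(mf)
  mf <- mf[ok, ]
  n <- nrow(mf)
  min_n <- 10 + 1 + length(main_terms) + length(interactions)
  if (n < min_n) {
    stop(sprintf("only %d complete cases; need at least %d", n, min_n))
  }

  fit_step <- function(terms) {
    X <- as.matrix(cbind(1, mf[, terms, drop = FALSE]))
    colnames(X)[1] <- "(Intercept)"
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient model; collinear term(s): ",
           paste(bad, collapse = ", "))
    }
    fit <- stats::lm.fit(X, mf$.y)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((mf$.y - mean(mf$.y))^2)
    df_res <- n - ncol(X)
    sigma2 <- ss_res / df_res
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(diag(XtXinv) * sigma2)
    tval <- fit$coefficients / se
    list(
      coef = tibble::tibble(
        term = colnames(X), estimate = unname(fit$coefficients),
        se = unname(se), t = unname(tval),
        p = 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
      ),
      r2 = 1 - ss_res / ss_tot
    )
  }

  steps <- list("baseline" = ".baseline")
  if (length(main_terms) > 0)
    steps[["main"]] <- c(".baseline", main_terms)
  if (length(interactions) > 0)
    steps[["interaction"]] <- c(".baseline", main_terms, interactions)
  fits <- lapply(steps, fit_step)
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  step_tbl <- tibble::tibble(
    step = names(steps),
    terms = vapply(steps, paste, character(1), collapse = " + "),
    r_squared = unname(r2),
    delta_r_squared = unname(r2 - dplyr::lag(r2, default = 0))
  )
  step_tbl$delta_r_squared[1] <- step_tbl$r_squared[1]

  structure(
    list(coefficients = fits[[length(fits)]]$coef, steps = step_tbl,
         n = n, outcome = outcome, part = part, baseline = baseline,
         indices = indices, interactions = interactions,
         stressors = stressors),
    class = "hier_fit"
  )
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("<hier_fit> %s part %d (baseline %s), n = %d\n",
              x$outcome, x$part, x$baseline, x$n))
  print(x$steps)
  print(x$coefficients)
  invisible(x)
}

#' Covariate-adjusted stressor main effect
#'
#' The effect of a stressor (disappointing exam failure, life-event count,
#' or life-event burden) on a Part-2/3 outcome, controlling for the
#' baseline level of the same instrument.
#'
#' @param data Analysis frame from [analysis_frame()].
#' @param stressor `"failed"`, `"NLE_count"` or `"NLE_weighted"`.
#' @param outcome,part As in [fit_hierarchical()].
#' @return One-row coefficient tibble for the stressor term plus `n` and
#'   `delta_r_squared`.
#' @export
stressor_effect <- function(data, stressor, outcome, part) {
  fit <- fit_hierarchical(data, outcome, part, indices = character(),
                          interactions = character(), stressors = stressor)
  row <- fit$coefficients[fit$coefficients$term == stressor, ]
  row$n <- fit$n
  row$delta_r_squared <- fit$steps$delta_r_squared[fit$steps$step == "main"]
  row
}

#' Run the full prediction-analysis grid
#'
#' Systematically fits the hierarchical models of the prediction analyses
#' and collects the focal term of each cell into one tidy ledger:
#' * `main`: each learning index alone (+ baseline covariate), per outcome
#'   and part;
#' * `failure`, `nle_count`, `nle_weighted`: each index, the stressor, and
#'   their interaction — the focal term is the interaction;
#' * `pairwise`: every unordered pair of indices with their product term —
#'   the focal term is the index-by-index interaction.
#'
#' Cells whose model cannot be fitted (empty subgroup, collinearity,
#' insufficient complete cases) are skipped and recorded in the
#' `skipped` attribute. No multiplicity correction is applied; the ledger
#' carries the raw two-sided p-values so a Benjamini-Hochberg or similar
#' adjustment can be layered on afterwards.
#'
#' @param data Analysis frame from [analysis_frame()].
#' @param outcomes Character vector of outcome instruments.
#' @param parts Outcome waves (subset of 2:3).
#' @param indices Index names (default all seven primary).
#' @param families Subset of `c("main", "failure", "nle_count",
#'   "nle_weighted", "pairwise")`.
#' @return Tibble ledger: `outcome`, `part`, `family`, `focal`, `term`,
#'   `estimate`, `se`, `t`, `p`, `n`, `delta_r_squared`; skipped cells in
#'   `attr(, "skipped")`.
#' @export
run_paper_grid <- function(data,
                           outcomes = c("DASS_A", "DASS_S", "DASS_D",
                                        "GAD7"),
                           parts = 2:3,
                           indices = index_names("primary-7"),
                           families = c("main", "failure", "nle_count",
                                        "nle_weighted", "pairwise")) {
  families <- match.arg(families, several.ok = TRUE)
  rows <- list()
  skipped <- list()
  add_cell <- function(outcome, part, family, focal, idx, inter) {
    res <- tryCatch(
      fit_hierarchical(data, outcome, part, indices = idx,
                       interactions = inter),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1]] <<- tibble::tibble(
        outcome = outcome, part = part, family = family, focal = focal,
        reason = conditionMessage(res))
      return(invisible(NULL))
    }
    focal_term <- if (length(inter) > 0) inter[1] else idx[1]
    row <- res$coefficients[res$coefficients$term == focal_term, ]
    last <- nrow(res$steps)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      outcome = outcome, part = part, family = family, focal = focal,
      term = row$term, estimate = row$estimate, se = row$se, t = row$t,
      p = row$p, n = res$n,
      delta_r_squared = res$steps$delta_r_squared[last])
  }

  for (outcome in outcomes) for (part in parts) {
    if ("main" %in% families) {
      for (ix in indices) add_cell(outcome, part, "main", ix, ix,
                                   character())
    }
    if ("failure" %in% families) {
      for (ix in indices) {
        add_cell(outcome, part, "failure", ix, ix, paste0(ix, ":failed"))
      }
    }
    if ("nle_count" %in% families) {
      for (ix in indices) {
        add_cell(outcome, part, "nle_count", ix, ix,
                 paste0(ix, ":NLE_count"))
      }
    }
    if ("nle_weighted" %in% families) {
      for (ix in indices) {
        add_cell(outcome, part, "nle_weighted", ix, ix,
                 paste0(ix, ":NLE_weighted"))
      }
    }
    if ("pairwise" %in% families && length(indices) >= 2) {
      prs <- utils::combn(indices, 2)
      for (j in seq_len(ncol(prs))) {
        a <- prs[1, j]; b <- prs[2, j]
        add_cell(outcome, part, "pairwise", paste0(a, ":", b),
                 c(a, b), paste0(a, ":", b))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}
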