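.p_from_f <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

.contrast_f <- function(con) {
  n <- length(con)
  v <- stats::var(con)
  m <- mean(con)
  if (v == 0) {
    f <- if (m == 0) 0 else Inf
    return(list(F = f, p = if (m == 0) 1 else 0, degenerate = TRUE))
  }
  f <- n * m^2 / v
  list(F = f, p = .p_from_f(f, 1, n - 1), degenerate = FALSE)
}

#' 2x2 within-subject ANOVA (Stimulus x Time)
#'
#' Classical repeated-measures ANOVA for the acquisition/extinction
#' manipulation check, with Stimulus (CS+, CS-) and Time (first vs. last
#' trial) as within-subject factors. Because both factors have two levels,
#' every effect is a single-df contrast on per-participant difference
#' scores, which is exact and needs no sphericity machinery: for a contrast
#' `c_i`, `F = n * mean(c)^2 / var(c)` on `(1, n - 1)` df, and partial
#' eta-squared is `F / (F + n - 1)`.
#'
#' @param cells Tibble with columns `participant_id`, `stimulus`
#'   (`"CS_PLUS"`/`"CS_MINUS"`), `time` (`"first"`/`"last"`), `value`;
#'   one complete 2x2 set of cells per participant.
#' @return Tibble with one row per effect (`Stimulus`, `Time`,
#'   `Stimulus:Time`): `statistic_name`, `value`, `df1`, `df2`, `p_value`,
#'   `effect_size` (partial eta-squared), `effect_size_kind`, `n`,
#'   `degenerate`.
#' @export
rm_anova_2x2 <- function(cells) {
  need <- c("participant_id", "stimulus", "time", "value")
  stopifnot(all(need %in% names(cells)))
  w <- tidyr::pivot_wider(cells[need],
                          names_from = c("stimulus", "time"),
                          values_from = "value")
  cols <- c("CS_PLUS_first", "CS_PLUS_last", "CS_MINUS_first",
            "CS_MINUS_last")
  if (!all(cols %in% names(w)) || anyNA(w[cols])) {
    stop("incomplete 2x2 cells: every participant needs all four cell means")
  }
  n <- nrow(w)
  if (n < 3) stop("at least 3 participants required")
  pf <- w$CS_PLUS_first; pl <- w$CS_PLUS_last
  mf <- w$CS_MINUS_first; ml <- w$CS_MINUS_last
  cons <- list(
    "Stimulus" = (pf + pl) / 2 - (mf + ml) / 2,
    "Time" = (pl + ml) / 2 - (pf + mf) / 2,
    "Stimulus:Time" = (pl - pf) - (ml - mf)
  )
  rows <- lapply(names(cons), function(nm) {
    r <- .contrast_f(cons[[nm]])
    tibble::tibble(
      effect = nm, statistic_name = "F", value = r$F,
      df1 = 1, df2 = n - 1, p_value = r$p,
      effect_size = if (is.infinite(r$F)) 1 else r$F / (r$F + (n - 1)),
      effect_size_kind = "partial_eta_sq", n = n, degenerate = r$degenerate
    )
  })
  dplyr::bind_rows(rows)
}

#' One-way within-subject ANOVA across the six stimuli
#'
#' Manipulation check for the generalization gradient: first-trial ratings
#' of CS+, CS-, GS1..GS4 decomposed into subject, stimulus and residual
#' sums of squares. Eta-squared is `SS_stimulus / SS_total`.
#'
#' @param data Tibble with columns `participant_id`, `stimulus`, `value`;
#'   one rating per participant per stimulus.
#' @return One-row tibble in the [rm_anova_2x2()] format (`effect =
#'   "Stimulus"`, `effect_size_kind = "eta_sq"`).
#' @export
rm_anova_oneway <- function(data) {
  need <- c("participant_id", "stimulus", "value")
  stopifnot(all(need %in% names(data)))
  w <- tidyr::pivot_wider(data[need], names_from = "stimulus",
                          values_from = "value")
  y <- as.matrix(w[, -1])
  if (anyNA(y)) stop("missing stimulus rating for at least one participant")
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_stim <- n * sum((colMeans(y) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_stim
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_err == 0) {
    f <- if (ss_stim == 0) 0 else Inf
    p <- if (ss_stim == 0) 1 else 0
    degen <- TRUE
  } else {
    f <- (ss_stim / df1) / (ss_err / df2)
    p <- .p_from_f(f, df1, df2)
    degen <- FALSE
  }
  tibble::tibble(
    effect = "Stimulus", statistic_name = "F", value = f,
    df1 = df1, df2 = df2, p_value = p,
    effect_size = if (ss_total == 0) 0 else ss_stim / ss_total,
    effect_size_kind = "eta_sq", n = n, degenerate = degen
  )
}

#' t-tests with Cohen's d
#'
#' One-sample t-test against zero or paired-samples t-test, with the
#' corresponding Cohen's d (`mean / sd` for one-sample, mean difference over
#' the sd of differences for paired). Zero-variance input yields a
#' degenerate flag and no p-value.
#'
#' @param x Numeric values (one-sample) or first member of the pairs.
#' @param y Second member of the pairs (paired mode only).
#' @param mode `"one_sample"` or `"paired"`.
#' @return One-row tibble: `statistic_name`, `value` (t), `df`, `p_value`,
#'   `effect_size` (Cohen's d), `effect_size_kind`, `n`, `degenerate`.
#' @export
t_tests <- function(x, y = NULL, mode = c("one_sample", "paired")) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(y) || length(y) != length(x)) {
      stop("paired mode requires equal-length `x` and `y`")
    }
    d <- x - y
  } else {
    d <- x
  }
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("at least 2 non-missing values required")
  s <- stats::sd(d)
  if (s == 0) {
    return(tibble::tibble(
      statistic_name = "t", value = NA_real_, df = n - 1,
      p_value = NA_real_, effect_size = NA_real_,
      effect_size_kind = "cohen_d", n = n, degenerate = TRUE
    ))
  }
  t <- mean(d) / (s / sqrt(n))
  tibble::tibble(
    statistic_name = "t", value = t, df = n - 1,
    p_value = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
    effect_size = mean(d) / s, effect_size_kind = "cohen_d",
    n = n, degenerate = FALSE
  )
}

#' Cronbach's alpha for an item matrix
#'
#' `alpha = k / (k - 1) * (1 - sum(item variances) / variance of the sum)`,
#' with sample (n - 1) variances over complete cases.
#'
#' @param items Numeric matrix or data frame, participants in rows, items
#'   in columns (`k >= 2`).
#' @return One-row tibble: `statistic_name = "alpha"`, `value`, `n`, `k`,
#'   `degenerate`.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  n <- nrow(items); k <- ncol(items)
  if (k < 2 || n < 2) stop("alpha needs at least 2 items and 2 participants")
  tot_var <- stats::var(rowSums(items))
  if (tot_var == 0) {
    return(tibble::tibble(statistic_name = "alpha", value = NA_real_,
                          n = n, k = k, degenerate = TRUE))
  }
  a <- k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / tot_var)
  tibble::tibble(statistic_name = "alpha", value = a, n = n, k = k,
                 degenerate = FALSE)
}

.normality_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  if (length(x) > 5000) x <- x[seq_len(5000)]
  stats::shapiro.test(x)$p.value
}

#' Correlation with a normality-switched method
#'
#' Pearson's r when both variables pass a Shapiro-Wilk normality gate at
#' `alpha = 0.05`; Spearman's rank correlation (average ranks for ties)
#' when either fails. The gate can be forced with `policy`.
#'
#' @param x,y Paired numeric vectors.
#' @param policy `"auto"` (normality gate), `"pearson"`, or `"spearman"`.
#' @param alpha Significance level of the normality gate.
#' @return One-row tibble: `statistic_name` (`"r"` or `"rho"`), `value`,
#'   `p_value`, `n`, `method`, the two gate p-values, `degenerate`.
#' @export
correlate <- function(x, y, policy = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  policy <- match.arg(policy)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("at least 4 complete pairs required")
  px <- .normality_p(x); py <- .normality_p(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(statistic_name = NA_character_, value = NA_real_,
                          p_value = NA_real_, n = n, method = NA_character_,
                          normality_p_x = px, normality_p_y = py,
                          degenerate = TRUE))
  }
  method <- switch(policy,
    pearson = "pearson",
    spearman = "spearman",
    auto = if (!is.na(px) && !is.na(py) && px >= alpha && py >= alpha)
      "pearson" else "spearman"
  )
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE)
  )
  tibble::tibble(
    statistic_name = if (method == "pearson") "r" else "rho",
    value = unname(ct$estimate), p_value = ct$p.value, n = n,
    method = method, normality_p_x = px, normality_p_y = py,
    degenerate = FALSE
  )
}

#' Pairwise correlations between learning indices
#'
#' All unordered pairs of the chosen index set, each on pairwise-complete
#' observations with the normality-switched method of [correlate()]. No
#' multiple-testing correction is applied (exploratory convention).
#'
#' @param index_table An `index_table` or its `indices` tibble.
#' @param set Index subset, see [index_names()].
#' @param policy Method policy passed to [correlate()].
#' @return Tibble with one row per pair: `index_a`, `index_b` plus the
#'   [correlate()] columns.
#' @export
pairwise_index_correlations <- function(index_table, set = "primary-7",
                                        policy = "auto") {
  idx <- if (inherits(index_table, "index_table")) index_table$indices else
    index_table
  cols <- index_names(set)
  stopifnot(all(cols %in% names(idx)))
  pairs <- utils::combn(cols, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    r <- correlate(idx[[a]], idx[[b]], policy = policy)
    dplyr::bind_cols(tibble::tibble(index_a = a, index_b = b), r)
  })
  dplyr::bind_rows(rows)
}
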