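#' Best-of-restarts k-means
#'
#' Wraps `stats::kmeans()` (Hartigan-Wong) with multiple seeded restarts
#' and returns the solution with the lowest within-cluster sum of squares.
#' `k = 1` returns the grand centroid with `W = ` total sum of squared
#' deviations.
#'
#' @param x Numeric matrix (complete cases; rows are participants).
#' @param k Number of clusters.
#' @param n_restarts Restarts (random starting centres per restart).
#' @param seed Integer seed for the restart stream.
#' @param iter_max Iteration cap per restart.
#' @return List with `labels`, `centers`, `W` (total within-cluster sum of
#'   squares), `k`.
#' @export
kmeans_fit <- function(x, k, n_restarts = 50, seed = 1, iter_max = 300) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("`x` must be complete cases (listwise deletion first)")
  if (k > nrow(x)) stop("`k` exceeds the number of rows")
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
    W <- sum(sweep(x, 2, ctr[1, ])^2)
    return(list(labels = rep(1L, nrow(x)), centers = ctr, W = W, k = 1L))
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = k, iter.max = iter_max,
                                     nstart = 1)),
      error = function(e) NULL
    )
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  list(labels = best$cluster, centers = best$centers,
       W = best$tot.withinss, k = as.integer(k))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Gap statistic for selecting the number of clusters
#'
#' Compares the observed `log(W_k)` curve with its expectation under a
#' reference null in which each feature is drawn uniformly over its
#' observed range. For each `k` in `1..kmax`, `gap(k) = mean(log W*_k) -
#' log W_k` over `B` reference draws, with spread `s_k = sd(log W*_k) *
#' sqrt(1 + 1/B)`. The selected `k` is the smallest with
#' `gap(k) >= gap(k + 1) - s(k + 1)` (falling back to `kmax` if none
#' qualifies).
#'
#' @param x Numeric matrix of complete-case profiles.
#' @param kmax Maximum number of clusters (default 10).
#' @param B Reference (bootstrap) iterations (default 100).
#' @param seed Integer seed; the whole curve is reproducible for fixed
#'   `(x, kmax, B, seed)`.
#' @param n_restarts k-means restarts per fit.
#' @return Object of class `gap_curve`: tibble `table` (`k`, `logW`,
#'   `E_logW`, `gap`, `s_k`) plus `chosen_k`, `B`, `kmax`.
#' @export
gap_statistic <- function(x, kmax = 10, B = 100, seed = 1, n_restarts = 10) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("`x` must be complete cases")
  if (nrow(x) < kmax + 1) stop("need at least kmax + 1 rows")
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  keep <- span > 0
  if (!all(keep)) {
    warning("dropping zero-range feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
    rng <- rng[, keep, drop = FALSE]
  }
  if (ncol(x) == 0) {
    # no variation at all: trivially a single cluster
    return(structure(
      list(table = tibble::tibble(k = seq_len(kmax), logW = NA_real_,
                                  E_logW = NA_real_, gap = NA_real_,
                                  s_k = NA_real_),
           chosen_k = 1L, B = B, kmax = as.integer(kmax)),
      class = "gap_curve"
    ))
  }

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  logW <- vapply(seq_len(kmax), function(k) {
    log(pmax(kmeans_fit(x, k, n_restarts = n_restarts,
                        seed = sample.int(.Machine$integer.max, 1))$W,
             1e-300))
  }, numeric(1))
  logWstar <- matrix(NA_real_, B, kmax)
  for (b in seq_len(B)) {
    ref <- vapply(seq_len(ncol(x)), function(j) {
      stats::runif(nrow(x), rng[1, j], rng[2, j])
    }, numeric(nrow(x)))
    logWstar[b, ] <- vapply(seq_len(kmax), function(k) {
      log(kmeans_fit(ref, k, n_restarts = n_restarts,
                     seed = sample.int(.Machine$integer.max, 1))$W)
    }, numeric(1))
  }
  E_logW <- colMeans(logWstar)
  gap <- E_logW - logW
  s_k <- apply(logWstar, 2, stats::sd) * sqrt(1 + 1 / B)

  chosen <- kmax
  for (k in seq_len(kmax - 1)) {
    if (gap[k] >= gap[k + 1] - s_k[k + 1]) { chosen <- k; break }
  }
  structure(
    list(table = tibble::tibble(k = seq_len(kmax), logW = logW,
                                E_logW = E_logW, gap = gap, s_k = s_k),
         chosen_k = as.integer(chosen), B = B, kmax = as.integer(kmax)),
    class = "gap_curve"
  )
}

#' @export
print.gap_curve <- function(x, ...) {
  cat("<gap_curve> chosen_k =", x$chosen_k, "(kmax =", x$kmax,
      ", B =", x$B, ")\n")
  print(x$table, n = x$kmax)
  invisible(x)
}

#' Learning-profile cluster analysis over an index set
#'
#' Runs the gap-statistic cluster-number selection and the k-means fit at
#' the chosen `k` over the Z-scored indices of one channel: the
#' preregistered five indices (extinction, avoidance, generalization), all
#' seven primary indices, or the six secondary indices. Rows with any
#' missing index in the chosen subset are dropped (listwise deletion).
#'
#' @param index_table An `index_table` from [compute_index_table()].
#' @param set `"primary-5"`, `"primary-7"` or `"secondary"`.
#' @param kmax,B,seed,n_restarts Passed to [gap_statistic()].
#' @return List with `gap` (a `gap_curve`), `fit` (the [kmeans_fit()] at
#'   the chosen k), `labels` tibble (`participant_id`, `cluster`),
#'   `n_complete`, `set`.
#' @export
profile_report <- function(index_table, set = "primary-7", kmax = 10,
                           B = 100, seed = 1, n_restarts = 10) {
  idx <- index_table$indices
  cols <- paste0("Z_", index_names(set))
  x <- as.matrix(idx[, cols])
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < kmax + 1) {
    stop(sprintf("only %d complete cases for set %s; need at least kmax + 1",
                 nrow(x), set))
  }
  gap <- gap_statistic(x, kmax = kmax, B = B, seed = seed,
                       n_restarts = n_restarts)
  fit <- kmeans_fit(x, gap$chosen_k, n_restarts = max(n_restarts, 25),
                    seed = seed)
  list(
    gap = gap, fit = fit,
    labels = tibble::tibble(participant_id = idx$participant_id[ok],
                            cluster = fit$labels),
    n_complete = nrow(x), set = set
  )
}
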