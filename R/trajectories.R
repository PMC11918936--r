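# Growth mixture modelling of the weekly impact-of-event series.
#
# Model: for participant i in latent class k,
#   y_i = X_i beta_k + Z_i b_i + e_i,  b_i ~ N(0, Psi),  e_i ~ N(0, sigma2 I)
# with class-specific fixed growth coefficients and residual/random-effect
# (co)variances shared across classes. Estimated by EM over class
# responsibilities and random-effect moments; all moments are computed per
# observed-week pattern, so balanced cohorts cost one matrix solve per
# iteration.

#' Growth-shape design basis
#'
#' @param shape `"linear"`, `"quadratic"`, `"cubic"` or `"logarithmic"`.
#' @return Function mapping a week vector `t` (coded 0..9) to the design
#'   matrix: `(1, t)`, `(1, t, t^2)`, `(1, t, t^2, t^3)` or
#'   `(1, log(t + 1))`.
#' @export
growth_basis <- function(shape = c("linear", "quadratic", "cubic",
                                   "logarithmic")) {
  shape <- match.arg(shape)
  switch(shape,
    linear = function(t) cbind(`(Intercept)` = 1, t = t),
    quadratic = function(t) cbind(`(Intercept)` = 1, t = t, t2 = t^2),
    cubic = function(t) cbind(`(Intercept)` = 1, t = t, t2 = t^2, t3 = t^3),
    logarithmic = function(t) cbind(`(Intercept)` = 1, logt = log(t + 1))
  )
}

.re_design <- function(effects) {
  switch(effects,
    fixed_only = function(t) NULL,
    random_intercept = function(t) cbind(1),
    random_intercept_slope = function(t) cbind(1, t)
  )
}

.traj_prep <- function(data, shape, effects) {
  stopifnot(all(c("participant_id", "week", "ies") %in% names(data)))
  data <- data[!is.na(data$ies), ]
  basis <- growth_basis(shape)
  zfun <- .re_design(effects)
  ids <- unique(data$participant_id)
  split_idx <- split(seq_len(nrow(data)), match(data$participant_id, ids))
  keys <- character(length(ids))
  ys <- ts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- split_idx[[i]]
    o <- order(data$week[rows])
    ts[[i]] <- data$week[rows][o]
    ys[[i]] <- as.numeric(data$ies[rows][o])
    keys[i] <- paste(ts[[i]], collapse = ",")
  }
  ukeys <- unique(keys)
  patterns <- lapply(ukeys, function(k) {
    t <- ts[[match(k, keys)]]
    X <- basis(t)
    Z <- if (identical(effects, "random_intercept")) matrix(1, length(t), 1)
      else if (identical(effects, "random_intercept_slope")) cbind(1, t)
      else NULL
    members <- which(keys == k)
    list(t = t, X = X, Z = Z, XtX = crossprod(X),
         members = members,
         Y = do.call(rbind, ys[members]))
  })
  list(ids = ids, n = length(ids),
       N_obs = sum(lengths(ys)),
       p = ncol(patterns[[1]]$X),
       q = if (is.null(patterns[[1]]$Z)) 0L else ncol(patterns[[1]]$Z),
       patterns = patterns, ys = ys, ts = ts, basis = basis,
       shape = shape, effects = effects)
}

# per-participant OLS intercept proxy used for start generation
.indiv_intercepts <- function(prep) {
  vapply(seq_len(prep$n), function(i) {
    t <- prep$ts[[i]]; y <- prep$ys[[i]]
    X <- prep$basis(t)
    if (length(y) > ncol(X)) {
      b <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
      if (!is.null(b) && !anyNA(b)) return(b[1])
    }
    mean(y)
  }, numeric(1))
}

.em_init <- function(prep, K, perturb) {
  ints <- .indiv_intercepts(prep)
  grp <- if (K == 1) rep(1L, prep$n) else
    cut(rank(ints, ties.method = "first"), breaks = K, labels = FALSE)
  p <- prep$p
  beta <- matrix(0, p, K)
  for (k in seq_len(K)) {
    A <- matrix(0, p, p); b <- numeric(p)
    for (pt in prep$patterns) {
      w <- grp[pt$members] == k
      if (!any(w)) next
      A <- A + sum(w) * pt$XtX
      b <- b + crossprod(pt$X, colSums(pt$Y[w, , drop = FALSE]))
    }
    beta[, k] <- tryCatch(solve(A, b), error = function(e) {
      c(mean(ints[grp == k]), rep(0, p - 1))
    })
  }
  if (perturb > 0) {
    sds <- apply(beta, 1, stats::sd)
    sds[!is.finite(sds) | sds == 0] <- stats::sd(ints) / max(K, 2) + 0.5
    beta <- beta + matrix(stats::rnorm(p * K, 0, perturb * sds), p, K)
  }
  Psi <- NULL
  if (prep$q == 1) Psi <- matrix(max(stats::var(ints) / 2, 0.5), 1, 1)
  if (prep$q == 2) Psi <- diag(c(max(stats::var(ints) / 2, 0.5), 0.1))
  vy <- stats::var(unlist(prep$ys))
  list(pi = rep(1 / K, K), beta = beta, Psi = Psi,
       sigma2 = max(vy / 2, 1e-3))
}

.em_run <- function(prep, K, init, max_iter = 500, tol = 1e-6) {
  pi_k <- init$pi; beta <- init$beta; Psi <- init$Psi
  sigma2 <- init$sigma2
  n <- prep$n; q <- prep$q; p <- prep$p
  logL_prev <- -Inf
  monotone_ok <- TRUE
  post <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    LL <- matrix(0, n, K)
    mlist <- vector("list", length(prep$patterns))
    Clist <- vector("list", length(prep$patterns))
    Vinvs <- vector("list", length(prep$patterns))
    for (pi_ in seq_along(prep$patterns)) {
      pt <- prep$patterns[[pi_]]
      np <- length(pt$t)
      if (q > 0) {
        V <- tcrossprod(pt$Z %*% Psi, pt$Z) + diag(sigma2, np)
        Rc <- chol(V)
        logdet <- 2 * sum(log(diag(Rc)))
        Vinv <- chol2inv(Rc)
        Clist[[pi_]] <- Psi - Psi %*% crossprod(pt$Z, Vinv %*% pt$Z) %*% Psi
        G <- Vinv %*% pt$Z %*% Psi
      } else {
        logdet <- np * log(sigma2)
        Vinv <- NULL
      }
      Vinvs[[pi_]] <- Vinv
      mk <- vector("list", K)
      for (k in seq_len(K)) {
        Rm <- pt$Y - matrix(pt$X %*% beta[, k], nrow(pt$Y), np,
                            byrow = TRUE)
        quad <- if (q > 0) rowSums((Rm %*% Vinv) * Rm) else
          rowSums(Rm^2) / sigma2
        LL[pt$members, k] <- -0.5 * (np * log(2 * pi) + logdet + quad)
        if (q > 0) mk[[k]] <- Rm %*% G
      }
      mlist[[pi_]] <- mk
    }
    A <- LL + matrix(log(pi_k), n, K, byrow = TRUE)
    amax <- apply(A, 1, max)
    li <- amax + log(rowSums(exp(A - amax)))
    logL <- sum(li)
    if (!is.finite(logL)) return(NULL)
    post <- exp(A - li)
    if (logL < logL_prev - 1e-6 * (abs(logL_prev) + 1)) monotone_ok <- FALSE
    done <- abs(logL - logL_prev) < tol * (abs(logL_prev) + 1)
    logL_prev <- logL
    if (done) { converged <- TRUE; break }

    # ---- M-step ---------------------------------------------------------
    pi_k <- colMeans(post)
    if (any(pi_k < 1e-8)) return(NULL)  # empty class; caller restarts
    newbeta <- beta
    for (k in seq_len(K)) {
      Ak <- matrix(0, p, p); bk <- numeric(p)
      for (pi_ in seq_along(prep$patterns)) {
        pt <- prep$patterns[[pi_]]
        w <- post[pt$members, k]
        Yadj <- pt$Y
        if (q > 0) Yadj <- Yadj - tcrossprod(mlist[[pi_]][[k]], pt$Z)
        Ak <- Ak + sum(w) * pt$XtX
        bk <- bk + crossprod(pt$X, colSums(Yadj * w))
      }
      newbeta[, k] <- solve(Ak, bk)
    }
    beta <- newbeta
    if (q > 0) {
      S <- matrix(0, q, q)
      for (pi_ in seq_along(prep$patterns)) {
        pt <- prep$patterns[[pi_]]
        nm <- length(pt$members)
        for (k in seq_len(K)) {
          Mk <- mlist[[pi_]][[k]]
          w <- post[pt$members, k]
          S <- S + crossprod(Mk, Mk * w)
        }
        S <- S + nm * Clist[[pi_]]
      }
      Psi <- S / n
      Psi <- (Psi + t(Psi)) / 2
    }
    tot <- 0
    for (pi_ in seq_along(prep$patterns)) {
      pt <- prep$patterns[[pi_]]
      np <- length(pt$t)
      trZCZ <- if (q > 0) sum((pt$Z %*% Clist[[pi_]]) * pt$Z) else 0
      for (k in seq_len(K)) {
        E <- pt$Y - matrix(pt$X %*% beta[, k], nrow(pt$Y), np, byrow = TRUE)
        if (q > 0) E <- E - tcrossprod(mlist[[pi_]][[k]], pt$Z)
        w <- post[pt$members, k]
        tot <- tot + sum(w * rowSums(E^2)) + sum(w) * trZCZ
      }
    }
    sigma2 <- max(tot / prep$N_obs, 1e-12)
  }
  list(logL = logL_prev, pi = pi_k, beta = beta, Psi = Psi,
       sigma2 = sigma2, post = post, converged = converged,
       iters = iter, monotone_ok = monotone_ok)
}

.npar <- function(K, p, q) {
  qvar <- unname(c(`0` = 0L, `1` = 1L, `2` = 3L)[as.character(q)])
  (K - 1L) + K * p + qvar + 1L
}

#' Fit a growth mixture model to weekly series
#'
#' Maximum-likelihood growth mixture model with `K` latent classes,
#' class-specific fixed growth coefficients on the chosen shape basis, and
#' residual/random-effect (co)variances shared across classes. `effects =
#' "fixed_only"` gives a latent class growth analysis (LCGA);
#' `"random_intercept"` and `"random_intercept_slope"` add the
#' corresponding normal random effects. Fitted by the package's EM routine
#' with multiple random starts (starts perturb a `K`-quantile split of the
#' individual OLS intercepts); the best start by log-likelihood is kept.
#' Missing weeks are allowed; every computation is grouped by the observed
#' week pattern.
#'
#' @param data Long tibble with `participant_id`, `week` (coded 0..9) and
#'   `ies`.
#' @param shape Growth shape, see [growth_basis()].
#' @param effects `"fixed_only"`, `"random_intercept"` or
#'   `"random_intercept_slope"`.
#' @param K Number of latent classes (1..6).
#' @param n_starts Random starts.
#' @param seed Integer seed for start generation.
#' @param max_iter,tol EM cap and relative log-likelihood tolerance.
#' @return Object of class `trajectory_fit`: class proportions `pi`,
#'   fixed-coefficient matrix `beta` (basis x class), `Psi`, `sigma2`,
#'   `log_likelihood`, `AIC`, `BIC`, `n_par`, posterior matrix `posterior`,
#'   `converged`, `n_starts_used`, `monotone_ok`, `sigma_floor` (residual
#'   variance pinned at the lower guard), shape/effects/K metadata and the
#'   participant ids.
#' @export
fit_gmm <- function(data, shape = "quadratic",
                    effects = c("random_intercept_slope", "random_intercept",
                                "fixed_only"),
                    K = 1, n_starts = 100, seed = 1, max_iter = 500,
                    tol = 1e-6) {
  effects <- match.arg(effects)
  stopifnot(K >= 1, K <= 6)
  prep <- .traj_prep(data, shape, effects)
  if (prep$n < 5 * K) stop("need at least 5 participants per class")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  best <- NULL
  used <- 0L
  for (s in seq_len(n_starts)) {
    init <- .em_init(prep, K, perturb = if (s == 1) 0 else 0.6)
    res <- .em_run(prep, K, init, max_iter = max_iter, tol = tol)
    used <- used + 1L
    if (is.null(res)) next
    if (is.null(best) || res$logL > best$logL) best <- res
  }
  if (is.null(best)) stop("all EM starts degenerated; no fit obtained")
  npar <- .npar(K, prep$p, prep$q)
  structure(
    list(
      shape = shape, effects = effects, K = as.integer(K),
      pi = best$pi, beta = best$beta, Psi = best$Psi, sigma2 = best$sigma2,
      log_likelihood = best$logL,
      AIC = -2 * best$logL + 2 * npar,
      BIC = -2 * best$logL + npar * log(prep$n),
      n_par = npar, n = prep$n, n_obs = prep$N_obs,
      posterior = best$post, participant_id = prep$ids,
      converged = best$converged, n_starts_used = used,
      monotone_ok = best$monotone_ok,
      sigma_floor = best$sigma2 <= 1e-8,
      basis_names = colnames(prep$patterns[[1]]$X)
    ),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s / %s, K = %d, n = %d\n",
              x$shape, x$effects, x$K, x$n))
  cat(sprintf("  logL = %.3f, AIC = %.1f, BIC = %.1f (%d parameters)%s\n",
              x$log_likelihood, x$AIC, x$BIC, x$n_par,
              if (x$converged) "" else " [not converged]"))
  cat("  class proportions:", paste(round(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Single-class growth model with random intercept and slope
#'
#' The `K = 1` special case of [fit_gmm()] used for growth-shape selection,
#' augmented with Wald z-tests of the fixed growth coefficients (standard
#' errors from the generalized-least-squares information matrix at the
#' fitted variance parameters).
#'
#' @param data Long tibble (`participant_id`, `week`, `ies`).
#' @param shape Growth shape.
#' @param ... Passed to [fit_gmm()].
#' @return A `trajectory_fit` with an extra `wald` tibble (term, estimate,
#'   se, z, p).
#' @export
fit_single_growth <- function(data, shape = "quadratic", ...) {
  fit <- fit_gmm(data, shape = shape, effects = "random_intercept_slope",
                 K = 1, n_starts = 1, ...)
  prep <- .traj_prep(data, shape, "random_intercept_slope")
  Info <- matrix(0, prep$p, prep$p)
  for (pt in prep$patterns) {
    np <- length(pt$t)
    V <- tcrossprod(pt$Z %*% fit$Psi, pt$Z) + diag(fit$sigma2, np)
    Vinv <- chol2inv(chol(V))
    Info <- Info + length(pt$members) * crossprod(pt$X, Vinv %*% pt$X)
  }
  se <- sqrt(diag(solve(Info)))
  z <- fit$beta[, 1] / se
  fit$wald <- tibble::tibble(
    term = fit$basis_names, estimate = fit$beta[, 1], se = se, z = z,
    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  )
  fit
}

#' Select the best mixture from a candidate set
#'
#' Lowest BIC among converged fits; exact BIC ties go to the fit with
#' fewer free parameters. The comparison table over all candidates (the
#' analogue of an 18-model selection table) is attached as the
#' `"comparison"` attribute.
#'
#' @param fits List of `trajectory_fit` objects.
#' @return The selected `trajectory_fit`.
#' @export
select_mixture <- function(fits) {
  stopifnot(length(fits) >= 1)
  tbl <- dplyr::bind_rows(lapply(fits, function(f) tibble::tibble(
    shape = f$shape, effects = f$effects, K = f$K, n_par = f$n_par,
    logL = f$log_likelihood, AIC = f$AIC, BIC = f$BIC,
    converged = f$converged
  )))
  ok <- which(tbl$converged)
  if (length(ok) == 0) stop("no converged fits among the candidates")
  o <- ok[order(tbl$BIC[ok], tbl$n_par[ok])]
  chosen <- fits[[o[1]]]
  attr(chosen, "comparison") <- tbl
  chosen
}

#' Fit the standard candidate grid of growth mixtures
#'
#' All combinations of the three effects structures (LCGA, random
#' intercept, random intercept + slope) and `K = 1..Kmax` for one shape:
#' the 3 x 6 = 18-model candidate set at the default `Kmax = 6`.
#'
#' @param data Long weekly tibble.
#' @param shape Growth shape (typically the winner of the single-class
#'   shape comparison).
#' @param Kmax Largest number of classes.
#' @param n_starts,seed,... Passed to [fit_gmm()].
#' @return List of `trajectory_fit` objects.
#' @export
fit_gmm_grid <- function(data, shape = "quadratic", Kmax = 6,
                         n_starts = 100, seed = 1, ...) {
  fits <- list()
  for (eff in c("fixed_only", "random_intercept",
                "random_intercept_slope")) {
    for (K in seq_len(Kmax)) {
      f <- tryCatch(
        fit_gmm(data, shape = shape, effects = eff, K = K,
                n_starts = n_starts, seed = seed + K, ...),
        error = function(e) NULL
      )
      if (!is.null(f)) fits[[length(fits) + 1]] <- f
    }
  }
  fits
}

#' Modal class assignment from a fitted mixture
#'
#' Classes are relabelled in descending order of their fixed intercept
#' (class 1 = highest starting level) and participants allocated to the
#' class with the highest posterior probability; exact posterior ties go to
#' the lower class index. An entropy summary of classification sharpness
#' is included (`1` = perfectly separated; `NA` for `K = 1`).
#'
#' @param fit A `trajectory_fit`.
#' @return List with `assignment` tibble (`participant_id`, `class`,
#'   `max_posterior`), `posterior` (relabelled matrix), `pi`, `beta`
#'   (relabelled), `entropy`, `order` (old-to-new label map).
#' @export
assign_classes <- function(fit) {
  ord <- order(fit$beta[1, ], decreasing = TRUE)
  post <- fit$posterior[, ord, drop = FALSE]
  cls <- apply(post, 1, which.max)  # ties -> lowest index
  mp <- post[cbind(seq_len(nrow(post)), cls)]
  ent <- if (fit$K > 1) {
    pl <- pmax(post, 1e-12)
    1 - sum(-pl * log(pl)) / (nrow(post) * log(fit$K))
  } else NA_real_
  list(
    assignment = tibble::tibble(participant_id = fit$participant_id,
                                class = as.integer(cls),
                                max_posterior = mp),
    posterior = post,
    pi = fit$pi[ord],
    beta = fit$beta[, ord, drop = FALSE],
    entropy = ent,
    order = ord
  )
}

#' Relate trajectory classes to learning indices
#'
#' One test per index of whether its distribution differs across trajectory
#' classes: a one-way ANOVA when the pooled within-class residuals pass a
#' Shapiro-Wilk normality gate at `alpha = 0.05`, otherwise a
#' Kruskal-Wallis test with the rank eta-squared `(H - k + 1) / (n - k)`.
#' Post-hoc pairwise comparisons (t or Wilcoxon, matching the omnibus
#' method) use Bonferroni-adjusted p-values. Classes with fewer than 3
#' members are dropped with a warning.
#'
#' @param assignment Result of [assign_classes()] (or its `assignment`
#'   tibble).
#' @param index_table An `index_table`.
#' @param indices Index names to test (default the seven primary).
#' @return List with `results` (one row per index: method, statistic, df,
#'   p, effect size, n) and `posthoc` (named list of pairwise adjusted-p
#'   matrices).
#' @export
class_index_tests <- function(assignment, index_table,
                              indices = index_names("primary-7")) {
  asg <- if (is.list(assignment) && !is.data.frame(assignment))
    assignment$assignment else assignment
  idx <- index_table$indices
  df <- dplyr::inner_join(asg, idx, by = "participant_id")
  keep_cls <- names(which(table(df$class) >= 3))
  if (length(keep_cls) < length(unique(df$class))) {
    warning("dropping class(es) with fewer than 3 members")
  }
  df <- df[df$class %in% as.integer(keep_cls), ]
  if (length(unique(df$class)) < 2) {
    stop("need at least 2 classes with at least 3 members")
  }
  rows <- list(); posthoc <- list()
  for (ix in indices) {
    x <- df[[paste0("Z_", ix)]]
    g <- factor(df$class)
    ok <- !is.na(x)
    x <- x[ok]; g <- droplevels(g[ok])
    if (length(unique(g)) < 2 || length(x) < 6) next
    resid <- x - stats::ave(x, g)
    normal <- { p <- .normality_p(resid); !is.na(p) && p >= 0.05 }
    k <- nlevels(g); n <- length(x)
    if (normal) {
      a <- stats::anova(stats::aov(x ~ g))
      ss <- a[["Sum Sq"]]
      rows[[ix]] <- tibble::tibble(
        index = ix, method = "anova", statistic_name = "F",
        value = a[["F value"]][1], df1 = a[["Df"]][1], df2 = a[["Df"]][2],
        p_value = a[["Pr(>F)"]][1],
        effect_size = ss[1] / sum(ss), effect_size_kind = "eta_sq", n = n
      )
      ph <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni")
    } else {
      kw <- stats::kruskal.test(x, g)
      rows[[ix]] <- tibble::tibble(
        index = ix, method = "kruskal", statistic_name = "H",
        value = unname(kw$statistic), df1 = unname(kw$parameter),
        df2 = NA_real_, p_value = kw$p.value,
        effect_size = (unname(kw$statistic) - k + 1) / (n - k),
        effect_size_kind = "eta_sq_H", n = n
      )
      ph <- suppressWarnings(
        stats::pairwise.wilcox.test(x, g, p.adjust.method = "bonferroni")
      )
    }
    posthoc[[ix]] <- ph$p.value
  }
  list(results = dplyr::bind_rows(rows), posthoc = posthoc)
}
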