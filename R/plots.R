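#' Plot a gap-statistic curve
#'
#' Gap value against the number of clusters with `s_k` error bars; the
#' chosen `k` is highlighted.
#'
#' @param gap A `gap_curve` from [gap_statistic()].
#' @return A ggplot object.
#' @export
plot_gap_curve <- function(gap) {
  tb <- gap$table
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$s_k,
                                          ymax = .data$gap + .data$s_k)) +
    ggplot2::geom_vline(xintercept = gap$chosen_k, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = tb$k) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic",
                  title = sprintf("Gap curve (chosen k = %d)",
                                  gap$chosen_k))
}

#' Spaghetti plot of weekly trajectories with class means
#'
#' Individual weekly impact-of-event series coloured by modal class, with
#' the fitted class mean curves overlaid.
#'
#' @param ies_weekly Long weekly tibble (`participant_id`, `week`, `ies`).
#' @param fit A `trajectory_fit`.
#' @param assignment Result of [assign_classes()] for `fit` (computed if
#'   missing).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(ies_weekly, fit, assignment = NULL) {
  if (is.null(assignment)) assignment <- assign_classes(fit)
  df <- dplyr::inner_join(ies_weekly, assignment$assignment,
                          by = "participant_id")
  df$class <- factor(df$class)
  wk <- seq(min(df$week), max(df$week), length.out = 50)
  X <- growth_basis(fit$shape)(wk)
  means <- dplyr::bind_rows(lapply(seq_len(fit$K), function(k) {
    tibble::tibble(week = wk, ies = as.numeric(X %*% assignment$beta[, k]),
                   class = factor(k))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$week, y = .data$ies,
                                   colour = .data$class)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.25) +
    ggplot2::geom_line(data = means, linewidth = 1.3) +
    ggplot2::labs(x = "week since exam results", y = "impact of events sum",
                  colour = "class")
}
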