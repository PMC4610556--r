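#' Plot a recognized session
#'
#' Fused singleton masses over the session as stacked areas with the decided
#' fatigue state marked along the top.
#'
#' @param object A `"fatigue_session"` tibble from [recognize_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fatigue_session
#' @export
autoplot.fatigue_session <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "window_start", "m_nf", "m_mf", "m_sf", "theta"),
    -"window_start", names_to = "hypothesis", values_to = "mass") |>
    dplyr::mutate(hypothesis = factor(.data$hypothesis,
                                      c("theta", "m_sf", "m_mf", "m_nf"),
                                      c("Θ", "SF", "MF", "NF")))
  ggplot2::ggplot(long, ggplot2::aes(.data$window_start / 60, .data$mass,
                                     fill = .data$hypothesis)) +
    ggplot2::geom_area(alpha = 0.85) +
    ggplot2::geom_point(
      data = dplyr::mutate(object,
                           state = factor(.data$decision, fatigue_states())),
      ggplot2::aes(x = .data$window_start / 60, y = 1.05,
                   colour = .data$state),
      inherit.aes = FALSE, shape = 15, size = 2) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "time (min)", y = "fused mass",
                  fill = "hypothesis", colour = "decision") +
    ggplot2::theme_minimal()
}

#' Plot a training fitness trace
#'
#' Best swarm fitness per iteration on a log scale; monotone non-increasing
#' by construction of the global-best bookkeeping.
#'
#' @param object A fitted `"tsfnn"` model.
#' @param ... Unused.
#' @method autoplot tsfnn
#' @export
autoplot.tsfnn <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace),
                       fitness = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$fitness)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "mean squared error") +
    ggplot2::theme_minimal()
}

#' Plot feature screening results
#'
#' Correlation-test statistic magnitude per feature against the critical
#' value; retained features are highlighted.
#'
#' @param object A `"feature_screening"` tibble from [select_features()].
#' @param ... Unused.
#' @method autoplot feature_screening
#' @export
autoplot.feature_screening <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(stats::reorder(.data$feature,
                                              abs(.data$statistic)),
                               abs(.data$statistic),
                               fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$quantile),
                        linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|t| statistic", fill = "retained") +
    ggplot2::theme_minimal()
}
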