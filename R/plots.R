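#' Plot a statement's probability trajectory
#'
#' Shows how the probability of a research statement changed over time,
#' with points colored by the estimation method that produced each record.
#'
#' @param kb A `helo_kb`.
#' @param statement_id Statement id.
#' @return A ggplot object.
#' @examples
#' plot_probability_trajectory(sirtuin_fixture(), "h1")
#' @export
plot_probability_trajectory <- function(kb, statement_id) {
  traj <- probability_trajectory(kb, statement_id)
  if (!nrow(traj)) stop("statement has no probability records", call. = FALSE)
  traj$time <- parse_timestamp(traj$timestamp)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_step(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$method, shape = .data$kind),
                        size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Probability trajectory of %s", statement_id),
      x = NULL, y = "P(statement)", color = "method", shape = "kind"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an elimination replay
#'
#' One line per hypothesis: its probability after each elimination cycle.
#'
#' @param history The `history` tibble from [replay_elimination()].
#' @return A ggplot object.
#' @export
plot_elimination_history <- function(history) {
  ggplot2::ggplot(history, ggplot2::aes(x = .data$cycle, y = .data$prob,
                                        color = .data$member)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "elimination cycle", y = "P(hypothesis)",
                  color = "hypothesis") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.helo_active_run <- function(object, ...) {
  it <- object$iterations
  long <- tidyr::pivot_longer(
    it[c("n_measured", "P1", "P2", "P3", "best_so_far")],
    cols = c("P1", "P2", "P3"),
    names_to = "probability", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_measured, y = .data$value,
                                     color = .data$probability)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      title = sprintf("Active k-optimization (%s, k = %d)",
                      object$strategy, object$k),
      x = "measurements", y = "probability of improvement"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.helo_strategy_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$checkpoint, y = .data$mean_best,
                               color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("Mean best activity found (%d repetitions)",
                      object$reps),
      x = "measurements", y = "mean best activity", color = "strategy"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
tidy.helo_hypothesis_set <- function(x, ...) {
  tibble::tibble(member = x$member, prob = x$prob)
}

#' @exportS3Method
glance.helo_hypothesis_set <- function(x, ...) {
  tibble::tibble(n = nrow(x), entropy_bits = entropy_bits(x),
                 prob_sum = sum(x$prob))
}

#' @exportS3Method
tidy.helo_kb <- function(x, ...) {
  dplyr::left_join(
    dplyr::select(x$prob_records, -"seq"),
    dplyr::select(x$statements, "id", "role"),
    by = c(statement_id = "id")
  )
}
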