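#' Plot group engagement curves
#'
#' Mean probability (and s.e.m. ribbon) of engaging the lever and the
#' magazine per 50-trial block, one panel per stimulus.
#'
#' @param result an [run_autoshaping()] result.
#' @return a ggplot object.
#' @export
plot_engagement <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires ggplot2")
  df <- result$engagement
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$probability,
                                   colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$probability - .data$sem,
                                      ymax = .data$probability + .data$sem,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~stimulus) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "50-trial block", y = "P(engage at least once)")
}

#' Plot session RPE curves at CS and US time
#'
#' Session means of the dopamine-analogue reward prediction error at CS
#' onset and US delivery, per group.
#'
#' @param result an [run_autoshaping()] result with RPE logs.
#' @return a ggplot object.
#' @export
plot_rpe <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires ggplot2")
  if (is.null(result$rpe)) stop("result has no RPE log (record = FALSE?)")
  ggplot2::ggplot(result$rpe,
                  ggplot2::aes(x = .data$session, y = .data$mean_delta,
                               colour = .data$event)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "session", y = "mean RPE")
}
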