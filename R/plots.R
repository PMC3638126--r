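#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text labs facet_wrap theme_minimal scale_fill_gradient geom_col
#'   geom_hline
NULL

#' @export
ggplot2::autoplot

#' Plot a pitch contour
#'
#' F0 of voiced windows over time, with window energy underneath.
#'
#' @param object A `pitch_contour`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pitch_contour <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(
    df[, c("time_s", "f0", "energy")], -"time_s",
    names_to = "quantity", values_to = "value"
  )
  ggplot(long, aes(x = .data$time_s, y = .data$value)) +
    geom_point(size = 0.6, na.rm = TRUE) +
    facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL, title = "Pitch contour") +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$predicted, y = .data$actual, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted", y = "actual") +
    theme_minimal()
}

#' Plot a learning session
#'
#' Mean projection weights across trials, with reward markers.
#'
#' @param object A `vnr_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vnr_session <- function(object, ...) {
  tr <- object$trials
  wcols <- grep("^w_.*_post$", names(tr), value = TRUE)
  long <- tidyr::pivot_longer(tr[, c("trial", wcols)], -"trial",
                              names_to = "projection",
                              values_to = "mean_weight_uS")
  long$projection <- gsub("^w_|_post$", "", long$projection)
  ggplot(long, aes(x = .data$trial, y = .data$mean_weight_uS,
                   color = .data$projection)) +
    geom_line() +
    geom_point(size = 0.8) +
    geom_hline(yintercept = object$config$network$initial_weight,
               linetype = "dashed", color = "grey50") +
    labs(x = "trial", y = "mean weight (uS)",
         title = "Projection weights across trials") +
    theme_minimal()
}

#' Plot the STDP curve
#'
#' @param rule An [stdp_rule()].
#' @param from,to Time-difference range in ms.
#' @return A ggplot object.
#' @export
plot_stdp_rule <- function(rule = stdp_rule(), from = -120, to = 120) {
  dt <- seq(from, to, by = 0.25)
  df <- tibble(delta_t = dt, delta_w = stdp_delta(dt, rule))
  ggplot(df, aes(x = .data$delta_t, y = .data$delta_w)) +
    geom_line() +
    geom_hline(yintercept = 0, color = "grey60") +
    labs(x = "t_pre - t_post (ms)", y = "weight change (% of max conductance)",
         title = "STDP pairing rule") +
    theme_minimal()
}
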