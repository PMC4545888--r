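#' Plot methods for simulation results
#'
#' `autoplot.search_batch()` shows reaction-time histograms split by
#' congruence; `plot_fr_traces()` shows mean LIP firing rates by condition
#' label; `plot_accuracy_rt()` shows binned accuracy against RT.
#'
#' @param object a `search_batch`.
#' @param binwidth RT histogram bin width (ms).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.search_batch <- function(object, binwidth = 25, ...) {
  tr <- object$trials %>%
    filter(!.data$timed_out) %>%
    mutate(congruence = ifelse(.data$congruent, "congruent", "incongruent"))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$rt_ms, fill = .data$correct)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "stack") +
    ggplot2::facet_grid(congruence ~ set_size, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "reaction time (ms)", y = "trials", fill = "correct")
}

#' @rdname autoplot.search_batch
#' @param batch a `search_batch` simulated with `keep_traces = TRUE`.
#' @export
plot_fr_traces <- function(batch) {
  tr <- model_fr_traces(batch) %>%
    mutate(congruence = ifelse(.data$congruent, "congruent", "incongruent"))
  ggplot2::ggplot(tr, ggplot2::aes(
    x = .data$t_ms, y = .data$rate_hz,
    colour = .data$label, group = .data$unit
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(congruence ~ set_size, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "time from cue onset (ms)", y = "mean LIP activity (Hz)",
      colour = NULL
    )
}

#' @rdname autoplot.search_batch
#' @param trials a trial tibble (see [accuracy_vs_rt()]).
#' @param bin_width accuracy bin width (ms).
#' @export
plot_accuracy_rt <- function(trials, bin_width = 100) {
  bins <- accuracy_vs_rt(trials, bin_width) %>%
    mutate(congruence = ifelse(.data$congruent, "congruent", "incongruent"))
  ggplot2::ggplot(bins, ggplot2::aes(
    x = .data$rt_bin + bin_width / 2, y = .data$accuracy,
    colour = factor(.data$set_size)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::facet_wrap(~congruence) +
    ggplot2::labs(
      x = "reaction time (ms)", y = "accuracy", colour = "set size",
      size = "trials"
    )
}
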