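#' Plot a simulated voltage trace
#'
#' Voltage against time with detected spikes marked.
#'
#' @param object A `neuron_trace` tibble.
#' @param level,debounce Spike-detection settings (see [detect_spikes()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.neuron_trace <- function(object, level = 0, debounce = 2, ...) {
  sp <- detect_spikes(object, level = level, debounce = debounce)
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$V)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "V (mV)")
  if (length(sp$times))
    gg <- gg + ggplot2::geom_point(
      data = tibble::tibble(t = sp$times, V = level),
      ggplot2::aes(x = .data$t, y = .data$V),
      colour = "red", shape = 3)
  gg
}

#' Plot a threshold kernel
#'
#' @param object A [threshold_kernel()].
#' @param t_max Right edge of the time axis (ms).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.threshold_kernel <- function(object, t_max = 600, ...) {
  df <- tibble::tibble(t = seq(0.1, t_max, length.out = 600))
  df$H <- kernel_eval(object, df$t)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$H)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since spike (ms)", y = "H_u (mV)")
}

#' Plot an f-I / noise-sensitivity curve
#'
#' @param object A tibble from [fi_curve()].
#' @param what `"f"` (rate vs current) or `"dispersion"` (delta_T / T vs
#'   rate).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fi_curve <- function(object, what = c("f", "dispersion"), ...) {
  what <- match.arg(what)
  if (what == "f") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$I_0, y = .data$f)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "I_0 (uA/cm^2)", y = "f (Hz)")
  } else {
    df <- dplyr::filter(object, .data$f > 0)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$f, y = .data$delta_T_over_T)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "f (Hz)", y = "|delta_T| / T")
  }
}

#' Plot the per-condition coincidence factors of an evaluation run
#'
#' @param object The tibble returned by [run_evaluation_protocol()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_gamma_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      condition = paste0(.data$input, .data$target_rate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$gamma_test)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "input condition", y = "test Gamma")
}
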