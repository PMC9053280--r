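#' Plot the total ion current of a measurement
#'
#' TIC against scan time, with detected (or supplied) exhalation windows
#' shaded — the standard visual check that the pulses were found.
#'
#' @param measurement A `raw_measurement`.
#' @param windows Optional windows tibble; detected with defaults when
#'   `NULL`.
#' @return A ggplot.
#' @export
plot_tic <- function(measurement, windows = NULL) {
  if (is.null(windows)) {
    windows <- detect_exhalations(measurement$tic, measurement$scan_times)
  }
  df <- tibble(t = measurement$scan_times, tic = measurement$tic)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$tic))
  if (nrow(windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.2, fill = "steelblue")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "total ion current (a.u.)",
                  title = measurement$measurement_id) +
    ggplot2::theme_minimal()
}
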