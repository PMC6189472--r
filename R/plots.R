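# ggplot2 display methods for the package's result types.

#' Plot a normalized FRAP curve
#' @param object A `frap_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.frap_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$t, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity (full scale)",
                  title = sprintf("FRAP recovery (%s normalization)",
                                  attr(object, "normalization"))) +
    ggplot2::theme_minimal()
}

#' Plot a FRAP fit over its data
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.frap_fit <- function(object, ...) {
  curve <- as_tibble(object$curve)
  tt <- seq(min(curve$t), max(curve$t), length.out = 200)
  yy <- if (object$model == "exponential") {
    object$mobile_fraction_raw * (1 - exp(-tt / object$tau))
  } else {
    object$mobile_fraction_raw *
      (1 - sqrt(object$w^2 / (object$w^2 + 4 * pi * object$D * tt)))
  }
  lab <- if (object$model == "exponential") {
    sprintf("A = %.3f, tau = %.3g s", object$mobile_fraction, object$tau)
  } else {
    sprintf("I[final] = %.3f, D = %.3g um^2/s", object$mobile_fraction, object$D)
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.5) +
    ggplot2::geom_line(data = tibble(t = tt, intensity = yy), colour = "red") +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity",
                  title = sprintf("%s fit: %s", object$model, lab)) +
    ggplot2::theme_minimal()
}

#' Display a kymograph
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot object (time down, position right, unless transposed).
#' @exportS3Method ggplot2::autoplot
autoplot.kymograph <- function(object, ...) {
  img <- object$image
  df <- tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    intensity = as.vector(img)
  )
  xl <- if (object$transposed) "time (frames)" else "position (px)"
  yl <- if (object$transposed) "position (px)" else "time (frames)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = xl, y = yl, title = "kymograph") +
    ggplot2::theme_minimal()
}

#' Plot a co-localization time series
#'
#' Mander's M1/M2 and the Pearson coefficient against time.
#' @param data A tibble from [coloc_timeseries()].
#' @return A ggplot object.
#' @export
plot_coloc_timeseries <- function(data) {
  long <- tidyr_pivot(data)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "time (s)", y = "coefficient") +
    ggplot2::theme_minimal()
}

# Minimal long-format reshape (m1/m2/pearson), avoiding a tidyr dependency
# for one call.
tidyr_pivot <- function(data) {
  bind_rows(lapply(c("m1", "m2", "pearson"), function(v) {
    tibble(t = data$t, coefficient = v, value = data[[v]])
  }))
}

#' Plot per-cell enrichment ratios
#' @param data A tibble from [spot_enrichment()].
#' @return A ggplot object with the no-recruitment baseline at 1.
#' @export
plot_enrichment <- function(data) {
  ggplot2::ggplot(dplyr::filter(data, !.data$excluded),
                  ggplot2::aes(x = factor(.data$cell_id), y = .data$ratio)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "cell", y = "on-spot / off-spot enrichment ratio") +
    ggplot2::theme_minimal()
}
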