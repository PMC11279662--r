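# ggplot2 surfaces for the diagnostic tables.

#' Plot a visual predictive check
#'
#' Observed percentile curves over the simulation-based prediction bands.
#'
#' @param object A `salbu_vpc` tibble from [vpc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.salbu_vpc <- function(object, ...) {
  object$pct <- factor(sprintf("%g%%", 100 * object$prob))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi_lo, ymax = .data$pi_hi,
                                      fill = .data$pct), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pi_med, colour = .data$pct),
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed, colour = .data$pct)) +
    ggplot2::geom_point(data = object[object$outlier, ],
                        ggplot2::aes(y = .data$observed), colour = "red") +
    ggplot2::labs(x = "time (h)", y = "concentration (ug/L)",
                  colour = "percentile", fill = "percentile",
                  title = sprintf("VPC (%d%% prediction intervals)",
                                  round(100 * attr(object, "level")))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.salbu_vpc
#' @export
plot_vpc <- autoplot.salbu_vpc

#' Goodness-of-fit panels
#'
#' Observations vs individual predictions, IWRES vs time and vs individual
#' predictions, and NPDE vs time, as a faceted long-format plot.
#'
#' @param object A `salbu_residuals` tibble from [residual_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.salbu_residuals <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "DV vs IPRED", x = object$ipred, y = object$dv),
    tibble::tibble(panel = "IWRES vs time", x = object$time, y = object$iwres),
    tibble::tibble(panel = "IWRES vs IPRED", x = object$ipred, y = object$iwres),
    tibble::tibble(panel = "NPDE vs time", x = object$time, y = object$npde)
  )
  ref <- tibble::tibble(
    panel = c("DV vs IPRED", "IWRES vs time", "IWRES vs IPRED", "NPDE vs time"),
    slope = c(1, 0, 0, 0))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(data = ref,
                         ggplot2::aes(slope = .data$slope, intercept = 0),
                         linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.salbu_residuals
#' @export
plot_gof <- autoplot.salbu_residuals

#' Plot simulated concentration profiles by stratum
#'
#' Mean observed concentration per nominal time, stratified by a covariate.
#'
#' @param data A `pk_dataset`.
#' @param by Covariate column to stratify by (default age bands 5-22 / 23-65).
#' @return A ggplot.
#' @export
plot_profiles <- function(data, by = NULL) {
  obs <- dplyr::filter(data, .data$EVID == 0)
  obs$stratum <- if (is.null(by)) {
    ifelse(obs$AGE <= 22, "5-22 y", "23-65 y")
  } else obs[[by]]
  summ <- obs |>
    dplyr::group_by(.data$stratum, .data$TIME) |>
    dplyr::summarise(conc = mean(.data$DV), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$TIME, .data$conc,
                                     colour = .data$stratum)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "mean concentration (ug/L)") +
    ggplot2::theme_minimal()
}
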