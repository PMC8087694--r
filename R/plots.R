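# ggplot2 displays for the main result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_raster geom_col labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot a binned parameter profile
#' @param object a `binned_series`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.binned_series <- function(object, ...) {
  ggplot(object, aes(x = .data$bin_center_h, y = .data$value)) +
    geom_line(na.rm = TRUE) +
    labs(x = "time (h)", y = "value",
         subtitle = sprintf("coverage %.0f%%", 100 * attr(object, "coverage"))) +
    theme_minimal()
}

#' Plot a cosinor fit over its data
#' @param object a `cosinor_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.cosinor_fit <- function(object, ...) {
  d <- object$fit$model
  t_h <- atan2(d$ss, d$cc) * object$period / (2 * pi)
  t_h <- t_h %% object$period
  grid <- seq(0, object$period, length.out = 200)
  pred <- cosine24(grid, object$mesor, object$amplitude, object$acrophase_h,
                   object$period)
  ggplot() +
    geom_point(aes(x = t_h, y = d$values), alpha = 0.4) +
    geom_line(aes(x = grid, y = pred), linewidth = 1) +
    labs(x = "circadian time (h)", y = "value") +
    theme_minimal()
}

#' Plot a relative-RR Poincare cloud
#' @param object an `hrv_result`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.hrv_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.3) +
    labs(x = expression(r[i]), y = expression(r[i + 1]),
         subtitle = sprintf("geometric HRV %.2f%%", object$measure)) +
    theme_minimal()
}

#' Plot an RR-interval distribution heatmap
#' @param object an `rr_heatmap`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.rr_heatmap <- function(object, ...) {
  d <- expand.grid(rr_ms = object$rr_centers_ms,
                   time_h = object$time_centers_h)
  d$p <- as.vector(object$prob)
  ggplot(d, aes(x = .data$time_h, y = .data$rr_ms, fill = .data$p)) +
    geom_raster() +
    scale_fill_viridis_c(name = "P(RR)") +
    labs(x = "time of day (h)", y = "RR (ms)") +
    theme_minimal()
}

#' Plot an activity-aligned parameter response
#' @param object an `aligned_response`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.aligned_response <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$rel_min, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem), alpha = 0.2) +
    geom_line() + geom_point() +
    labs(x = sprintf("time from %s (min)", object$anchor),
         y = "deviation from rest fit") +
    theme_minimal()
}

#' Plot a delta-RR dependency curve
#' @param object a `dependency_curve`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.dependency_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$delta_rr_center, y = .data$mean_delta)) +
    geom_point(aes(size = .data$n), alpha = 0.7) +
    geom_line() +
    labs(x = expression(Delta * "RR"), y = expression(Delta * "parameter")) +
    theme_minimal()
}
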