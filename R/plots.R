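#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a walking simulation
#'
#' Trunk angle, CoM height, forward speed and per-leg vertical GRF against
#' time, faceted.
#'
#' @param object A recorded `gait_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_sim <- function(object, ...) {
  stopifnot(!is.null(object$trajectory))
  tr <- object$trajectory
  bw <- body_weight(object$params)
  d <- dplyr::bind_rows(
    tibble::tibble(t = tr$t, value = tr$phi * 180 / pi,
                   variable = "trunk angle (deg)"),
    tibble::tibble(t = tr$t, value = tr$y, variable = "CoM height (m)"),
    tibble::tibble(t = tr$t, value = tr$vx, variable = "forward speed (m/s)"),
    tibble::tibble(t = tr$t,
                   value = pmax(tr$fy_1, tr$fy_2, 0, na.rm = TRUE) / bw,
                   variable = "vertical GRF (BW)"))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$t_perturb))
    p <- p + ggplot2::geom_vline(xintercept = object$t_perturb,
                                 linetype = 2, colour = "red")
  p
}

#' Plot a gait cycle against reference curves
#'
#' Overlays the simulated stride (normalised to stride phase) on
#' mean-and-band reference curves from [generate_reference_curves()].
#'
#' @param cycle A `gait_cycle`.
#' @param reference Reference curve tibble.
#' @return A ggplot object.
#' @export
plot_gait_comparison <- function(cycle, reference = generate_reference_curves()) {
  stopifnot(inherits(cycle, "gait_cycle"))
  tr <- cycle$cycle
  bw <- body_weight(cycle$params)
  ph <- (tr$t - tr$t[1]) / (tr$t[length(tr$t)] - tr$t[1])
  leg <- if (any(tr$stance_1)) 1 else 2
  sim <- dplyr::bind_rows(
    tibble::tibble(phase = ph, value = tr[[paste0("fy_", leg)]] / bw,
                   variable = "grf_vertical_bw"),
    tibble::tibble(phase = ph, value = tr[[paste0("fx_", leg)]] / bw,
                   variable = "grf_horizontal_bw"),
    tibble::tibble(phase = ph, value = 100 * (tr$y - tr$y[1]),
                   variable = "com_vertical_cm"),
    tibble::tibble(phase = ph,
                   value = (dplyr::coalesce(tr$tau_1, 0) +
                              dplyr::coalesce(tr$tau_2, 0)) / bw,
                   variable = "hip_torque_bw"))
  ggplot2::ggplot(reference, ggplot2::aes(.data$phase, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_line(data = sim, ggplot2::aes(y = .data$value),
                       colour = "black", linetype = 2, na.rm = TRUE) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "stride phase", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a basin of attraction
#'
#' @param object A `basin_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.basin_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$phi * 180 / pi, .data$phidot,
                               fill = .data$stable)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c("FALSE" = "grey90",
                                          "TRUE" = "forestgreen")) +
    ggplot2::labs(x = "trunk angle (deg)", y = "trunk angular velocity (rad/s)",
                  fill = "stable",
                  title = paste("basin of attraction:", attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' Plot GRF lines in the trunk frame with the virtual pivot point
#'
#' @param traj Recorded cycle trajectory.
#' @param params A [walker_params()] object.
#' @param vpp Optional precomputed [estimate_vpp()] result.
#' @param scale Line length per newton of GRF.
#' @return A ggplot object.
#' @export
plot_vpp <- function(traj, params, vpp = estimate_vpp(traj, params),
                     scale = 4e-4) {
  segs <- list()
  for (leg in 1:2) {
    st <- traj[[paste0("stance_", leg)]] &
      !is.na(traj[[paste0("fy_", leg)]]) & traj[[paste0("fy_", leg)]] > 1
    if (!any(st)) next
    fx <- traj[[paste0("fx_", leg)]][st]; fy <- traj[[paste0("fy_", leg)]][st]
    footx <- traj[[paste0("foot_x_", leg)]][st]
    th <- pi / 2 - traj$phi[st]
    px <- footx - traj$x[st]; py <- -traj$y[st]
    qx <- cos(th) * px - sin(th) * py
    qy <- sin(th) * px + cos(th) * py
    dx <- cos(th) * fx - sin(th) * fy
    dy <- sin(th) * fx + cos(th) * fy
    segs[[leg]] <- tibble::tibble(x = qx, y = qy,
                                  xend = qx + scale * dx,
                                  yend = qy + scale * dy)
  }
  segs <- dplyr::bind_rows(segs)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          alpha = 0.25, colour = "grey40") +
    ggplot2::annotate("point", x = 0, y = 0, colour = "darkgreen", size = 3) +
    ggplot2::annotate("point", x = vpp$point[1], y = vpp$point[2],
                      colour = "red", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "trunk-frame x (m)", y = "trunk-frame y (m)",
                  title = sprintf("VPP at (%.3f, %.3f) m, residual %.3f m",
                                  vpp$point[1], vpp$point[2], vpp$residual)) +
    ggplot2::theme_minimal()
}
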