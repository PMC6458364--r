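#' Hip position below the centre of mass
#'
#' The hip sits a distance `r_h` down the trunk axis from the CoM:
#' \eqn{x_h = x - r_h \cos\phi}, \eqn{y_h = y - r_h \sin\phi}, where
#' \eqn{\phi} is the trunk angle from the horizontal (upright trunk:
#' \eqn{\phi = \pi/2}).
#'
#' @param x,y CoM position, m.
#' @param phi Trunk angle from horizontal, rad.
#' @param params A [walker_params()] object.
#' @return Named numeric vector `c(x_h, y_h)`.
#' @export
hip_position <- function(x, y, phi, params) {
  c(x_h = x - params$r_h * cos(phi), y_h = y - params$r_h * sin(phi))
}

#' Leg length between hip and foot
#'
#' @param hip,foot Length-2 numeric vectors (x, y), m.
#' @return Euclidean distance, m.
#' @export
leg_length <- function(hip, foot) {
  sqrt(sum((as.numeric(hip) - as.numeric(foot))^2))
}

#' Axial leg-spring force
#'
#' The prismatic leg spring is repulsive in compression and cannot pull:
#' the force is \eqn{F_s = k (l_0 - l)} clamped at zero for an extended leg.
#'
#' @param l Leg length, m. Must be positive.
#' @param params A [walker_params()] object.
#' @return Axial force, N (repulsive positive; 0 when `l >= l0`).
#' @export
leg_spring_force <- function(l, params) {
  if (any(l <= 0)) stop("leg length must be positive")
  pmax(0, params$k * (params$l0 - l))
}

#' Ground reaction force of one stance leg
#'
#' Decomposes the spring force along the leg axis and the hip torque acting
#' across the leg into ground-frame components at the foot:
#' \deqn{F_x = F_s (x_h - x_f)/l + \tau y_h / l^2, \quad
#'       F_y = F_s y_h / l - \tau (x_h - x_f) / l^2.}
#'
#' @param state Named numeric with at least `x`, `y`, `phi` (CoM position and
#'   trunk angle).
#' @param torque Hip torque of this leg, N m.
#' @param foot Length-2 foot position (y normally 0), m.
#' @param params A [walker_params()] object.
#' @param Fs Optional axial force override, N; by default computed from the
#'   leg compression.
#' @return Named numeric `c(fx, fy)`, N.
#' @export
grf_leg <- function(state, torque, foot, params, Fs = NULL) {
  h <- hip_position(state[["x"]], state[["y"]], state[["phi"]], params)
  dx <- h[["x_h"]] - foot[1]
  yh <- h[["y_h"]] - (if (length(foot) > 1) foot[2] else 0)
  l <- sqrt(dx^2 + yh^2)
  if (l < 1e-12) stop("degenerate leg of zero length")
  if (is.null(Fs)) Fs <- leg_spring_force(l, params)
  c(fx = Fs * dx / l + torque * yh / l^2,
    fy = Fs * yh / l - torque * dx / l^2)
}

#' Hip angle between trunk and leg
#'
#' The angle from the trunk axis to the hip-to-foot leg axis, computed with a
#' quadrant-aware arctangent so it is continuous as the hip crosses the foot
#' vertical: \eqn{\varphi_h = \phi + \mathrm{atan2}(y_h, x_f - x_h)}. A
#' straight configuration (upright trunk over a vertical leg) gives
#' \eqn{\varphi_h = \pi}; the angle increases as the leg extends backward
#' relative to the trunk, so the hamstring shortens with increasing
#' \eqn{\varphi_h}.
#'
#' @inheritParams grf_leg
#' @param foot Length-2 foot position, m.
#' @return Hip angle, rad.
#' @export
hip_angle <- function(state, foot, params) {
  h <- hip_position(state[["x"]], state[["y"]], state[["phi"]], params)
  yh <- h[["y_h"]] - (if (length(foot) > 1) foot[2] else 0)
  if (yh <= 0) stop("hip at or below ground: hip angle undefined")
  unname(state[["phi"]] + atan2(yh, foot[1] - h[["x_h"]]))
}

#' Single-support equations of motion
#'
#' Point-mass translation driven by the stance-leg ground reaction force and
#' gravity, plus trunk rotation driven by the hip torque and the moment of
#' the hip force about the CoM:
#' \deqn{m\ddot x = F_x,\quad m\ddot y = F_y - m g,\quad
#'       J\ddot\phi = \tau + r_h (F_x \sin\phi - F_y \cos\phi).}
#'
#' @param state Named numeric with `x`, `y`, `vx`, `vy`, `phi`, `phidot`.
#' @param torque Stance-leg hip torque, N m.
#' @param foot Stance foot position, m.
#' @param params A [walker_params()] object.
#' @return Named numeric derivative of the mechanical state.
#' @export
dynamics_single <- function(state, torque, foot, params) {
  f <- grf_leg(state, torque, foot, params)
  accel_from_forces(state, f[["fx"]], f[["fy"]], torque, params)
}

#' Double-support equations of motion
#'
#' Sums the per-leg ground reaction forces and hip torques of both stance
#' legs into the same trunk equations as [dynamics_single()].
#'
#' @inheritParams dynamics_single
#' @param torques Length-2 numeric, hip torque of each stance leg, N m.
#' @param feet List of two foot positions.
#' @export
dynamics_double <- function(state, torques, feet, params) {
  f1 <- grf_leg(state, torques[1], feet[[1]], params)
  f2 <- grf_leg(state, torques[2], feet[[2]], params)
  accel_from_forces(state, f1[["fx"]] + f2[["fx"]], f1[["fy"]] + f2[["fy"]],
                    sum(torques), params)
}

accel_from_forces <- function(state, fx, fy, tau, params) {
  phi <- state[["phi"]]
  c(x = state[["vx"]], y = state[["vy"]],
    vx = fx / params$m,
    vy = fy / params$m - params$g,
    phi = state[["phidot"]],
    phidot = (tau + params$r_h * (fx * sin(phi) - fy * cos(phi))) /
      params$J_trunk)
}

#' Mechanical energy of the walker
#'
#' Kinetic plus gravitational plus leg-spring potential energy. With zero hip
#' torque this quantity is conserved across smooth phases and phase changes
#' (touchdown adds an unloaded spring; takeoff removes one).
#'
#' @inheritParams dynamics_single
#' @param feet List of stance-foot positions (possibly empty).
#' @return Energy, J.
#' @export
walker_energy <- function(state, feet, params) {
  h <- hip_position(state[["x"]], state[["y"]], state[["phi"]], params)
  e <- 0.5 * params$m * (state[["vx"]]^2 + state[["vy"]]^2) +
    0.5 * params$J_trunk * state[["phidot"]]^2 +
    params$m * params$g * state[["y"]]
  for (f in feet) {
    l <- leg_length(h, f)
    if (l < params$l0) e <- e + 0.5 * params$k * (params$l0 - l)^2
  }
  e
}
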