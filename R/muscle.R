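#' Force-length relation of the contractile element
#'
#' Bell-shaped factor \eqn{f_l(l) = \exp(c |(l - l_{opt})/(l_{opt} w)|^3)}
#' with maximum 1 at the optimal length and value \eqn{e^c = 0.05} one bell
#' width away.
#'
#' @param l_ce Contractile-element length, m (positive).
#' @param params A [walker_params()] object.
#' @return Dimensionless factor in (0, 1].
#' @export
force_length <- function(l_ce, params) {
  stopifnot(all(l_ce > 0))
  z <- abs((l_ce - params$l_opt) / (params$l_opt * params$w))
  exp(params$c * z^3)
}

#' Force-velocity relation of the contractile element
#'
#' Hyperbolic concentric branch for shortening (`v_ce < 0`, in optimal
#' lengths per second) and an eccentric branch saturating at the enhancement
#' factor `N_ecc` for lengthening; both branches equal 1 at zero velocity.
#' Shortening faster than `v_max` yields zero force.
#'
#' @param v_ce Contraction velocity, optimal lengths per second
#'   (lengthening positive).
#' @param params A [walker_params()] object.
#' @return Dimensionless factor, >= 0.
#' @export
force_velocity <- function(v_ce, params) {
  vmax <- params$v_max
  ifelse(v_ce < 0,
         ifelse(v_ce <= vmax, 0, (vmax - v_ce) / (vmax + params$kappa * v_ce)),
         params$N_ecc + (params$N_ecc - 1) * (vmax + v_ce) /
           (7.56 * params$kappa * v_ce - vmax))
}

#' Contractile-element force
#'
#' Product form \eqn{F = A\, F_{max} f_l(l) f_v(v)} of activation, maximum
#' isometric force, and the force-length and force-velocity factors.
#'
#' @param A Activation in \eqn{[0, 1]}.
#' @param l_ce Contractile-element length, m.
#' @param v_ce Contraction velocity, optimal lengths per second.
#' @param params A [walker_params()] object.
#' @return Force, N.
#' @export
ce_force <- function(A, l_ce, v_ce, params) {
  stopifnot(all(A >= 0), all(A <= 1))
  A * params$F_max * force_length(l_ce, params) * force_velocity(v_ce, params)
}

#' Muscle lengths from the hip angle
#'
#' Linear length maps of the antagonistic pair: the rectus femoris lengthens
#' and the hamstring shortens as the hip angle increases (leg extending
#' backward relative to the trunk), with slope \eqn{\rho r_0} per radian
#' about the muscle-specific reference angles.
#'
#' @param phi_h Hip angle, rad.
#' @param params A [walker_params()] object.
#' @return Named numeric `c(L_rf, L_ham)`, m.
#' @export
muscle_lengths <- function(phi_h, params) {
  sl <- params$rho * params$r0
  L <- c(L_rf = params$L_rf0 + sl * (phi_h - params$phi_ref_rf),
         L_ham = params$L_ham0 + sl * (params$phi_ref_ham - phi_h))
  if (any(L <= 0)) stop("non-positive muscle length: geometry misconfigured")
  L
}

#' Net hip torque from the antagonistic pair
#'
#' \eqn{\tau = (F_{HAM} - F_{RF}) r_0}: the hamstring extends the hip
#' (positive torque pitches the trunk backward), the rectus femoris flexes
#' it.
#'
#' @param F_rf,F_ham Muscle forces, N (non-negative).
#' @param r0 Lever arm, m.
#' @return Torque, N m.
#' @export
hip_torque <- function(F_rf, F_ham, r0) {
  stopifnot(all(F_rf >= 0), all(F_ham >= 0))
  (F_ham - F_rf) * r0
}

#' Reflex stimulation from delayed leg force
#'
#' Saturated affine map \eqn{\mathrm{STIM} = \mathrm{Sat}(STIM_0 + G
#' F_s(t - \Delta p))}.
#'
#' @param F_s_delayed Delayed leg force, N (non-negative).
#' @param gain Feedback gain, 1/N.
#' @param params A [walker_params()] object (supplies bias and saturation
#'   bounds).
#' @return Stimulation, dimensionless, within the saturation bounds.
#' @export
stimulation <- function(F_s_delayed, gain, params) {
  stopifnot(all(F_s_delayed >= 0))
  pmin(params$stim_hi, pmax(params$stim_lo,
                            params$stim0 + gain * F_s_delayed))
}

#' Excitation-contraction coupling derivative
#'
#' First-order lag of activation toward the saturated stimulation:
#' \eqn{T \dot A = \mathrm{STIM} - A}.
#'
#' @param A Activation in \eqn{[0, 1]}.
#' @param stim Saturated stimulation.
#' @param T_ecc Time constant, s (positive).
#' @return Activation rate, 1/s.
#' @export
activation_derivative <- function(A, stim, T_ecc) {
  if (T_ecc <= 0) stop("T_ecc must be positive")
  (stim - A) / T_ecc
}

#' Delayed leg force from a recorded history
#'
#' Linear interpolation of a time-indexed axial-force record at `t - delta_p`.
#' Queries before the start of the record return 0 (no force before the
#' simulation began).
#'
#' @param history A data frame (or list) with numeric `t` and `force`.
#' @param t Current time, s.
#' @param delta_p Delay, s.
#' @return Force, N.
#' @export
delayed_leg_force <- function(history, t, delta_p) {
  tq <- t - delta_p
  if (length(history$t) == 0 || tq < history$t[1]) return(0)
  if (tq >= history$t[length(history$t)])
    return(history$force[length(history$force)])
  approx(history$t, history$force, xout = tq)$y
}

#' Quasi-steady neuromuscular hip torque
#'
#' The hip torque the reflex-driven muscle pair produces at a frozen
#' operating point, with activations at their fixed point
#' \eqn{A = \mathrm{Sat}(STIM_0 + G F_s)} (the limit of vanishing delay and
#' excitation-contraction time constant). Used to study the correspondence
#' between the neuromuscular pathway and a force-modulated compliant hip.
#'
#' @param phi_h Hip angle, rad.
#' @param F_s Leg force, N.
#' @param phidot_h Hip angular velocity, rad/s (default 0: frozen geometry).
#' @param params A [walker_params()] object.
#' @param pin_fl_fv If `TRUE`, pin the force-length and force-velocity
#'   factors to 1 (muscles at their optimal operating point).
#' @return Torque, N m (vectorised over `phi_h` and `F_s`).
#' @export
nmf_quasisteady_torque <- function(phi_h, F_s, phidot_h = 0, params,
                                   pin_fl_fv = FALSE) {
  A_rf <- stimulation(F_s, params$G_rf, params)
  A_ham <- stimulation(F_s, params$G_ham, params)
  if (pin_fl_fv) {
    flv_rf <- flv_ham <- 1
  } else {
    sl <- params$rho * params$r0
    L_rf <- params$L_rf0 + sl * (phi_h - params$phi_ref_rf)
    L_ham <- params$L_ham0 + sl * (params$phi_ref_ham - phi_h)
    v_rf <- sl * phidot_h / params$l_opt
    flv_rf <- force_length(L_rf, params) * force_velocity(v_rf, params)
    flv_ham <- force_length(L_ham, params) * force_velocity(-v_rf, params)
  }
  hip_torque(A_rf * params$F_max * flv_rf,
             A_ham * params$F_max * flv_ham, params$r0)
}
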