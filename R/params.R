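#' Walker model parameters
#'
#' Constructs the full parameter set of the bipedal trunk spring-loaded
#' inverted pendulum (BTSLIP) walker with Hill-type hip muscles. Defaults
#' reproduce the reference configuration of an average human: trunk mass
#' 80 kg, trunk moment of inertia 4.6 kg m^2, hip 0.1 m below the centre of
#' mass, leg rest length 1 m, dimensionless leg stiffness 40 (dimensionalised
#' as \eqn{k = k_N m g / l_0}), and velocity-based leg adjustment weight
#' \eqn{\mu = 0.34}.
#'
#' Muscle defaults describe the antagonistic rectus femoris (RF) and
#' hamstring (HAM) groups: maximum isometric force 2000 N, optimal
#' contractile-element length 0.111 m, maximum shortening velocity -12
#' optimal lengths per second, force-length bell width 0.2, eccentric force
#' enhancement 1.5, force-velocity curvature 5, pennation factor 0.5, lever
#' arm 0.1 m, and muscle-tendon reference length 0.11 m. Reflex constants:
#' stimulation bias 0.01, force-feedback delay 1 ms, excitation-contraction
#' time constant 1 ms, gains 0.624/F_max (RF) and 0.936/F_max (HAM).
#'
#' The reference joint angles carry a calibrated common offset
#' (`phi_ref_offset`, default [nmf_ref_offset()]): the hip angle is defined
#' only up to an additive constant by the model geometry, and the offset is
#' fixed once so that the printed reflex gains admit a period-1 walking gait
#' at 1 m/s (see the methods vignette).
#'
#' @param m Trunk mass, kg.
#' @param J_trunk Trunk moment of inertia about the CoM, kg m^2.
#' @param r_h Distance from CoM down the trunk axis to the hip, m.
#' @param l0 Leg spring rest length, m.
#' @param g Gravitational acceleration, m s^-2.
#' @param k_N Dimensionless leg stiffness; the spring constant is
#'   `k_N * m * g / l0`.
#' @param mu_vbla Velocity-based leg adjustment weight in \eqn{[0, 1]}.
#' @param F_max Maximum isometric muscle force, N.
#' @param l_opt Optimal contractile-element length, m.
#' @param v_max Maximum shortening velocity, optimal lengths per second
#'   (negative: shortening is negative).
#' @param w Force-length bell width as a fraction of `l_opt`.
#' @param c Force-length shape constant (`log(0.05)`: the curve falls to 0.05
#'   one bell width from the optimum).
#' @param N_ecc Eccentric force enhancement (asymptote of the lengthening
#'   branch).
#' @param kappa Force-velocity curvature constant.
#' @param rho Pennation factor scaling fibre length change per joint radian.
#' @param r0 Muscle lever arm at the hip, m.
#' @param L_rf0,L_ham0 Muscle-tendon reference lengths, m.
#' @param phi_ref_rf,phi_ref_ham Reference hip angles (rad) at which each
#'   muscle is at its reference length, before the common offset is added.
#' @param phi_ref_offset Calibrated additive offset applied to both
#'   reference angles, rad.
#' @param G_rf,G_ham Leg-force reflex gains, 1/N.
#' @param stim0 Stimulation bias.
#' @param delta_p Reflex feedback delay, s.
#' @param T_ecc Excitation-contraction coupling time constant, s.
#' @param stim_bounds Length-2 saturation interval for the stimulation.
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param hmax Maximum integrator step, s (additionally capped at `delta_p`).
#' @param refractory Minimum time between a takeoff and the next touchdown, s
#'   (numerical guard against event chatter).
#' @param fall_yh Hip height below which a fall is declared, m.
#' @param fall_tilt Trunk tilt from vertical beyond which a fall is
#'   declared, rad.
#'
#' @return An object of class `walker_params`: a named list with all model
#'   constants, including the derived spring stiffness `k`.
#' @examples
#' p <- walker_params()
#' p$k  # 31392 N/m
#' @export
walker_params <- function(m = 80, J_trunk = 4.6, r_h = 0.1, l0 = 1, g = 9.81,
                          k_N = 40, mu_vbla = 0.34,
                          F_max = 2000, l_opt = 0.111, v_max = -12, w = 0.2,
                          c = log(0.05), N_ecc = 1.5, kappa = 5, rho = 0.5,
                          r0 = 0.1, L_rf0 = 0.11, L_ham0 = 0.11,
                          phi_ref_rf = 3.291, phi_ref_ham = 3.246,
                          phi_ref_offset = nmf_ref_offset(),
                          G_rf = 0.624 / F_max, G_ham = 0.936 / F_max,
                          stim0 = 0.01, delta_p = 1e-3, T_ecc = 1e-3,
                          stim_bounds = c(0, 1),
                          rtol = 1e-9, atol = 1e-11, hmax = 2e-3,
                          refractory = 2e-3,
                          fall_yh = 0.2, fall_tilt = pi / 3) {
  stopifnot(m > 0, J_trunk > 0, r_h > 0, l0 > 0, g > 0, k_N > 0,
            mu_vbla >= 0, mu_vbla <= 1,
            F_max > 0, l_opt > 0, w > 0, kappa > 0, N_ecc > 1, c < 0,
            v_max < 0, rho > 0, r0 > 0,
            G_rf >= 0, G_ham >= 0, delta_p >= 0, T_ecc > 0,
            length(stim_bounds) == 2, stim_bounds[1] < stim_bounds[2])
  p <- list(
    m = m, J_trunk = J_trunk, r_h = r_h, l0 = l0, g = g, k_N = k_N,
    k = k_N * m * g / l0, mu_vbla = mu_vbla,
    F_max = F_max, l_opt = l_opt, v_max = v_max, w = w, c = c,
    N_ecc = N_ecc, kappa = kappa, rho = rho, r0 = r0,
    L_rf0 = L_rf0, L_ham0 = L_ham0,
    phi_ref_rf = phi_ref_rf + phi_ref_offset,
    phi_ref_ham = phi_ref_ham + phi_ref_offset,
    phi_ref_offset = phi_ref_offset,
    G_rf = G_rf, G_ham = G_ham,
    stim0 = stim0, delta_p = delta_p, T_ecc = T_ecc,
    stim_lo = stim_bounds[1], stim_hi = stim_bounds[2],
    rtol = rtol, atol = atol, hmax = hmax, hmin = 1e-10,
    refractory = refractory, fall_yh = fall_yh, fall_tilt = fall_tilt)
  class(p) <- "walker_params"
  p
}

#' @export
print.walker_params <- function(x, ...) {
  cat("<walker_params>\n")
  cat(sprintf("  trunk: m = %g kg, J = %g kg m^2, r_h = %g m\n",
              x$m, x$J_trunk, x$r_h))
  cat(sprintf("  leg:   l0 = %g m, k = %g N/m (k_N = %g), mu = %g\n",
              x$l0, x$k, x$k_N, x$mu_vbla))
  cat(sprintf("  muscle: F_max = %g N, l_opt = %g m, v_max = %g l_opt/s\n",
              x$F_max, x$l_opt, x$v_max))
  cat(sprintf("  reflex: G_RF = %.3g, G_HAM = %.3g 1/N, delay = %g ms\n",
              x$G_rf, x$G_ham, 1000 * x$delta_p))
  invisible(x)
}

#' Write and read walker configuration files
#'
#' Serialises a [walker_params()] object (and optionally a controller
#' description) to a YAML file with one section per parameter group, and
#' reads it back.
#'
#' @param params A `walker_params` object.
#' @param path File path.
#' @param controller Optional controller object from [controller_fmch()] and
#'   friends; stored under a `controller` section.
#' @return `write_gait_config()` returns `path` invisibly;
#'   `read_gait_config()` returns a list with elements `params` and
#'   (if present) `controller`.
#' @export
write_gait_config <- function(params, path, controller = NULL) {
  stopifnot(inherits(params, "walker_params"))
  cfg <- list(
    model = params[c("m", "J_trunk", "r_h", "l0", "g", "k_N", "mu_vbla")],
    muscle = params[c("F_max", "l_opt", "v_max", "w", "c", "N_ecc", "kappa",
                      "rho", "r0", "L_rf0", "L_ham0")],
    muscle_reference = list(
      phi_ref_rf = params$phi_ref_rf - params$phi_ref_offset,
      phi_ref_ham = params$phi_ref_ham - params$phi_ref_offset,
      phi_ref_offset = params$phi_ref_offset),
    reflex = c(params[c("G_rf", "G_ham", "stim0", "delta_p", "T_ecc")],
               list(stim_bounds = c(params$stim_lo, params$stim_hi))),
    numerics = params[c("rtol", "atol", "hmax", "refractory",
                        "fall_yh", "fall_tilt")])
  if (!is.null(controller)) cfg$controller <- unclass(controller)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_gait_config
#' @export
read_gait_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- c(cfg$model, cfg$muscle, cfg$muscle_reference,
            cfg$reflex[setdiff(names(cfg$reflex), "stim_bounds")],
            cfg$numerics)
  if (!is.null(cfg$reflex$stim_bounds))
    args$stim_bounds <- as.numeric(cfg$reflex$stim_bounds)
  params <- do.call(walker_params, args)
  ctrl <- NULL
  if (!is.null(cfg$controller)) {
    ctrl <- cfg$controller
    class(ctrl) <- "gait_controller"
  }
  list(params = params, controller = ctrl)
}

# flatten params for the C++ engine
engine_pars <- function(params) {
  stopifnot(inherits(params, "walker_params"))
  unclass(params)
}
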