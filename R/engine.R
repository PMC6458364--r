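TRAJ_COLS <- c("t", "x", "y", "vx", "vy", "phi", "phidot",
               "a_rf_1", "a_ham_1", "a_rf_2", "a_ham_2",
               paste0(rep(c("stance", "foot_x", "fs", "fx", "fy", "tau",
                            "phi_h", "phidot_h", "a_rf_used", "a_ham_used"),
                          2),
                      rep(c("_1", "_2"), each = 10)))

EVENT_KINDS <- c("touchdown", "takeoff_ds", "midstance", "unused",
                 "takeoff_flight", "fall_height", "fall_tilt",
                 "perturbation")

#' Full walker state
#'
#' The continuous mechanical state plus muscle activations and per-leg
#' stance-foot anchors. Exactly one foot anchor is defined in single
#' support, two in double support.
#'
#' @param x,y,vx,vy CoM position and velocity, m, m/s.
#' @param phi,phidot Trunk angle (rad, from horizontal) and rate (rad/s).
#' @param activations Length-4 numeric in \eqn{[0,1]}: RF and HAM of legs 1
#'   and 2.
#' @param foot_x Length-2 numeric: stance-foot x of each leg (NA = swing).
#' @param stance Length-2 logical: which legs are in stance.
#' @return A `walker_state` list.
#' @export
walker_state <- function(x = 0, y, vx, vy, phi, phidot,
                         activations = rep(0.01, 4),
                         foot_x = c(x - 0.1 * cos(phi), NA),
                         stance = c(TRUE, FALSE)) {
  stopifnot(y > 0, length(activations) == 4,
            all(activations >= 0), all(activations <= 1),
            length(foot_x) == 2, length(stance) == 2,
            sum(stance) == sum(!is.na(foot_x)))
  structure(list(x = x, y = y, vx = vx, vy = vy, phi = phi, phidot = phidot,
                 activations = activations, foot_x = foot_x,
                 stance = stance),
            class = "walker_state")
}

# quasi-steady activation of the stance-leg reflex at a reconstructed state
quasi_steady_activations <- function(fs, params, ctrl) {
  g_rf <- if (!is.null(ctrl$g_rf)) ctrl$g_rf else 0
  g_ham <- if (!is.null(ctrl$g_ham)) ctrl$g_ham else 0
  c(stimulation(fs, g_rf, params), stimulation(fs, g_ham, params))
}

engine_ctrl <- function(controller) {
  ctrl <- unclass(controller)
  if (ctrl$type == "adaptive_nmf") {
    ctrl$K <- as.matrix(ctrl$K)
    ctrl$S_star <- as.numeric(ctrl$S_star)
    ctrl$U_star <- as.numeric(ctrl$U_star)
  }
  ctrl
}

engine_perturb <- function(perturb) {
  if (is.null(perturb)) return(list())
  stopifnot(inherits(perturb, "perturbation_spec"))
  list(kind = perturb$kind, magnitude = perturb$magnitude,
       touchdown_index = as.integer(perturb$touchdown_index))
}

sim_from_midstance <- function(S, params, ctrl, stop_td = -1L, stop_ms = -1L,
                               t_max = 60, record = FALSE, perturb = NULL) {
  S <- as.numeric(S)
  phi <- S[4]
  foot0 <- -params$r_h * cos(phi)
  yh <- S[2] - params$r_h * sin(phi)
  fs0 <- max(0, params$k * (params$l0 - yh))   # stance leg vertical under hip
  act <- quasi_steady_activations(fs0, params, ctrl)
  y0 <- c(0, S[2], S[1], S[3], S[4], S[5], act[1], act[2],
          params$stim0, params$stim0)
  # a feed-forward replay must know each leg's stride phase at the section
  last_td <- if (ctrl$type == "preflex" && !is.null(ctrl$last_td_rel) &&
                 all(is.finite(ctrl$last_td_rel)))
    ctrl$last_td_rel else c(-0.25, -0.5)
  cpp_sim(y0, c(TRUE, FALSE), c(foot0, NA_real_), last_td,
          engine_pars(params), engine_ctrl(ctrl), 0, t_max,
          as.integer(stop_td), as.integer(stop_ms),
          engine_perturb(perturb), record)
}

sim_from_state <- function(state, params, ctrl, stop_td = -1L, stop_ms = -1L,
                           t_max = 60, record = FALSE, perturb = NULL) {
  stopifnot(inherits(state, "walker_state"))
  y0 <- c(state$x, state$y, state$vx, state$vy, state$phi, state$phidot,
          state$activations)
  cpp_sim(y0, state$stance, ifelse(is.na(state$foot_x), 0, state$foot_x),
          c(-0.25, -0.5), engine_pars(params), engine_ctrl(ctrl), 0, t_max,
          as.integer(stop_td), as.integer(stop_ms),
          engine_perturb(perturb), record)
}

#' Perturbation specification
#'
#' An instantaneous state modification applied at the touchdown that opens a
#' given stride. The standard postural disturbance sets the trunk angular
#' velocity to -50 deg/s at the beginning of stride 4.
#'
#' @param kind One of `"set_phidot"`, `"add_phidot"`, `"set_phi"`.
#' @param magnitude New value (or increment), rad/s for the angular-velocity
#'   kinds, rad for `set_phi`.
#' @param stride Stride index whose opening touchdown triggers the
#'   perturbation (strides pair consecutive steps: stride `k` opens at
#'   touchdown `2k - 1`).
#' @return A `perturbation_spec`.
#' @export
perturbation <- function(kind = "set_phidot", magnitude = -50 * pi / 180,
                         stride = 4) {
  kind <- match.arg(kind, c("set_phidot", "add_phidot", "set_phi"))
  structure(list(kind = kind, magnitude = magnitude, stride = stride,
                 touchdown_index = 2L * as.integer(stride) - 1L),
            class = "perturbation_spec")
}

#' Apply a perturbation to a walker state
#'
#' Pure state modification used by the engine at the trigger event: all
#' other fields are untouched.
#'
#' @param state A [walker_state()].
#' @param spec A [perturbation()] specification.
#' @return The modified state.
#' @export
apply_perturbation <- function(state, spec) {
  stopifnot(inherits(state, "walker_state"),
            inherits(spec, "perturbation_spec"))
  switch(spec$kind,
         set_phidot = { state$phidot <- spec$magnitude },
         add_phidot = { state$phidot <- state$phidot + spec$magnitude },
         set_phi = { state$phi <- spec$magnitude })
  state
}

#' Simulate walking
#'
#' Runs the hybrid walker simulation from a mid-stance Poincare state, a
#' full [walker_state()], or a converged [find_limit_cycle()] gait, chaining
#' single- and double-support phases through touchdown, takeoff and
#' mid-stance events until `n_steps` touchdowns have occurred (or the walker
#' falls). The gait is judged stable if all `n_steps` steps complete and
#' every per-step mean forward speed lies within `speed_tol` of
#' `speed_target`.
#'
#' @param from A `poincare_state` (or plain length-5 numeric), a
#'   `walker_state`, or a `gait_cycle`.
#' @param params A [walker_params()] object.
#' @param controller A `gait_controller` (taken from the cycle if `from` is
#'   a `gait_cycle` and `controller` is missing).
#' @param n_steps Number of steps (touchdowns) to take; default 50.
#' @param speed_target Target forward speed for the stability verdict, m/s.
#' @param speed_tol Relative per-step speed tolerance (default 0.05).
#' @param perturb Optional [perturbation()].
#' @param record Record the full trajectory (default `TRUE`).
#' @param t_max Simulated-time cap, s.
#' @return A `gait_sim` object: list with `status`, `stable`,
#'   `failure_reason`, `steps` (tibble of per-step times, positions,
#'   speeds), `events`, `poincare` (section samples with the gains in
#'   force), `trajectory` (tibble if recorded), `t_perturb`, and scalars
#'   `n_steps`, `t_end`, `distance`.
#' @export
simulate_walk <- function(from, params = walker_params(), controller = NULL,
                          n_steps = 50, speed_target = 1, speed_tol = 0.05,
                          perturb = NULL, record = TRUE, t_max = 120) {
  if (inherits(from, "gait_cycle")) {
    if (is.null(controller)) controller <- from$controller
    from <- from$S_star
  }
  if (is.null(controller)) stop("a controller is required")
  r <- if (inherits(from, "walker_state")) {
    sim_from_state(from, params, controller, stop_td = as.integer(n_steps),
                   t_max = t_max, record = record, perturb = perturb)
  } else {
    sim_from_midstance(as.numeric(from), params, controller,
                       stop_td = as.integer(n_steps), t_max = t_max,
                       record = record, perturb = perturb)
  }
  as_gait_sim(r, params, controller, n_steps, speed_target, speed_tol)
}

as_gait_sim <- function(r, params, controller, n_steps, speed_target,
                        speed_tol) {
  steps <- tibble::tibble(
    t = r$steps[, 1], x = r$steps[, 2], leg = as.integer(r$steps[, 3]) + 1L)
  if (nrow(steps) > 0) {
    t0 <- c(0, steps$t[-nrow(steps)])
    x0 <- c(0, steps$x[-nrow(steps)])
    steps$step <- seq_len(nrow(steps))
    steps$duration <- steps$t - t0
    steps$speed <- (steps$x - x0) / steps$duration
  } else {
    steps$step <- integer(); steps$duration <- numeric()
    steps$speed <- numeric()
  }
  events <- tibble::tibble(
    t = r$events[, 1],
    kind = EVENT_KINDS[as.integer(r$events[, 2])],
    leg = ifelse(r$events[, 3] < 0, NA_integer_,
                 as.integer(r$events[, 3]) + 1L))
  poincare <- tibble::as_tibble(as.data.frame(r$poincare))
  if (nrow(poincare) > 0 || ncol(r$poincare) == 9) {
    names(poincare) <- c("t", "leg", "vx", "y", "vy", "phi", "phidot",
                         "G_ham", "G_rf")
    poincare$leg <- as.integer(poincare$leg) + 1L
  }
  traj <- NULL
  if (nrow(r$trajectory) > 0) {
    traj <- tibble::as_tibble(as.data.frame(r$trajectory))
    names(traj) <- TRAJ_COLS
    traj$stance_1 <- traj$stance_1 > 0.5
    traj$stance_2 <- traj$stance_2 > 0.5
  }
  completed <- r$status == "completed" && nrow(steps) >= n_steps
  speed_ok <- completed &&
    all(abs(steps$speed - speed_target) <= speed_tol * speed_target)
  structure(list(
    status = r$status,
    failure_reason = if (nzchar(r$reason)) r$reason else NULL,
    stable = completed && speed_ok,
    completed_steps = nrow(steps),
    n_steps_requested = n_steps,
    speed_target = speed_target, speed_tol = speed_tol,
    t_end = r$t_end, distance = r$y_end[1],
    t_perturb = r$t_perturb,
    steps = steps, events = events, poincare = poincare,
    trajectory = traj,
    final_state = walker_state(
      x = r$y_end[1], y = r$y_end[2], vx = r$y_end[3], vy = r$y_end[4],
      phi = r$y_end[5], phidot = r$y_end[6],
      activations = pmin(1, pmax(0, r$y_end[7:10])),
      foot_x = ifelse(r$stance_end, r$foot_x_end, NA),
      stance = r$stance_end),
    params = params, controller = controller),
    class = "gait_sim")
}

#' @export
print.gait_sim <- function(x, ...) {
  cat("<gait_sim>", x$completed_steps, "steps in",
      sprintf("%.2f s over %.2f m;", x$t_end, x$distance),
      "status:", x$status, "\n")
  cat("  stable:", x$stable,
      sprintf("(target %.2f m/s +/- %.0f%%)\n",
              x$speed_target, 100 * x$speed_tol))
  if (!is.null(x$failure_reason)) cat("  failure:", x$failure_reason, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a walking simulation
#'
#' `tidy()` returns the per-step summary table; `glance()` a one-row run
#' summary.
#'
#' @param x A `gait_sim`.
#' @param ... Unused.
#' @method tidy gait_sim
#' @export
tidy.gait_sim <- function(x, ...) x$steps

#' @rdname tidy.gait_sim
#' @method glance gait_sim
#' @export
glance.gait_sim <- function(x, ...) {
  tibble::tibble(
    status = x$status, stable = x$stable, steps = x$completed_steps,
    duration = x$t_end, distance = x$distance,
    mean_speed = if (nrow(x$steps)) mean(x$steps$speed) else NA_real_,
    min_speed = if (nrow(x$steps)) min(x$steps$speed) else NA_real_,
    max_speed = if (nrow(x$steps)) max(x$steps$speed) else NA_real_,
    failure_reason = x$failure_reason %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- stride metrics -----------------------------------------------------

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

hip_power_series <- function(traj) {
  p1 <- abs(traj$phidot_h_1 * traj$tau_1)
  p2 <- abs(traj$phidot_h_2 * traj$tau_2)
  p1[is.na(p1)] <- 0
  p2[is.na(p2)] <- 0
  p1 + p2
}

#' Stride energy
#'
#' The energy consumed at the hip over a trajectory window: the integral of
#' the summed absolute hip powers \eqn{\int |\dot\varphi_{h1}\tau_1| +
#' |\dot\varphi_{h2}\tau_2| \, dt} (positive and negative work both cost).
#' Swing legs exert no torque and contribute nothing.
#'
#' @param traj Trajectory tibble (from a recorded `gait_sim`), or a slice of
#'   one.
#' @param t_start,t_end Optional window bounds, s.
#' @return Energy, J.
#' @export
stride_energy <- function(traj, t_start = -Inf, t_end = Inf) {
  i <- traj$t >= t_start & traj$t <= t_end
  trapz(traj$t[i], hip_power_series(traj)[i])
}

#' Per-stride summaries
#'
#' Splits a recorded run into strides (ipsilateral touchdown to touchdown of
#' the leg that struck first) and reports per-stride duration, mean forward
#' speed, hip energy, peak instantaneous hip power, and duty factor of the
#' reference leg.
#'
#' @param sim A recorded `gait_sim`.
#' @return A tibble with one row per complete stride.
#' @export
stride_summaries <- function(sim) {
  stopifnot(inherits(sim, "gait_sim"), !is.null(sim$trajectory))
  st <- sim$steps
  if (nrow(st) < 3) return(tibble::tibble())
  ref_leg <- st$leg[1]
  td_ref <- st$t[st$leg == ref_leg]
  if (length(td_ref) < 2) return(tibble::tibble())
  traj <- sim$trajectory
  pw <- hip_power_series(traj)
  ev <- sim$events
  foot_col <- paste0("stance_", ref_leg)
  purrr::map_dfr(seq_len(length(td_ref) - 1), function(k) {
    a <- td_ref[k]; b <- td_ref[k + 1]
    i <- traj$t >= a & traj$t <= b
    x <- traj$x[i]
    # stance time of the reference leg inside the stride
    stance_frac <- if (sum(i) > 2)
      trapz(traj$t[i], as.numeric(traj[[foot_col]][i])) / (b - a)
    else NA_real_
    tibble::tibble(
      stride = k, t_start = a, t_end = b, duration = b - a,
      speed = (x[length(x)] - x[1]) / (b - a),
      energy = trapz(traj$t[i], pw[i]),
      peak_power = max(pw[i]),
      duty_factor = stance_frac)
  })
}

#' Recovery time after a perturbation
#'
#' Measures how long after the perturbation the trunk-angle trace re-enters
#' (and stays for one full stride within) a band around the unperturbed
#' orientation pattern. The reference pattern is the converged cycle's trunk
#' angle as a function of time since the most recent touchdown, so a phase
#' shift of the stride rhythm does not spuriously count as deviation.
#'
#' @param sim A recorded, perturbed `gait_sim`.
#' @param cycle The unperturbed `gait_cycle` providing the reference
#'   pattern.
#' @param band Half-width of the tolerance band, rad (default 2 degrees).
#' @return Recovery time in seconds (0 if never outside the band after the
#'   perturbation; `Inf` if the walker falls or never recovers).
#' @export
recovery_time <- function(sim, cycle, band = 2 * pi / 180) {
  stopifnot(inherits(sim, "gait_sim"), !is.null(sim$trajectory),
            inherits(cycle, "gait_cycle"))
  if (is.na(sim$t_perturb)) return(0)  # nothing to recover from
  if (sim$status == "fall") return(Inf)
  ref <- cycle$phi_pattern      # tibble: s (since touchdown), phi
  step_T <- cycle$step_time
  traj <- sim$trajectory
  td <- sim$steps$t
  # time since most recent touchdown, periodically wrapped for t before the
  # first touchdown of the run
  s_of <- function(t) {
    prev <- vapply(t, function(ti) {
      j <- which(td <= ti)
      if (length(j) == 0) td[1] - step_T else td[max(j)]
    }, numeric(1))
    (t - prev) %% step_T
  }
  i <- traj$t >= sim$t_perturb
  tt <- traj$t[i]
  dev <- abs(traj$phi[i] -
               approx(ref$s, ref$phi, xout = pmin(s_of(tt), max(ref$s)),
                      rule = 2)$y)
  stride_T <- 2 * step_T
  ok <- dev <= band
  # first time from which the trace stays in-band for one full stride
  run_start <- NA_real_
  for (j in seq_along(tt)) {
    if (ok[j]) {
      if (is.na(run_start)) run_start <- tt[j]
      if (tt[j] - run_start >= stride_T)
        return(max(0, run_start - sim$t_perturb))
    } else run_start <- NA_real_
  }
  if (!is.na(run_start) && (sim$t_end - run_start) >= 0.9 * stride_T)
    return(max(0, run_start - sim$t_perturb))
  Inf
}
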