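# ---- calibrated constants ----------------------------------------------

#' Calibrated model constants
#'
#' `nmf_ref_offset()` returns the calibrated common offset of the muscle
#' reference angles (rad): the hip-angle origin is fixed once so the
#' reflex gains admit a period-1 walking gait at 1 m/s (reproducible with
#' [calibrate_nmf_ref_offset()]). `fmch_calibration()` returns the
#' calibrated force-modulated-compliant-hip constants: rest angle
#' \eqn{\varphi_{h0} = \pi} (the straight-hip configuration at mid-stance)
#' and the gain found by [calibrate_fmch()] for a 1 m/s period-1 gait.
#' `nmf_cycle_guess()` and `fmch_cycle_guess()` return the shipped
#' mid-stance fixed-point estimates used to seed [find_limit_cycle()].
#'
#' @return Numeric offset, list of constants, or a length-5 state guess.
#' @export
nmf_ref_offset <- function() -0.05936254

#' @rdname nmf_ref_offset
#' @export
fmch_calibration <- function() list(G = 0.31746505, phi_h0 = pi)

#' @rdname nmf_ref_offset
#' @export
nmf_cycle_guess <- function() {
  poincare_state(vx = 0.99493123, y = 1.09036805, vy = 0.00053703,
                 phi = 1.57167803, phidot = -0.00405074)
}

#' @rdname nmf_ref_offset
#' @export
fmch_cycle_guess <- function() {
  poincare_state(vx = 0.99645846, y = 1.09074090, vy = 0,
                 phi = 1.57079633, phidot = 0.02400481)
}

# ---- limit-cycle search -------------------------------------------------

#' Find a period-1 walking limit cycle
#'
#' Damped (Levenberg-Marquardt) Newton iteration on the residual of the
#' step-to-step Poincare map, \eqn{\|P(S) - S\|}, from a mid-stance guess.
#' On convergence the full gait cycle (one stride, two steps) is
#' re-simulated and recorded.
#'
#' @param params A [walker_params()] object.
#' @param controller A `gait_controller`.
#' @param guess Length-5 mid-stance state guess (defaults to the shipped
#'   calibrated guess for the controller type).
#' @param tol Residual tolerance for convergence.
#' @param max_iter Newton iteration cap.
#' @param h_fd Finite-difference step for the map Jacobian.
#' @return A `gait_cycle`: `S_star`, `residual`, `speed` (m/s over the
#'   cycle), `step_time`, `stride_time`, `cycle` (recorded one-stride
#'   trajectory tibble), `phi_pattern` (trunk angle vs time since
#'   touchdown), `controller`, `params`.
#' @export
find_limit_cycle <- function(params, controller, guess = NULL, tol = 1e-8,
                             max_iter = 60, h_fd = 1e-6) {
  if (is.null(guess)) {
    guess <- switch(controller$type,
                    nmf = , adaptive_nmf = nmf_cycle_guess(),
                    fmch = fmch_cycle_guess(),
                    stop("a mid-stance guess is required for this controller"))
  }
  S <- as.numeric(guess)
  fmap <- function(S) {
    r <- poincare_map(S, params, controller)
    if (!r$ok) NULL else r$S
  }
  FS <- fmap(S)
  if (is.null(FS)) stop("the initial guess falls before the next mid-stance")
  rn <- sqrt(sum((FS - S)^2))
  lam <- 1e-4
  for (it in seq_len(max_iter)) {
    if (rn < tol) break
    J <- matrix(0, 5, 5)
    for (j in 1:5) {
      Sp <- S; Sp[j] <- Sp[j] + h_fd
      Sm <- S; Sm[j] <- Sm[j] - h_fd
      fp <- fmap(Sp); fm <- fmap(Sm)
      if (is.null(fp) || is.null(fm))
        stop("a finite-difference probe fell; supply a better guess")
      J[, j] <- (fp - fm) / (2 * h_fd)
    }
    A <- J - diag(5)
    res <- FS - S
    improved <- FALSE
    for (try in 1:40) {
      dS <- tryCatch(
        solve(crossprod(A) + lam * diag(5), -crossprod(A, res)),
        error = function(e) NULL)
      if (!is.null(dS)) {
        Sn <- S + as.numeric(dS)
        FSn <- fmap(Sn)
        if (!is.null(FSn)) {
          rnn <- sqrt(sum((FSn - Sn)^2))
          if (rnn < rn) {
            S <- Sn; FS <- FSn; rn <- rnn
            lam <- max(lam / 3, 1e-9)
            improved <- TRUE
            break
          }
        }
      }
      lam <- lam * 5
    }
    if (!improved) break
  }
  if (rn >= tol)
    stop(sprintf("limit-cycle search did not converge: residual %.3e", rn))

  # record one full stride (two section crossings) from the fixed point
  r <- sim_from_midstance(S, params, controller, stop_ms = 2L, t_max = 10,
                          record = TRUE)
  sim <- as_gait_sim(r, params, controller, n_steps = 2, speed_target = 1,
                     speed_tol = Inf)
  traj <- sim$trajectory
  ev <- sim$events
  td <- ev[ev$kind == "touchdown", ]
  step_time <- r$t_end / 2
  # reference trunk-angle pattern vs time since the most recent touchdown
  phi_pattern <- NULL
  if (nrow(td) >= 2) {
    i <- traj$t >= td$t[1] & traj$t <= td$t[2]
    phi_pattern <- tibble::tibble(s = traj$t[i] - td$t[1], phi = traj$phi[i])
  }
  # engine-time offsets of each leg's last touchdown relative to the final
  # mid-stance sample (needed to phase a feed-forward replay)
  last_td_rel <- c(NA_real_, NA_real_)
  for (lg in 1:2) {
    tds <- td$t[td$leg == lg]
    if (length(tds) > 0) last_td_rel[lg] <- max(tds) - r$t_end
  }
  structure(list(
    S_star = S, residual = rn,
    speed = r$y_end[1] / r$t_end,
    step_time = step_time, stride_time = r$t_end,
    cycle = traj, events = ev, phi_pattern = phi_pattern,
    last_td_rel = last_td_rel,
    controller = controller, params = params),
    class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat("<gait_cycle>", x$controller$type,
      sprintf("| speed %.4f m/s | stride %.3f s | residual %.2e\n",
              x$speed, x$stride_time, x$residual))
  invisible(x)
}

#' @rdname tidy.gait_sim
#' @method tidy gait_cycle
#' @export
tidy.gait_cycle <- function(x, ...) x$cycle

#' @rdname tidy.gait_sim
#' @method glance gait_cycle
#' @export
glance.gait_cycle <- function(x, ...) {
  tr <- x$cycle
  tibble::tibble(
    controller = x$controller$type, speed = x$speed,
    stride_time = x$stride_time, residual = x$residual,
    com_excursion_cm = 100 * (max(tr$y) - min(tr$y)),
    grf_peak_bw = max(pmax(tr$fy_1, tr$fy_2, na.rm = TRUE), na.rm = TRUE) /
      body_weight(x$params),
    stride_energy = stride_energy(tr))
}

# ---- calibration routines ----------------------------------------------

secant_calibrate <- function(eval_speed, x1, x2, target = 1, tol = 1e-6,
                             max_iter = 12) {
  s1 <- eval_speed(x1); s2 <- eval_speed(x2)
  for (i in seq_len(max_iter)) {
    if (!is.finite(s2)) stop("calibration lost the gait")
    if (abs(s2 - target) < tol) break
    xn <- x2 + (target - s2) * (x2 - x1) / (s2 - s1)
    x1 <- x2; s1 <- s2
    x2 <- xn; s2 <- eval_speed(xn)
  }
  list(x = x2, speed = s2)
}

#' Calibrate the FMCH hip gain
#'
#' With the rest angle fixed at the straight-hip mid-stance configuration
#' (\eqn{\varphi_{h0} = \pi}), searches the normalised hip stiffness `G` by
#' secant iteration so that the period-1 gait's forward speed equals
#' `speed_target`. Deterministic; reproduces [fmch_calibration()].
#'
#' @param params A [walker_params()] object.
#' @param speed_target Target speed, m/s.
#' @param G_init Two starting gains for the secant.
#' @param guess Mid-stance fixed-point guess.
#' @param tol Speed tolerance.
#' @return List with `G`, `phi_h0`, the converged `cycle`, and the achieved
#'   `speed`.
#' @export
calibrate_fmch <- function(params = walker_params(), speed_target = 1,
                           G_init = c(0.2, 0.25), guess = fmch_cycle_guess(),
                           tol = 1e-5) {
  cur_guess <- as.numeric(guess)
  eval_speed <- function(G) {
    cyc <- find_limit_cycle(params, controller_fmch(G = G, phi_h0 = pi),
                            guess = cur_guess)
    cur_guess <<- cyc$S_star
    cyc$speed
  }
  out <- secant_calibrate(eval_speed, G_init[1], G_init[2],
                          target = speed_target, tol = tol)
  cyc <- find_limit_cycle(params, controller_fmch(G = out$x, phi_h0 = pi),
                          guess = cur_guess)
  list(G = out$x, phi_h0 = pi, cycle = cyc, speed = cyc$speed)
}

#' Calibrate the muscle reference-angle offset
#'
#' The hip-angle origin of the muscle length maps is fixed by requiring the
#' printed reflex gains to admit a period-1 nmF gait at `speed_target`;
#' the common offset added to both reference angles is searched by secant
#' iteration on the fixed point's forward speed. Deterministic; reproduces
#' [nmf_ref_offset()].
#'
#' @param speed_target Target speed, m/s.
#' @param offset_init Two starting offsets, rad.
#' @param guess Mid-stance fixed-point guess.
#' @param tol Speed tolerance.
#' @return List with `offset`, the converged `cycle`, and the achieved
#'   `speed`.
#' @export
calibrate_nmf_ref_offset <- function(speed_target = 1,
                                     offset_init = c(-0.05, -0.065),
                                     guess = NULL, tol = 1e-5) {
  cur_guess <- if (is.null(guess))
    c(1.043, 1.0894, 0, 1.5726, 0.02) else as.numeric(guess)
  eval_speed <- function(d) {
    p <- walker_params(phi_ref_offset = d)
    cyc <- find_limit_cycle(p, controller_nmf(p), guess = cur_guess)
    cur_guess <<- cyc$S_star
    cyc$speed
  }
  out <- secant_calibrate(eval_speed, offset_init[1], offset_init[2],
                          target = speed_target, tol = tol)
  p <- walker_params(phi_ref_offset = out$x)
  cyc <- find_limit_cycle(p, controller_nmf(p), guess = cur_guess)
  list(offset = out$x, cycle = cyc, speed = cyc$speed)
}

# ---- preflex library ----------------------------------------------------

#' Record a preflex activation library
#'
#' Replays of a steady gait need the muscle activations of the converged
#' reflex gait as a function of time since the leg's touchdown. This
#' simulates two strides from the converged cycle and extracts one full
#' stride of the first leg's RF and HAM activations.
#'
#' @param cycle A converged nmF `gait_cycle`.
#' @param params A [walker_params()] object.
#' @param dt Sampling interval of the library, s.
#' @return A tibble with columns `time`, `a_rf`, `a_ham` and attributes
#'   `stride_time`, `last_td_rel`.
#' @export
record_preflex_library <- function(cycle, params = cycle$params, dt = 2e-3) {
  stopifnot(inherits(cycle, "gait_cycle"))
  r <- sim_from_midstance(cycle$S_star, params, cycle$controller,
                          stop_ms = 4L, t_max = 20, record = TRUE)
  sim <- as_gait_sim(r, params, cycle$controller, 4, 1, Inf)
  traj <- sim$trajectory
  td <- sim$events[sim$events$kind == "touchdown", ]
  lg <- td$leg[1]
  tds <- td$t[td$leg == lg]
  if (length(tds) < 2) stop("recording too short for a full stride")
  a <- tds[1]; b <- tds[2]
  grid <- seq(0, b - a, by = dt)
  col_rf <- paste0("a_rf_", lg); col_ham <- paste0("a_ham_", lg)
  lib <- tibble::tibble(
    time = grid,
    a_rf = approx(traj$t - a, traj[[col_rf]], xout = grid, rule = 2)$y,
    a_ham = approx(traj$t - a, traj[[col_ham]], xout = grid, rule = 2)$y)
  attr(lib, "stride_time") <- b - a
  attr(lib, "last_td_rel") <- cycle$last_td_rel
  lib
}

# ---- basin of attraction ------------------------------------------------

#' Basin of attraction over trunk posture perturbations
#'
#' Sweeps a grid of initial trunk angles and angular velocities: each cell
#' replaces \eqn{(\phi, \dot\phi)} in the limit cycle's mid-stance state,
#' keeps the remaining coordinates at their limit-cycle values, and checks
#' whether the walker completes `n_steps` touchdowns without falling. Cell
#' failures of any kind count as unstable; the sweep never aborts.
#'
#' The default grid spans trunk angles 60-120 degrees in 1-degree steps and
#' angular velocities -200 to +150 deg/s in 0.1 rad/s steps; the coarse
#' preset (`resolution = "coarse"`) uses 5 degrees and 0.2 rad/s for
#' desk-scale runs.
#'
#' @param cycle A converged `gait_cycle` (supplies the mid-stance state and,
#'   by default, the controller).
#' @param params A [walker_params()] object.
#' @param controller Controller to evaluate (defaults to the cycle's).
#' @param phi_range Trunk-angle range, rad.
#' @param phidot_range Trunk angular-velocity range, rad/s.
#' @param phi_step Grid step in trunk angle, rad.
#' @param phidot_step Grid step in angular velocity, rad/s.
#' @param resolution `"fine"`, `"coarse"`, or `"custom"` (use the explicit
#'   steps).
#' @param n_steps Steps required for a stable verdict (default 50).
#' @param t_max Per-cell simulated-time cap, s.
#' @return A `basin_grid` tibble with columns `phi`, `phidot`, `stable`,
#'   and attributes `area` (rad * rad/s), `cell_area`, `model`.
#' @export
basin_of_attraction <- function(cycle, params = cycle$params,
                                controller = cycle$controller,
                                phi_range = c(60, 120) * pi / 180,
                                phidot_range = c(-200, 150) * pi / 180,
                                phi_step = pi / 180, phidot_step = 0.1,
                                resolution = c("custom", "fine", "coarse"),
                                n_steps = 50, t_max = 90) {
  resolution <- match.arg(resolution)
  if (resolution == "fine") { phi_step <- pi / 180; phidot_step <- 0.1 }
  if (resolution == "coarse") { phi_step <- 5 * pi / 180; phidot_step <- 0.2 }
  phis <- seq(phi_range[1], phi_range[2], by = phi_step)
  phidots <- seq(phidot_range[1], phidot_range[2], by = phidot_step)
  M <- cpp_basin(as.numeric(cycle$S_star), phis, phidots,
                 engine_pars(params), engine_ctrl(controller),
                 as.integer(n_steps), t_max)
  grid <- tidyr::expand_grid(phi = phis, phidot = phidots)
  grid$stable <- as.vector(t(M))
  cell <- phi_step * phidot_step
  structure(
    tibble::as_tibble(grid),
    area = sum(grid$stable) * cell,
    cell_area = cell,
    n_stable = sum(grid$stable),
    model = controller$type,
    class = c("basin_grid", class(grid)))
}

#' Basin area
#'
#' @param basin A `basin_grid`.
#' @return Stable area in rad * rad/s.
#' @export
basin_area <- function(basin) attr(basin, "area")

# ---- virtual pivot point ------------------------------------------------

#' Estimate the virtual pivot point
#'
#' Transforms every recorded stance-phase ground-reaction-force line (foot
#' application point plus force direction) into the trunk-fixed frame
#' centred on the CoM (ordinate along the trunk axis) and finds the point
#' minimising the summed squared perpendicular distances to all lines. In
#' upright walking these force lines intersect above the CoM at the virtual
#' pivot point.
#'
#' @param traj Recorded trajectory tibble (e.g. `cycle$cycle`).
#' @param params A [walker_params()] object.
#' @param min_force Minimum vertical GRF for a sample to contribute, N.
#' @return A `vpp_estimate`: list with `point` (x, y in the trunk frame, m),
#'   `residual` (RMS perpendicular distance, m), `n_lines`, and
#'   `condition` (of the normal matrix).
#' @export
estimate_vpp <- function(traj, params, min_force = 1) {
  pts <- list(); dirs <- list()
  for (leg in 1:2) {
    st <- traj[[paste0("stance_", leg)]] &
      !is.na(traj[[paste0("fy_", leg)]]) &
      traj[[paste0("fy_", leg)]] > min_force
    if (!any(st)) next
    fx <- traj[[paste0("fx_", leg)]][st]
    fy <- traj[[paste0("fy_", leg)]][st]
    footx <- traj[[paste0("foot_x_", leg)]][st]
    phi <- traj$phi[st]
    cx <- traj$x[st]; cy <- traj$y[st]
    # rotate by (pi/2 - phi) about the CoM so the trunk axis is the ordinate
    th <- pi / 2 - phi
    px <- footx - cx; py <- 0 - cy
    pts[[length(pts) + 1]] <- cbind(cos(th) * px - sin(th) * py,
                                    sin(th) * px + cos(th) * py)
    nrm <- sqrt(fx^2 + fy^2)
    dx <- fx / nrm; dy <- fy / nrm
    dirs[[length(dirs) + 1]] <- cbind(cos(th) * dx - sin(th) * dy,
                                      sin(th) * dx + cos(th) * dy)
  }
  P <- do.call(rbind, pts); D <- do.call(rbind, dirs)
  if (is.null(P) || nrow(P) < 10)
    stop("need at least 10 loaded stance samples to estimate a pivot point")
  vpp_from_lines(P, D)
}

#' Least-squares intersection point of a line bundle
#'
#' Finds the point minimising the summed squared perpendicular distances to
#' a set of lines given by points and unit directions; the workhorse behind
#' [estimate_vpp()].
#'
#' @param P n x 2 matrix of points on the lines.
#' @param D n x 2 matrix of unit direction vectors.
#' @return A `vpp_estimate` (see [estimate_vpp()]).
#' @export
vpp_from_lines <- function(P, D) {
  P <- as.matrix(P); D <- as.matrix(D)
  stopifnot(nrow(P) == nrow(D), ncol(P) == 2, ncol(D) == 2)
  # least-squares intersection: sum_i (I - d_i d_i^T) (v - p_i) = 0
  A <- matrix(0, 2, 2); b <- c(0, 0)
  for (i in seq_len(nrow(P))) {
    Mi <- diag(2) - tcrossprod(D[i, ] / sqrt(sum(D[i, ]^2)))
    A <- A + Mi
    b <- b + Mi %*% P[i, ]
  }
  cond <- kappa(A, exact = TRUE)
  if (cond > 1e8)
    warning("near-parallel force lines: the pivot point is ill-conditioned")
  v <- tryCatch(as.numeric(solve(A, b)), error = function(e) {
    # pseudo-inverse fallback for a numerically singular bundle
    e_ <- eigen(A, symmetric = TRUE)
    keep <- e_$values > 1e-12 * max(e_$values)
    as.numeric(e_$vectors[, keep, drop = FALSE] %*%
                 ((t(e_$vectors[, keep, drop = FALSE]) %*% b) /
                    e_$values[keep]))
  })
  perp <- vapply(seq_len(nrow(P)), function(i) {
    r <- v - P[i, ]
    r2 <- sum(r^2) - sum(r * D[i, ])^2
    sqrt(max(r2, 0))
  }, numeric(1))
  structure(list(point = c(x = v[1], y = v[2]),
                 residual = sqrt(mean(perp^2)),
                 n_lines = nrow(P), condition = cond),
            class = "vpp_estimate")
}

#' @export
print.vpp_estimate <- function(x, ...) {
  cat(sprintf("<vpp_estimate> (%.4f, %.4f) m in the trunk frame; RMS residual %.4f m over %d lines\n",
              x$point[1], x$point[2], x$residual, x$n_lines))
  invisible(x)
}

# ---- Q/R trade-off ------------------------------------------------------

#' LQR weighting trade-off study
#'
#' Repeats the standard stride-4 trunk push for the adaptive nmF controller
#' under different LQR weightings and reports recovery time, total and
#' per-stride hip energy after the perturbation, and peak hip power. The
#' canonical presets weight state error over gain effort (`Q = 100 I`),
#' weight them equally (identity), or penalise gain effort (`R = 100 I`).
#'
#' @param cycle A converged nmF `gait_cycle`.
#' @param params A [walker_params()] object.
#' @param presets Named list of `list(Q = , R = )` weightings.
#' @param perturb The perturbation to apply.
#' @param n_steps Steps to simulate.
#' @return A tibble with one row per preset.
#' @export
qr_tradeoff <- function(cycle, params = cycle$params,
                        presets = list(
                          "Q=100I" = list(Q = 100 * diag(5), R = diag(2)),
                          "Q=R=I" = list(Q = diag(5), R = diag(2)),
                          "R=100I" = list(Q = diag(5), R = 100 * diag(2))),
                        perturb = perturbation(), n_steps = 30) {
  purrr::imap_dfr(presets, function(w, nm) {
    ctrl <- design_adaptive_nmf(cycle, params, Q = w$Q, R = w$R)
    sim <- simulate_walk(cycle$S_star, params, ctrl, n_steps = n_steps,
                         perturb = perturb, record = TRUE, t_max = 60)
    rec <- recovery_time(sim, cycle)
    post <- sim$trajectory[sim$trajectory$t >= sim$t_perturb, ]
    strides <- stride_summaries(sim)
    post_strides <- strides[strides$t_start >= sim$t_perturb - 1e-9, ]
    tibble::tibble(
      preset = nm,
      recovery_time = rec,
      total_energy = stride_energy(post),
      mean_stride_energy = mean(post_strides$energy),
      max_stride_energy = max(post_strides$energy),
      peak_power = max(hip_power_series(post)),
      fell = sim$status == "fall")
  })
}

# ---- synthetic reference curves ----------------------------------------

#' Synthetic reference gait curves
#'
#' Deterministic generator of stride-phase-indexed mean-and-band curves with
#' the qualitative structure of treadmill walking at moderate speed: a
#' double-humped vertical GRF peaking near 1.1 body weight, an S-shaped
#' horizontal GRF, a double-humped CoM vertical displacement of about 5 cm
#' peak to peak, and a smooth hip-torque wave. These are synthetic fixtures
#' for exercising comparison plots; they are not measured data.
#'
#' @param seed Integer seed (same seed, same curves).
#' @param n_phase Number of stride-phase samples.
#' @return A tibble with columns `phase` (0-1), `variable`, `mean`,
#'   `lower`, `upper`.
#' @export
generate_reference_curves <- function(seed = 1L, n_phase = 101) {
  set.seed(seed)
  ph <- seq(0, 1, length.out = n_phase)
  bump <- function(c0, w) exp(-0.5 * ((ph - c0) / w)^2)
  jitter_amp <- function(a) a * (1 + 0.05 * rnorm(1))
  # per-leg vertical GRF: loading and push-off humps with a mid-stance valley
  grf_v <- jitter_amp(0.75) * bump(0.12, 0.07) +
    jitter_amp(0.72) * bump(0.48, 0.08) + 0.35 * bump(0.3, 0.18)
  grf_v <- grf_v / max(grf_v) * jitter_amp(1.1)
  grf_v[ph > 0.62] <- 0
  grf_h <- jitter_amp(0.16) * (-bump(0.12, 0.08) + bump(0.5, 0.08))
  grf_h[ph > 0.62] <- 0
  com <- jitter_amp(0.025) * (-cos(4 * pi * ph))          # two humps
  com <- com - min(com)                                   # cm-scale below
  torque <- jitter_amp(0.06) * sin(2 * pi * ph + 0.4) +
    0.02 * sin(4 * pi * ph)
  curves <- list(
    grf_vertical_bw = grf_v,
    grf_horizontal_bw = grf_h,
    com_vertical_cm = 100 * com,
    hip_torque_bw = torque)
  purrr::imap_dfr(curves, function(v, nm) {
    band <- pmax(0.05 * max(abs(v)), 0.12 * abs(v))
    tibble::tibble(phase = ph, variable = nm, mean = v,
                   lower = v - band, upper = v + band)
  })
}

#' Read and write preflex libraries as CSV
#'
#' Plain tabular storage of a recorded activation library (time since the
#' leg's touchdown vs RF and HAM activations); the stride timing metadata
#' needed to phase a replay is kept in commented header lines.
#'
#' @param library A library from [record_preflex_library()].
#' @param path File path.
#' @return `write_preflex_library()` returns `path` invisibly;
#'   `read_preflex_library()` returns the library tibble with its
#'   attributes restored.
#' @export
write_preflex_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# stride_time: %.12g", attr(library, "stride_time")),
    sprintf("# last_td_rel: %.12g %.12g",
            attr(library, "last_td_rel")[1], attr(library, "last_td_rel")[2])),
    con)
  utils::write.csv(as.data.frame(library), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_preflex_library
#' @export
read_preflex_library <- function(path) {
  hdr <- readLines(path, n = 2)
  lib <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(lib, "stride_time") <-
    as.numeric(sub("# stride_time: ", "", hdr[1]))
  attr(lib, "last_td_rel") <-
    as.numeric(strsplit(sub("# last_td_rel: ", "", hdr[2]), " ")[[1]])
  lib
}
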