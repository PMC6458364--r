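test_that("passive walking conserves mechanical energy across phases", {
  p <- default_params()
  # start at mid-stance with no hip actuation; runs through touchdown and
  # double support before it eventually tips over
  sim <- simulate_walk(c(1.1, 1.085, 0, 1.5708, 0), p, controller_passive(),
                       n_steps = 10, record = TRUE, t_max = 3)
  tr <- sim$trajectory
  tr <- tr[tr$t <= max(tr$t[tr$y > 0.8], 0), ]   # up to the fall
  E <- vapply(seq_len(nrow(tr)), function(i) {
    feet <- list()
    if (tr$stance_1[i]) feet <- c(feet, list(c(tr$foot_x_1[i], 0)))
    if (tr$stance_2[i]) feet <- c(feet, list(c(tr$foot_x_2[i], 0)))
    walker_energy(c(x = tr$x[i], y = tr$y[i], vx = tr$vx[i], vy = tr$vy[i],
                    phi = tr$phi[i], phidot = tr$phidot[i]), feet, p)
  }, numeric(1))
  # conservation within each smooth phase (a gate-bound touchdown may land
  # with a slightly pre-compressed spring, a documented impact artefact that
  # adds its elastic term discontinuously at the event itself)
  ev_t <- sort(sim$events$t)
  seg <- findInterval(tr$t, ev_t + 1e-12)
  for (sg in unique(seg)) {
    i <- which(seg == sg)
    if (length(i) < 5) next
    dt <- tr$t[max(i)] - tr$t[min(i)]
    if (dt < 0.02) next
    expect_lt(abs(E[max(i)] - E[min(i)]) / (E[min(i)] * dt), 1e-6)
  }
  # takeoff removes an unloaded spring: energy is continuous across it
  to_t <- sim$events$t[sim$events$kind %in% c("takeoff_ds", "takeoff_flight")]
  for (tt in to_t[1]) {
    before <- max(which(tr$t < tt - 1e-9)); after <- min(which(tr$t > tt + 1e-9))
    expect_lt(abs(E[after] - E[before]) / E[before], 1e-4)
  }
})

test_that("the engine matches an independent ODE solver on a smooth phase", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  S0 <- c(1.1, 1.085, 0, 1.5708, 0)
  sim <- simulate_walk(S0, p, controller_passive(), n_steps = 2,
                       record = TRUE, t_max = 3)
  ev1 <- min(sim$events$t)           # first event ends the smooth phase
  t_cmp <- 0.8 * ev1
  foot <- sim$trajectory$foot_x_1[1]
  rhs <- function(t, y, parms) {
    names(y) <- c("x", "y", "vx", "vy", "phi", "phidot")
    d <- dynamics_single(y, 0, c(foot, 0), p)
    list(d[c("x", "y", "vx", "vy", "phi", "phidot")])
  }
  y0 <- c(x = 0, y = S0[2], vx = S0[1], vy = S0[3], phi = S0[4], phidot = S0[5])
  # compare at an exactly recorded sample (no trajectory interpolation)
  tr <- sim$trajectory
  i <- which.min(abs(tr$t - t_cmp))
  t_cmp <- tr$t[i]
  ref <- deSolve::lsoda(y0, c(0, t_cmp), rhs, NULL, rtol = 1e-11, atol = 1e-12)
  mine <- c(tr$x[i], tr$y[i], tr$vx[i], tr$vy[i], tr$phi[i], tr$phidot[i])
  expect_equal(unname(mine), unname(ref[2, 2:7]), tolerance = 1e-7)
})

test_that("takeoff events are root-accurate in the unloading condition", {
  p <- default_params()
  cyc <- cached_cycle("nmf")
  sim <- simulate_walk(cyc, n_steps = 8, record = TRUE, t_max = 10)
  tr <- sim$trajectory
  to <- sim$events[sim$events$kind == "takeoff_ds", ]
  expect_gt(nrow(to), 3)
  for (i in seq_len(nrow(to))) {
    row <- tr[which.min(abs(tr$t - to$t[i])), ]
    leg <- to$leg[i]
    fy <- row[[paste0("fy_", leg)]]
    # unloading: either the vertical GRF or the spring compression is zero
    h <- hip_position(row$x, row$y, row$phi, p)
    l <- sqrt((h[["x_h"]] - row[[paste0("foot_x_", leg)]])^2 + h[["y_h"]]^2)
    expect_lt(min(abs(fy), p$k * abs(p$l0 - l)), 1e-6 * p$m * p$g)
  }
})

test_that("a periodic gait alternates legs with equal step durations", {
  cyc <- cached_cycle("fmch")
  sim <- simulate_walk(cyc, n_steps = 12, record = FALSE)
  st <- sim$steps
  expect_true(all(diff(st$leg) != 0))          # strict alternation
  d <- st$duration[-1]
  expect_lt(max(d) - min(d), 1e-4)             # equal periods on the cycle
})

test_that("touchdown and takeoff counts balance per leg", {
  cyc <- cached_cycle("nmf")
  sim <- simulate_walk(cyc, n_steps = 20, record = FALSE)
  ev <- sim$events
  for (leg in 1:2) {
    td <- sum(ev$kind == "touchdown" & ev$leg == leg)
    to <- sum(ev$kind %in% c("takeoff_ds", "takeoff_flight") & ev$leg == leg)
    expect_lte(abs(td - to), 1)
  }
})

test_that("impulse-momentum balance holds over the recorded run", {
  p <- default_params()
  cyc <- cached_cycle("nmf")
  sim <- simulate_walk(cyc, n_steps = 6, record = TRUE)
  tr <- sim$trajectory
  fy <- dplyr::coalesce(tr$fy_1, 0) * tr$stance_1 +
    dplyr::coalesce(tr$fy_2, 0) * tr$stance_2
  n <- nrow(tr)
  impulse <- sum(diff(tr$t) * (fy[-1] + fy[-n]) / 2) -
    p$m * p$g * (tr$t[n] - tr$t[1])
  expect_equal(impulse, p$m * (tr$vy[n] - tr$vy[1]), tolerance = 0.05)
})

test_that("a torqueless walker dropped from flight registers a fall", {
  p <- default_params()
  st <- walker_state(y = 1.05, vx = 1, vy = 0, phi = pi / 2, phidot = 0,
                     foot_x = c(NA, NA), stance = c(FALSE, FALSE))
  sim <- simulate_walk(st, p, controller_passive(), n_steps = 5, t_max = 2)
  expect_equal(sim$status, "fall")
  expect_false(sim$stable)
})

test_that("unstabilised walking from a generic start is judged unstable", {
  p <- default_params()
  sim <- simulate_walk(c(1.0, 1.07, 0, 1.45, -0.4), p, controller_passive(),
                       n_steps = 50, t_max = 30, record = FALSE)
  expect_false(sim$stable)
})

test_that("perturbations modify exactly the targeted coordinate", {
  st <- walker_state(y = 1.09, vx = 1, vy = 0, phi = pi / 2, phidot = 0.1)
  sp <- perturbation("set_phidot", -50 * pi / 180, stride = 4)
  st2 <- apply_perturbation(st, sp)
  expect_equal(st2$phidot, -0.8727, tolerance = 1e-4)
  expect_equal(st2[c("x", "y", "vx", "vy", "phi")],
               st[c("x", "y", "vx", "vy", "phi")])
  # zero-magnitude add leaves the state untouched; add then subtract inverts
  expect_equal(apply_perturbation(st, perturbation("add_phidot", 0)), st)
  st3 <- apply_perturbation(
    apply_perturbation(st, perturbation("add_phidot", 0.3)),
    perturbation("add_phidot", -0.3))
  expect_equal(st3, st)
  # the engine applies it at the touchdown opening the requested stride
  cyc <- cached_cycle("nmf")
  sim <- simulate_walk(cyc, n_steps = 10, perturb = perturbation(stride = 4),
                       record = FALSE, t_max = 20)
  td7 <- sim$steps$t[7]
  expect_equal(sim$t_perturb, td7, tolerance = 1e-12)
})

test_that("stride energy integrates |power| and is additive", {
  mk <- function(t, tau, phidot_h) tibble::tibble(
    t = t, tau_1 = tau, phidot_h_1 = phidot_h,
    tau_2 = NA_real_, phidot_h_2 = NA_real_)
  t <- seq(0, 1, by = 0.001)
  # constant torque and joint speed: rectangle rule
  expect_equal(stride_energy(mk(t, 10, 1)), 10, tolerance = 1e-9)
  expect_equal(stride_energy(mk(t, 0, 1)), 0)
  # sign flips of power do not change the cost
  expect_equal(stride_energy(mk(t, 10, -1)), 10, tolerance = 1e-9)
  expect_equal(stride_energy(mk(t, -10, 1)), 10, tolerance = 1e-9)
  # additive over sub-intervals
  tr <- mk(t, 5 + 3 * sin(6 * t), 1 + 0.2 * cos(3 * t))
  expect_equal(stride_energy(tr, 0, 0.4) + stride_energy(tr, 0.4, 1),
               stride_energy(tr), tolerance = 1e-6)
  expect_gte(stride_energy(tr), 0)
})

test_that("identical inputs give identical event sequences", {
  cyc <- cached_cycle("nmf")
  a <- simulate_walk(cyc, n_steps = 12, record = FALSE)
  b <- simulate_walk(cyc, n_steps = 12, record = FALSE)
  expect_identical(a$events$t, b$events$t)
  expect_identical(a$steps$x, b$steps$x)
})

test_that("event times converge as integrator tolerance tightens", {
  p_loose <- walker_params(rtol = 1e-7, atol = 1e-9)
  p_tight <- walker_params(rtol = 1e-10, atol = 1e-12)
  ctrl <- controller_nmf(default_params())
  S <- as.numeric(nmf_cycle_guess())
  a <- simulate_walk(S, p_loose, ctrl, n_steps = 4, record = FALSE)
  b <- simulate_walk(S, p_tight, ctrl, n_steps = 4, record = FALSE)
  expect_equal(a$steps$t, b$steps$t, tolerance = 1e-5)
})

test_that("recovery time is zero without perturbation and finite with one", {
  cyc <- cached_cycle("fmch")
  sim0 <- simulate_walk(cyc, n_steps = 10)
  expect_equal(recovery_time(sim0, cyc), 0)
  simp <- simulate_walk(cyc, n_steps = 50,
                        perturb = perturbation(magnitude = -0.15), t_max = 60)
  rt <- recovery_time(simp, cyc)
  expect_true(is.finite(rt))
  expect_gte(rt, 0)
})
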