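test_that("velocity-based leg adjustment interpolates velocity and gravity", {
  p <- default_params()
  pv <- walker_params(mu_vbla = 1)
  expect_equal(vbla_direction(c(2, 0.3), pv), c(0, -1))
  p0 <- walker_params(mu_vbla = 0)
  expect_equal(vbla_direction(c(1, 0), p0), c(1, 0))
  # default weighting: leg about 11.2 degrees in front of vertical
  d <- vbla_direction(c(1, 0), p)
  expect_equal(d * sqrt(0.66^2 + 3.3354^2), c(0.66, -3.3354), tolerance = 1e-4)
  expect_equal(atan(d[1] / -d[2]) * 180 / pi, 11.2, tolerance = 0.05)
  expect_error(vbla_direction(c(0, 0), p0), "zero-norm")
})

test_that("FMCH torque is linear in force and spring deflection", {
  expect_equal(fmch_torque(0, 3.0, 0.3, pi), 0)
  expect_equal(fmch_torque(800, pi, 0.3, pi), 0)
  expect_equal(fmch_torque(800, pi - 0.1, 0.001, pi), 0.001 * 800 * 0.1)
  expect_equal(fmch_torque(400, pi - 0.1, 0.3, pi),
               2 * fmch_torque(200, pi - 0.1, 0.3, pi))
})

test_that("discrete LQR solves the scalar golden-ratio Riccati equation", {
  s <- solve_dlqr(matrix(1), matrix(1), matrix(1), matrix(1))
  expect_equal(s$P[1, 1], (1 + sqrt(5)) / 2, tolerance = 1e-10)
  expect_equal(s$K[1, 1], (1 + sqrt(5)) / 2 / ((1 + sqrt(5)) / 2 + 1),
               tolerance = 1e-10)
  expect_lt(s$closed_loop_radius, 1)
})

test_that("with no actuation the Riccati solution is the Lyapunov solution", {
  set.seed(11)
  A <- matrix(rnorm(9), 3); A <- 0.6 * A / max(Mod(eigen(A)$values))
  Q <- diag(3)
  s <- solve_dlqr(A, matrix(0, 3, 1), Q, matrix(1))
  expect_equal(s$K, matrix(0, 1, 3), tolerance = 1e-9)
  expect_equal(s$P, Q + t(A) %*% s$P %*% A, tolerance = 1e-8)
})

test_that("Riccati iteration matches an independent spectral solver", {
  set.seed(7)
  for (i in 1:12) {
    n <- sample(2:5, 1); m <- sample(1:2, 1)
    sys <- random_system(n, m)
    s <- solve_dlqr(sys$A, sys$B, sys$Q, sys$R)
    P_ref <- dare_spectral(sys$A, sys$B, sys$Q, sys$R)
    expect_lt(max(abs(s$P - P_ref)), 1e-8 * max(1, max(abs(P_ref))))
    expect_lt(s$closed_loop_radius, 1)
  }
})

test_that("non-convergent Riccati iteration reports the spectral radius", {
  A <- matrix(2)  # uncontrollable unstable scalar
  expect_error(solve_dlqr(A, matrix(0), matrix(1), matrix(1), max_iter = 50),
               "spectral radius")
  expect_error(solve_dlqr(matrix(1), matrix(1), matrix(1), matrix(0)),
               "positive definite")
})

test_that("gain adaptation is affine feedback with a floor", {
  S_star <- c(1, 1.09, 0, pi / 2, 0)
  U_star <- c(4.68e-4, 3.12e-4)
  K <- matrix(0.001, 2, 5)
  expect_equal(adapt_gains(S_star, S_star, U_star, K), U_star)
  expect_equal(adapt_gains(S_star + 0.1, S_star, U_star, 0 * K), U_star)
  # a large deviation drives gains onto the floor
  expect_equal(adapt_gains(S_star + 1, S_star, U_star, K), c(0, 0))
  dS <- c(0.01, 0, 0, 0, 0)
  expect_equal(adapt_gains(S_star + dS, S_star, U_star, K),
               U_star - as.numeric(K %*% dS))
})

test_that("map linearisation recovers analytic Jacobians to O(h^2)", {
  # analytic discrete map with known derivatives, standing in for the engine
  M <- matrix(c(0.9, 0.1, -0.2, 0.8), 2)
  N <- matrix(c(0.5, -0.3), 2)
  f <- function(S, U) as.numeric(M %*% S + N * U[1] + 0.05 * S^3)
  S0 <- c(0.4, -0.2); U0 <- 0.1
  J_true <- M + diag(0.15 * S0^2)
  lin1 <- linearize_map(f, S0, U0, h_S = 1e-3, h_U = 1e-3)
  expect_equal(lin1$A_s, J_true, tolerance = 1e-5)
  expect_equal(lin1$B_s, N, tolerance = 1e-8)
  # halving the step shrinks the error like h^2 (cubic term residual)
  lin2 <- linearize_map(f, S0, U0, h_S = 5e-4, h_U = 5e-4)
  e1 <- max(abs(lin1$A_s - J_true)); e2 <- max(abs(lin2$A_s - J_true))
  expect_equal(e1 / e2, 4, tolerance = 0.2)
  # failing evaluations trigger step shrinking rather than an error
  g <- function(S, U) if (max(abs(S - S0)) > 2e-4) NULL else f(S, U)
  lin3 <- linearize_map(g, S0, U0, h_S = 1e-3, h_U = 1e-4)
  expect_equal(lin3$A_s, J_true, tolerance = 1e-3)
})

test_that("the reflex pathway reduces to a force-modulated compliant hip", {
  p <- default_params()
  # (i) with force-length and force-velocity pinned to 1, the quasi-steady
  # torque is exactly r0 Fmax (Sat(stim0+G_H Fs) - Sat(stim0+G_R Fs)):
  # pure force modulation, the stimulation bias cancelling
  Fs <- seq(0, 1500, by = 100)
  tau <- nmf_quasisteady_torque(pi, Fs, 0, p, pin_fl_fv = TRUE)
  expect_equal(tau, p$r0 * p$F_max * (p$G_ham - p$G_rf) * Fs, tolerance = 1e-9)
  # (ii) over the stance operating range the full quasi-steady torque is an
  # Fs-modulated linear angular spring: tau ~ G_eff Fs (phi_h0_eff - phi_h)
  phih <- seq(pi - 0.12, pi + 0.12, length.out = 41)
  for (Fs in c(400, 800)) {
    tau <- nmf_quasisteady_torque(phih, Fs, 0, p)
    fit <- lm(tau ~ phih)
    expect_gt(summary(fit)$r.squared, 0.95)      # linear in the hip angle
    expect_lt(coef(fit)[2], 0)                   # restoring spring sign
  }
  # the effective stiffness scales with the leg force (force modulation)
  s400 <- unname(coef(lm(nmf_quasisteady_torque(phih, 400, 0, p) ~ phih))[2])
  s800 <- unname(coef(lm(nmf_quasisteady_torque(phih, 800, 0, p) ~ phih))[2])
  expect_equal(s800 / s400, 2, tolerance = 0.25)
})

test_that("the step map contracts small deviations over the control horizon", {
  # with the adaptive layer the closed-loop map is strictly contracting
  cyc <- cached_cycle("nmf")
  p <- default_params()
  ad <- design_adaptive_nmf(cyc, p)
  expect_lt(attr(ad, "design")$closed_loop_radius, 1)
  lin <- attr(ad, "design")
  # LQR guarantee holds on the identified system
  expect_lt(max(Mod(eigen(lin$A_s - lin$B_s %*% lin$K)$values)), 1)
})

test_that("poincare map has the limit cycle as fixed point and composes", {
  cyc <- cached_cycle("nmf")
  p <- default_params()
  r1 <- poincare_map(cyc$S_star, p, cyc$controller)
  expect_true(r1$ok)
  expect_lt(sqrt(sum((r1$S - cyc$S_star)^2)), 1e-7)
  # semigroup property: two single steps equal one two-step map
  S0 <- cyc$S_star + c(5e-3, 0, 0, 2e-3, 0)
  a <- poincare_map(S0, p, cyc$controller)
  b <- poincare_map(a$S, p, cyc$controller)
  two <- poincare_map(S0, p, cyc$controller, n_steps = 2)
  expect_equal(two$S, b$S, tolerance = 1e-6)
})

test_that("closed-loop cost beats the unadapted cost for a perturbed start", {
  cyc <- cached_cycle("nmf")
  p <- default_params()
  ad <- design_adaptive_nmf(cyc, p)
  des <- attr(ad, "design")
  run_cost <- function(ctrl) {
    sim <- simulate_walk(cyc$S_star, p, ctrl, n_steps = 24,
                         perturb = perturbation(magnitude = -0.2),
                         record = FALSE, t_max = 30)
    po <- sim$poincare
    po <- po[po$t > sim$t_perturb, ]
    dS <- sweep(as.matrix(po[, c("vx", "y", "vy", "phi", "phidot")]),
                2, cyc$S_star)
    dU <- sweep(as.matrix(po[, c("G_ham", "G_rf")]), 2, des$K %*% rep(0, 5) +
                  c(ad$U_star))
    # scale gains so the R-term is comparable to the design's scaling
    dU <- dU / abs(ad$U_star)[col(dU)]
    list(J = lqr_cost(dS, dU), fell = sim$status == "fall")
  }
  with_K <- run_cost(ad)
  without_K <- run_cost(controller_nmf(p))
  expect_false(with_K$fell)
  expect_true(without_K$fell || without_K$J > with_K$J)
})
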