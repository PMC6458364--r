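#' Velocity-based swing-leg direction
#'
#' The target leg direction is the normalised weighted sum of the CoM
#' velocity vector and the gravity vector,
#' \eqn{O = (1-\mu) V + \mu (0, -g)}: \eqn{\mu = 0} aligns the leg with the
#' velocity, \eqn{\mu = 1} points it straight down.
#'
#' @param V Length-2 CoM velocity, m/s.
#' @param params A [walker_params()] object (supplies `mu_vbla` and `g`).
#' @return Unit direction vector (pointing from hip toward the target foot).
#' @export
vbla_direction <- function(V, params) {
  mu <- params$mu_vbla
  O <- c((1 - mu) * V[1], (1 - mu) * V[2] - mu * params$g)
  n <- sqrt(sum(O^2))
  if (n < 1e-12) stop("degenerate leg direction: zero-norm target vector")
  O / n
}

#' Force-modulated compliant hip torque
#'
#' Rotational spring whose stiffness is modulated by the axial leg force:
#' \eqn{\tau = G F_s (\varphi_{h0} - \varphi_h)}. An unloaded leg exerts no
#' torque.
#'
#' @param F_s Axial leg force, N (non-negative).
#' @param phi_h Hip angle, rad.
#' @param G Normalised hip stiffness.
#' @param phi_h0 Rest angle of the virtual hip spring, rad.
#' @return Torque, N m.
#' @export
fmch_torque <- function(F_s, phi_h, G, phi_h0) {
  stopifnot(all(F_s >= 0), G >= 0)
  G * F_s * (phi_h0 - phi_h)
}

# ---- controller constructors -------------------------------------------

new_controller <- function(x) structure(x, class = "gait_controller")

#' Gait controllers
#'
#' Constructors for the balance strategies of the walker:
#' \describe{
#'   \item{`controller_fmch()`}{force-modulated compliant hip springs with
#'     calibrated gain and rest angle (defaults from [fmch_calibration()]).}
#'   \item{`controller_nmf()`}{delayed positive leg-force reflexes driving
#'     the Hill-type RF/HAM pair (gains default to the values in `params`).}
#'   \item{`controller_preflex()`}{feed-forward replay of activation traces
#'     recorded from a steady nmF gait (see [record_preflex_library()]); no
#'     sensing.}
#'   \item{`controller_adaptive_nmf()`}{the nmF reflex with a discrete LQR
#'     layer that retunes the gain vector (G_HAM, G_RF) once per step at
#'     mid-stance (see [design_adaptive_nmf()]).}
#'   \item{`controller_passive()`}{zero hip torque (for conservation tests).}
#' }
#'
#' @param G,phi_h0 FMCH gain and rest angle.
#' @param params Optional [walker_params()] supplying reflex gains.
#' @param G_rf,G_ham Reflex gains, 1/N.
#' @param library Preflex activation library: a data frame with columns
#'   `time` (s since the leg's touchdown), `a_rf`, `a_ham`.
#' @param K 2 x 5 LQR feedback gain matrix (rows: G_HAM, G_RF).
#' @param S_star Fixed-point Poincare state, length 5.
#' @param U_star Fixed-point gain vector `c(G_ham, G_rf)`.
#' @return A `gait_controller` object.
#' @name controllers
NULL

#' @rdname controllers
#' @export
controller_fmch <- function(G = fmch_calibration()$G,
                            phi_h0 = fmch_calibration()$phi_h0) {
  new_controller(list(type = "fmch", G_fmch = G, phi_h0 = phi_h0))
}

#' @rdname controllers
#' @export
controller_nmf <- function(params = walker_params(), G_rf = params$G_rf,
                           G_ham = params$G_ham) {
  new_controller(list(type = "nmf", g_rf = G_rf, g_ham = G_ham))
}

#' @rdname controllers
#' @export
controller_preflex <- function(library) {
  stopifnot(is.data.frame(library),
            all(c("time", "a_rf", "a_ham") %in% names(library)))
  new_controller(list(type = "preflex",
                      pf_time = library$time, pf_a_rf = library$a_rf,
                      pf_a_ham = library$a_ham,
                      stride_time = attr(library, "stride_time"),
                      last_td_rel = attr(library, "last_td_rel")))
}

#' @rdname controllers
#' @export
controller_adaptive_nmf <- function(K, S_star, U_star) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == 2, ncol(K) == 5, length(S_star) == 5,
            length(U_star) == 2)
  new_controller(list(type = "adaptive_nmf", K = K,
                      S_star = as.numeric(S_star),
                      U_star = as.numeric(U_star),
                      g_ham = U_star[1], g_rf = U_star[2]))
}

#' @rdname controllers
#' @export
controller_passive <- function() new_controller(list(type = "passive"))

#' @export
print.gait_controller <- function(x, ...) {
  cat("<gait_controller:", x$type, ">\n")
  invisible(x)
}

# ---- Poincare map -------------------------------------------------------

#' Mid-stance Poincare state
#'
#' The five-dimensional discrete state sampled where the stance leg passes
#' vertically under the hip: forward speed, CoM height, vertical speed,
#' trunk angle and trunk angular velocity.
#'
#' @param vx,y,vy,phi,phidot Components.
#' @return Named numeric of class `poincare_state`.
#' @export
poincare_state <- function(vx, y, vy, phi, phidot) {
  structure(c(vx = vx, y = y, vy = vy, phi = phi, phidot = phidot),
            class = "poincare_state")
}

#' Step-to-step Poincare map
#'
#' Reconstructs a full walker configuration from a mid-stance state (the
#' horizontal position is free and set to 0; the stance foot is placed under
#' the hip; activations start at their quasi-steady values), simulates one
#' full step to the next mid-stance crossing, and returns the sampled
#' five-vector. A fall before the next crossing is reported as failure.
#'
#' @param S Mid-stance state (length-5 numeric: vx, y, vy, phi, phidot).
#' @param params A [walker_params()] object.
#' @param controller A `gait_controller`.
#' @param gains Optional length-2 reflex gain override `c(G_ham, G_rf)`
#'   (the LQR's control input).
#' @param n_steps Number of section crossings to advance (default 1).
#' @param t_max Wall of simulated time, s.
#' @return A list with `ok` (logical), `S` (the next section state, or
#'   `NULL` after a fall), `t` (elapsed time), `speed` (mean forward speed
#'   over the map), and `reason` for failures.
#' @export
poincare_map <- function(S, params, controller, gains = NULL, n_steps = 1,
                         t_max = 5 * n_steps) {
  ctrl <- controller
  if (!is.null(gains)) {
    stopifnot(ctrl$type %in% c("nmf", "adaptive_nmf"))
    ctrl$g_ham <- gains[1]
    ctrl$g_rf <- gains[2]
    if (ctrl$type == "adaptive_nmf") ctrl <- new_controller(
      list(type = "nmf", g_ham = gains[1], g_rf = gains[2]))
  }
  r <- sim_from_midstance(S, params, ctrl, stop_ms = n_steps, t_max = t_max)
  if (r$status != "completed" || nrow(r$poincare) < n_steps) {
    reason <- if (r$status == "fall") paste("fall:", r$reason) else r$status
    return(list(ok = FALSE, S = NULL, t = r$t_end, speed = NA_real_,
                reason = reason))
  }
  po <- r$poincare
  list(ok = TRUE, S = as.numeric(po[nrow(po), 3:7]), t = r$t_end,
       speed = r$y_end[1] / r$t_end, reason = NULL)
}

# ---- finite-difference linearisation ------------------------------------

#' Linearise a discrete map about a fixed point
#'
#' Central finite-difference Jacobians of a map `f(S, U)` with respect to the
#' state `S` (giving `A_s`) and the input `U` (giving `B_s`), column by
#' column. If a perturbed evaluation fails (e.g. the walker falls), the step
#' for that column is shrunk and retried.
#'
#' @param f Function of `(S, U)` returning the next state, or `NULL` on
#'   failure.
#' @param S_star,U_star Fixed point at which to linearise.
#' @param h_S,h_U Finite-difference steps per component (scalar or vector).
#' @param shrink Factor applied to the step on failure; at most 6 shrinks
#'   are attempted before erroring.
#' @return List with matrices `A_s` (n x n) and `B_s` (n x m).
#' @export
linearize_map <- function(f, S_star, U_star, h_S = 1e-5, h_U = 1e-6,
                          shrink = 0.25) {
  n <- length(S_star); m <- length(U_star)
  h_S <- rep_len(h_S, n); h_U <- rep_len(h_U, m)
  fd_col <- function(pert) {
    # pert(h) returns list(fp, fm); retries with smaller h on failure
    function(h0) {
      h <- h0
      for (i in 1:6) {
        v <- pert(h)
        if (!is.null(v$fp) && !is.null(v$fm)) return((v$fp - v$fm) / (2 * h))
        h <- h * shrink
      }
      stop("finite-difference evaluation kept failing after shrinking the step")
    }
  }
  A <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    col <- fd_col(function(h) {
      Sp <- S_star; Sp[j] <- Sp[j] + h
      Sm <- S_star; Sm[j] <- Sm[j] - h
      list(fp = f(Sp, U_star), fm = f(Sm, U_star))
    })
    A[, j] <- col(h_S[j])
  }
  B <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    col <- fd_col(function(h) {
      Up <- U_star; Up[j] <- Up[j] + h
      Um <- U_star; Um[j] <- Um[j] - h
      list(fp = f(S_star, Up), fm = f(S_star, Um))
    })
    B[, j] <- col(h_U[j])
  }
  list(A_s = A, B_s = B)
}

#' Linearise the walking map about a limit cycle
#'
#' Wraps [linearize_map()] around [poincare_map()] at a converged gait: the
#' state is the mid-stance five-vector, the input is the reflex gain vector
#' `(G_HAM, G_RF)`.
#'
#' @param cycle A `gait_cycle` from [find_limit_cycle()].
#' @param params A [walker_params()] object.
#' @param h_rel Relative finite-difference step (of each state's
#'   characteristic scale: 1 m/s, 1 m, 1 rad, 1 rad/s).
#' @return List with `A_s` (5 x 5), `B_s` (5 x 2), and the fixed point.
#' @export
linearize_gait <- function(cycle, params, h_rel = 1e-4) {
  stopifnot(inherits(cycle, "gait_cycle"))
  ctrl <- cycle$controller
  U_star <- c(ctrl$g_ham, ctrl$g_rf)
  f <- function(S, U) {
    r <- poincare_map(S, params, ctrl, gains = U)
    if (!r$ok) NULL else r$S
  }
  lin <- linearize_map(f, cycle$S_star, U_star,
                       h_S = h_rel * c(1, 1, 1, 1, 1),
                       h_U = h_rel * abs(U_star))
  c(lin, list(S_star = cycle$S_star, U_star = U_star))
}

# ---- discrete LQR -------------------------------------------------------

#' Discrete-time LQR by Riccati fixed-point iteration
#'
#' Iterates the discrete algebraic Riccati recursion
#' \deqn{P \leftarrow Q + A^T (P - P B (B^T P B + R)^{-1} B^T P) A}
#' from \eqn{P_0 = Q} until the supremum-norm update falls below `tol`, then
#' forms the feedback gain \eqn{K = (B^T P B + R)^{-1} B^T P A}. The
#' controlled system is \eqn{\Delta S_{k+1} = A \Delta S_k + B \Delta U_k}
#' with \eqn{\Delta U_k = -K \Delta S_k}.
#'
#' @param A,B State and input matrices of the linearised step map.
#' @param Q,R Symmetric state and input weights (R positive definite).
#' @param tol Convergence tolerance on `max(abs(P_new - P))`.
#' @param max_iter Iteration cap.
#' @return List with `K` (m x n), `P` (n x n), `iterations`, and
#'   `closed_loop_radius` (spectral radius of `A - B K`).
#' @examples
#' # scalar golden-ratio case: P^2 = P + 1
#' solve_dlqr(matrix(1), matrix(1), matrix(1), matrix(1))$P  # (1+sqrt(5))/2
#' @export
solve_dlqr <- function(A, B, Q, R, tol = 1e-12, max_iter = 10000) {
  A <- as.matrix(A); B <- as.matrix(B); Q <- as.matrix(Q); R <- as.matrix(R)
  n <- nrow(A)
  stopifnot(ncol(A) == n, nrow(B) == n, nrow(Q) == n, ncol(Q) == n,
            nrow(R) == ncol(B), ncol(R) == ncol(B))
  ev_R <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_R) <= 0) stop("R must be positive definite")
  P <- Q
  for (i in seq_len(max_iter)) {
    BtP <- crossprod(B, P)
    M <- solve(BtP %*% B + R, BtP)
    Pn <- Q + crossprod(A, (P - P %*% B %*% M)) %*% A
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol) {
      P <- Pn
      K <- solve(crossprod(B, P %*% B) + R, crossprod(B, P %*% A))
      rad <- max(Mod(eigen(A - B %*% K, only.values = TRUE)$values))
      return(list(K = K, P = P, iterations = i, closed_loop_radius = rad))
    }
    P <- Pn
  }
  rad <- max(Mod(eigen(A, only.values = TRUE)$values))
  stop(sprintf(
    "Riccati iteration did not converge in %d iterations (open-loop spectral radius %.4f)",
    max_iter, rad))
}

#' Per-step gain adaptation
#'
#' The event-based outer loop: at each mid-stance the reflex gain vector is
#' set to \eqn{U_k = U^* - K (S_k - S^*)}, clamped below at `gain_floor`
#' (muscle force feedback cannot be negative), and held for the step.
#'
#' @param S_k Current mid-stance state (length 5).
#' @param S_star Fixed-point state.
#' @param U_star Fixed-point gain vector `c(G_ham, G_rf)`.
#' @param K 2 x 5 feedback gain.
#' @param gain_floor Lower clamp (default 0).
#' @return Adapted gain vector `c(G_ham, G_rf)`.
#' @export
adapt_gains <- function(S_k, S_star, U_star, K, gain_floor = 0) {
  U <- as.numeric(U_star - K %*% (S_k - S_star))
  pmax(U, gain_floor)
}

#' Design the adaptive nmF controller
#'
#' Linearises the step map about a converged nmF limit cycle and solves the
#' discrete LQR for the reflex-gain feedback, returning a ready-to-run
#' adaptive controller.
#'
#' @param cycle A `gait_cycle` for the nmF controller.
#' @param params A [walker_params()] object.
#' @param Q,R LQR weights (defaults: identity matrices, equal emphasis on
#'   state error and gain effort). The weighting presets studied in the
#'   efficiency/performance trade-off are `Q = 100 I`, `Q = R = I`, and
#'   `R = 100 I`.
#' @param h_rel Finite-difference step for the linearisation.
#' @return A `gait_controller` of type `adaptive_nmf`, with the LQR design
#'   attached as attribute `design`.
#' @export
design_adaptive_nmf <- function(cycle, params, Q = diag(5), R = diag(2),
                                h_rel = 1e-4) {
  lin <- linearize_gait(cycle, params, h_rel = h_rel)
  # gains are O(1e-4); scale the input channel for a well-conditioned DARE
  u_sc <- diag(abs(lin$U_star))
  des <- solve_dlqr(lin$A_s, lin$B_s %*% u_sc, Q, R)
  K <- u_sc %*% des$K   # back to physical gain units
  ctrl <- controller_adaptive_nmf(K, lin$S_star, lin$U_star)
  attr(ctrl, "design") <- list(A_s = lin$A_s, B_s = lin$B_s, Q = Q, R = R,
                               K = K, P = des$P,
                               closed_loop_radius = des$closed_loop_radius)
  ctrl
}

#' LQR cost of a recorded deviation sequence
#'
#' Evaluates the quadratic cost \eqn{J = \sum_k \Delta S_k^T Q \Delta S_k +
#' \Delta U_k^T R \Delta U_k} on sequences of state and input deviations.
#'
#' @param dS Matrix of state deviations (rows = steps).
#' @param dU Matrix of input deviations (rows = steps).
#' @param Q,R Weight matrices.
#' @return Scalar cost.
#' @export
lqr_cost <- function(dS, dU, Q = diag(ncol(dS)), R = diag(ncol(dU))) {
  dS <- as.matrix(dS); dU <- as.matrix(dU)
  sum(rowSums((dS %*% Q) * dS)) + sum(rowSums((dU %*% R) * dU))
}
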