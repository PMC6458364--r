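# shared fixtures: default parameters and cached limit cycles.
# cycles are memoised per test file; the search itself is exercised in
# test-analysis.R
default_params <- function() walker_params()

.cycle_cache <- new.env(parent = emptyenv())

cached_cycle <- function(which = c("nmf", "fmch")) {
  which <- match.arg(which)
  if (is.null(.cycle_cache[[which]])) {
    p <- default_params()
    ctrl <- if (which == "nmf") controller_nmf(p) else controller_fmch()
    .cycle_cache[[which]] <- find_limit_cycle(p, ctrl)
  }
  .cycle_cache[[which]]
}

# independent spectral (symplectic-eigenvector) solver for the discrete
# algebraic Riccati equation; used as the oracle against the package's
# fixed-point iteration
dare_spectral <- function(A, B, Q, R) {
  n <- nrow(A)
  G <- B %*% solve(R, t(B))
  Ait <- solve(t(A))
  Z <- rbind(cbind(A + G %*% Ait %*% Q, -G %*% Ait),
             cbind(-Ait %*% Q, Ait))
  e <- eigen(Z)
  idx <- order(Mod(e$values))[1:n]   # eigenvalues inside the unit circle
  V <- e$vectors[, idx, drop = FALSE]
  P <- Re(V[(n + 1):(2 * n), , drop = FALSE] %*% solve(V[1:n, , drop = FALSE]))
  (P + t(P)) / 2
}

# random controllable discrete system with positive-definite weights
random_system <- function(n, m) {
  A <- matrix(rnorm(n * n), n)
  A <- A / (1.1 * max(Mod(eigen(A, only.values = TRUE)$values)))
  B <- matrix(rnorm(n * m), n)
  Cq <- matrix(rnorm(n * n), n)
  Q <- crossprod(Cq) + diag(n)
  Cr <- matrix(rnorm(m * m), m)
  R <- crossprod(Cr) + diag(m)
  list(A = A, B = B, Q = Q, R = R)
}
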