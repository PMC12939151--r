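# Shared fixtures and independent oracles for the test suite.

# asymmetric "fitted-like" landscape: right (correct) well deeper
asym_spec <- function(EwR = 0.12)
  well_spec(EwL = 0.45, EwR = EwR, Em = 0.85, w = 1.1, e = 0.3, m_gap = 0.6)

# mirror-symmetric landscape (null drift expected)
sym_spec <- function()
  well_spec(EwL = 0.45, EwR = 0.45, Em = 0.85, w = 1.1, e = 0.3, m_gap = 0.6)

# flat box: every interior energy zero, so the spectrum is the analytic
# particle-in-a-box ladder of the effective box (walls one spacing outside
# the grid)
box_spec <- function(w = 2, e = 1, m_gap = 2)
  well_spec(Eb = 1, EwL = 0, EwR = 0, Em = 0, w = w, e = e, m_gap = m_gap,
            E_edge = 0)

box_energies <- function(grid, alpha, k) {
  L_eff <- (grid$x_max - grid$x_min) + 2 * grid$dx
  alpha * k^2 * pi^2 / (2 * L_eff^2)
}

# Independent finite-square-well oracle: bound-state energies of a single
# well of depth V0 and width a on an infinite domain, kinetic term
# -(alpha/2) d^2/dx^2, from the even/odd transcendental equations
#   even:  k tan(k a / 2) = kappa
#   odd:  -k cot(k a / 2) = kappa
# with k = sqrt(2 E / alpha), kappa = sqrt(2 (V0 - E) / alpha).
finite_well_bound_energies <- function(V0, a, alpha) {
  # substitute u = k a / 2; then E = 2 alpha u^2 / a^2 and the equations
  # become u tan(u) = sqrt(u0^2 - u^2) (even), -u cot(u) = sqrt(u0^2 - u^2)
  # (odd) with u0 = (a/2) sqrt(2 V0 / alpha). Each tangent branch holds at
  # most one root, so branch-wise bisection is reliable.
  u0 <- (a / 2) * sqrt(2 * V0 / alpha)
  g_even <- function(u) u * tan(u) - sqrt(pmax(u0^2 - u^2, 0))
  g_odd <- function(u) -u / tan(u) - sqrt(pmax(u0^2 - u^2, 0))
  eps <- 1e-9
  roots <- c()
  for (m in 0:ceiling(u0 / pi)) {
    br <- list(list(g = g_even, lo = m * pi, hi = m * pi + pi / 2),
               list(g = g_odd, lo = m * pi + pi / 2, hi = (m + 1) * pi))
    for (b in br) {
      lo <- max(b$lo, eps)
      hi <- min(b$hi - eps, u0 - eps)
      if (hi <= lo) next
      flo <- b$g(lo)
      fhi <- b$g(hi)
      if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) next
      roots <- c(roots, stats::uniroot(b$g, c(lo, hi), tol = 1e-13)$root)
    }
  }
  sort(2 * alpha * roots^2 / a^2)
}

# analytic probability mass inside the well for the finite-well ground state
finite_well_ground_mass_inside <- function(V0, a, alpha) {
  E0 <- finite_well_bound_energies(V0, a, alpha)[1]
  k <- sqrt(2 * E0 / alpha)
  kap <- sqrt(2 * (V0 - E0) / alpha)
  inside <- a / 2 + sin(k * a) / (2 * k)        # integral of cos^2(kx)
  outside <- cos(k * a / 2)^2 / kap             # two exponential tails
  inside / (inside + outside)
}

expect_drift_null <- function(A, tol = 1e-10) {
  expect_true(abs(A) <= tol,
              label = sprintf("|drift| = %.3g (tolerance %.1g)", abs(A), tol))
}
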