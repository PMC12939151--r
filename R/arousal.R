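#' Classical energy-sampling distribution
#'
#' The distribution `p(E)` over continuous cognitive energies in
#' `(0, Emax]` from which the total-energy arousal mechanism draws the
#' arousal criterion `E*`. The default family is uniform; a truncated
#' normal is available for unimodal sampling.
#'
#' @param family `"uniform"` or `"truncnorm"`.
#' @param Emax Maximum cognitive energy (> 0). A common choice is twice the
#'   barrier energy.
#' @param mean,sd Location and scale of the truncated-normal family
#'   (ignored for the uniform family).
#' @return Object of class `energy_sampler`.
#' @export
energy_sampler <- function(family = c("uniform", "truncnorm"), Emax = 2,
                           mean = Emax / 2, sd = Emax / 4) {
  family <- match.arg(family)
  if (!is.numeric(Emax) || Emax <= 0)
    stop("`Emax` must be > 0", call. = FALSE)
  structure(list(family = family, Emax = Emax, mean = mean, sd = sd),
            class = "energy_sampler")
}

#' Draw energies from a sampler
#'
#' @param sampler An [energy_sampler()].
#' @param n Number of draws.
#' @param seed Optional integer seed (scoped).
#' @return Numeric vector of energies in `(0, Emax]`.
#' @export
sample_energy <- function(sampler, n = 1, seed = NULL) {
  stopifnot(inherits(sampler, "energy_sampler"))
  if (!is.null(seed)) withr::local_seed(seed)
  switch(sampler$family,
    uniform = sampler$Emax * (1 - stats::runif(n)),  # (0, Emax]
    truncnorm = {
      lo <- stats::pnorm(0, sampler$mean, sampler$sd)
      hi <- stats::pnorm(sampler$Emax, sampler$mean, sampler$sd)
      stats::qnorm(lo + (hi - lo) * (1 - stats::runif(n)),
                   sampler$mean, sampler$sd)
    })
}

# Window classification shared by sampling and curve code. delta is the
# maximum adjacent gap of the bound spectrum, so every E* in [E0, Ef] is
# guaranteed a nonempty window [E*, E* + delta].
classify_window <- function(eig, E_star) {
  if (eig$n_states == 0L)
    return(list(regime = "hyperarousal", idx = integer(0)))
  idx <- which(eig$energies >= E_star & eig$energies <= E_star + eig$delta)
  if (length(idx) > 0L) return(list(regime = "engaged", idx = idx))
  if (E_star > eig$energies[eig$n_states])
    list(regime = "hyperarousal", idx = integer(0))
  else
    list(regime = "hypoarousal", idx = integer(0))
}

#' Sample an arousal state (total-energy mechanism)
#'
#' Draws an arousal criterion `E*` from the classical sampling distribution,
#' forms the selection window `[E*, E* + delta]` (with `delta` the maximum
#' adjacent gap of the bound spectrum) and, when the window contains bound
#' eigen-energies, selects one uniformly; the corresponding eigenstate
#' becomes the decision state. An empty window below the ground energy is
#' hypoarousal; `E*` above the highest bound energy (including the case of
#' an empty bound spectrum) is hyperarousal. In both disengaged regimes no
#' state is produced and task performance is zero.
#'
#' @param eig A [bound_eigensystem()] (possibly empty).
#' @param sampler An [energy_sampler()].
#' @param seed Optional integer seed (scoped); fixes both the `E*` draw and
#'   the within-window selection.
#' @return Object of class `arousal_outcome`: `regime` (`"engaged"`,
#'   `"hypoarousal"` or `"hyperarousal"`), `E_star`, `selected_energy`
#'   (`NA` unless engaged) and `state` (a [quantum_state()] or `NULL`).
#' @export
sample_arousal_state <- function(eig, sampler, seed = NULL) {
  stopifnot(inherits(eig, "eigensystem"))
  if (!is.null(seed)) withr::local_seed(seed)
  E_star <- sample_energy(sampler, 1)
  cl <- classify_window(eig, E_star)
  if (cl$regime == "engaged") {
    pick <- cl$idx[sample.int(length(cl$idx), 1)]
    out <- list(regime = "engaged", E_star = E_star,
                selected_energy = eig$energies[pick],
                state = quantum_state(eig$states[, pick]))
  } else {
    out <- list(regime = cl$regime, E_star = E_star,
                selected_energy = NA_real_, state = NULL)
  }
  structure(out, class = "arousal_outcome")
}

#' @export
print.arousal_outcome <- function(x, ...) {
  cat(sprintf("<arousal_outcome> regime = %s, E* = %.6g", x$regime, x$E_star))
  if (x$regime == "engaged")
    cat(sprintf(", selected E = %.6g", x$selected_energy))
  cat("\n")
  invisible(x)
}

#' Performance curve container
#'
#' @param arousal Arousal grid (`E*` for the total-energy mechanism, `alpha`
#'   for the kinetic-scaling mechanism).
#' @param performance Performance value per grid point (drift rate or
#'   accuracy).
#' @param method `"A"` (eigenstate sampling) or `"B"` (kinetic scaling).
#' @param measure What `performance` holds (`"accuracy"` or `"drift"`).
#' @return Object of class `performance_curve`.
#' @export
performance_curve <- function(arousal, performance, method, measure) {
  stopifnot(length(arousal) == length(performance),
            all(is.finite(performance)))
  structure(list(arousal = arousal, performance = performance,
                 method = method, measure = measure),
            class = "performance_curve")
}

#' @export
print.performance_curve <- function(x, ...) {
  cat(sprintf(
    "<performance_curve> method %s, %d points, %s in [%.4g, %.4g]\n",
    x$method, length(x$arousal), x$measure,
    min(x$performance), max(x$performance)))
  invisible(x)
}

#' @export
as.data.frame.performance_curve <- function(x, ...) {
  data.frame(arousal = x$arousal, performance = x$performance)
}

#' Plot a performance curve
#'
#' @param x A [performance_curve()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.performance_curve <- function(x, ...) {
  xl <- if (x$method == "A") "arousal criterion E*" else "kinetic scale alpha"
  graphics::plot(x$arousal, x$performance, type = "l", xlab = xl,
                 ylab = x$measure, ...)
  invisible(x)
}

#' Performance versus arousal criterion (total-energy mechanism)
#'
#' Deterministic performance curve of the eigenstate-sampling mechanism over
#' a grid of arousal criteria `E*`. At each `E*` the selection window
#' `[E*, E* + delta]` is formed; when it contains bound eigen-energies the
#' reported performance is, by default, the expected DDM accuracy over a
#' uniform selection among them (each eigenstate's well masses give a drift
#' rate via `A = lam (P_C - P_W)`, and the drift gives an accuracy through
#' the closed-form choice probability). Outside the engaged regime
#' performance is exactly zero, producing the characteristic sharp drops at
#' the spectrum edges `E0` and `Ef`.
#'
#' @param spec A [well_spec()].
#' @param alpha Kinetic scale used to build the Hamiltonian.
#' @param E_star Grid of arousal criteria (all in `(0, Emax]` of the
#'   intended sampler).
#' @param ddm A [ddm_spec()] providing `d2`, `z`, `x0` and `lam` for the
#'   accuracy mapping.
#' @param n Grid resolution (default 512).
#' @param measure `"accuracy"` (default) or raw `"drift"`.
#' @return A [performance_curve()] with `method = "A"`; the per-point regime
#'   is attached as attribute `"regime"`.
#' @export
method_a_curve <- function(spec, alpha, E_star, ddm = ddm_spec(),
                           n = 512, measure = c("accuracy", "drift")) {
  measure <- match.arg(measure)
  stopifnot(inherits(spec, "well_spec"))
  grid <- grid_for_spec(spec, n)
  pot <- potential_on_grid(spec, grid)
  H <- assemble_hamiltonian(numerov_kinetic(grid), pot, alpha)
  eig <- bound_eigensystem(H)
  sets <- well_index_sets(spec, grid)
  perf <- numeric(length(E_star))
  regime <- character(length(E_star))
  for (i in seq_along(E_star)) {
    cl <- classify_window(eig, E_star[i])
    regime[i] <- cl$regime
    if (cl$regime != "engaged") next  # disengaged: performance exactly 0
    vals <- vapply(cl$idx, function(j) {
      st <- quantum_state(eig$states[, j])
      A <- drift_from_mie(mie_pair(st, sets), ddm$lam)
      if (measure == "drift") A
      else choice_probability(ddm_spec(A = A, d2 = ddm$d2, z = ddm$z,
                                       x0 = ddm$x0, T0 = ddm$T0,
                                       lam = ddm$lam))
    }, numeric(1))
    perf[i] <- mean(vals)  # expectation over the uniform window selection
  }
  out <- performance_curve(E_star, perf, method = "A", measure = measure)
  attr(out, "regime") <- regime
  attr(out, "eigensystem") <- eig
  out
}

#' Drift rate from kinetic-scaling arousal (time-evolution mechanism)
#'
#' The fully quantum pipeline: uniform initial state, unitary evolution for
#' the non-decision time `T0` under `H = alpha K + V`, well masses of the
#' evolved state, and the drift mapping `A = lam (P_C - P_W)`. Because
#' empirical non-decision times vary slightly across trials, the drift can
#' be averaged over `k_times` evolution times spanning `[T0 - delta_t,
#' T0 + delta_t]`; `k_times = 1` (or `delta_t = 0`) evaluates at `T0`
#' exactly.
#'
#' @param spec A [well_spec()].
#' @param alpha Nonnegative kinetic scale (the arousal parameter).
#' @param T0 Evolution time in seconds (the non-decision time).
#' @param lam Drift scaling.
#' @param delta_t Averaging half-width (default `0.05 * T0`). Clipped with a
#'   warning if it would produce negative times.
#' @param k_times Number of averaging times (default 11).
#' @param n Grid resolution (default 512).
#' @return The drift rate `A` (a single number).
#' @export
method_b_drift <- function(spec, alpha, T0, lam = 1,
                           delta_t = 0.05 * T0, k_times = 11, n = 512) {
  stopifnot(inherits(spec, "well_spec"))
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (T0 < 0) stop("`T0` must be >= 0", call. = FALSE)
  times <- evolution_times(T0, delta_t, k_times)
  grid <- grid_for_spec(spec, n)
  pot <- potential_on_grid(spec, grid)
  sets <- well_index_sets(spec, grid)
  he <- hamiltonian_eigen(assemble_hamiltonian(numerov_kinetic(grid), pot, alpha))
  psi0 <- uniform_initial_state(grid)
  drifts <- vapply(times, function(tt) {
    drift_from_mie(mie_pair(propagate(he, psi0, tt), sets), lam)
  }, numeric(1))
  mean(drifts)
}

evolution_times <- function(T0, delta_t, k_times) {
  if (delta_t < 0) stop("`delta_t` must be >= 0", call. = FALSE)
  if (k_times < 1L) stop("`k_times` must be >= 1", call. = FALSE)
  if (k_times == 1L || delta_t == 0) return(T0)
  lo <- T0 - delta_t
  if (lo < 0) {
    warning("averaging window extends below t = 0; clipped at 0")
    lo <- 0
  }
  seq(lo, T0 + delta_t, length.out = k_times)
}

#' Yerkes-Dodson scan (kinetic-scaling mechanism)
#'
#' Sweeps the kinetic scale `alpha` over a grid (default 50 points on
#' `[0, 200]`) and records the method-B drift rate at each point: the
#' performance-versus-arousal curve, which for landscapes with a deeper
#' correct well takes a smooth inverted-U shape with an interior optimum.
#'
#' @param spec A [well_spec()].
#' @param alpha Increasing nonnegative grid of kinetic scales.
#' @param T0 Evolution time (seconds).
#' @param lam Drift scaling.
#' @param delta_t,k_times Averaging window, as in [method_b_drift()].
#' @param n Grid resolution (default 512).
#' @return A [performance_curve()] with `method = "B"`, `measure = "drift"`.
#' @export
yerkes_dodson_scan <- function(spec, alpha = seq(0, 200, length.out = 50),
                               T0 = 0.3, lam = 1, delta_t = 0.05 * T0,
                               k_times = 11, n = 512) {
  if (any(alpha < 0) || any(diff(alpha) <= 0))
    stop("`alpha` must be nonnegative and increasing", call. = FALSE)
  A <- vapply(alpha, function(a)
    method_b_drift(spec, a, T0, lam, delta_t, k_times, n), numeric(1))
  performance_curve(alpha, A, method = "B", measure = "drift")
}
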