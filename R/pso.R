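# Seeded global-best particle swarm with box constraints.
#
# Standard constriction configuration (inertia 0.7298, acceleration
# coefficients 1.49618), velocity clamped to half the box range, positions
# clipped to the bounds with the offending velocity component zeroed.
# Stopping follows the conventions of the common particle-swarm
# implementations: a maximum iteration count, a windowed stall criterion
# (the swarm best improved by less than a relative `reltol` over the last
# `stall_iter` iterations) and an optional objective limit.

pso_minimize <- function(fn, lower, upper, n_particles = 60, max_iter = 300,
                         seed = NULL, inertia = 0.7298, c_cog = 1.49618,
                         c_soc = 1.49618, stall_iter = 20, reltol = 1e-6,
                         objective_limit = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  if (!is.null(seed)) withr::local_seed(seed)
  rng <- upper - lower
  X <- matrix(stats::runif(n_particles * d), n_particles, d)
  X <- sweep(sweep(X, 2, rng, "*"), 2, lower, "+")
  Vel <- matrix(stats::runif(n_particles * d, -0.5, 0.5), n_particles, d)
  Vel <- sweep(Vel, 2, rng, "*")
  vmax <- 0.5 * rng

  f <- apply(X, 1, fn)
  pbest_x <- X
  pbest_f <- f
  g <- which.min(f)
  gbest_x <- X[g, ]
  gbest_f <- f[g]
  trace <- numeric(max_iter + 1L)
  trace[1L] <- gbest_f
  iters <- 0L
  reason <- "max_iter"

  for (it in seq_len(max_iter)) {
    iters <- it
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    Vel <- inertia * Vel +
      c_cog * r1 * (pbest_x - X) +
      c_soc * r2 * sweep(-X, 2, gbest_x, "+")
    Vel <- pmin(pmax(Vel, matrix(-vmax, n_particles, d, byrow = TRUE)),
                matrix(vmax, n_particles, d, byrow = TRUE))
    X <- X + Vel
    # clip to bounds, zero the velocity component that hit the wall
    for (j in seq_len(d)) {
      hit_lo <- X[, j] < lower[j]
      hit_hi <- X[, j] > upper[j]
      X[hit_lo, j] <- lower[j]
      X[hit_hi, j] <- upper[j]
      Vel[hit_lo | hit_hi, j] <- 0
    }
    f <- apply(X, 1, fn)
    imp <- f < pbest_f
    pbest_x[imp, ] <- X[imp, , drop = FALSE]
    pbest_f[imp] <- f[imp]
    g <- which.min(pbest_f)
    if (pbest_f[g] < gbest_f) {
      gbest_f <- pbest_f[g]
      gbest_x <- pbest_x[g, ]
    }
    trace[it + 1L] <- gbest_f
    if (!is.null(objective_limit) && gbest_f <= objective_limit) {
      reason <- "objective_limit"
      break
    }
    if (it > stall_iter) {
      ref <- trace[it + 1L - stall_iter]
      if ((ref - gbest_f) / max(abs(ref), 1e-30) < reltol) {
        reason <- "stall"
        break
      }
    }
  }
  list(par = gbest_x, value = gbest_f, trace = trace[seq_len(iters + 1L)],
       iterations = iters, reason = reason)
}
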