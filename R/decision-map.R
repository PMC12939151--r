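#' Mean integration efficiency over a well
#'
#' The probability mass of a quantum state inside one well region: the sum
#' of squared amplitude moduli over the well's grid indices. Computed as a
#' discrete sum, consistent with the unit-vector normalization of the
#' discretized state (a trapezoid integral would differ only by O(dx) edge
#' terms).
#'
#' @param state A [quantum_state()].
#' @param indices Integer index set of the well's grid points (see
#'   [well_index_sets()]).
#' @return A probability in `[0, 1]`.
#' @export
mie <- function(state, indices) {
  stopifnot(inherits(state, "quantum_state"))
  if (length(indices) == 0L)
    stop("resolution error: empty well index set", call. = FALSE)
  if (any(indices < 1L | indices > length(state$amplitudes)))
    stop("well indices out of range", call. = FALSE)
  sum(Mod(state$amplitudes[indices])^2)
}

#' Correct/incorrect MIE pair
#'
#' @param state A [quantum_state()].
#' @param sets Index sets from [well_index_sets()].
#' @return List with `P_C` (correct-well mass) and `P_W` (incorrect-well
#'   mass). The two need not sum to one: mass may sit outside both wells.
#' @export
mie_pair <- function(state, sets) {
  list(P_C = mie(state, sets$correct), P_W = mie(state, sets$incorrect))
}

#' Drift rate from a MIE pair
#'
#' Maps the two well occupancies to the DDM mean drift rate,
#' `A = lam * (P_C - P_W)`: evidence accumulates toward the correct boundary
#' at a rate proportional to how much more probability mass the quantum
#' state holds in the correct well than in the incorrect one.
#'
#' @param pair A list with `P_C`, `P_W` (see [mie_pair()]), or a numeric
#'   `P_C` when `P_W` is given separately.
#' @param lam Positive scaling parameter, chosen in practice to match the
#'   maximum attainable drift magnitude.
#' @param P_W Incorrect-well mass when `pair` is numeric.
#' @return The drift rate `A`, with `|A| <= lam`.
#' @export
drift_from_mie <- function(pair, lam = 1, P_W = NULL) {
  if (is.numeric(pair) && !is.null(P_W)) pair <- list(P_C = pair, P_W = P_W)
  stopifnot(is.list(pair), is.numeric(pair$P_C), is.numeric(pair$P_W))
  lam * (pair$P_C - pair$P_W)
}

#' Drift-diffusion model specification
#'
#' Parameters of the evidence-accumulation layer: `dx = A dt + sqrt(d2) dW`
#' with absorbing boundaries at `+z` (correct) and `-z` (incorrect), start
#' `x0`, non-decision time `T0` (seconds) and drift scaling `lam`. The
#' quantum layer supplies only `A`; `d2` and `z` are free DDM-layer
#' parameters.
#'
#' @param A Mean drift rate.
#' @param d2 Diffusion variance (> 0), default 1.
#' @param z Boundary half-separation (> 0), default 1.
#' @param x0 Start point, `|x0| < z`, default 0 (unbiased).
#' @param T0 Non-decision time in seconds (>= 0), default 0.3.
#' @param lam Drift scaling (> 0), default 1.
#' @return Object of class `ddm_spec`.
#' @export
ddm_spec <- function(A = 0, d2 = 1, z = 1, x0 = 0, T0 = 0.3, lam = 1) {
  if (!is.finite(A)) stop("`A` must be finite", call. = FALSE)
  if (d2 <= 0) stop("`d2` must be > 0", call. = FALSE)
  if (z <= 0) stop("`z` must be > 0", call. = FALSE)
  if (abs(x0) >= z) stop("`x0` must satisfy |x0| < z", call. = FALSE)
  if (T0 < 0) stop("`T0` must be >= 0", call. = FALSE)
  if (lam <= 0) stop("`lam` must be > 0", call. = FALSE)
  structure(list(A = A, d2 = d2, z = z, x0 = x0, T0 = T0, lam = lam),
            class = "ddm_spec")
}

#' @export
print.ddm_spec <- function(x, ...) {
  cat(sprintf(
    "<ddm_spec> A = %g, d2 = %g, z = %g, x0 = %g, T0 = %g s, lam = %g\n",
    x$A, x$d2, x$z, x$x0, x$T0, x$lam))
  invisible(x)
}

#' Choice probability (upper-boundary absorption)
#'
#' Closed-form Wiener absorption probability of hitting the correct (`+z`)
#' boundary before `-z`. For an unbiased start this is
#' `1 / (1 + exp(-2 A z / d2))`.
#'
#' @param spec A [ddm_spec()].
#' @return Probability of a correct response.
#' @export
choice_probability <- function(spec) {
  stopifnot(inherits(spec, "ddm_spec"))
  u <- 2 * spec$A / spec$d2
  if (abs(u * spec$z) < 1e-9) return((spec$x0 + spec$z) / (2 * spec$z))
  # scale-function ratio, written via expm1 for stability at small |u|
  expm1(-u * (spec$x0 + spec$z)) / expm1(-u * 2 * spec$z)
}

#' Mean decision time
#'
#' Closed-form expected first-passage time to either boundary. For an
#' unbiased start this is `(z/A) tanh(A z / d2)`, with the drift-free limit
#' `z^2 / d2`; the general-start form is used otherwise. The expected
#' response time is `T0 + DT`.
#'
#' @param spec A [ddm_spec()].
#' @return Named list with `mean_dt` (seconds) and `mean_rt = T0 + mean_dt`.
#' @export
mean_decision_time <- function(spec) {
  stopifnot(inherits(spec, "ddm_spec"))
  z <- spec$z; A <- spec$A; d2 <- spec$d2; y <- spec$x0 + z; a <- 2 * z
  if (abs(2 * A * z / d2) < 1e-7) {
    dt <- (z^2 - spec$x0^2) / d2
  } else {
    u <- 2 * A / d2
    dt <- (a / A) * expm1(-u * y) / expm1(-u * a) - y / A
  }
  list(mean_dt = dt, mean_rt = spec$T0 + dt)
}

# Standardized two-boundary first-passage density at the *lower* boundary
# for unit diffusion, boundary separation `a`, relative start `w` in (0,1),
# drift `v`, evaluated at times `t`. Small-time and large-time series with
# an automatic switch at the standard crossover of the normalized time
# u = t / a^2 (both series agree to ~1e-12 around the switch point).
fpt_density_lower <- function(t, v, a, w, u_switch = 0.25) {
  u <- t / a^2
  pref <- exp(-v * a * w - v^2 * t / 2) / a^2
  f0 <- numeric(length(t))
  small <- u > 0 & u <= u_switch
  large <- u > u_switch
  if (any(small)) {
    us <- u[small]
    k <- -7:7                                  # |terms| < 1e-16 for u <= 0.25
    wk <- outer(rep(1, length(us)), w + 2 * k)
    s <- rowSums(wk * exp(-wk^2 / (2 * us)))
    f0[small] <- s / sqrt(2 * pi * us^3)
  }
  if (any(large)) {
    ul <- u[large]
    k <- 1:40                                  # exp(-k^2 pi^2 u / 2) underflows fast
    ek <- exp(outer(ul, -k^2 * pi^2 / 2))
    f0[large] <- pi * as.vector(ek %*% (k * sin(k * pi * w)))
  }
  pref * f0
}

#' First-passage (decision-time) densities at the two boundaries
#'
#' Defective first-passage time densities of the decision variable at the
#' correct (`+z`, "upper") and incorrect (`-z`, "lower") boundaries, on a
#' grid of decision times. Each density integrates to the probability of
#' absorption at its boundary. Densities are computed by the classical
#' small-time/large-time series expansions with an automatic switch based on
#' the normalized time `t d2 / (2z)^2`.
#'
#' @param spec A [ddm_spec()].
#' @param t Strictly increasing grid of positive decision times (seconds,
#'   decision time only; add `T0` for response times).
#' @return Object of class `rt_density`: list with `t`, `upper`, `lower`
#'   density vectors and the absorption probabilities `p_upper`, `p_lower`.
#' @export
rt_density <- function(spec, t) {
  stopifnot(inherits(spec, "ddm_spec"))
  if (any(t <= 0) || any(diff(t) <= 0))
    stop("`t` must be positive and strictly increasing", call. = FALSE)
  s <- sqrt(spec$d2)
  v <- spec$A / s
  a <- 2 * spec$z / s
  w <- (spec$x0 + spec$z) / (2 * spec$z)
  lower <- fpt_density_lower(t, v, a, w)
  upper <- fpt_density_lower(t, -v, a, 1 - w)
  p_up <- choice_probability(spec)
  structure(list(t = t, upper = upper, lower = lower,
                 p_upper = p_up, p_lower = 1 - p_up),
            class = "rt_density")
}

#' Simulate decision paths (Euler-Maruyama)
#'
#' Monte-Carlo oracle for the closed-form DDM quantities: simulates
#' `n_paths` trajectories of `dx = A dt + sqrt(d2) dW` to absorption at
#' `+z`/`-z`. Deterministic under a fixed seed.
#'
#' @param spec A [ddm_spec()].
#' @param n_paths Number of trajectories.
#' @param dt Time step; a warning is issued when `dt > z^2 / (100 d2)`
#'   (discretization bias becomes visible).
#' @param seed Optional integer seed (scoped).
#' @param max_time Simulation horizon in seconds; paths not absorbed by then
#'   get `choice = 0`, `dt = NA`.
#' @return Data frame with per-path `choice` (+1 upper, -1 lower, 0
#'   unabsorbed) and decision time `dt`.
#' @export
simulate_paths <- function(spec, n_paths, dt = 1e-3, seed = NULL,
                           max_time = 100 * spec$z^2 / spec$d2) {
  stopifnot(inherits(spec, "ddm_spec"))
  if (n_paths < 1L) stop("`n_paths` must be >= 1", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (dt > spec$z^2 / (100 * spec$d2))
    warning("`dt` is large relative to z^2/d2; first-passage times will be biased")
  if (!is.null(seed)) withr::local_seed(seed)
  res <- ddm_simulate_cpp(spec$A, spec$d2, spec$z, spec$x0,
                          as.integer(n_paths), dt,
                          as.integer(ceiling(max_time / dt)))
  data.frame(choice = res$choice, dt = res$dt)
}

#' Full DDM prediction
#'
#' Bundles the closed-form choice probability, mean decision/response time
#' and the per-boundary decision-time densities into one object.
#'
#' @param spec A [ddm_spec()].
#' @param t Decision-time grid for the densities (default 512 points up to
#'   8 mean decision times).
#' @return Object of class `ddm_prediction` with fields `p_correct`,
#'   `mean_dt`, `mean_rt`, and `density` (an [rt_density()]).
#' @export
ddm_predict <- function(spec, t = NULL) {
  stopifnot(inherits(spec, "ddm_spec"))
  mdt <- mean_decision_time(spec)
  if (is.null(t))
    t <- seq(1e-4, 8 * max(mdt$mean_dt, spec$z^2 / spec$d2), length.out = 512)
  structure(list(p_correct = choice_probability(spec),
                 mean_dt = mdt$mean_dt, mean_rt = mdt$mean_rt,
                 density = rt_density(spec, t), spec = spec),
            class = "ddm_prediction")
}

#' @export
print.ddm_prediction <- function(x, ...) {
  cat(sprintf(
    "<ddm_prediction> p(correct) = %.4f, mean DT = %.4f s, mean RT = %.4f s\n",
    x$p_correct, x$mean_dt, x$mean_rt))
  invisible(x)
}

#' Export a DDM prediction as delimited text
#'
#' Long-format table with columns `(p_correct, mean_rt, boundary, t,
#' density)`.
#'
#' @param pred A [ddm_predict()] result.
#' @param path Output file.
#' @param header Optional comment lines (prefixed `#`) to prepend.
#' @return Invisibly, `path`.
#' @export
export_prediction <- function(pred, path, header = NULL) {
  stopifnot(inherits(pred, "ddm_prediction"))
  d <- pred$density
  tab <- data.frame(
    p_correct = pred$p_correct, mean_rt = pred$mean_rt,
    boundary = rep(c("upper", "lower"), each = length(d$t)),
    t = c(d$t, d$t), density = c(d$upper, d$lower))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
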