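#' Parameter-sharing scheme for drift-rate fitting
#'
#' Defines which landscape/DDM parameters are shared, per-coherence or
#' per-participant when fitting a participant-by-coherence table of mean
#' drift rates. The barrier energy is fixed (`Eb = 1`, setting the energy
#' scale) and the middle-region width is a fixed constant; six parameters
#' are shared across the whole table (`EwL`, `Em`, `w`, `e`, `T0`, `lam`),
#' the correct-well bottom energy `EwR` varies per coherence level (the
#' stimulus defines the landscape) and the kinetic scale `alpha` varies per
#' participant (individual differences are arousal differences). The free
#' parameter count is therefore `6 + C + P` - for 17 participants and 5
#' coherence levels, 28 parameters in place of the 85 table cells.
#'
#' @param P Number of participants.
#' @param C Number of coherence levels.
#' @param coherence Coherence labels in percent (length `C`); default the
#'   classic 0, 4, 8, 16, 32 when `C = 5`.
#' @param Eb Fixed barrier energy (default 1).
#' @param m_gap Fixed middle-region width (default 0.6).
#' @param xbL Fixed left box boundary (default 0).
#' @param correct_side Which well is correct in every condition (default
#'   `"right"`).
#' @param bounds Named list of `c(lower, upper)` bounds for `EwL`, `Em`,
#'   `w`, `e`, `T0`, `lam`, `EwR`, `alpha`; see [default_bounds()].
#' @return Object of class `param_scheme`.
#' @export
param_scheme <- function(P = 17, C = 5,
                         coherence = if (C == 5) c(0, 4, 8, 16, 32)
                                     else seq_len(C),
                         Eb = 1, m_gap = 0.6, xbL = 0,
                         correct_side = "right",
                         bounds = default_bounds(Eb)) {
  P <- as.integer(P); C <- as.integer(C)
  stopifnot(P >= 1L, C >= 1L, length(coherence) == C)
  need <- c("EwL", "Em", "w", "e", "T0", "lam", "EwR", "alpha")
  if (!all(need %in% names(bounds)))
    stop("`bounds` must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (nm in need)
    if (length(bounds[[nm]]) != 2L || diff(bounds[[nm]]) <= 0)
      stop(sprintf("bound for `%s` must be c(lower, upper)", nm),
           call. = FALSE)
  structure(list(P = P, C = C, coherence = coherence, Eb = Eb,
                 m_gap = m_gap, xbL = xbL, correct_side = correct_side,
                 bounds = bounds),
            class = "param_scheme")
}

#' Default fitting bounds
#'
#' Energies in `[0, Eb)`, widths in `(0, 5]` (edge width may be 0),
#' non-decision time in the conventional 0.2-0.5 s range, drift scaling in
#' `(0, 10]` and kinetic scale in `(0, 200]` (the arousal scan interval).
#'
#' @param Eb Barrier energy.
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function(Eb = 1) {
  eps <- 1e-3
  list(EwL = c(0, Eb - eps), Em = c(0, Eb), w = c(eps, 5), e = c(0, 5),
       T0 = c(0.2, 0.5), lam = c(eps, 10), EwR = c(0, Eb - eps),
       alpha = c(eps, 200))
}

#' @export
print.param_scheme <- function(x, ...) {
  cat(sprintf(
    "<param_scheme> P = %d participants x C = %d coherence levels (%s%%)\n",
    x$P, x$C, paste(x$coherence, collapse = ", ")))
  cat(sprintf(
    "  fixed: Eb = %g, m_gap = %g; free parameters: 6 shared + %d EwR + %d alpha = %d\n",
    x$Eb, x$m_gap, x$C, x$P, n_free(x)))
  invisible(x)
}

#' Number of free parameters in a scheme
#'
#' @param scheme A [param_scheme()].
#' @return `6 + C + P`.
#' @export
n_free <- function(scheme) {
  stopifnot(inherits(scheme, "param_scheme"))
  6L + scheme$C + scheme$P
}

param_names <- function(scheme) {
  c("EwL", "Em", "w", "e", "T0", "lam",
    paste0("EwR_", seq_len(scheme$C)),
    paste0("alpha_", seq_len(scheme$P)))
}

#' Pack parameters into a flat vector
#'
#' Fixed packing order: `EwL, Em, w, e, T0, lam, EwR[1..C], alpha[1..P]`.
#'
#' @param params List with scalars `EwL`, `Em`, `w`, `e`, `T0`, `lam` and
#'   vectors `EwR` (length `C`), `alpha` (length `P`).
#' @param scheme A [param_scheme()].
#' @return Named numeric vector of length `6 + C + P`.
#' @export
pack_params <- function(params, scheme) {
  stopifnot(inherits(scheme, "param_scheme"))
  if (length(params$EwR) != scheme$C)
    stop("`EwR` must have length C", call. = FALSE)
  if (length(params$alpha) != scheme$P)
    stop("`alpha` must have length P", call. = FALSE)
  theta <- c(params$EwL, params$Em, params$w, params$e, params$T0,
             params$lam, params$EwR, params$alpha)
  names(theta) <- param_names(scheme)
  theta
}

#' Unpack a flat parameter vector
#'
#' Inverse of [pack_params()]: `unpack_params(pack_params(x)) == x`.
#'
#' @param theta Numeric vector of length `6 + C + P`.
#' @param scheme A [param_scheme()].
#' @return List with `EwL`, `Em`, `w`, `e`, `T0`, `lam`, `EwR`, `alpha`.
#' @export
unpack_params <- function(theta, scheme) {
  stopifnot(inherits(scheme, "param_scheme"))
  if (length(theta) != n_free(scheme))
    stop(sprintf("parameter vector must have length %d, got %d",
                 n_free(scheme), length(theta)), call. = FALSE)
  list(EwL = theta[[1]], Em = theta[[2]], w = theta[[3]], e = theta[[4]],
       T0 = theta[[5]], lam = theta[[6]],
       EwR = unname(theta[7:(6 + scheme$C)]),
       alpha = unname(theta[(7 + scheme$C):(6 + scheme$C + scheme$P)]))
}

scheme_bounds <- function(scheme) {
  b <- scheme$bounds
  lower <- c(b$EwL[1], b$Em[1], b$w[1], b$e[1], b$T0[1], b$lam[1],
             rep(b$EwR[1], scheme$C), rep(b$alpha[1], scheme$P))
  upper <- c(b$EwL[2], b$Em[2], b$w[2], b$e[2], b$T0[2], b$lam[2],
             rep(b$EwR[2], scheme$C), rep(b$alpha[2], scheme$P))
  names(lower) <- names(upper) <- param_names(scheme)
  list(lower = lower, upper = upper)
}

#' Participant-by-coherence drift-rate table
#'
#' @param values `P x C` numeric matrix of mean drift rates.
#' @param coherence Coherence labels (column order).
#' @param participants Participant ids (row order; default `p1..pP`).
#' @return Object of class `drift_table`.
#' @export
drift_table <- function(values, coherence = seq_len(ncol(values)),
                        participants = paste0("p", seq_len(nrow(values)))) {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)), length(coherence) == ncol(values),
            length(participants) == nrow(values))
  dimnames(values) <- list(participants, paste0("coh_", coherence))
  structure(list(values = values, coherence = coherence,
                 participants = participants),
            class = "drift_table")
}

#' @export
print.drift_table <- function(x, ...) {
  cat(sprintf("<drift_table> %d participants x %d coherence levels\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Read / write a drift table as CSV
#'
#' Comma-separated with a header row of coherence labels and one row per
#' participant; lines starting `#` are metadata and ignored on read.
#'
#' @param path File path.
#' @param table A [drift_table()] (for writing).
#' @param header Optional `#` comment lines to prepend when writing.
#' @return `read_drift_table`: a [drift_table()]. `write_drift_table`:
#'   invisibly, `path`.
#' @export
read_drift_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  participants <- as.character(d[[1]])
  vals <- as.matrix(d[, -1, drop = FALSE])
  coh <- as.numeric(sub("^coh_", "", colnames(vals)))
  drift_table(unname(vals), coh, participants)
}

#' @rdname read_drift_table
#' @export
write_drift_table <- function(table, path, header = NULL) {
  stopifnot(inherits(table, "drift_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  d <- data.frame(participant = table$participants, table$values,
                  check.names = FALSE)
  utils::write.table(d, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# well_spec for coherence level c under a scheme, or NULL when the
# parameter combination violates the landscape invariants (the objective
# converts NULL into a finite penalty so swarm trajectories stay alive).
spec_for_level <- function(p, EwR_c, scheme) {
  tryCatch(
    well_spec(Eb = scheme$Eb, EwL = p$EwL, EwR = EwR_c, Em = p$Em,
              w = p$w, e = p$e, m_gap = scheme$m_gap, xbL = scheme$xbL,
              correct_side = scheme$correct_side),
    error = function(e) NULL)
}

# Fast path shared by forward_model / sse_objective: batched C++ kernel.
# Returns the P x C drift matrix, or NULL when any landscape is infeasible
# or too narrow for the grid.
forward_matrix <- function(theta, scheme, grid_n) {
  p <- unpack_params(theta, scheme)
  spec1 <- spec_for_level(p, p$EwR[1], scheme)
  if (is.null(spec1)) return(NULL)
  grid <- grid_for_spec(spec1, grid_n)   # geometry is shared across levels
  sets <- tryCatch(well_index_sets(spec1, grid), error = function(e) NULL)
  if (is.null(sets)) return(NULL)
  V <- matrix(0, grid$n, scheme$C)
  for (cc in seq_len(scheme$C)) {
    spec_c <- spec_for_level(p, p$EwR[cc], scheme)
    if (is.null(spec_c)) return(NULL)
    V[, cc] <- potential_on_grid(spec_c, grid)$values
  }
  drift_kernel_cpp(numerov_k0(grid$n), grid$dx, V,
                   sets$left - 1L, sets$right - 1L,
                   p$alpha, p$T0, p$lam,
                   scheme$correct_side == "right")
}

#' Forward model: drift table from packed parameters
#'
#' Builds the per-coherence landscape from the shared parameters plus
#' `EwR[c]`, evolves the uniform state for `T0` under each participant's
#' kinetic scale `alpha[p]`, and maps the evolved well masses to a drift
#' rate. Within a coherence level the landscape is identical across
#' participants. The objective evaluates the drift at the single time `T0`;
#' the scan-time averaging window is a presentation device, not part of the
#' fit.
#'
#' @param theta Packed parameter vector (see [pack_params()]).
#' @param scheme A [param_scheme()].
#' @param grid_n Grid resolution (default 256 for fitting speed; re-evaluate
#'   at 512 to confirm stability).
#' @return A [drift_table()].
#' @export
forward_model <- function(theta, scheme, grid_n = 256) {
  M <- forward_matrix(theta, scheme, grid_n)
  if (is.null(M))
    stop("parameter vector yields an infeasible landscape", call. = FALSE)
  drift_table(M, scheme$coherence)
}

#' Squared-error objective
#'
#' `sum((forward_model(theta) - target)^2)`; infeasible parameter vectors
#' receive a large finite penalty (1e6) rather than an exception, keeping
#' global-search trajectories alive.
#'
#' @param theta Packed parameter vector.
#' @param target Target [drift_table()].
#' @param scheme A [param_scheme()].
#' @param grid_n Grid resolution.
#' @return Nonnegative scalar; zero iff the prediction matches exactly.
#' @export
sse_objective <- function(theta, target, scheme, grid_n = 256) {
  stopifnot(inherits(target, "drift_table"))
  if (nrow(target$values) != scheme$P || ncol(target$values) != scheme$C)
    stop("target table dimensions do not match the scheme", call. = FALSE)
  M <- forward_matrix(theta, scheme, grid_n)
  if (is.null(M)) return(1e6)
  sum((M - target$values)^2)
}

#' Generate a synthetic drift table
#'
#' Forward-model output plus independent Gaussian noise: the synthetic
#' stand-in for an empirically fitted participant-by-coherence drift-rate
#' table, used for parameter-recovery studies.
#'
#' @param theta Packed generator parameters.
#' @param scheme A [param_scheme()].
#' @param noise_sd Noise standard deviation (>= 0; 0 gives the exact
#'   forward model).
#' @param seed Optional integer seed (scoped).
#' @param grid_n Grid resolution.
#' @return A [drift_table()]; the generator settings are attached as
#'   attributes `"theta"` and `"noise_sd"`.
#' @export
generate_synthetic_table <- function(theta, scheme, noise_sd = 0,
                                     seed = NULL, grid_n = 256) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  tab <- forward_model(theta, scheme, grid_n)
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    tab$values <- tab$values +
      matrix(stats::rnorm(length(tab$values), 0, noise_sd),
             nrow(tab$values))
  }
  attr(tab, "theta") <- theta
  attr(tab, "noise_sd") <- noise_sd
  tab
}

#' Fit the parameter-sharing model to a drift table
#'
#' Seeded, bounded global search: restarted particle swarm on the packed
#' parameter space, minimizing the squared error between predicted and
#' target drift rates, optionally followed by a bounded quasi-Newton polish
#' (`L-BFGS-B`) from the best swarm point. Each restart uses an independent
#' sub-seed derived from `seed`; when `objective_limit` is reached the
#' remaining restarts are skipped.
#'
#' @param target Target [drift_table()].
#' @param scheme A [param_scheme()] matching the table dimensions.
#' @param particles,iters,restarts Swarm size, maximum iterations per
#'   restart, and number of restarts (defaults 60, 300, 3).
#' @param grid_n Grid resolution during search (default 256).
#' @param seed Integer seed controlling the whole search.
#' @param polish Run the quasi-Newton refinement after each restart
#'   (default `TRUE`).
#' @param stall_iter,reltol Stall-based stopping: a restart ends after
#'   `stall_iter` iterations without relative improvement above `reltol`.
#' @param objective_limit Stop as soon as the objective falls to or below
#'   this value (default `NULL`: never).
#' @return Object of class `fit_result`: `par` (named packed vector),
#'   `params` (unpacked), `sse`, `trace` (objective per iteration, per
#'   restart), `predicted` drift table, `seed`, `scheme`, and the per-
#'   restart summaries.
#' @export
fit_drift_table <- function(target, scheme, particles = 60, iters = 300,
                            restarts = 3, grid_n = 256, seed = 1,
                            polish = TRUE, stall_iter = 20, reltol = 1e-6,
                            objective_limit = NULL) {
  stopifnot(inherits(target, "drift_table"), inherits(scheme, "param_scheme"))
  b <- scheme_bounds(scheme)
  if (any(!is.finite(b$lower)) || any(!is.finite(b$upper)))
    stop("all parameters must have finite bounds", call. = FALSE)
  obj <- function(theta) sse_objective(theta, target, scheme, grid_n)
  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, restarts))
  best <- NULL
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    run <- pso_minimize(obj, b$lower, b$upper,
                        n_particles = particles, max_iter = iters,
                        seed = sub_seeds[r], stall_iter = stall_iter,
                        reltol = reltol, objective_limit = objective_limit)
    if (polish) {
      # finite-difference steps scaled to each parameter's range (the
      # optim default of 1e-3 is far too coarse near the optimum)
      pol <- stats::optim(run$par, obj, method = "L-BFGS-B",
                          lower = b$lower, upper = b$upper,
                          control = list(maxit = 200, factr = 1e4,
                                         ndeps = pmax(1e-8,
                                           1e-7 * (b$upper - b$lower))))
      if (pol$value < run$value) {
        run$par <- pol$par
        run$value <- pol$value
        run$trace <- c(run$trace, pol$value)
      }
    }
    runs[[r]] <- run
    if (is.null(best) || run$value < best$value) best <- run
    if (!is.null(objective_limit) && best$value <= objective_limit) break
  }
  runs <- runs[!vapply(runs, is.null, logical(1))]
  par <- best$par
  names(par) <- param_names(scheme)
  structure(list(par = par, params = unpack_params(par, scheme),
                 sse = best$value, trace = lapply(runs, `[[`, "trace"),
                 predicted = forward_model(par, scheme, grid_n),
                 seed = seed, grid_n = grid_n, scheme = scheme,
                 restarts = length(runs),
                 stop_reasons = vapply(runs, `[[`, character(1), "reason")),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> SSE = %.6g after %d restart(s) (%s)\n",
              x$sse, x$restarts, paste(x$stop_reasons, collapse = ", ")))
  cat(sprintf("  seed = %d, grid_n = %d, %d free parameters\n",
              x$seed, x$grid_n, length(x$par)))
  cat(sprintf("  EwR = %s\n",
              paste(sprintf("%.4f", x$params$EwR), collapse = ", ")))
  cat(sprintf("  alpha = %s\n",
              paste(sprintf("%.3f", x$params$alpha), collapse = ", ")))
  invisible(x)
}

#' Export a fit result as JSON
#'
#' @param fit A [fit_result][fit_drift_table()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(sse = fit$sse, seed = fit$seed, grid_n = fit$grid_n,
         restarts = fit$restarts, stop_reasons = fit$stop_reasons,
         par = as.list(fit$par),
         predicted = fit$predicted$values,
         coherence = fit$scheme$coherence),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
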