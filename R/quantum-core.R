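# Cache for the unit-spacing Numerov kinetic matrix, keyed by n. The
# physical operator only rescales by 1/dx^2, so one matrix per grid size
# serves every landscape and every kinetic scale.
.k0_cache <- new.env(parent = emptyenv())

numerov_k0 <- function(n) {
  key <- as.character(n)
  if (!is.null(.k0_cache[[key]])) return(.k0_cache[[key]])
  A <- diag(-2, n)
  A[cbind(1:(n - 1L), 2:n)] <- 1
  A[cbind(2:n, 1:(n - 1L))] <- 1
  B <- diag(10 / 12, n)
  B[cbind(1:(n - 1L), 2:n)] <- 1 / 12
  B[cbind(2:n, 1:(n - 1L))] <- 1 / 12
  K <- -0.5 * solve(B, A)     # tridiagonal solve, never an explicit inverse
  K <- (K + t(K)) / 2         # absorb round-off; A, B commute so K is symmetric
  .k0_cache[[key]] <- K
  K
}

#' Matrix Numerov kinetic operator
#'
#' Builds the discretized kinetic-energy matrix `K = -(1/2) B^{-1} A` with
#' `A = dx^{-2} tridiag(1, -2, 1)` and `B = tridiag(1, 10, 1)/12`, the
#' Matrix Numerov discretization of `-(1/2) d^2/dx^2` (units `hbar = m = 1`),
#' accurate to fourth order in `dx`. `A` and `B` are polynomials in the same
#' shift matrix, so they commute and `K` is exactly symmetric; it is
#' symmetrized after the tridiagonal solve to absorb round-off. The implied
#' Dirichlet walls sit one spacing outside the grid (see [spatial_grid()]).
#'
#' @param grid A [spatial_grid()].
#' @return Dense symmetric `n x n` matrix.
#' @references Pillai, M., Goglio, J., & Walker, T. G. (2012). Matrix
#'   Numerov method for solving Schroedinger's equation. American Journal of
#'   Physics, 80(11), 1017-1019.
#' @export
numerov_kinetic <- function(grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  if (grid$dx <= 0) stop("degenerate grid: dx must be > 0", call. = FALSE)
  numerov_k0(grid$n) / grid$dx^2
}

#' Assemble the discretized Hamiltonian
#'
#' `H = alpha * K + diag(V)`: kinetic term scaled by the dimensionless
#' arousal parameter `alpha`, plus the diagonal potential.
#'
#' @param K Kinetic matrix from [numerov_kinetic()].
#' @param potential A [potential_on_grid()] result.
#' @param alpha Nonnegative kinetic scale.
#' @return An object of class `hamiltonian`: list with the symmetric
#'   `matrix`, `alpha`, and the `potential` (with its grid) it was built
#'   from.
#' @export
assemble_hamiltonian <- function(K, potential, alpha) {
  stopifnot(inherits(potential, "potential_vector"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("`alpha` must be a single nonnegative number", call. = FALSE)
  n <- length(potential$values)
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
    stop("dimension mismatch between kinetic matrix and potential", call. = FALSE)
  H <- alpha * K
  diag(H) <- diag(H) + potential$values
  structure(list(matrix = H, alpha = alpha, potential = potential,
                 grid = potential$grid),
            class = "hamiltonian")
}

#' @export
print.hamiltonian <- function(x, ...) {
  cat(sprintf("<hamiltonian> n = %d, alpha = %g\n", nrow(x$matrix), x$alpha))
  invisible(x)
}

as_h_matrix <- function(H) {
  if (inherits(H, "hamiltonian")) H$matrix
  else if (is.matrix(H)) H
  else stop("`H` must be a hamiltonian or a matrix", call. = FALSE)
}

#' Full spectral decomposition of a Hamiltonian
#'
#' Eigendecomposition of the (symmetric) Hamiltonian with eigenvalues in
#' ascending order, reused by [propagate()] across evolution times. Each
#' eigenvector's first significant component is made positive so the
#' decomposition is deterministic.
#'
#' @param H A `hamiltonian` or symmetric matrix.
#' @return Object of class `hamiltonian_eigen` with `values` (ascending) and
#'   orthonormal `vectors` (columns).
#' @export
hamiltonian_eigen <- function(H) {
  M <- as_h_matrix(H)
  ee <- eigen(M, symmetric = TRUE)
  ord <- rev(seq_along(ee$values))      # eigen() returns descending
  vals <- ee$values[ord]
  vecs <- ee$vectors[, ord, drop = FALSE]
  vecs <- fix_eigvec_signs(vecs)
  structure(list(values = vals, vectors = vecs, n = nrow(M)),
            class = "hamiltonian_eigen")
}

# first significant component of each column made positive
fix_eigvec_signs <- function(vecs) {
  for (j in seq_len(ncol(vecs))) {
    v <- vecs[, j]
    i <- which(abs(v) > 1e-8 * max(abs(v)))[1]
    if (!is.na(i) && v[i] < 0) vecs[, j] <- -v
  }
  vecs
}

#' Bound eigensystem below the barrier energy
#'
#' Solves the time-independent problem and retains exactly the eigenpairs
#' with energy below the cutoff `Eb` (the bound states of the two-well
#' landscape), sorted ascending. `delta` is the maximum gap between adjacent
#' retained energies, the width of the eigenstate-sampling selection window
#' used by the total-energy arousal mechanism. An empty spectrum (no energy
#' below `Eb`) is a legal result, not an error; the arousal layer interprets
#' it.
#'
#' @param H A `hamiltonian` or symmetric matrix.
#' @param Eb Bound-state cutoff energy. Defaults to the `Eb` of the spec the
#'   Hamiltonian was built from, when available.
#' @return Object of class `eigensystem`: `energies`, `states` (one column
#'   per bound state), `Eb_cutoff`, `delta`, `n_states`.
#' @export
bound_eigensystem <- function(H, Eb = NULL) {
  if (is.null(Eb)) {
    if (inherits(H, "hamiltonian")) Eb <- H$potential$spec$Eb
    else stop("`Eb` must be given when `H` is a plain matrix", call. = FALSE)
  }
  he <- hamiltonian_eigen(H)
  keep <- which(he$values < Eb)
  energies <- he$values[keep]
  states <- he$vectors[, keep, drop = FALSE]
  delta <- if (length(energies) >= 2L) max(diff(energies)) else 0
  structure(list(energies = energies, states = states, Eb_cutoff = Eb,
                 delta = delta, n_states = length(energies), n = he$n),
            class = "eigensystem")
}

#' @export
print.eigensystem <- function(x, ...) {
  cat(sprintf("<eigensystem> %d bound state(s) below Eb = %g", x$n_states,
              x$Eb_cutoff))
  if (x$n_states > 0L)
    cat(sprintf("; E0 = %.6g, Ef = %.6g, delta = %.6g",
                x$energies[1], x$energies[x$n_states], x$delta))
  cat("\n")
  invisible(x)
}

#' Quantum state on a grid
#'
#' Validates and wraps a complex amplitude vector; the squared moduli must
#' sum to one (within 1e-10).
#'
#' @param amplitudes Complex (or numeric) vector of amplitudes.
#' @param grid The [spatial_grid()] the state lives on (optional).
#' @return Object of class `quantum_state` with `amplitudes` and `grid`.
#' @export
quantum_state <- function(amplitudes, grid = NULL) {
  amplitudes <- as.complex(amplitudes)
  nrm2 <- sum(Mod(amplitudes)^2)
  if (abs(nrm2 - 1) > 1e-10)
    stop(sprintf("state not normalized: sum |psi|^2 = %.12g", nrm2),
         call. = FALSE)
  structure(list(amplitudes = amplitudes, grid = grid),
            class = "quantum_state")
}

#' @export
print.quantum_state <- function(x, ...) {
  cat(sprintf("<quantum_state> n = %d, norm deviation = %.3g\n",
              length(x$amplitudes), abs(sum(Mod(x$amplitudes)^2) - 1)))
  invisible(x)
}

#' Uniform (neutral) initial state
#'
#' The discretized uniform superposition: every amplitude equal to
#' `1/sqrt(n)`, real and positive. It is the simplest state that is neutral
#' between the two options, with equal probability mass in each well of any
#' symmetric landscape.
#'
#' @param grid A [spatial_grid()].
#' @return A [quantum_state()].
#' @export
uniform_initial_state <- function(grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  quantum_state(rep(1 / sqrt(grid$n), grid$n) + 0i, grid)
}

#' Unitary time evolution
#'
#' Evolves a state by `psi(t) = exp(-i H t) psi(0)`, computed through the
#' full spectral decomposition of `H` (all eigenpairs, not only the bound
#' ones), which is exact for the discretized Hamiltonian and unconditionally
#' unitary. Pass a precomputed [hamiltonian_eigen()] to reuse the
#' decomposition across times.
#'
#' @param H A `hamiltonian`, a symmetric matrix, or a `hamiltonian_eigen`.
#' @param psi0 Initial [quantum_state()] (unit norm).
#' @param t Evolution time, a single nonnegative finite number.
#' @return The evolved [quantum_state()].
#' @export
propagate <- function(H, psi0, t) {
  stopifnot(inherits(psi0, "quantum_state"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("`t` must be a single finite nonnegative number", call. = FALSE)
  he <- if (inherits(H, "hamiltonian_eigen")) H else hamiltonian_eigen(H)
  if (he$n != length(psi0$amplitudes))
    stop("dimension mismatch between H and psi0", call. = FALSE)
  c0 <- crossprod(he$vectors, psi0$amplitudes)
  amps <- as.vector(he$vectors %*% (exp(-1i * he$values * t) * c0))
  # spectral evolution is unitary up to round-off; renormalize the residual
  amps <- amps / sqrt(sum(Mod(amps)^2))
  quantum_state(amps, psi0$grid)
}

#' Export an eigensystem as delimited text
#'
#' Writes `<prefix>_energies.csv` (one energy per row) and
#' `<prefix>_states.csv` (grid points in rows, bound states in columns).
#'
#' @param eig An [bound_eigensystem()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
export_eigensystem <- function(eig, prefix) {
  stopifnot(inherits(eig, "eigensystem"))
  f1 <- paste0(prefix, "_energies.csv")
  f2 <- paste0(prefix, "_states.csv")
  utils::write.table(data.frame(energy = eig$energies), f1, sep = ",",
                     row.names = FALSE, quote = FALSE)
  states <- eig$states
  colnames(states) <- if (eig$n_states > 0L)
    paste0("state_", seq_len(eig$n_states) - 1L) else character(0)
  utils::write.table(states, f2, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2))
}
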