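#' Uniform spatial grid
#'
#' Builds the uniform one-dimensional grid on which the Hamiltonian is
#' discretized. Both endpoints are grid points and all `n` points are
#' dynamical degrees of freedom; the hard (Dirichlet) walls of the Matrix
#' Numerov discretization sit implicitly one spacing outside the grid, at
#' `x_min - dx` and `x_max + dx`.
#'
#' @param x_min,x_max Extent of the grid (dimensionless position).
#' @param n Number of grid points (at least 3).
#' @return An object of class `spatial_grid` with fields `x_min`, `x_max`,
#'   `n`, `dx = (x_max - x_min)/(n - 1)` and the point vector `x`.
#' @examples
#' g <- spatial_grid(0, 8, 9)
#' g$dx
#' @export
spatial_grid <- function(x_min, x_max, n) {
  if (!is.numeric(x_min) || !is.numeric(x_max) || x_min >= x_max)
    stop("`x_min` must be strictly less than `x_max`", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 3L)
    stop("`n` must be an integer >= 3", call. = FALSE)
  dx <- (x_max - x_min) / (n - 1)
  structure(
    list(x_min = x_min, x_max = x_max, n = n, dx = dx,
         x = x_min + dx * (0:(n - 1L))),
    class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> %d points on [%g, %g], dx = %.6g\n",
              x$n, x$x_min, x$x_max, x$dx))
  invisible(x)
}

#' Two-square-well potential specification
#'
#' Describes the piecewise-constant potential used to model a 2AFC decision:
#' two wells of common width `w` (left bottom energy `EwL`, right bottom
#' energy `EwR`), separated by a middle region of width `m_gap` and energy
#' `Em`, flanked by edge regions of common width `e`, inside an outer box
#' `[xbL, xbR]` beyond which the barrier/free energy is `Eb`. The geometry is
#' symmetric by construction (equal well widths, equal edge widths); only the
#' well bottom energies may differ. A deeper well (lower bottom energy)
#' encodes a stronger signal for that option.
#'
#' @param Eb Barrier (free) energy, the bound-state cutoff. The fitting
#'   pipeline fixes `Eb = 1` to set the energy scale.
#' @param EwL,EwR Bottom energies of the left and right wells; both must lie
#'   strictly below `Eb`.
#' @param Em Middle-region energy (`Em <= Eb`), the conceptual "gap" between
#'   the two options.
#' @param w Common well width (> 0).
#' @param e Common edge width (>= 0), the distance from the outer box
#'   boundary to the nearer well.
#' @param m_gap Width of the middle region (>= 0).
#' @param xbL Position of the left box boundary (default 0).
#' @param correct_side Which well encodes the correct option, `"left"` or
#'   `"right"`.
#' @param E_edge Energy of the two edge regions. Defaults to `Em`.
#' @return An object of class `well_spec`.
#' @examples
#' spec <- well_spec(EwL = 0.45, EwR = 0.2, Em = 0.85, w = 1.1, e = 0.3,
#'                   m_gap = 0.6)
#' derive_breakpoints(spec)
#' @export
well_spec <- function(Eb = 1, EwL, EwR, Em, w, e, m_gap,
                      xbL = 0, correct_side = c("right", "left"),
                      E_edge = NULL) {
  correct_side <- match.arg(correct_side)
  if (is.null(E_edge)) E_edge <- Em
  vals <- c(Eb = Eb, EwL = EwL, EwR = EwR, Em = Em, w = w, e = e,
            m_gap = m_gap, xbL = xbL, E_edge = E_edge)
  if (!all(is.finite(vals)))
    stop("all well_spec fields must be finite numbers", call. = FALSE)
  if (w <= 0) stop("invalid well_spec: well width `w` must be > 0", call. = FALSE)
  if (e < 0) stop("invalid well_spec: edge width `e` must be >= 0", call. = FALSE)
  if (m_gap < 0) stop("invalid well_spec: `m_gap` must be >= 0", call. = FALSE)
  if (EwL >= Eb || EwR >= Eb)
    stop("invalid well_spec: well bottoms EwL, EwR must lie below Eb", call. = FALSE)
  if (Em > Eb) stop("invalid well_spec: `Em` must not exceed Eb", call. = FALSE)
  if (E_edge > Eb) stop("invalid well_spec: `E_edge` must not exceed Eb", call. = FALSE)
  structure(
    list(Eb = Eb, EwL = EwL, EwR = EwR, Em = Em, E_edge = E_edge,
         w = w, e = e, m_gap = m_gap, xbL = xbL, correct_side = correct_side),
    class = "well_spec")
}

#' @export
print.well_spec <- function(x, ...) {
  cat("<well_spec>\n")
  cat(sprintf("  energies: Eb = %g, EwL = %g, EwR = %g, Em = %g, E_edge = %g\n",
              x$Eb, x$EwL, x$EwR, x$Em, x$E_edge))
  cat(sprintf("  widths:   w = %g, e = %g, m_gap = %g  (box [%g, %g])\n",
              x$w, x$e, x$m_gap, x$xbL, x$xbL + 2 * x$e + 2 * x$w + x$m_gap))
  cat(sprintf("  correct side: %s\n", x$correct_side))
  invisible(x)
}

#' Reflect a well specification
#'
#' Swaps the two well energies and the correct-side label, i.e. the mirror
#' image of the landscape about the box center.
#' @param spec A [well_spec()].
#' @return The mirrored `well_spec`.
#' @export
reflect_spec <- function(spec) {
  well_spec(Eb = spec$Eb, EwL = spec$EwR, EwR = spec$EwL, Em = spec$Em,
            w = spec$w, e = spec$e, m_gap = spec$m_gap, xbL = spec$xbL,
            correct_side = if (spec$correct_side == "right") "left" else "right",
            E_edge = spec$E_edge)
}

#' Region breakpoints of a two-well potential
#'
#' @param spec A [well_spec()].
#' @return Named numeric vector `(xbL, xwL_l, xwL_r, xwR_l, xwR_r, xbR)`:
#'   box, left-well and right-well boundaries in increasing order. The
#'   geometry is symmetric: `xwL_l - xbL = xbR - xwR_r` and the two wells
#'   have equal width.
#' @export
derive_breakpoints <- function(spec) {
  stopifnot(inherits(spec, "well_spec"))
  bp <- spec$xbL + cumsum(c(0, spec$e, spec$w, spec$m_gap, spec$w, spec$e))
  names(bp) <- c("xbL", "xwL_l", "xwL_r", "xwR_l", "xwR_r", "xbR")
  bp
}

#' Grid spanning a well specification's box
#'
#' Convenience constructor for the grid most operations expect: `n` points
#' spanning exactly `[xbL, xbR]`. With `pad > 0`, `pad` extra points at the
#' barrier energy are added beyond each box boundary (same spacing), a
#' sensitivity-check mode for the hard-wall truncation.
#'
#' @param spec A [well_spec()].
#' @param n Number of points across the box (default 512).
#' @param pad Number of extra barrier-energy points on each side (default 0).
#' @return A [spatial_grid()].
#' @export
grid_for_spec <- function(spec, n = 512, pad = 0) {
  bp <- derive_breakpoints(spec)
  dx <- (bp[["xbR"]] - bp[["xbL"]]) / (n - 1)
  pad <- as.integer(pad)
  spatial_grid(bp[["xbL"]] - pad * dx, bp[["xbR"]] + pad * dx, n + 2L * pad)
}

# Region code per grid point: 0 outside the box (barrier), 1 left edge,
# 2 left well, 3 middle, 4 right well, 5 right edge.
#
# Membership is half-open [l, r) for points left of the box center and the
# mirror-image rule (l, r] for points right of it, so that reflecting the
# landscape reflects the region vector exactly and symmetric landscapes put
# equal point counts in the two wells on every grid. In particular a point
# exactly at the left well's right boundary belongs to the middle region,
# and the final point xbR belongs to the right edge region.
region_codes <- function(spec, grid) {
  stopifnot(inherits(spec, "well_spec"), inherits(grid, "spatial_grid"))
  bp <- derive_breakpoints(spec)
  span <- bp[["xbR"]] - bp[["xbL"]]
  tol <- 1e-9 * span
  if (grid$x_min > bp[["xbL"]] + tol || grid$x_max < bp[["xbR"]] - tol)
    stop("domain mismatch: grid does not cover the box [xbL, xbR]",
         call. = FALSE)
  x <- grid$x
  center <- (bp[["xbL"]] + bp[["xbR"]]) / 2
  reg <- integer(grid$n)
  inside <- x >= bp[["xbL"]] - tol & x <= bp[["xbR"]] + tol
  lhs <- inside & x < center - tol
  rhs <- inside & x > center + tol
  # findInterval on tolerance-shifted points implements the half-open rule;
  # right-half points are classified by reflecting them onto the left half,
  # which is exactly the mirrored (l, r] rule
  reg[lhs] <- findInterval(x[lhs] + tol, bp)
  reg[rhs] <- 6L - findInterval((2 * center - x[rhs]) + tol, bp)
  reg[inside & !lhs & !rhs] <- 3L  # center point -> middle region
  reg
}

#' Evaluate the two-well potential on a grid
#'
#' Assigns each grid point its region energy: `EwL` inside the left well,
#' `EwR` inside the right well, `Em` in the middle region, `E_edge` in the
#' two edge regions and `Eb` at any padded points outside the box. The grid
#' must cover the box `[xbL, xbR]`.
#'
#' @param spec A [well_spec()].
#' @param grid A [spatial_grid()] covering the spec's box (see
#'   [grid_for_spec()]).
#' @return An object of class `potential_vector`: list with `values` (length
#'   `grid$n`), `region` codes, and references `spec`, `grid`.
#' @export
potential_on_grid <- function(spec, grid) {
  reg <- region_codes(spec, grid)
  lut <- c(spec$Eb, spec$E_edge, spec$EwL, spec$Em, spec$EwR, spec$E_edge)
  structure(
    list(values = lut[reg + 1L], region = reg, spec = spec, grid = grid),
    class = "potential_vector")
}

#' @export
print.potential_vector <- function(x, ...) {
  cat(sprintf("<potential_vector> %d points, energies in [%g, %g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Well membership index sets
#'
#' Indices of the grid points inside each well, plus the correct/incorrect
#' aliases according to `spec$correct_side`. These are the integration index
#' sets over which the wavefunction's probability mass is summed to form the
#' two mean integration efficiencies.
#'
#' @inheritParams potential_on_grid
#' @return List with integer index vectors `left`, `right`, `correct`,
#'   `incorrect`.
#' @export
well_index_sets <- function(spec, grid) {
  reg <- region_codes(spec, grid)
  left <- which(reg == 2L)
  right <- which(reg == 4L)
  if (length(left) == 0L || length(right) == 0L)
    stop("resolution error: a well contains no grid point; increase `n`",
         call. = FALSE)
  if (spec$correct_side == "right")
    list(left = left, right = right, correct = right, incorrect = left)
  else
    list(left = left, right = right, correct = left, incorrect = right)
}

#' Random well specifications
#'
#' Draws physically sensible random landscapes (barrier at `Eb`, well bottoms
#' uniform below it, order-one widths), used for property checks such as
#' hermiticity, unitarity and arousal-regime classification.
#'
#' @param n_specs Number of specs to draw.
#' @param Eb Barrier energy (default 1).
#' @param symmetric If `TRUE`, force `EwR = EwL`.
#' @param seed Optional integer seed (scoped; does not disturb the global
#'   RNG stream).
#' @return A list of [well_spec()] objects.
#' @export
random_well_spec <- function(n_specs = 1, Eb = 1, symmetric = FALSE,
                             seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  replicate(n_specs, {
    EwL <- stats::runif(1, 0, 0.8 * Eb)
    EwR <- if (symmetric) EwL else stats::runif(1, 0, 0.8 * Eb)
    well_spec(Eb = Eb, EwL = EwL, EwR = EwR,
              Em = stats::runif(1, 0.5 * Eb, Eb),
              w = stats::runif(1, 0.5, 2),
              e = stats::runif(1, 0, 0.5),
              m_gap = stats::runif(1, 0.1, 1.5),
              correct_side = if (stats::runif(1) < 0.5) "right" else "left")
  }, simplify = FALSE)
}
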