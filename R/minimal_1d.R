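#' One-dimensional cell-file state
#'
#' Per-cell auxin and PIN1 concentrations for an ordered file of `N` cells
#' along the central root axis. Cell 1 is the root end (outermost columella
#' cell); cell `N` is the shoot-to-root junction, where the shoot's auxin
#' enters.
#'
#' @param a numeric vector of auxin concentrations (cu), cell 1 first.
#' @param PIN numeric vector of PIN1 concentrations (cu), same length.
#' @return An object of class `profile1d`.
#' @export
profile1d <- function(a, PIN = rep(0, length(a))) {
  if (length(a) != length(PIN)) stop("a and PIN must have equal length")
  if (length(a) < 2) stop("a cell file needs at least 2 cells")
  if (any(!is.finite(a)) || any(!is.finite(PIN))) stop("non-finite state")
  if (any(a < 0) || any(PIN < 0)) stop("concentrations must be nonnegative")
  structure(list(N = length(a), a = as.numeric(a), PIN = as.numeric(PIN)),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat("1D cell file,", x$N, "cells (cell 1 = root end)\n")
  i <- which.max(x$a)
  cat(sprintf("  auxin: max %.4g cu in cell %d; total %.4g cu\n",
              x$a[i], i, sum(x$a)))
  cat(sprintf("  PIN1 : range [%.4g, %.4g] cu\n", min(x$PIN), max(x$PIN)))
  invisible(x)
}

# Unchecked RHS kernel shared by the public assembler, the integrator and the
# steady-state solver. `alpha` is passed separately so the growing-root model
# can evaluate a flux schedule. Small negative excursions are tolerated here
# (implicit integrators probe them); public entry points validate.
rhs_1d_raw <- function(a, PIN, p, alpha = p$alpha) {
  N <- length(a)
  da <- -p$Kd * a
  da[N] <- da[N] + alpha
  # passive diffusion between longitudinal neighbours
  d <- p$D * diff(a)                       # flux into i from i+1, i = 1..N-1
  da[-N] <- da[-N] + d
  da[-1] <- da[-1] - d
  # acropetal active transport i -> i-1 for i = 2..N (cell 1 has no target)
  tr <- p$K0 * PIN[-1] * a[-1]
  da[-1] <- da[-1] - tr
  da[-N] <- da[-N] + tr
  u <- (pmax(a, 0) / p$q1)^p$h1
  v <- (pmax(a, 0) / p$q2)^p$h1
  dPIN <- p$k1 * u / (1 + u + v) - p$k2 * PIN * (1 + (pmax(a, 0) / p$q3)^p$h2)
  list(da = da, dPIN = dPIN)
}

#' Right-hand side of the 1D minimal model
#'
#' Assembles the time derivatives of the auxin and PIN1 concentrations for
#' the full cell file. Interior cells exchange auxin by diffusion with both
#' neighbours, import actively from cell i+1 and export actively to cell
#' i-1, and degrade auxin; cell `N` additionally receives the shoot influx
#' `alpha` and has no efflux or diffusion towards the shoot; cell 1, at the
#' physical root end, has no distal export or diffusion. PIN1 in every cell
#' follows auxin-activated synthesis minus auxin-enhanced degradation.
#'
#' The assembled field satisfies the mass-balance identity
#' `sum(da) == alpha - Kd * sum(a)` exactly: all internal fluxes cancel
#' pairwise and only influx and degradation are non-conservative.
#'
#' @param state a [profile1d()].
#' @param p an [transport_params()] object.
#' @return list with numeric vectors `da` and `dPIN` (cu/tu).
#' @export
build_rhs_1d <- function(state, p) {
  stopifnot(inherits(state, "profile1d"))
  rhs_1d_raw(state$a, state$PIN, p)
}

desolve_func_1d <- function(p) {
  function(t, y, parms) {
    N <- length(y) / 2L
    r <- rhs_1d_raw(y[seq_len(N)], y[N + seq_len(N)], p)
    list(c(r$da, r$dPIN))
  }
}

#' Integrate the 1D minimal model
#'
#' Stiff implicit multistep (BDF) integration of the cell-file system. The
#' sharply thresholded PIN1 degradation makes the system stiff, so tight
#' default tolerances are used.
#'
#' @param init a [profile1d()] initial condition.
#' @param p an [transport_params()] object.
#' @param t_end final time (tu).
#' @param times optional output times; default 200 points on `[0, t_end]`.
#' @param rtol,atol relative and absolute integration tolerances.
#' @return An object of class `trajectory1d`: list with `times`, matrices
#'   `a` and `PIN` (rows = times, columns = cells), and `diagnostics`.
#' @export
integrate_1d <- function(init, p, t_end, times = NULL,
                         rtol = 1e-8, atol = 1e-10, maxsteps = 50000) {
  stopifnot(inherits(init, "profile1d"), t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = 200L)
  N <- init$N
  sol <- deSolve::ode(y = c(init$a, init$PIN), times = times,
                      func = desolve_func_1d(p), parms = NULL,
                      method = "bdf", rtol = rtol, atol = atol,
                      maxsteps = maxsteps)
  diag <- attributes(sol)[c("istate", "rstate")]
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed at t = ", max(sol[, 1]))
  structure(list(times = sol[, 1],
                 a = unname(sol[, 1 + seq_len(N), drop = FALSE]),
                 PIN = unname(sol[, 1 + N + seq_len(N), drop = FALSE]),
                 diagnostics = diag),
            class = "trajectory1d")
}

#' @export
print.trajectory1d <- function(x, ...) {
  nt <- length(x$times)
  cat("1D trajectory:", ncol(x$a), "cells,", nt, "time points, t in [",
      min(x$times), ",", max(x$times), "] tu\n")
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param traj a `trajectory1d`.
#' @return the last time point as a [profile1d()].
#' @export
final_state <- function(traj) {
  nt <- length(traj$times)
  profile1d(pmax(traj$a[nt, ], 0), pmax(traj$PIN[nt, ], 0))
}

#' Stationary solution of the 1D minimal model
#'
#' Solves for a steady state by integrating the Cauchy problem (zero initial
#' data by default, mirroring how the stationary auxin distribution arises
#' developmentally) until the dynamics slow down, then polishing with damped
#' Newton iteration to a residual max-norm below `tol`.
#'
#' @param p an [transport_params()] object.
#' @param N number of cells (default 50).
#' @param init optional [profile1d()] initial guess; default zero state.
#' @param tol residual max-norm tolerance (default 1e-10).
#' @param t_relax horizon of the relaxation integration (tu).
#' @param newton_only skip the relaxation and run Newton from `init`
#'   (used by the continuation routine, which supplies good predictors).
#' @return list of class `steady1d`: `profile` ([profile1d()]), `residual`,
#'   `converged`, `iterations`, and `leading_eigenvalue` (max real part of
#'   the Jacobian spectrum; negative means the state is linearly stable).
#' @export
steady_state_1d <- function(p, N = 50, init = NULL, tol = 1e-10,
                            t_relax = 2000, newton_only = FALSE) {
  if (is.null(init)) init <- profile1d(rep(0, N), rep(0, N))
  N <- init$N
  f <- function(y) {
    r <- rhs_1d_raw(y[seq_len(N)], y[N + seq_len(N)], p)
    c(r$da, r$dPIN)
  }
  x0 <- c(init$a, init$PIN)
  if (!newton_only) {
    traj <- integrate_1d(init, p, t_end = t_relax,
                         times = c(0, t_relax / 2, t_relax))
    x0 <- pmax(c(traj$a[3, ], traj$PIN[3, ]), 0)
  }
  jac <- function(y) jac_1d_raw(y[seq_len(N)], y[N + seq_len(N)], p)
  ns <- newton_solve(f, x0, jac = jac, tol = tol, lower = rep(0, 2 * N))
  if (!ns$converged && !newton_only) {
    # second chance: relax for longer from where Newton stalled
    traj <- integrate_1d(profile1d(pmax(ns$x[seq_len(N)], 0),
                                   pmax(ns$x[N + seq_len(N)], 0)),
                         p, t_end = 5 * t_relax,
                         times = c(0, 5 * t_relax))
    ns <- newton_solve(f, pmax(c(traj$a[2, ], traj$PIN[2, ]), 0),
                       jac = jac, tol = tol, lower = rep(0, 2 * N))
  }
  prof <- profile1d(pmax(ns$x[seq_len(N)], 0), pmax(ns$x[N + seq_len(N)], 0))
  lead <- if (ns$converged) {
    J <- jac(ns$x)
    max(Re(eigen(J, only.values = TRUE)$values))
  } else NA_real_
  structure(list(profile = prof, residual = ns$residual,
                 converged = ns$converged, iterations = ns$iterations,
                 leading_eigenvalue = lead,
                 stable = if (is.na(lead)) NA else lead < 0),
            class = "steady1d")
}

#' @export
print.steady1d <- function(x, ...) {
  cat("1D stationary solution (residual ", format(x$residual, digits = 3),
      if (isTRUE(x$stable)) ", stable" else if (isFALSE(x$stable)) ", unstable" else "",
      ")\n", sep = "")
  print(x$profile)
  invisible(x)
}

#' Perturb the auxin level of one cell
#'
#' Returns a copy of the state with `delta_a` added to cell `i`'s auxin,
#' emulating localized exogenous auxin application (or depletion).
#'
#' @param state a [profile1d()].
#' @param i 1-based cell index.
#' @param delta_a auxin increment (cu); the result must stay nonnegative.
#' @return a new [profile1d()].
#' @export
perturb_cell <- function(state, i, delta_a) {
  stopifnot(inherits(state, "profile1d"))
  if (i < 1 || i > state$N) stop("cell index out of range")
  a <- state$a
  a[i] <- a[i] + delta_a
  if (a[i] < 0) stop("perturbation drives cell ", i, " negative")
  profile1d(a, state$PIN)
}
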