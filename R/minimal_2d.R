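#' Two-dimensional cell layout
#'
#' An `M x N` rectangular layout representing a longitudinal section of the
#' root at an early developmental stage. Rows (layers) `3 .. M-2` are
#' provascular: they run the full 1D transport machinery (influx at their
#' basal cell `N`, acropetal PIN1-mediated transport, auxin-regulated PIN1
#' expression). Rows `1, 2, M-1, M` are epidermal: they neither synthesise
#' nor degrade PIN1 (PIN1 is identically zero there) and carry no active
#' transport or shoot influx; auxin reaches them only by transverse
#' diffusion from the adjacent provascular rows and moves within them by
#' diffusion, subject to degradation everywhere. Columns are indexed like
#' the 1D model: column 1 is the root end.
#'
#' @param a,PIN numeric `M x N` matrices of concentrations (cu); `PIN` must
#'   be zero in epidermal rows.
#' @return An object of class `layout2d`.
#' @export
layout2d <- function(a, PIN = matrix(0, nrow(a), ncol(a))) {
  if (!is.matrix(a) || !is.matrix(PIN) || !all(dim(a) == dim(PIN)))
    stop("a and PIN must be matrices of identical dimension")
  M <- nrow(a); N <- ncol(a)
  if (M < 6) stop("layout needs M >= 6 rows (two epidermal rows each side of",
                  " at least two provascular rows)")
  if (N < 2) stop("layout needs N >= 2 columns")
  if (any(a < 0) || any(PIN < 0)) stop("concentrations must be nonnegative")
  epi <- epidermal_rows(M)
  if (any(PIN[epi, ] != 0)) stop("PIN1 must be zero in epidermal rows")
  structure(list(M = M, N = N, a = a, PIN = PIN), class = "layout2d")
}

#' Row roles of a 2D layout
#'
#' @param M number of rows.
#' @return integer vector of epidermal (`epidermal_rows`) or provascular
#'   (`provascular_rows`) row indices.
#' @export
epidermal_rows <- function(M) c(1L, 2L, M - 1L, M)

#' @rdname epidermal_rows
#' @export
provascular_rows <- function(M) seq(3L, M - 2L)

#' @export
print.layout2d <- function(x, ...) {
  pv <- provascular_rows(x$M)
  idx <- arrayInd(which.max(x$a[pv, , drop = FALSE]), c(length(pv), x$N))
  cat("2D layout:", x$M, "rows x", x$N, "columns;",
      length(pv), "provascular rows", min(pv), "-", max(pv), "\n")
  cat(sprintf("  provascular auxin max %.4g cu at row %d, column %d\n",
              max(x$a[pv, ]), pv[idx[1]], idx[2]))
  invisible(x)
}

# Unchecked RHS kernel on matrices. Provascular rows: full 1D machinery plus
# transverse diffusion; epidermal rows: diffusion and degradation only.
# Outermost rows have a one-sided transverse term (delta_1 = +1 couples row 1
# to row 2; delta_M = -1 couples row M to row M-1).
rhs_2d_raw <- function(a, PIN, p, alpha = p$alpha, D_transverse = p$D) {
  M <- nrow(a); N <- ncol(a)
  pv <- provascular_rows(M)
  da <- -p$Kd * a
  dPIN <- matrix(0, M, N)
  # longitudinal diffusion, all rows
  d <- p$D * (a[, -1, drop = FALSE] - a[, -N, drop = FALSE])
  da[, -N] <- da[, -N] + d
  da[, -1] <- da[, -1] - d
  # transverse diffusion between vertically adjacent cells, all rows;
  # one-sidedness at rows 1 and M falls out of the pairwise sum
  dv <- D_transverse * (a[-1, , drop = FALSE] - a[-M, , drop = FALSE])
  da[-M, ] <- da[-M, ] + dv
  da[-1, ] <- da[-1, ] - dv
  # provascular rows: influx, active transport, PIN1 expression
  apv <- a[pv, , drop = FALSE]; Ppv <- PIN[pv, , drop = FALSE]
  da[pv, N] <- da[pv, N] + alpha
  tr <- p$K0 * Ppv[, -1, drop = FALSE] * apv[, -1, drop = FALSE]
  da[pv, -1] <- da[pv, -1, drop = FALSE] - tr
  da[pv, -N] <- da[pv, -N, drop = FALSE] + tr
  u <- (pmax(apv, 0) / p$q1)^p$h1
  v <- (pmax(apv, 0) / p$q2)^p$h1
  dPIN[pv, ] <- p$k1 * u / (1 + u + v) -
    p$k2 * Ppv * (1 + (pmax(apv, 0) / p$q3)^p$h2)
  list(da = da, dPIN = dPIN)
}

#' Right-hand side of the 2D minimal model
#'
#' Assembles auxin and PIN1 time derivatives on the full layout. The field
#' satisfies the mass-balance identity
#' `sum(da) == n_provascular * alpha - Kd * sum(a)` exactly, since each
#' provascular row receives the full influx `alpha` at its basal cell and
#' all diffusion/transport fluxes cancel pairwise.
#'
#' @param state a [layout2d()].
#' @param p an [transport_params()] object.
#' @param D_transverse transverse diffusion rate constant; defaults to the
#'   longitudinal `p$D`.
#' @return list of matrices `da` and `dPIN` (cu/tu).
#' @export
build_rhs_2d <- function(state, p, D_transverse = p$D) {
  stopifnot(inherits(state, "layout2d"))
  rhs_2d_raw(state$a, state$PIN, p, D_transverse = D_transverse)
}

desolve_func_2d <- function(p, M, N, D_transverse) {
  MN <- M * N
  function(t, y, parms) {
    r <- rhs_2d_raw(matrix(y[seq_len(MN)], M, N),
                    matrix(y[MN + seq_len(MN)], M, N),
                    p, D_transverse = D_transverse)
    list(c(as.vector(r$da), as.vector(r$dPIN)))
  }
}

#' Integrate the 2D minimal model
#'
#' @param init a [layout2d()] initial condition.
#' @param p an [transport_params()] object.
#' @param t_end final time (tu).
#' @param times optional output times.
#' @param D_transverse transverse diffusion constant (default `p$D`).
#' @param rtol,atol,maxsteps integrator controls.
#' @return object of class `trajectory2d`: `times`, list of `a` and `PIN`
#'   matrices per time point.
#' @export
integrate_2d <- function(init, p, t_end, times = NULL, D_transverse = p$D,
                         rtol = 1e-8, atol = 1e-10, maxsteps = 50000) {
  stopifnot(inherits(init, "layout2d"), t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = 50L)
  M <- init$M; N <- init$N; MN <- M * N
  sol <- deSolve::ode(y = c(as.vector(init$a), as.vector(init$PIN)),
                      times = times, func = desolve_func_2d(p, M, N, D_transverse),
                      parms = NULL, method = "bdf",
                      rtol = rtol, atol = atol, maxsteps = maxsteps)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed at t = ", max(sol[, 1]))
  states <- lapply(seq_len(nrow(sol)), function(k) {
    layout2d(matrix(pmax(sol[k, 1 + seq_len(MN)], 0), M, N),
             matrix(pmax(sol[k, 1 + MN + seq_len(MN)], 0), M, N))
  })
  structure(list(times = sol[, 1], states = states), class = "trajectory2d")
}

#' Stationary solution of the 2D minimal model
#'
#' Relaxation from zero initial data followed by Newton polishing, as in
#' [steady_state_1d()] but on the full grid. PIN1 components of epidermal
#' rows are excluded from the Newton unknowns (they are structurally zero).
#'
#' @param p an [transport_params()] object.
#' @param M,N layout dimensions (defaults 8 x 50).
#' @param init optional [layout2d()] starting state.
#' @param tol residual max-norm tolerance.
#' @param t_relax relaxation horizon (tu).
#' @return list of class `steady2d` with `layout`, `residual`, `converged`.
#' @export
steady_state_2d <- function(p, M = 8, N = 50, init = NULL, tol = 1e-10,
                            t_relax = 3000) {
  if (is.null(init)) init <- layout2d(matrix(0, M, N))
  M <- init$M; N <- init$N; MN <- M * N
  pv <- provascular_rows(M)
  traj <- integrate_2d(init, p, t_end = t_relax, times = c(0, t_relax))
  st <- traj$states[[2]]
  # unknowns: all of a, plus PIN on provascular rows only
  pin_idx <- as.vector(outer(pv, (seq_len(N) - 1) * M, `+`))
  pack <- function(a, PIN) c(as.vector(a), as.vector(PIN)[pin_idx])
  unpack <- function(x) {
    a <- matrix(x[seq_len(MN)], M, N)
    PIN <- matrix(0, M, N); PIN[pv, ] <- matrix(x[MN + seq_along(pin_idx)],
                                                length(pv), N)
    list(a = a, PIN = PIN)
  }
  f <- function(x) {
    s <- unpack(x)
    r <- rhs_2d_raw(s$a, s$PIN, p)
    c(as.vector(r$da), as.vector(r$dPIN)[pin_idx])
  }
  ns <- newton_solve(f, pack(st$a, st$PIN), tol = tol,
                     lower = rep(0, MN + length(pin_idx)))
  s <- unpack(pmax(ns$x, 0))
  structure(list(layout = layout2d(s$a, s$PIN), residual = ns$residual,
                 converged = ns$converged, iterations = ns$iterations),
            class = "steady2d")
}

#' @export
print.steady2d <- function(x, ...) {
  cat("2D stationary solution (residual ", format(x$residual, digits = 3), ")\n",
      sep = "")
  print(x$layout)
  invisible(x)
}

#' Tip excision / QC ablation restart
#'
#' Removes the `n_cut` most distal columns of a stationary layout (the root
#' cap and quiescent centre) and integrates the truncated root onwards, so
#' that cells formerly at columns `n_cut+1, n_cut+2, ...` become the new
#' columns `1, 2, ...`. Tracks the auxin maximum of a chosen provascular
#' row through time: immediately after the cut auxin piles up near the new
#' root end, and a new distal maximum then re-forms at a distance from the
#' wound by the reflected-flow mechanism.
#'
#' @param stationary a [layout2d()] (typically from [steady_state_2d()]).
#' @param p an [transport_params()] object.
#' @param n_cut number of columns removed at the root end (default 5).
#' @param t_end horizon of the regeneration integration (tu).
#' @param times optional output times.
#' @param track_row provascular row whose maximum is followed (default 4).
#' @return list of class `ablation`: `trajectory` (a `trajectory2d` on the
#'   truncated layout) and `max_track`, a data.frame with columns `time`,
#'   `max_column`, `max_value` for the tracked row.
#' @export
ablate_and_restart <- function(stationary, p, n_cut = 5, t_end = 2000,
                               times = NULL, track_row = 4) {
  stopifnot(inherits(stationary, "layout2d"))
  if (n_cut < 0 || n_cut >= stationary$N) stop("n_cut must be in [0, N)")
  keep <- seq(n_cut + 1L, stationary$N)
  init <- layout2d(stationary$a[, keep, drop = FALSE],
                   stationary$PIN[, keep, drop = FALSE])
  if (is.null(times)) times <- unique(c(seq(0, min(50, t_end), length.out = 26),
                                        seq(min(50, t_end), t_end,
                                            length.out = 25)))
  traj <- integrate_2d(init, p, t_end = t_end, times = times)
  track <- do.call(rbind, lapply(seq_along(traj$times), function(k) {
    row_a <- traj$states[[k]]$a[track_row, ]
    data.frame(time = traj$times[k], max_column = which.max(row_a),
               max_value = max(row_a))
  }))
  structure(list(trajectory = traj, max_track = track, n_cut = n_cut),
            class = "ablation")
}
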