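# Shared numerical kernels: finite-difference Jacobians and a damped Newton
# solver. These back the steady-state, stability and continuation machinery.

#' Central finite-difference Jacobian
#'
#' @param f vector-valued function of a numeric vector.
#' @param x evaluation point.
#' @param step relative step; the per-coordinate step is
#'   `step * max(1, abs(x[i]))`.
#' @return the Jacobian matrix `df_i/dx_j`.
#' @keywords internal
fd_jacobian <- function(f, x, step = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- step * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Damped Newton iteration for F(x) = 0
#'
#' Newton's method with step-halving line search on the residual max-norm.
#' The Jacobian is recomputed at every iteration by central differences
#' unless an analytic `jac` is supplied.
#'
#' @param f residual function.
#' @param x0 starting point.
#' @param jac optional Jacobian function.
#' @param tol convergence tolerance on the residual max-norm.
#' @param maxit maximum Newton iterations.
#' @param lower optional elementwise lower bound; steps are clipped onto it
#'   (used to keep concentrations nonnegative).
#' @return list with `x`, `residual` (max-norm), `converged`, `iterations`.
#' @keywords internal
newton_solve <- function(f, x0, jac = NULL, tol = 1e-10, maxit = 60,
                         lower = NULL) {
  x <- x0
  Fx <- f(x)
  nrm <- max(abs(Fx))
  for (it in seq_len(maxit)) {
    if (nrm < tol)
      return(list(x = x, residual = nrm, converged = TRUE, iterations = it - 1L))
    J <- if (is.null(jac)) fd_jacobian(f, x) else jac(x)
    dx <- tryCatch(solve(J, -Fx), error = function(e) NULL)
    if (is.null(dx)) {
      # near-singular Jacobian: fall back to a regularised least-squares step
      dx <- tryCatch(qr.solve(J, -Fx, tol = 1e-14), error = function(e) NULL)
      if (is.null(dx))
        return(list(x = x, residual = nrm, converged = FALSE, iterations = it))
    }
    lambda <- 1
    repeat {
      xn <- x + lambda * dx
      if (!is.null(lower)) xn <- pmax(xn, lower)
      Fn <- tryCatch(f(xn), error = function(e) rep(Inf, length(Fx)))
      nn <- max(abs(Fn))
      if (is.finite(nn) && (nn < nrm || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    if (!is.finite(nn) || nn >= nrm) {
      return(list(x = x, residual = nrm, converged = nrm < tol, iterations = it))
    }
    x <- xn; Fx <- Fn; nrm <- nn
  }
  list(x = x, residual = nrm, converged = nrm < tol, iterations = maxit)
}

# Analytic Jacobian of the 1D cell-file field (auxin block tridiagonal plus
# transport coupling, PIN1 block diagonal). Orders the state as
# (a_1..a_N, PIN_1..PIN_N), matching rhs_1d_raw.
jac_1d_raw <- function(a, PIN, p) {
  N <- length(a)
  J <- matrix(0, 2 * N, 2 * N)
  ia <- seq_len(N); ip <- N + ia
  a_pos <- pmax(a, 0)
  # auxin-auxin block
  diag_a <- rep(-p$Kd, N)
  diag_a[-N] <- diag_a[-N] - p$D
  diag_a[-1] <- diag_a[-1] - p$D - p$K0 * PIN[-1]
  for (i in ia) J[i, i] <- diag_a[i]
  for (i in seq_len(N - 1)) {
    J[i, i + 1] <- p$D + p$K0 * PIN[i + 1]   # import from i+1
    J[i + 1, i] <- p$D                        # diffusion from i
  }
  # auxin-PIN block: export of cell i (i > 1) and import into i - 1
  for (i in 2:N) {
    J[i, N + i] <- -p$K0 * a[i]
    J[i - 1, N + i] <- p$K0 * a[i]
  }
  # PIN equation derivatives
  u <- (a_pos / p$q1)^p$h1
  v <- (a_pos / p$q2)^p$h1
  w <- (a_pos / p$q3)^p$h2
  dsyn <- ifelse(a_pos > 0,
                 p$k1 * p$h1 * (u * (1 + v) - u * v) / (a_pos * (1 + u + v)^2),
                 if (p$h1 == 1) p$k1 / p$q1 else 0)
  dw <- ifelse(a_pos > 0, p$h2 * w / a_pos,
               if (p$h2 == 1) 1 / p$q3 else 0)
  for (i in ia) {
    J[N + i, i] <- dsyn[i] - p$k2 * PIN[i] * dw[i]
    J[N + i, N + i] <- -p$k2 * (1 + w[i])
  }
  J
}
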