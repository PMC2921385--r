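#' Locate local maxima of a concentration profile
#'
#' A cell is a maximum if its value is at least that of both neighbours
#' (one-sided at the file ends) and exceeds the larger of the two flanking
#' local minima by at least `epsilon` (prominence). Plateaus report their
#' smallest index. A constant profile has no maxima.
#'
#' @param profile numeric vector, or a [profile1d()] (its auxin is used).
#' @param epsilon minimum prominence (cu); default 1% of the profile
#'   maximum, below which a peak is considered within measurement error.
#' @return integer vector of 1-based maxima indices.
#' @export
find_maxima <- function(profile, epsilon = NULL) {
  a <- if (inherits(profile, "profile1d")) profile$a else as.numeric(profile)
  if (is.null(epsilon)) epsilon <- 0.01 * max(a)
  if (epsilon < 0) stop("epsilon must be nonnegative")
  n <- length(a)
  if (n == 0 || max(a) == min(a)) return(integer(0))
  cand <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && a[j + 1] == a[i]) j <- j + 1  # plateau extent
    left_ok <- i == 1 || a[i - 1] < a[i]
    right_ok <- j == n || a[j + 1] < a[i]
    if (left_ok && right_ok) cand <- c(cand, i)
    i <- j + 1
  }
  # prominence: each candidate must rise >= epsilon above the larger of the
  # minima separating it from higher ground (or the file ends)
  keep <- vapply(cand, function(k) {
    lmin <- if (k > 1) min(a[1:(k - 1)]) else NA
    rmin <- if (k < n) min(a[(k + 1):n]) else NA
    a[k] - max(lmin, rmin, na.rm = TRUE) >= epsilon
  }, logical(1))
  cand[keep]
}

# residual function of the 1D system in packed coordinates, with alpha as a
# free parameter (used by stability and continuation)
make_f_1d <- function(p, N) {
  function(x, alpha = p$alpha) {
    r <- rhs_1d_raw(x[seq_len(N)], x[N + seq_len(N)],
                    p, alpha = alpha)
    c(r$da, r$dPIN)
  }
}

#' Leading eigenvalue of a steady state
#'
#' Maximal real part of the Jacobian spectrum of the 1D minimal model at a
#' stationary profile; negative means linear (asymptotic) stability.
#'
#' @param p an [transport_params()] object.
#' @param steady a [profile1d()] at (approximate) stationarity.
#' @return the leading eigenvalue real part (1/tu).
#' @export
stability <- function(p, steady) {
  stopifnot(inherits(steady, "profile1d"))
  J <- jac_1d_raw(steady$a, steady$PIN, p)
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Pseudo-arclength continuation of 1D steady states
#'
#' Follows the branch of stationary solutions as one transport parameter
#' varies, through folds, using a secant predictor and a Newton corrector
#' on the system augmented with an arclength constraint. Steps adapt to
#' corrector performance; folds are detected as sign changes of the
#' parameter's arclength derivative; the leading eigenvalue is computed at
#' every accepted point.
#'
#' @param p an [transport_params()] object (the varied parameter's entry is
#'   the branch start).
#' @param param_name name of the varied parameter (e.g. `"alpha"`, `"K0"`).
#' @param range numeric length-2: parameter interval to cover.
#' @param N number of cells.
#' @param start optional converged starting [profile1d()] at `range[1]`;
#'   computed by [steady_state_1d()] if omitted.
#' @param ds0 initial arclength step; `ds_max`/`ds_min` bound adaptation.
#' @param max_points safety cap on branch length.
#' @param compute_stability logical; leading eigenvalues are costly on long
#'   branches and can be disabled.
#' @return object of class `continuation_branch`: data.frame `points` with
#'   columns `param`, per-state summary columns (`a_max`, `max_cell`,
#'   `a1`), `leading_eig`, `stable`; list `profiles` of [profile1d()];
#'   `folds`, the parameter values where the branch turns.
#' @export
continue_branch <- function(p, param_name = "alpha", range = c(0.01, 2),
                            N = 50, start = NULL, ds0 = 0.02,
                            ds_max = 0.25, ds_min = 1e-7, max_points = 4000,
                            compute_stability = TRUE) {
  if (!param_name %in% names(p)) stop("unknown parameter ", param_name)
  lam0 <- range[1]
  p0 <- p; p0[[param_name]] <- lam0
  if (is.null(start)) {
    ss <- steady_state_1d(p0, N = N)
    if (!ss$converged) stop("no converged steady state at range start")
    start <- ss$profile
  }
  N <- start$N
  f_aug <- function(x, lam) {
    pp <- p; pp[[param_name]] <- lam
    r <- rhs_1d_raw(x[seq_len(N)], x[N + seq_len(N)], pp)
    c(r$da, r$dPIN)
  }
  # scale the parameter direction so steps are comparable to state changes
  w_lam <- 1
  xs <- list(c(c(start$a, start$PIN), lam0))
  jac_state <- function(x, lam) {
    pp <- p; pp[[param_name]] <- lam
    jac_1d_raw(x[seq_len(N)], x[N + seq_len(N)], pp)
  }
  # derivative of the field in the continuation parameter
  dF_dlam <- function(x, lam) {
    if (param_name == "alpha") {
      d <- numeric(2 * N); d[N] <- 1
      d
    } else {
      h <- 1e-7 * max(1, abs(lam))
      (f_aug(x, lam + h) - f_aug(x, lam - h)) / (2 * h)
    }
  }
  # second point: natural continuation a small parameter step away
  dlam <- ds0 * sign(diff(range))
  ns <- newton_solve(function(x) f_aug(x, lam0 + dlam), xs[[1]][1:(2 * N)],
                     jac = function(x) jac_state(x, lam0 + dlam),
                     tol = 1e-10)
  if (!ns$converged) stop("could not take the first continuation step")
  xs[[2]] <- c(ns$x, lam0 + dlam)
  ds <- ds0
  repeat {
    k <- length(xs)
    if (k >= max_points) break
    lam_cur <- xs[[k]][2 * N + 1]
    if ((lam_cur - range[2]) * sign(diff(range)) >= 0) break
    tan_vec <- xs[[k]] - xs[[k - 1]]
    tl <- sqrt(sum(tan_vec[1:(2 * N)]^2) + w_lam * tan_vec[2 * N + 1]^2)
    tan_vec <- tan_vec / tl
    pred <- xs[[k]] + ds * tan_vec
    g <- function(z) {
      c(f_aug(z[1:(2 * N)], z[2 * N + 1]),
        sum((z - xs[[k]])[1:(2 * N)] * tan_vec[1:(2 * N)]) +
          w_lam * (z - xs[[k]])[2 * N + 1] * tan_vec[2 * N + 1] - ds)
    }
    g_jac <- function(z) {
      x <- z[1:(2 * N)]; lam <- z[2 * N + 1]
      rbind(cbind(jac_state(x, lam), dF_dlam(x, lam)),
            c(tan_vec[1:(2 * N)], w_lam * tan_vec[2 * N + 1]))
    }
    ns <- newton_solve(g, pred, jac = g_jac, tol = 1e-9, maxit = 12)
    if (ns$converged) {
      xs[[k + 1]] <- ns$x
      if (ns$iterations <= 3) ds <- min(ds * 1.5, ds_max)
    } else {
      ds <- ds / 2
      if (ds < ds_min) {
        warning("continuation step collapsed at ", param_name, " = ",
                signif(lam_cur, 6))
        break
      }
    }
  }
  lam <- vapply(xs, function(z) z[2 * N + 1], numeric(1))
  profiles <- lapply(xs, function(z)
    profile1d(pmax(z[seq_len(N)], 0), pmax(z[N + seq_len(N)], 0)))
  lead <- rep(NA_real_, length(xs))
  if (compute_stability) {
    for (k in seq_along(xs)) {
      pp <- p; pp[[param_name]] <- lam[k]
      lead[k] <- stability(pp, profiles[[k]])
    }
  }
  # folds: sign changes of d(param)/ds
  dl <- diff(lam)
  folds <- lam[1 + which(dl[-1] * dl[-length(dl)] < 0)]
  pts <- data.frame(
    param = lam,
    a_max = vapply(profiles, function(q) max(q$a), numeric(1)),
    max_cell = vapply(profiles, function(q) which.max(q$a), numeric(1)),
    a1 = vapply(profiles, function(q) q$a[1], numeric(1)),
    leading_eig = lead,
    stable = lead < 0
  )
  structure(list(param_name = param_name, points = pts, profiles = profiles,
                 folds = folds),
            class = "continuation_branch")
}

#' @export
print.continuation_branch <- function(x, ...) {
  cat("Continuation branch in '", x$param_name, "': ", nrow(x$points),
      " points, ", x$param_name, " in [",
      signif(min(x$points$param), 4), ", ", signif(max(x$points$param), 4),
      "], ", length(x$folds), " folds\n", sep = "")
  invisible(x)
}

#' Count branch crossings at a parameter value
#'
#' Number of times the continuation branch crosses the vertical line at
#' `param_value` in the (parameter, component) plane — the count of
#' stationary solutions (stable and unstable) known to the branch at that
#' parameter value.
#'
#' @param branch a `continuation_branch`.
#' @param param_value the parameter value of the vertical line.
#' @return integer crossing count.
#' @export
count_solutions_at <- function(branch, param_value) {
  lam <- branch$points$param
  s <- lam - param_value
  sum(s[-1] * s[-length(s)] < 0) + sum(s == 0)
}

#' Detect sustained oscillations
#'
#' Integrates the 1D minimal model past a transient and measures, per
#' cell, the peak-to-trough amplitude over the measurement window; the
#' dominant period is estimated from the mean spacing of the peaks of the
#' highest-amplitude cell.
#'
#' @param p an [transport_params()] object.
#' @param init initial [profile1d()] (e.g. a steady state just past the
#'   critical influx).
#' @param t_transient time discarded before measuring (tu).
#' @param t_measure measurement window (tu); should cover several periods.
#' @param n_out number of output samples in the window.
#' @param traj optional precomputed `trajectory1d` covering the window
#'   (overrides the integration; used for synthetic signals).
#' @return object of class `oscillation_report`: `amplitude` (per-cell
#'   cu), `period` (tu, `NA` if no oscillation), `oscillating` (logical),
#'   and `transient` used.
#' @export
detect_oscillation <- function(p, init, t_transient = 2000, t_measure = 2000,
                               n_out = 2000, traj = NULL) {
  if (is.null(traj)) {
    warm <- integrate_1d(init, p, t_end = t_transient,
                         times = c(0, t_transient))
    traj <- integrate_1d(final_state(warm), p, t_end = t_measure,
                         times = seq(0, t_measure, length.out = n_out))
  }
  amp <- apply(traj$a, 2, function(v) max(v) - min(v))
  osc <- max(amp) > 1e-4
  period <- NA_real_
  if (osc) {
    v <- traj$a[, which.max(amp)]
    pk <- which(diff(sign(diff(v))) == -2) + 1
    thr <- min(v) + 0.5 * (max(v) - min(v))
    pk <- pk[v[pk] > thr]
    if (length(pk) >= 2) period <- mean(diff(traj$times[pk]))
  }
  structure(list(amplitude = amp, period = period, oscillating = osc,
                 transient = t_transient),
            class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  if (x$oscillating)
    cat(sprintf("Oscillation: peak amplitude %.4g cu (cell %d), period %.4g tu\n",
                max(x$amplitude), which.max(x$amplitude), x$period))
  else cat("No sustained oscillation detected\n")
  invisible(x)
}

#' Single-cell perturbation tolerance
#'
#' Measures the homeostatic capacity of the auxin pattern: the smallest
#' auxin addition to one cell that, after relaxation back to stationarity,
#' leaves the global maximum in a different cell. Scanned on a coarse grid
#' and refined by bisection.
#'
#' @param p an [transport_params()] object.
#' @param base_state a stable stationary [profile1d()].
#' @param cell cell index perturbed (default: the maximum cell).
#' @param grid_max largest perturbation tried (cu).
#' @param step coarse grid step (cu).
#' @param refine bisection refinement width (cu).
#' @param t_relax relaxation horizon (tu).
#' @return list: `threshold` (cu; `Inf` if no grid point shifts the
#'   maximum), `shifted_to` (new maximum cell at threshold, `NA` if none).
#' @export
perturbation_tolerance <- function(p, base_state, cell = NULL, grid_max = 10,
                                   step = 0.25, refine = 0.05,
                                   t_relax = 4000) {
  stopifnot(inherits(base_state, "profile1d"))
  if (is.null(cell)) cell <- which.max(base_state$a)
  base_max <- which.max(base_state$a)
  relaxed_max <- function(delta) {
    st <- perturb_cell(base_state, cell, delta)
    ss <- steady_state_1d(p, init = st, t_relax = t_relax)
    if (!ss$converged) return(NA_integer_)
    which.max(ss$profile$a)
  }
  shifts <- function(delta) {
    m <- relaxed_max(delta)
    !is.na(m) && m != base_max
  }
  deltas <- seq(step, grid_max, by = step)
  hit <- NA_real_
  for (d in deltas) if (shifts(d)) { hit <- d; break }
  if (is.na(hit)) return(list(threshold = Inf, shifted_to = NA_integer_))
  lo <- hit - step; hi <- hit
  while (hi - lo > refine) {
    mid <- (lo + hi) / 2
    if (shifts(mid)) hi <- mid else lo <- mid
  }
  list(threshold = hi, shifted_to = relaxed_max(hi))
}

#' Compare a model profile with a digitized reporter profile
#'
#' Least-squares affine match of the model auxin profile to a digitized
#' staining-density profile (the reporter responds proportionally but sits
#' on a background, hence scale plus nonnegative offset). The reference is
#' linearly resampled to the model's cell count if the lengths differ.
#'
#' @param model a [profile1d()] or numeric vector.
#' @param reference numeric vector of intensities, or a 2-column
#'   data.frame (position, intensity).
#' @return list: `rmse`, `scale`, `offset`, `fitted` (scaled model).
#' @export
compare_profile <- function(model, reference) {
  m <- if (inherits(model, "profile1d")) model$a else as.numeric(model)
  if (is.data.frame(reference)) {
    pos <- reference[[1]]; val <- reference[[2]]
    reference <- stats::approx(pos, val, xout = seq(min(pos), max(pos),
                                                    length.out = length(m)))$y
  }
  r <- as.numeric(reference)
  if (length(r) != length(m))
    r <- stats::approx(seq_along(r), r, xout = seq(1, length(r),
                                                   length.out = length(m)))$y
  fit <- stats::lm(r ~ m)
  off <- coef(fit)[1]; sc <- coef(fit)[2]
  if (off < 0) {      # reporter background cannot be negative
    off <- 0
    sc <- sum(m * r) / sum(m * m)
  }
  fitted <- sc * m + off
  list(rmse = sqrt(mean((fitted - r)^2)), scale = unname(sc),
       offset = unname(off), fitted = fitted)
}

#' Coordinatewise-descent parameter fitting
#'
#' Cyclic golden-section line searches, one parameter at a time within
#' bounds, until a full cycle improves the objective by less than `tol`
#' (relative). Deterministic given the starting point and cycle order. A
#' coordinate whose line search moves far while the objective stays flat
#' is reported in `flat` — the signature of a non-identifiable direction —
#' and the fit is then not flagged as converged.
#'
#' @param objective function of a named numeric vector, returning a scalar.
#' @param p0 named numeric starting vector.
#' @param lower,upper named bounds (same names as `p0`).
#' @param tol relative improvement threshold per cycle (default 1e-8).
#' @param max_cycles cap on full cycles.
#' @param check_identifiability logical; probe the objective's curvature at
#'   the solution and flag near-null directions.
#' @param line_tol absolute tolerance of each golden-section line search.
#' @return list: `par`, `value`, `converged`, `cycles`, `flat` (character
#'   vector of coordinates spanning a near-flat objective direction).
#' @export
coordinate_descent_fit <- function(objective, p0, lower, upper, tol = 1e-8,
                                   max_cycles = 60,
                                   check_identifiability = TRUE,
                                   line_tol = 1e-10) {
  par <- p0
  val <- objective(par)
  if (!is.finite(val)) stop("objective not finite at the starting point")
  cycles <- 0
  repeat {
    cycles <- cycles + 1
    val_start <- val
    for (nm in names(par)) {
      obj1 <- function(x) { q <- par; q[nm] <- x; objective(q) }
      opt <- stats::optimize(obj1, lower = lower[nm], upper = upper[nm],
                             tol = line_tol)
      if (opt$objective < val) { par[nm] <- opt$minimum; val <- opt$objective }
    }
    improv <- (val_start - val) / max(1, abs(val_start))
    if (improv < tol || cycles >= max_cycles) break
  }
  # identifiability probe: a finite-difference Hessian whose spectrum has a
  # near-null direction signals a flat valley the cyclic search cannot see
  # (e.g. two parameters entering the model only through their product)
  flat <- character(0)
  if (check_identifiability && length(par) > 1) {
    n <- length(par)
    h <- pmax(1e-4 * (upper - lower), 1e-10)
    H <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(i)) {
      pp <- function(si, sj) {
        q <- par
        q[i] <- q[i] + si * h[i]; q[j] <- q[j] + sj * h[j]
        objective(q)
      }
      H[i, j] <- H[j, i] <-
        (pp(1, 1) - pp(1, -1) - pp(-1, 1) + pp(-1, -1)) / (4 * h[i] * h[j])
    }
    ev <- eigen(H, symmetric = TRUE)
    lam <- abs(ev$values)
    if (min(lam) < 1e-8 * max(lam, 1e-300)) {
      v <- ev$vectors[, which.min(lam)]
      flat <- names(par)[abs(v) > 0.3]
    }
  }
  list(par = par, value = val,
       converged = cycles < max_cycles && length(flat) == 0,
       cycles = cycles, flat = flat)
}
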