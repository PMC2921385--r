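#' Growing-root state
#'
#' The hybrid model couples continuous dynamics (auxin, PIN1, Division
#' Factor concentrations, cell sizes) with discrete stochastic events
#' (growth-phase completion, division, sloughing) on a cell file whose
#' length changes over time. Cells are ordered with cell 1 at the root end;
#' the x axis points from the outer wall of cell 1 towards the base, and
#' each cell's centre coordinate is the cumulative size of the cells distal
#' to it plus half its own size.
#'
#' A `root_state` is a list with fields `time`, per-cell vectors `id`, `r`
#' (size), `phase` (`"growth"`/`"idle"`), `a`, `PIN`, `DivF`, per-cell
#' hazard accumulators `acc` and exponential thresholds `thr`, the
#' parameter bundle, a flux schedule, and an event log.
#'
#' @name root_state
NULL

#' Initialise a growing root
#'
#' Starts the hybrid simulation from a few cells with the auxin maximum
#' placed in cell 2, the configuration of the embryonic root apical
#' meristem. All cells start in growth phase at birth size `r0`; PIN1 and
#' Division Factor start at zero.
#'
#' @param set parameter set from [param_preset()] (or a list with elements
#'   `transport`, `divf`, `cycle`).
#' @param n_cells initial cell count (default 3, minimum 2).
#' @param a_init optional auxin initial condition; default zero except
#'   `a_max` in cell 2.
#' @param a_max auxin seeded in cell 2 (cu, default 2).
#' @param schedule a [flux_schedule()]; default constant at the transport
#'   parameter `alpha`.
#' @param slough_cap sloughing policy: cell 1 is removed whenever more than
#'   `slough_cap` cells lie distal to the global auxin maximum. `Inf`
#'   disables sloughing. Removals are rate limited: the running simulation
#'   checks the policy at most once every `slough_dt` time units (25 tu),
#'   so cap turnover cannot outpace division.
#' @return an object of class `root_state`.
#' @export
init_root <- function(set, n_cells = 3, a_init = NULL, a_max = 2,
                      schedule = NULL, slough_cap = 5) {
  if (n_cells < 2) stop("need at least 2 cells")
  if (is.null(a_init)) {
    a_init <- rep(0, n_cells)
    a_init[2] <- a_max
  }
  if (length(a_init) != n_cells || any(a_init < 0))
    stop("a_init must be ", n_cells, " nonnegative values")
  if (is.null(schedule)) schedule <- flux_schedule(set$transport$alpha, 0)
  n <- n_cells
  structure(list(
    time = 0,
    id = seq_len(n), next_id = n + 1L,
    r = rep(set$cycle$r0, n),
    phase = rep("growth", n),
    a = a_init, PIN = rep(0, n), DivF = rep(0, n),
    acc = rep(0, n), thr = stats::rexp(n),
    params = set, schedule = schedule, slough_cap = slough_cap,
    slough_dt = 25, last_slough = -Inf,
    events = data.frame(time = numeric(0), event = character(0),
                        cell_id = integer(0), index = integer(0))
  ), class = "root_state")
}

#' @export
print.root_state <- function(x, ...) {
  cat("Growing root at t =", format(x$time, digits = 6), "tu:",
      length(x$a), "cells, length", format(sum(x$r), digits = 4), "\n")
  cat(sprintf("  auxin max %.3g cu in cell %d; %d events logged\n",
              max(x$a), which.max(x$a), nrow(x$events)))
  invisible(x)
}

#' Cell centre coordinates
#'
#' @param root a `root_state`.
#' @return numeric vector of x coordinates (origin at the outer wall of
#'   cell 1).
#' @export
cell_positions <- function(root) cumsum(root$r) - root$r / 2

#' Division Factor derivatives on a cell file
#'
#' Per-cell rate of change of the Division Factor: gradient-driven
#' synthesis (zero in the basal-most cell, whose gradient is undefined),
#' auxin-dependent degradation, and diffusion with one-sided boundaries.
#'
#' @param a,DivF per-cell auxin and Division Factor concentrations (cu).
#' @param dp a [divf_params()] object.
#' @return numeric vector of dDivF/dt (cu/tu).
#' @export
divf_rhs <- function(a, DivF, dp) {
  N <- length(a)
  syn <- divf_synthesis_rate(a, c(a[-1], 0), dp,
                             is_boundary = c(rep(FALSE, N - 1), TRUE))
  deg <- dp$kdeg * DivF * (1 + (pmax(a, 0) / dp$q4)^dp$h3) /
    (1 + (pmax(a, 0) / dp$q5)^dp$h4)
  dD <- syn - deg
  d <- dp$D_DivF * diff(DivF)
  dD[-N] <- dD[-N] + d
  dD[-1] <- dD[-1] - d
  dD
}

# Full continuous-part derivative of the hybrid model. Growth dilutes all
# intensive concentrations at rate (dr/dt)/r.
rhs_ext <- function(a, PIN, DivF, r, growing, set, alpha_t) {
  p <- set$transport
  tr <- rhs_1d_raw(a, PIN, p, alpha = alpha_t)
  dD <- divf_rhs(pmax(a, 0), DivF, set$divf)
  dr <- ifelse(growing, set$cycle$K_growth, 0)
  dil <- dr / r
  list(da = tr$da - dil * a, dPIN = tr$dPIN - dil * PIN,
       dDivF = dD - dil * DivF, dr = dr)
}

# Per-cell completion hazard of the currently active phase.
phase_hazard <- function(root) {
  growing <- root$phase == "growth"
  h <- numeric(length(root$a))
  cp <- root$params$cycle
  if (any(growing)) h[growing] <- f_gp(root$r[growing], cp)
  if (any(!growing)) h[!growing] <- f_ip(pmax(root$DivF[!growing], 0), cp)
  h
}

# One RK4 sub-step of length dt from the given continuous state; returns the
# updated continuous fields. Hazards are handled outside.
rk4_step <- function(root, dt, alpha_fun) {
  g <- root$phase == "growth"
  set <- root$params
  y <- list(a = root$a, PIN = root$PIN, DivF = root$DivF, r = root$r)
  t0 <- root$time
  k1 <- rhs_ext(y$a, y$PIN, y$DivF, y$r, g, set, alpha_fun(t0))
  adv <- function(f, h) list(a = y$a + h * f$da, PIN = y$PIN + h * f$dPIN,
                             DivF = y$DivF + h * f$dDivF, r = y$r + h * f$dr)
  y2 <- adv(k1, dt / 2)
  k2 <- rhs_ext(y2$a, y2$PIN, y2$DivF, y2$r, g, set, alpha_fun(t0 + dt / 2))
  y3 <- adv(k2, dt / 2)
  k3 <- rhs_ext(y3$a, y3$PIN, y3$DivF, y3$r, g, set, alpha_fun(t0 + dt / 2))
  y4 <- adv(k3, dt)
  k4 <- rhs_ext(y4$a, y4$PIN, y4$DivF, y4$r, g, set, alpha_fun(t0 + dt))
  w <- dt / 6
  list(a = y$a + w * (k1$da + 2 * k2$da + 2 * k3$da + k4$da),
       PIN = y$PIN + w * (k1$dPIN + 2 * k2$dPIN + 2 * k3$dPIN + k4$dPIN),
       DivF = y$DivF + w * (k1$dDivF + 2 * k2$dDivF + 2 * k3$dDivF + k4$dDivF),
       r = y$r + w * (k1$dr + 2 * k2$dr + 2 * k3$dr + k4$dr))
}

# stability-limited step: the stiffest local rate is the thresholded PIN1
# degradation; diffusion and transport contribute a tridiagonal bound.
stable_dt <- function(root, dt_max) {
  p <- root$params$transport
  lam <- max(p$k2 * (1 + (pmax(root$a, 0) / p$q3)^p$h2),
             4 * p$D + p$K0 * max(root$PIN * pmax(root$a, 0)) / max(root$a, 1e-8),
             4 * root$params$divf$D_DivF, p$Kd, 1e-8)
  min(dt_max, 2.5 / lam)
}

#' Divide a cell
#'
#' Replaces cell `i` by two daughters of half its size. Daughters inherit
#' the mother's concentrations unchanged (intensive inheritance, so amounts
#' `a * r` are conserved exactly), enter growth phase immediately, and draw
#' fresh completion thresholds. Cells are renumbered by their order on the
#' x axis.
#'
#' @param root a `root_state`.
#' @param i index of the dividing cell.
#' @return the updated `root_state`.
#' @export
divide <- function(root, i) {
  n <- length(root$a)
  if (i < 1 || i > n) stop("cell index out of range")
  ins <- function(v, val1, val2) append(v[-i], c(val1, val2), after = i - 1)
  half <- root$r[i] / 2
  root$events <- rbind(root$events,
                       data.frame(time = root$time, event = "division",
                                  cell_id = root$id[i], index = i))
  root$r <- ins(root$r, half, half)
  root$a <- ins(root$a, root$a[i], root$a[i])
  root$PIN <- ins(root$PIN, root$PIN[i], root$PIN[i])
  root$DivF <- ins(root$DivF, root$DivF[i], root$DivF[i])
  root$phase <- ins(root$phase, "growth", "growth")
  root$acc <- ins(root$acc, 0, 0)
  root$thr <- ins(root$thr, stats::rexp(1), stats::rexp(1))
  root$id <- as.integer(ins(root$id, root$next_id, root$next_id + 1L))
  root$next_id <- root$next_id + 2L
  root
}

#' Slough the distal-most cell
#'
#' Root-cap turnover policy: when the number of cells distal to the global
#' auxin maximum exceeds the configured cap, cell 1 (the outermost root-cap
#' cell) is removed and its auxin amount leaves the system. One cell at
#' most is removed per check.
#'
#' @param root a `root_state`.
#' @param cap maximum allowed number of cells distal to the auxin maximum;
#'   defaults to the policy stored in the state. `Inf` disables sloughing.
#' @return the (possibly shortened) `root_state`.
#' @export
slough <- function(root, cap = root$slough_cap) {
  imax <- which.max(root$a)
  n_distal <- imax - 1L
  # turnover applies beneath an established distal maximum; a maximum at
  # the basal boundary cell (a base-heavy profile) is not one
  if (is.finite(cap) && n_distal > cap && imax < length(root$a) &&
      length(root$a) > 2) {
    root$events <- rbind(root$events,
                         data.frame(time = root$time, event = "removal",
                                    cell_id = root$id[1], index = 1L))
    for (f in c("id", "r", "a", "PIN", "DivF", "phase", "acc", "thr"))
      root[[f]] <- root[[f]][-1]
  }
  root
}

# fire the phase-completion event of cell i (growth -> idle, idle -> divide)
fire_event <- function(root, i) {
  if (root$phase[i] == "growth") {
    root$events <- rbind(root$events,
                         data.frame(time = root$time, event = "phase_change",
                                    cell_id = root$id[i], index = i))
    root$phase[i] <- "idle"
    root$acc[i] <- 0
    root$thr[i] <- stats::rexp(1)
  } else {
    root <- divide(root, i)
  }
  root
}

#' Advance the hybrid simulation by one step
#'
#' Takes one stability-limited 4th-order Runge-Kutta step (at most
#' `dt_max`), accumulating each cell's phase-completion hazard along the
#' way. If an accumulator crosses its pre-drawn exponential threshold
#' within the step, the step is split at the crossing time (bisection to
#' 1e-6 tu), the event (phase change or division) is applied atomically,
#' and the remainder of the interval is left for subsequent calls. If a
#' concentration would go negative the step is retried with half the step
#' size.
#'
#' @param root a `root_state`.
#' @param dt_max maximum step size (tu).
#' @return the advanced `root_state` (its `events` field accumulates the
#'   event log).
#' @export
step_hybrid <- function(root, dt_max = 0.01) {
  alpha_fun <- function(t) flux_schedule_eval(root$schedule, t)
  dt <- stable_dt(root, dt_max)
  h0 <- phase_hazard(root)

  advance_by <- function(dt) {
    y <- rk4_step(root, dt, alpha_fun)
    if (any(y$a < -1e-9) || any(y$PIN < -1e-9) || any(y$DivF < -1e-9))
      return(NULL)
    y
  }
  y <- advance_by(dt)
  tries <- 0
  while (is.null(y) && tries < 40) {
    dt <- dt / 2; tries <- tries + 1
    y <- advance_by(dt)
  }
  if (is.null(y)) stop("step rejection did not resolve negativity at t = ",
                       root$time)
  trial <- root
  trial$a <- pmax(y$a, 0); trial$PIN <- pmax(y$PIN, 0)
  trial$DivF <- pmax(y$DivF, 0); trial$r <- y$r
  h1 <- phase_hazard(trial)
  inc <- (h0 + h1) / 2 * dt
  crossing <- which(root$acc + inc >= root$thr)

  if (length(crossing) == 0) {
    trial$acc <- root$acc + inc
    trial$time <- root$time + dt
    return(slough_check(trial))
  }

  # locate the earliest crossing by bisection on the sub-step length
  lo <- 0; hi <- dt
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    ym <- rk4_step(root, mid, alpha_fun)
    tm <- root
    tm$a <- pmax(ym$a, 0); tm$PIN <- pmax(ym$PIN, 0)
    tm$DivF <- pmax(ym$DivF, 0); tm$r <- ym$r
    hm <- phase_hazard(tm)
    im <- (h0 + hm) / 2 * mid
    if (any(root$acc + im >= root$thr)) hi <- mid else lo <- mid
  }
  ye <- rk4_step(root, hi, alpha_fun)
  out <- root
  out$a <- pmax(ye$a, 0); out$PIN <- pmax(ye$PIN, 0)
  out$DivF <- pmax(ye$DivF, 0); out$r <- ye$r
  he <- phase_hazard(out)
  out$acc <- root$acc + (h0 + he) / 2 * hi
  out$time <- root$time + hi
  i <- which(out$acc >= out$thr)[1]
  out <- fire_event(out, i)
  slough_check(out)
}

# rate-limited sloughing used by the stepper
slough_check <- function(root) {
  if (root$time - root$last_slough < root$slough_dt) return(root)
  n0 <- length(root$a)
  root <- slough(root)
  if (length(root$a) < n0) root$last_slough <- root$time
  root
}

#' Run the hybrid growing-root simulation
#'
#' Repeatedly calls [step_hybrid()] until `t_end`, optionally recording
#' snapshots. All randomness (phase-completion thresholds) flows through
#' R's RNG; set a seed beforehand (or pass `seed`) for reproducibility.
#'
#' @param root a `root_state` from [init_root()].
#' @param t_end simulation horizon (tu).
#' @param dt_max maximum RK4 step (tu). The effective step is additionally
#'   stability-limited by the sharp PIN1 degradation term.
#' @param snapshot_dt interval between recorded snapshots (tu); `Inf`
#'   records only the final state.
#' @param seed optional integer seed applied before the run.
#' @return list of class `root_run`: `root` (final state), `events`
#'   (the event log), and `snapshots`, a long-format data.frame with
#'   columns time, cell_id, index, x, r, phase, a, PIN, DivF.
#' @export
simulate_root <- function(root, t_end, dt_max = 0.01, snapshot_dt = Inf,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snaps <- list()
  take_snap <- function(root) {
    data.frame(time = root$time, cell_id = root$id,
               index = seq_along(root$a), x = cell_positions(root),
               r = root$r, phase = root$phase,
               a = root$a, PIN = root$PIN, DivF = root$DivF)
  }
  next_snap <- if (is.finite(snapshot_dt)) snapshot_dt else Inf
  snaps[[1]] <- take_snap(root)
  while (root$time < t_end) {
    root <- step_hybrid(root, dt_max = min(dt_max, t_end - root$time))
    if (root$time >= next_snap) {
      snaps[[length(snaps) + 1L]] <- take_snap(root)
      next_snap <- next_snap + snapshot_dt
    }
  }
  if (snaps[[length(snaps)]]$time[1] < root$time)
    snaps[[length(snaps) + 1L]] <- take_snap(root)
  structure(list(root = root, events = root$events,
                 snapshots = do.call(rbind, snaps)),
            class = "root_run")
}

#' @export
print.root_run <- function(x, ...) {
  print(x$root)
  ev <- table(x$events$event)
  if (length(ev)) cat("  events:", paste(names(ev), ev, collapse = ", "), "\n")
  invisible(x)
}

#' Per-position division rates from an event log
#'
#' Bins division events by the cell index at which they occurred and
#' divides by the window length, giving divisions per cell position per
#' unit time. Along an established root the profile is bimodal: one peak
#' at the root-cap initial and one in the meristematic zone, with the
#' quiescent centre silent between them.
#'
#' @param events an event log (data.frame with `time`, `event`, `index`).
#' @param window numeric length-2 vector, the time window analysed.
#' @param positions integer vector of positions to report (default: up to
#'   the largest index seen).
#' @return data.frame with columns `index` and `rate` (divisions/tu).
#' @export
division_rate_profile <- function(events, window, positions = NULL) {
  if (diff(window) <= 0) stop("window must have positive length")
  div <- events[events$event == "division" &
                  events$time >= window[1] & events$time <= window[2], ]
  if (is.null(positions))
    positions <- seq_len(max(c(div$index, 1L)))
  counts <- tabulate(factor(div$index, levels = positions),
                     nbins = length(positions))
  data.frame(index = positions, rate = counts / diff(window))
}

#' Classify cells of an established root
#'
#' Assigns root-zone identities from the two morphogen gradients and the
#' observed division activity, mirroring how positional information is read
#' out along the axis: cells distal to the global auxin maximum are
#' columella; the maximum cell itself is the root-cap initial; the next
#' proximal cell is the quiescent centre; then rarely-dividing vascular
#' initials, the actively dividing meristematic zone, and finally the
#' non-dividing differentiation zone.
#'
#' @param root a `root_state`.
#' @param events event log covering `window`.
#' @param window length-2 time window used to estimate division rates.
#' @param active_frac fraction of the peak division rate above which a cell
#'   counts as actively dividing (default 0.25).
#' @return character vector of labels, one per cell: `"columella"`,
#'   `"root_cap_initial"`, `"QC"`, `"vascular_initial"`, `"meristem"`,
#'   `"differentiation"`.
#' @export
classify_cells <- function(root, events, window, active_frac = 0.25) {
  if (diff(window) <= 0) stop("window too short to estimate division rates")
  n <- length(root$a)
  prof <- division_rate_profile(events, window, positions = seq_len(n))
  rate <- prof$rate
  thr <- active_frac * max(rate, 1e-12)
  active <- rate >= thr & rate > 0
  lab <- rep("differentiation", n)
  imax <- which.max(root$a)
  # distal, non-dividing, high-auxin run: columella; dividing cells there
  # do not qualify
  if (imax > 1) lab[seq_len(imax - 1)] <- ifelse(active[seq_len(imax - 1)],
                                                 "meristem", "columella")
  lab[imax] <- if (active[imax]) "meristem" else "root_cap_initial"
  if (imax + 1 <= n) lab[imax + 1] <- if (active[imax + 1]) "meristem" else "QC"
  if (imax + 2 <= n) {
    rest <- seq(imax + 2, n)
    if (any(active[rest])) {
      first_active <- rest[which(active[rest])[1]]
      last_active <- rest[max(which(active[rest]))]
      if (first_active > imax + 2)
        lab[seq(imax + 2, first_active - 1)] <- "vascular_initial"
      lab[seq(first_active, last_active)] <- "meristem"
      if (last_active < n) lab[seq(last_active + 1, n)] <- "differentiation"
    } else {
      lab[rest] <- "differentiation"
    }
  }
  lab
}
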