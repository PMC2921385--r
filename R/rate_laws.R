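#' @title Elementary rate laws of the auxin/PIN1 system
#' @description
#' Pure, side-effect-free rate functions from which the 1D and 2D models are
#' assembled. Negative concentrations raise errors rather than being clamped,
#' so that integrator failures surface immediately.
#' @name rate_laws
NULL

check_nonneg <- function(x, what) {
  if (any(x < 0)) stop(what, " must be nonnegative (got ", min(x), ")")
  invisible(x)
}

#' Auxin influx rate from the shoot
#'
#' Constant in the minimal models; in the growing-root model the influx is
#' evaluated from a [flux_schedule()] at the current time.
#'
#' @param p an [transport_params()] object (or any list with `$alpha`).
#' @return influx rate alpha (cu/tu).
#' @export
auxin_influx_rate <- function(p) p$alpha

#' First-order auxin degradation rate
#'
#' Summarises conjugation, oxidation and lateral losses from the modelled
#' cell file as one first-order sink, `Kd * a`.
#'
#' @param a auxin concentration (cu); vectorised.
#' @param p parameters with `$Kd`.
#' @return degradation rate (cu/tu).
#' @export
auxin_degradation_rate <- function(a, p) {
  check_nonneg(a, "auxin concentration")
  p$Kd * a
}

#' Cell-to-cell diffusion rate
#'
#' Rate of change of the concentration in cell i due to passive exchange with
#' a neighbour j: `D * (a_j - a_i)`. Antisymmetric in (i, j), so summed over
#' a donor/acceptor pair the contribution cancels exactly.
#'
#' @param a_i,a_j concentrations in the receiving and neighbouring cell (cu).
#' @param D diffusion rate constant (1/tu).
#' @return rate of change of `a_i` (cu/tu); may be negative.
#' @export
diffusion_rate <- function(a_i, a_j, D) {
  check_nonneg(a_i, "concentration"); check_nonneg(a_j, "concentration")
  D * (a_j - a_i)
}

#' PIN1-mediated active transport rate
#'
#' Mass-action rate `K0 * PIN * a` at which auxin is exported from a cell to
#' its distal neighbour (towards the root tip); PIN1 is polarly localised on
#' the distal membrane, so transport is strictly acropetal.
#'
#' @param a auxin concentration in the exporting cell (cu).
#' @param PIN PIN1 concentration in the exporting cell (cu).
#' @param K0 active transport rate constant (1/(cu*tu)).
#' @return export rate (cu/tu).
#' @export
active_transport_rate <- function(a, PIN, K0) {
  check_nonneg(a, "auxin concentration"); check_nonneg(PIN, "PIN1 concentration")
  K0 * PIN * a
}

#' Auxin-activated PIN1 synthesis rate
#'
#' Generalized Hill function
#' \deqn{V_{syn}(a) = k_1 \frac{(a/q_1)^{h_1}}{1 + (a/q_1)^{h_1} + (a/q_2)^{h_1}}}
#' which is zero at zero auxin, strictly increasing, and saturates at the
#' finite supremum \eqn{k_1 / (1 + (q_1/q_2)^{h_1})}. `q1` sets the auxin
#' level at which synthesis turns on, `q2` the level by which it saturates.
#'
#' @param a auxin concentration (cu); vectorised.
#' @param p parameters with `$k1`, `$q1`, `$q2`, `$h1`.
#' @return synthesis rate (cu/tu).
#' @export
pin_synthesis_rate <- function(a, p) {
  check_nonneg(a, "auxin concentration")
  u <- (a / p$q1)^p$h1
  v <- (a / p$q2)^p$h1
  p$k1 * u / (1 + u + v)
}

#' Supremum of the PIN1 synthesis rate
#'
#' Closed-form limit of [pin_synthesis_rate()] as auxin grows without bound.
#'
#' @param p parameters with `$k1`, `$q1`, `$q2`, `$h1`.
#' @return the finite supremum (cu/tu).
#' @export
pin_synthesis_sup <- function(p) p$k1 / (1 + (p$q1 / p$q2)^p$h1)

#' Auxin-enhanced PIN1 degradation rate
#'
#' Rational polynomial
#' \deqn{V_{deg}(a, PIN) = k_2 \, PIN \, (1 + (a/q_3)^{h_2})}
#' monotone nondecreasing in both arguments: at `a = 0` it reduces to basal
#' turnover `k2 * PIN`, and once auxin exceeds the threshold `q3` degradation
#' rises steeply (the steeper the larger `h2`). It vanishes at `PIN = 0`,
#' which keeps PIN1 trajectories nonnegative.
#'
#' @param a auxin concentration (cu); vectorised.
#' @param PIN PIN1 concentration (cu); vectorised.
#' @param p parameters with `$k2`, `$q3`, `$h2`.
#' @return degradation rate (cu/tu).
#' @export
pin_degradation_rate <- function(a, PIN, p) {
  check_nonneg(a, "auxin concentration"); check_nonneg(PIN, "PIN1 concentration")
  p$k2 * PIN * (1 + (a / p$q3)^p$h2)
}

#' Gradient-driven Division Factor synthesis rate
#'
#' A saturating sigmoid of the distal-ward auxin drop across a cell,
#' \deqn{V_s(a_i, a_{i+1}) = \beta \frac{g^2}{T^2 + g^2}, \qquad
#'   g = \max(a_i - a_{i+1}, 0),}
#' bounded in \[0, beta\), monotone in the drop, and zero where the profile
#' is flat or rising towards the base. Synthesis is therefore confined to
#' the proximal flank of the auxin maximum, which (combined with strong
#' degradation at high auxin) places the Division Factor peak in the cell
#' next to the auxin maximum — the quiescent centre. The basal-most cell
#' (index N) has no proximal neighbour, so its synthesis is defined as zero
#' (use `is_boundary = TRUE`).
#'
#' @param a_i auxin in the synthesising cell (cu).
#' @param a_ip1 auxin in its proximal neighbour, cell i+1 (cu).
#' @param p a [divf_params()] object.
#' @param is_boundary logical; `TRUE` for cell N, where the gradient is
#'   undefined and synthesis is zero.
#' @return synthesis rate (cu/tu).
#' @export
divf_synthesis_rate <- function(a_i, a_ip1, p, is_boundary = FALSE) {
  check_nonneg(a_i, "auxin concentration"); check_nonneg(a_ip1, "auxin concentration")
  g <- pmax(a_i - a_ip1, 0)
  r <- p$beta * g^2 / (p$T^2 + g^2)
  r[is_boundary] <- 0
  r
}

#' Auxin-dependent Division Factor degradation rate
#'
#' Generalized Hill response of the auxin level times the Division Factor
#' concentration,
#' \deqn{V_d(a, DivF) = k_{deg} \, DivF \,
#'   \frac{1 + (a/q_4)^{h_3}}{1 + (a/q_5)^{h_4}},}
#' a plateau-transition-plateau shape for `h3 = h4`: basal turnover
#' `kdeg * DivF` below the lower threshold `q4`, rising to the high plateau
#' `kdeg * DivF * (q5/q4)^h3` above the upper threshold `q5`. Vanishes at
#' `DivF = 0`. The high degradation at high auxin confines the Division
#' Factor away from the auxin maximum's distal flank, which positions its
#' own peak in the cell next to the auxin maximum.
#'
#' @param a auxin concentration (cu); vectorised.
#' @param DivF Division Factor concentration (cu); vectorised.
#' @param p a [divf_params()] object.
#' @return degradation rate (cu/tu).
#' @export
divf_degradation_rate <- function(a, DivF, p) {
  check_nonneg(a, "auxin concentration")
  check_nonneg(DivF, "Division Factor concentration")
  p$kdeg * DivF * (1 + (a / p$q4)^p$h3) / (1 + (a / p$q5)^p$h4)
}

#' Division Factor diffusion rate
#'
#' Same contract as [diffusion_rate()] with the Division Factor's own
#' diffusion constant.
#'
#' @param d_i,d_j Division Factor concentrations in the receiving and
#'   neighbouring cell (cu).
#' @param D_DivF diffusion rate constant (1/tu).
#' @return rate of change of `d_i` (cu/tu).
#' @export
divf_diffusion_rate <- function(d_i, d_j, D_DivF) {
  check_nonneg(d_i, "concentration"); check_nonneg(d_j, "concentration")
  D_DivF * (d_j - d_i)
}

#' Cell elongation rate
#'
#' `K_growth` during the growth phase, zero during the idle phase, so cell
#' size is piecewise linear in time.
#'
#' @param phase `"growth"` or `"idle"`; vectorised.
#' @param p a [cycle_params()] object.
#' @return dr/dt (length/tu).
#' @export
growth_rate <- function(phase, p) {
  if (!all(phase %in% c("growth", "idle")))
    stop("phase must be 'growth' or 'idle'")
  ifelse(phase == "growth", p$K_growth, 0)
}

#' Growth-phase completion hazard
#'
#' Instantaneous hazard of completing the growth phase at size `r`,
#' \deqn{f_{GP}(r) = k_{gp} \frac{(r/r_{min})^{h_{gp}}}{1 + (r/r_{min})^{h_{gp}}},}
#' nondecreasing in `r` and negligible below the minimal division size
#' `r_min` when the exponent is large.
#'
#' @param r cell size (length); vectorised, must be positive.
#' @param p a [cycle_params()] object.
#' @return completion hazard (1/tu).
#' @export
f_gp <- function(r, p) {
  if (any(r <= 0)) stop("cell size must be positive")
  u <- (r / p$r_min)^p$gp_exp
  p$gp_rate * u / (1 + u)
}

#' Idle-phase completion hazard
#'
#' Bell-shaped response to the Division Factor level, a generalized Hill
#' function with two exponents,
#' \deqn{f_{IP}(Y) = k_{ip} \frac{(Y/m)^{h_{up}}}{1 + (Y/m)^{h_{up}} + (Y/m)^{h_{down}}},}
#' with \eqn{h_{down} > h_{up}}: the completion hazard (hence the division
#' rate) is low at Division Factor deficiency and excess and maximal at
#' intermediate levels.
#'
#' @param DivF Division Factor concentration (cu); vectorised.
#' @param p a [cycle_params()] object.
#' @return completion hazard (1/tu).
#' @export
f_ip <- function(DivF, p) {
  check_nonneg(DivF, "Division Factor concentration")
  u <- (DivF / p$ip_mid)^p$ip_hup
  w <- (DivF / p$ip_mid)^p$ip_hdown
  p$ip_rate * u / (1 + u + w)
}
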