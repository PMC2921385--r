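#' Auxin transport parameters
#'
#' Rate constants and thresholds of the auxin/PIN1 transport system for one
#' cell file. Concentrations are measured in abstract concentration units
#' (cu) and time in time units (tu); no SI conversion is attempted.
#'
#' @param alpha auxin influx rate from the shoot into the basal cell (cu/tu).
#' @param Kd first-order auxin degradation rate constant (1/tu).
#' @param D cell-to-cell auxin diffusion rate constant (1/tu).
#' @param K0 active (PIN1-mediated) transport rate constant (1/(cu*tu)).
#' @param k1 PIN1 synthesis rate constant (cu/tu).
#' @param q1 activation threshold of auxin-dependent PIN1 synthesis (cu).
#' @param q2 saturation threshold of auxin-dependent PIN1 synthesis (cu);
#'   must satisfy `q1 <= q2`.
#' @param h1 response exponent of PIN1 synthesis (>= 1).
#' @param k2 basal PIN1 degradation rate constant (1/tu).
#' @param q3 threshold of auxin-dependent PIN1 degradation (cu).
#' @param h2 response exponent of PIN1 degradation (>= 1).
#'
#' @return An object of class `auxin_transport_params` (a validated list).
#' @seealso [param_preset()] for the bundled `"basic"` and `"robust"` sets.
#' @export
transport_params <- function(alpha, Kd, D, K0, k1, q1, q2, h1, k2, q3, h2) {
  p <- list(alpha = alpha, Kd = Kd, D = D, K0 = K0, k1 = k1,
            q1 = q1, q2 = q2, h1 = h1, k2 = k2, q3 = q3, h2 = h2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  # alpha may legitimately be zero (no influx experiments); all others > 0
  if (alpha < 0) stop("alpha must be nonnegative")
  strict <- p[setdiff(names(p), "alpha")]
  bad <- names(strict)[vapply(strict, function(v) v <= 0, logical(1))]
  if (length(bad)) stop("parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (q1 > q2) stop("q1 (activation threshold) must not exceed q2 (saturation threshold)")
  if (h1 < 1 || h2 < 1) stop("response exponents h1, h2 must be >= 1")
  structure(p, class = "auxin_transport_params")
}

#' Division Factor parameters
#'
#' The Division Factor is a hypothetical morphogen combining the inhibitory
#' action of cytokinin and the activating action of ethylene on root cell
#' division. It is synthesised in proportion to the proximal-to-distal auxin
#' gradient across a cell, degraded at an auxin-dependent rate, and diffuses
#' between neighbouring cells.
#'
#' @param beta maximal Division Factor synthesis rate (cu/tu).
#' @param T sigmoid steepness scale of the gradient-driven synthesis (cu);
#'   default 0.1.
#' @param kdeg rate coefficient of auxin-dependent degradation (1/tu).
#' @param q4 lower auxin threshold of the degradation response (cu).
#' @param q5 upper auxin threshold of the degradation response (cu).
#' @param h3,h4 Hill exponents of the degradation response (>= 1).
#' @param D_DivF Division Factor diffusion rate constant (1/tu).
#'
#' @return An object of class `divf_params`.
#' @export
divf_params <- function(beta, T = 0.1, kdeg, q4, q5, h3, h4, D_DivF) {
  p <- list(beta = beta, T = T, kdeg = kdeg, q4 = q4, q5 = q5,
            h3 = h3, h4 = h4, D_DivF = D_DivF)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single finite positive number")
  }
  if (h3 < 1 || h4 < 1) stop("Hill exponents h3, h4 must be >= 1")
  structure(p, class = "divf_params")
}

#' Cell cycle parameters
#'
#' Parameters of the two-phase cell cycle of the growing-root model: a
#' deterministic growth phase (linear elongation at rate `K_growth`) whose
#' completion hazard rises with cell size, and an idle phase whose completion
#' (division) hazard depends bell-shapedly on the Division Factor level.
#'
#' @param K_growth cell elongation rate (length/tu).
#' @param r_min minimal size allowing division (length).
#' @param r0 daughter birth size (length); must satisfy `0 < r0 < r_min`.
#' @param gp_rate hazard scale of growth-phase completion (1/tu).
#' @param gp_exp sharpness exponent of the size response of growth-phase
#'   completion; large values make completion negligible below `r_min`.
#' @param ip_rate hazard scale of idle-phase completion (1/tu).
#' @param ip_mid Division Factor level of half-activation of the idle-phase
#'   completion hazard (cu).
#' @param ip_hup rising exponent of the idle-phase response.
#' @param ip_hdown falling exponent of the idle-phase response; must exceed
#'   `ip_hup` for the response to be bell-shaped.
#'
#' @return An object of class `cycle_params`.
#' @export
cycle_params <- function(K_growth, r_min, r0, gp_rate = 1, gp_exp = 20,
                         ip_rate = 1, ip_mid = 1, ip_hup = 2, ip_hdown = 6) {
  p <- list(K_growth = K_growth, r_min = r_min, r0 = r0,
            gp_rate = gp_rate, gp_exp = gp_exp,
            ip_rate = ip_rate, ip_mid = ip_mid,
            ip_hup = ip_hup, ip_hdown = ip_hdown)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a single finite nonnegative number")
  }
  # rates may be zero (frozen growth / no divisions); shapes must be positive
  for (nm in c("r_min", "r0", "gp_exp", "ip_mid", "ip_hup", "ip_hdown"))
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  if (r0 >= r_min) stop("r0 (birth size) must be below r_min (minimal division size)")
  if (ip_hdown <= ip_hup)
    stop("ip_hdown must exceed ip_hup (bell-shaped idle-phase response)")
  structure(p, class = "cycle_params")
}

#' Linear influx schedule
#'
#' Time-dependent auxin influx from the shoot, `alpha(t) = alpha0 + k * t`,
#' used in growing-root simulations where the shoot's output increases as the
#' plant develops.
#'
#' @param alpha0 initial influx (cu/tu).
#' @param k linear ramp coefficient (cu/tu^2); may be zero.
#' @return An object of class `flux_schedule`.
#' @export
flux_schedule <- function(alpha0, k = 0) {
  if (!is.numeric(alpha0) || length(alpha0) != 1L || alpha0 < 0)
    stop("alpha0 must be a single nonnegative number")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k))
    stop("k must be a single finite number")
  structure(list(alpha0 = alpha0, k = k), class = "flux_schedule")
}

#' Evaluate an influx schedule
#'
#' @param s a [flux_schedule()].
#' @param t time (tu); vectorised.
#' @return influx rate(s) alpha(t) = alpha0 + k t (cu/tu).
#' @export
flux_schedule_eval <- function(s, t) {
  stopifnot(inherits(s, "flux_schedule"))
  v <- s$alpha0 + s$k * t
  if (any(v < 0)) stop("flux schedule evaluates negative at t = ",
                       t[which(v < 0)[1]])
  v
}

#' Load a named parameter set
#'
#' Reads a full model parameterisation (transport, Division Factor and cell
#' cycle parameters) from a YAML file, or one of the bundled presets.
#' The bundled `"robust"` set carries sharp auxin-dependent PIN1 degradation
#' (`h2 = 10`, `q3 = 3.26`), which is asserted at load time, as is the
#' Division Factor sigmoid scale `T = 0.1` for both sets.
#'
#' @param name `"basic"`, `"robust"`, or a path to a YAML file.
#' @return A list with elements `name`, `transport`
#'   ([transport_params()]), `divf` ([divf_params()]) and
#'   `cycle` ([cycle_params()]).
#' @export
param_preset <- function(name = "basic") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("params_", name, ".yaml"),
                package = "rootauxin")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown parameter set '", name, "'")
  raw <- yaml::read_yaml(path)
  for (sec in c("transport", "divf", "cycle"))
    if (is.null(raw[[sec]])) stop("parameter file lacks section '", sec, "'")
  set <- list(
    name      = if (is.null(raw$name)) name else raw$name,
    transport = do.call(transport_params, raw$transport),
    divf      = do.call(divf_params, raw$divf),
    cycle     = do.call(cycle_params, raw$cycle)
  )
  # in-text anchor values: fail loudly if a preset file was edited inconsistently
  if (identical(set$name, "robust")) {
    stopifnot(set$transport$h2 == 10, set$transport$q3 == 3.26)
  }
  stopifnot(set$divf$T == 0.1)
  set
}

#' @export
print.auxin_transport_params <- function(x, ...) {
  cat("Auxin/PIN1 transport parameters (cu, tu):\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.divf_params <- function(x, ...) {
  cat("Division Factor parameters (cu, tu):\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.cycle_params <- function(x, ...) {
  cat("Cell cycle parameters:\n")
  print(unlist(x)); invisible(x)
}
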