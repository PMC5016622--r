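#' Kinetic constants of the FvCB leaf model at 25 degrees C
#'
#' Bundles the Rubisco kinetic constants, compensation points and the spectral
#' correction factor used throughout the leaf model. All values are held at a
#' leaf temperature of 25 degrees C; no temperature-response functions are
#' applied anywhere in the package.
#'
#' @param Kc Michaelis-Menten constant of Rubisco for CO2 (Pa).
#' @param Ko Michaelis-Menten constant of Rubisco for O2 (Pa).
#' @param O Oxygen partial pressure (Pa).
#' @param gamma CO2 compensation point of net photosynthesis (Pa).
#' @param gamma_star CO2 compensation point in the absence of mitochondrial
#'   respiration (Pa). Must be below `gamma`.
#' @param f Spectral correction factor (dimensionless) for the fraction of
#'   absorbed light not reaching PSII.
#' @param resp_coef Ratio of dark respiration to Rubisco capacity,
#'   `R_l = resp_coef * V_l`, used by the `"table3"` respiration rule.
#'
#' @return An object of class `fvcb_constants` (a validated list).
#' @export
#' @examples
#' cs <- fvcb_constants()
#' effective_km(cs)
fvcb_constants <- function(Kc = 40.4, Ko = 24.8e3, O = 20.5e3,
                           gamma = 4.4, gamma_star = 3.69,
                           f = 0.15, resp_coef = 0.0089) {
  stopifnot(Kc > 0, Ko > 0, O >= 0, gamma > 0, gamma_star > 0,
            gamma > gamma_star, f >= 0, f <= 1, resp_coef >= 0)
  structure(list(Kc = Kc, Ko = Ko, O = O, gamma = gamma,
                 gamma_star = gamma_star, f = f, resp_coef = resp_coef),
            class = "fvcb_constants")
}

#' @export
print.fvcb_constants <- function(x, ...) {
  cat("FvCB constants at 25 C:\n")
  cat(sprintf("  Kc = %.4g Pa, Ko = %.4g Pa, O = %.4g Pa\n", x$Kc, x$Ko, x$O))
  cat(sprintf("  gamma = %.4g Pa, gamma* = %.4g Pa, f = %.3g, R_l/V_l = %.4g\n",
              x$gamma, x$gamma_star, x$f, x$resp_coef))
  invisible(x)
}

#' Leaf photosynthetic parameters at 25 degrees C
#'
#' @param vl Maximum Rubisco carboxylation capacity V_l (umol m-2 s-1).
#' @param jm Maximum potential electron transport rate J_m (umol m-2 s-1).
#' @param theta Curvature of the electron-transport light response,
#'   strictly between 0 and 1. Leaf-level estimates typically fall in
#'   0.68-0.83; the default 0.75 is the midpoint of that range.
#' @param resp_rule Either `"table3"` (R_l = resp_coef * V_l) or `"eqA7"`
#'   (R_l = V_l (gamma - gamma*)/(gamma + K')). The two differ by about 2%.
#'
#' @return An object of class `fvcb_params`.
#' @export
fvcb_params <- function(vl, jm, theta = 0.75,
                        resp_rule = c("table3", "eqA7")) {
  resp_rule <- match.arg(resp_rule)
  stopifnot(is.numeric(vl), is.numeric(jm), vl > 0, jm > 0,
            theta > 0, theta < 1)
  structure(list(vl = vl, jm = jm, theta = theta, resp_rule = resp_rule),
            class = "fvcb_params")
}

#' Effective Michaelis-Menten constant of Rubisco
#'
#' `K' = Kc (1 + O/Ko)`, the CO2 constant inflated by competitive O2 binding.
#'
#' @param constants An [fvcb_constants()] object.
#' @return K' in Pa.
#' @export
effective_km <- function(constants = fvcb_constants()) {
  constants$Kc * (1 + constants$O / constants$Ko)
}

#' Rubisco-limited gross assimilation rate
#'
#' `Av = V_l (c_i - gamma*) / (c_i + K')`. Negative below the photorespiratory
#' compensation point gamma*.
#'
#' @param vl Rubisco capacity (umol m-2 s-1).
#' @param ci Internal CO2 partial pressure (Pa); vectorised.
#' @param constants An [fvcb_constants()] object.
#' @return Av (umol m-2 s-1), same length as `ci`.
#' @export
rubisco_limited <- function(vl, ci, constants = fvcb_constants()) {
  stopifnot(all(ci >= 0), all(vl > 0))
  vl * (ci - constants$gamma_star) / (ci + effective_km(constants))
}

#' PAR effectively absorbed by photosystem II
#'
#' `I_le = I_l (1 - f) / 2`: half the absorbed photon flux, corrected for the
#' spectral fraction `f` not driving PSII.
#'
#' @param il Total absorbed PAR per unit leaf area (umol m-2 s-1).
#' @param f Spectral correction factor.
#' @return I_le (umol m-2 s-1).
#' @export
effective_irradiance <- function(il, f = 0.15) {
  stopifnot(all(il >= 0), f >= 0, f <= 1)
  il * (1 - f) / 2
}

#' Potential electron transport rate
#'
#' Smaller root of `theta J^2 - (I_le + J_m) J + I_le J_m = 0`, computed with
#' the cancellation-safe form `2 I_le J_m / (b + sqrt(b^2 - 4 theta I_le J_m))`
#' with `b = I_le + J_m`, so that J is accurate at low irradiance.
#'
#' @param ile PAR effectively absorbed by PSII (umol m-2 s-1); vectorised.
#' @param jm Maximum electron transport rate (umol m-2 s-1).
#' @param theta Curvature parameter in (0, 1).
#' @return J (umol m-2 s-1), with `J <= min(ile, jm)`.
#' @export
electron_transport <- function(ile, jm, theta = 0.75) {
  if (theta <= 0 || theta >= 1) {
    stop("theta must lie strictly between 0 and 1, got ", theta)
  }
  stopifnot(all(ile >= 0), all(jm > 0))
  b <- ile + jm
  disc <- b * b - 4 * theta * ile * jm
  # disc >= (1-theta) * b^2 >= 0 analytically; clamp rounding noise
  disc[disc < 0] <- 0
  2 * ile * jm / (b + sqrt(disc))
}

#' RuBP-regeneration-limited gross assimilation rate
#'
#' `Aj = J (c_i - gamma*) / (4 (c_i + 2 gamma*))`.
#'
#' @param j Electron transport rate (umol m-2 s-1).
#' @param ci Internal CO2 partial pressure (Pa).
#' @param constants An [fvcb_constants()] object.
#' @return Aj (umol m-2 s-1).
#' @export
rubp_limited <- function(j, ci, constants = fvcb_constants()) {
  stopifnot(all(ci >= 0), all(j >= 0))
  gs <- constants$gamma_star
  j * (ci - gs) / (4 * (ci + 2 * gs))
}

#' Dark respiration rate of the leaf
#'
#' Two rules are exposed because the source constants state both and they
#' disagree slightly: `"table3"` uses the fixed coefficient
#' `R_l = resp_coef * V_l` (default 0.0089), while `"eqA7"` ties respiration
#' to the two compensation points, `R_l = V_l (gamma - gamma*)/(gamma + K')`
#' (about 0.00908 * V_l at the default constants). The eqA7 rule makes the
#' net CO2 compensation point exactly `gamma` when Rubisco limits.
#'
#' @param vl Rubisco capacity (umol m-2 s-1).
#' @param rule `"table3"` or `"eqA7"`.
#' @param constants An [fvcb_constants()] object.
#' @return R_l (umol m-2 s-1).
#' @export
leaf_respiration <- function(vl, rule = c("table3", "eqA7"),
                             constants = fvcb_constants()) {
  rule <- match.arg(rule)
  stopifnot(all(vl >= 0))
  if (rule == "table3") {
    constants$resp_coef * vl
  } else {
    vl * (constants$gamma - constants$gamma_star) /
      (constants$gamma + effective_km(constants))
  }
}

#' Net leaf assimilation rate
#'
#' The FvCB net rate `A_l = min(Av, Aj) - R_l` at 25 degrees C, together with
#' its components and the active limitation.
#'
#' @param il Total absorbed PAR per unit leaf area (umol m-2 s-1); vectorised.
#' @param ci Internal CO2 partial pressure (Pa); vectorised (recycled against
#'   `il`).
#' @param params An [fvcb_params()] object.
#' @param constants An [fvcb_constants()] object.
#'
#' @return A data frame with columns `il`, `ci`, `av`, `aj`, `j`, `rl`, `al`
#'   and `limitation` (`"rubisco"` or `"rubp"`).
#' @export
#' @examples
#' p <- fvcb_params(vl = 88.62, jm = 175.42)
#' net_assimilation(1000, ci = c(10, 30, 60), p)
net_assimilation <- function(il, ci, params, constants = fvcb_constants()) {
  stopifnot(inherits(params, "fvcb_params"))
  n <- max(length(il), length(ci))
  il <- rep_len(il, n)
  ci <- rep_len(ci, n)
  av <- rubisco_limited(params$vl, ci, constants)
  ile <- effective_irradiance(il, constants$f)
  j <- electron_transport(ile, params$jm, params$theta)
  aj <- rubp_limited(j, ci, constants)
  rl <- leaf_respiration(params$vl, params$resp_rule, constants)
  al <- pmin(av, aj) - rl
  data.frame(il = il, ci = ci, av = av, aj = aj, j = j, rl = rl, al = al,
             limitation = ifelse(av <= aj, "rubisco", "rubp"),
             stringsAsFactors = FALSE)
}

#' Non-rectangular hyperbola light response
#'
#' `A(I) = [phi I + Amax - sqrt((phi I + Amax)^2 - 4 theta phi I Amax)]
#' / (2 theta) - Rd`, evaluated in the cancellation-safe form
#' `2 phi I Amax / (b + sqrt(b^2 - 4 theta phi I Amax)) - Rd` so the
#' rectangular-hyperbola limit theta -> 0 is reached smoothly.
#'
#' @param i Incident PPFD (umol m-2 s-1); vectorised.
#' @param amax Light-saturated gross assimilation (umol m-2 s-1).
#' @param phi Apparent quantum yield (mol CO2 / mol photons).
#' @param theta Curvature in \[0, 1).
#' @param rd Dark respiration (umol m-2 s-1).
#' @return Net assimilation A (umol m-2 s-1).
#' @export
nrh_light_response <- function(i, amax, phi, theta, rd) {
  stopifnot(all(i >= 0), amax > 0, phi > 0, theta >= 0, theta < 1, rd >= 0)
  b <- phi * i + amax
  disc <- b * b - 4 * theta * phi * i * amax
  disc[disc < 0] <- 0
  2 * phi * i * amax / (b + sqrt(disc)) - rd
}

#' CO2 compensation points by root finding
#'
#' Locates the internal CO2 partial pressure at which either the
#' Rubisco-limited gross rate (`which = "gross"`; root at gamma*) or the net
#' assimilation rate (`which = "net"`) crosses zero, by bisection.
#'
#' @param params An [fvcb_params()] object (only used for `which = "net"`).
#' @param il Absorbed PPFD for the net-rate root (umol m-2 s-1).
#' @param which `"gross"` or `"net"`.
#' @param constants An [fvcb_constants()] object.
#' @param interval Search interval in Pa.
#' @param tol Absolute root tolerance in Pa.
#' @return The root c_i in Pa.
#' @export
compensation_point <- function(params = NULL, il = 1000,
                               which = c("gross", "net"),
                               constants = fvcb_constants(),
                               interval = c(1e-3, 30), tol = 1e-9) {
  which <- match.arg(which)
  fn <- if (which == "gross") {
    vl <- if (is.null(params)) 50 else params$vl
    function(ci) rubisco_limited(vl, ci, constants)
  } else {
    stopifnot(inherits(params, "fvcb_params"))
    function(ci) net_assimilation(il, ci, params, constants)$al
  }
  stats::uniroot(fn, interval = interval, tol = tol)$root
}
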