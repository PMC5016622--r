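# Estimation of Amax, Vl, Jm and theta per canopy layer from light-response
# and A/Ci curves, using partitioned windows: Rubisco limitation below
# ci = 30 Pa, RuBP-regeneration limitation above ci = 40 Pa.

#' Construct a gas-exchange curve
#'
#' @param ppfd Incident PPFD per point (umol m-2 s-1).
#' @param ca External CO2 partial pressure (Pa).
#' @param ci Internal CO2 partial pressure (Pa); must not exceed `ca`.
#' @param a_net Net assimilation (umol m-2 s-1).
#' @param kind `"aci_curve"` (fixed PPFD) or `"light_curve"`.
#' @param layer,replicate Optional grouping labels.
#' @return A data frame of class `gas_exchange_curve`.
#' @export
gas_exchange_curve <- function(ppfd, ca, ci, a_net,
                               kind = c("aci_curve", "light_curve"),
                               layer = NA, replicate = NA) {
  kind <- match.arg(kind)
  n <- length(a_net)
  stopifnot(length(ppfd) %in% c(1, n), length(ca) %in% c(1, n),
            length(ci) %in% c(1, n), n >= 4)
  ppfd <- rep_len(ppfd, n); ca <- rep_len(ca, n); ci <- rep_len(ci, n)
  if (any(ci > ca + 1e-9)) stop("ci must not exceed ca")
  if (kind == "aci_curve" && length(unique(round(ppfd, 6))) != 1) {
    stop("an A/Ci curve must be measured at a single PPFD")
  }
  structure(data.frame(ppfd = ppfd, ca_pa = ca, ci_pa = ci, a_net = a_net,
                       layer = layer, replicate = replicate),
            kind = kind, class = c("gas_exchange_curve", "data.frame"))
}

#' Read gas-exchange curves from CSV
#'
#' Expects columns `layer,replicate,kind,ppfd,ca_pa,ci_pa,a_net`; `kind` is
#' `aci` or `light`. Returns a list of [gas_exchange_curve()] objects, one
#' per (layer, replicate, kind) group.
#' @param path CSV path.
#' @export
read_gasx_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("layer", "replicate", "kind", "ppfd", "ca_pa", "ci_pa", "a_net")
  if (!all(needed %in% names(d))) {
    stop("curves CSV must have columns: ", paste(needed, collapse = ","))
  }
  groups <- split(d, interaction(d$layer, d$replicate, d$kind, drop = TRUE))
  lapply(groups, function(g) {
    gas_exchange_curve(g$ppfd, g$ca_pa, g$ci_pa, g$a_net,
                       kind = if (g$kind[1] %in% c("aci", "aci_curve"))
                         "aci_curve" else "light_curve",
                       layer = g$layer[1], replicate = g$replicate[1])
  })
}

new_fit_result <- function(estimate, se, r2, n_used, window, converged,
                           extra = list()) {
  structure(c(list(estimate = estimate, standard_error = se,
                   r_squared = r2, n_points_used = n_used,
                   window = window, converged = converged), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %.4g +/- %.3g (n = %d, R2 = %.3f, %s)\n",
              x$estimate, x$standard_error, x$n_points_used,
              ifelse(is.na(x$r_squared), NA, x$r_squared),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit a non-rectangular hyperbola to a light-response curve
#'
#' Nonlinear least squares of [nrh_light_response()] with box constraints
#' `Amax > 0`, `phi` in (0, 0.125], `theta` in (0, 1), `Rd >= 0`, using a
#' Levenberg-Marquardt optimizer with three deterministic starts to guard
#' against local minima. Non-convergence is flagged, not thrown.
#'
#' @param curve A light-response [gas_exchange_curve()] with >= 5 points.
#' @return A list of `fit_result`s: `amax`, `phi`, `theta`, `rd`.
#' @export
fit_light_curve <- function(curve) {
  if (attr(curve, "kind") != "light_curve") {
    stop("fit_light_curve needs a light_curve")
  }
  if (nrow(curve) < 5) stop("need at least 5 points, got ", nrow(curve))
  i <- curve$ppfd; a <- curve$a_net
  amax0 <- max(a) - min(min(a), 0)
  starts <- list(
    c(amax = max(amax0, 1), phi = 0.05, theta = 0.75, rd = max(-min(a), 0.1)),
    c(amax = max(amax0, 1) * 1.5, phi = 0.08, theta = 0.5, rd = 0.5),
    c(amax = max(amax0, 1) * 0.8, phi = 0.03, theta = 0.9, rd = 1.0))
  lower <- c(1e-6, 1e-6, 1e-6, 0)
  upper <- c(Inf, 0.125, 1 - 1e-6, Inf)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        a ~ nrh_light_response(i, amax, phi, theta, rd),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  window <- range(i)
  if (is.null(best)) {
    nafit <- new_fit_result(NA_real_, NA_real_, NA_real_, nrow(curve),
                            window, FALSE)
    return(list(amax = nafit, phi = nafit, theta = nafit, rd = nafit))
  }
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  r2 <- 1 - best$rss / sum((a - mean(a))^2)
  conv <- fit$convInfo$isConv %||% TRUE
  mk <- function(nm) new_fit_result(unname(cf[nm]), unname(se[nm]), r2,
                                    nrow(curve), window, conv)
  list(amax = mk("amax"), phi = mk("phi"), theta = mk("theta"),
       rd = mk("rd"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate Rubisco capacity Vl from the low-Ci window of an A/Ci curve
#'
#' Least-squares fit of the Rubisco-limited branch over points with
#' `gamma* < ci < ci_window_max`:
#' `A_net = Vl * ((ci - gamma*)/(ci + K') - r)` where `r` couples dark
#' respiration to Vl (`"table3"` coefficient by default, or the `"eqA7"`
#' ratio). Because the model is linear in Vl the least-squares solution is
#' computed exactly by linear regression through the origin. A fixed-Rl
#' mode (`rl_fixed`) treats respiration as a known constant instead.
#'
#' @param curve An A/Ci [gas_exchange_curve()].
#' @param ci_window_max Upper ci bound of the Rubisco window (Pa).
#' @param resp_rule `"table3"` or `"eqA7"`.
#' @param rl_fixed Optional fixed respiration (umol m-2 s-1) replacing the
#'   Vl-coupled term.
#' @param constants An [fvcb_constants()].
#' @return A `fit_result` for Vl.
#' @export
fit_vl <- function(curve, ci_window_max = 30,
                   resp_rule = c("table3", "eqA7"), rl_fixed = NULL,
                   constants = fvcb_constants()) {
  resp_rule <- match.arg(resp_rule)
  if (attr(curve, "kind") != "aci_curve") stop("fit_vl needs an aci_curve")
  gs <- constants$gamma_star
  kp <- effective_km(constants)
  sel <- curve$ci_pa > gs & curve$ci_pa < ci_window_max
  if (sum(sel) < 3) {
    stop(sprintf(
      "need >= 3 points with %.3g < ci < %.3g Pa, found %d", gs,
      ci_window_max, sum(sel)))
  }
  ci <- curve$ci_pa[sel]; a <- curve$a_net[sel]
  r_coef <- if (resp_rule == "table3") constants$resp_coef
            else (constants$gamma - gs) / (constants$gamma + kp)
  if (is.null(rl_fixed)) {
    x <- (ci - gs) / (ci + kp) - r_coef
    y <- a
  } else {
    x <- (ci - gs) / (ci + kp)
    y <- a + rl_fixed
  }
  fit <- stats::lm(y ~ 0 + x)
  est <- unname(stats::coef(fit)[1])
  # noiseless curves fit exactly; the "perfect fit" diagnostic is expected
  se <- unname(suppressWarnings(summary(fit))$coefficients[1, 2])
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  new_fit_result(est, se, r2, sum(sel), c(gs, ci_window_max), TRUE,
                 extra = list(resp_rule = resp_rule))
}

#' Estimate Jm from the high-Ci window of an A/Ci curve
#'
#' For each point with `ci > ci_window_min`, the gross RuBP-limited rate
#' `Aj = A_net + Rl` is inverted algebraically to the electron transport
#' rate `J = 4 Aj (ci + 2 gamma*)/(ci - gamma*)` and then to
#' `Jm = J (Ile - theta J)/(Ile - J)`, where `Ile` is the effective PSII
#' irradiance at the measurement PPFD. The estimate is the mean of the
#' per-point `Jm` values and the SE their standard error. Points with
#' `J >= Ile` are physically impossible under the quadratic and are dropped
#' with a warning.
#'
#' @param curve An A/Ci [gas_exchange_curve()].
#' @param rl Dark respiration used to restore the gross rate
#'   (umol m-2 s-1); supply `vl * 0.0089` or a [fit_vl()] result's value.
#' @param theta Curvature of the light response; use the same layer's
#'   light-curve estimate when available, else the 0.75 midpoint.
#' @param ci_window_min Lower ci bound of the RuBP window (Pa).
#' @param measurement_ppfd PPFD at which the A/Ci curve was measured.
#' @param constants An [fvcb_constants()].
#' @return A `fit_result` for Jm (with per-point values in `$jm_points`).
#' @export
fit_jm <- function(curve, rl, theta = 0.75, ci_window_min = 40,
                   measurement_ppfd = 1000,
                   constants = fvcb_constants()) {
  if (attr(curve, "kind") != "aci_curve") stop("fit_jm needs an aci_curve")
  stopifnot(theta > 0, theta < 1, rl >= 0)
  gs <- constants$gamma_star
  sel <- curve$ci_pa > ci_window_min
  if (sum(sel) < 3) {
    stop(sprintf("need >= 3 points with ci > %.3g Pa, found %d",
                 ci_window_min, sum(sel)))
  }
  ci <- curve$ci_pa[sel]
  aj <- curve$a_net[sel] + rl
  ile <- effective_irradiance(measurement_ppfd, constants$f)
  j <- 4 * aj * (ci + 2 * gs) / (ci - gs)
  usable <- j > 0 & j < ile
  if (any(!usable)) {
    warning(sum(!usable), " point(s) dropped: inverted J outside (0, Ile)")
  }
  if (!any(usable)) stop("no usable points: all inverted J outside (0, Ile)")
  j <- j[usable]
  jm_pts <- j * (ile - theta * j) / (ile - j)
  n <- length(jm_pts)
  se <- if (n > 1) stats::sd(jm_pts) / sqrt(n) else 0
  new_fit_result(mean(jm_pts), se, NA_real_, n,
                 c(ci_window_min, Inf), TRUE,
                 extra = list(jm_points = jm_pts, theta = theta))
}

#' Per-layer parameter profile and vertical trend
#'
#' Fits every curve in a list grouped by layer: light curves give Amax (and
#' theta, used for the same layer's Jm inversion), A/Ci curves give Vl and
#' Jm. Returns per-layer means +/- SE across replicates and an ordinary
#' least-squares line of each mean against layer index.
#'
#' @param curves A list of [gas_exchange_curve()] objects carrying `layer`
#'   (and optionally `replicate`) labels.
#' @param resp_rule Respiration rule passed to [fit_vl()].
#' @param constants An [fvcb_constants()].
#' @return A list with `profile` (data frame: layer, vlo, vlo_se, jmo,
#'   jmo_se, amax, amax_se, theta, n) and `trend` (data frame: parameter,
#'   slope, intercept, r_squared).
#' @export
fit_layer_profile <- function(curves, resp_rule = c("table3", "eqA7"),
                              constants = fvcb_constants()) {
  resp_rule <- match.arg(resp_rule)
  layers <- vapply(curves, function(cv) cv$layer[1], numeric(1))
  rows <- list()
  for (ly in sort(unique(layers))) {
    grp <- curves[layers == ly]
    kinds <- vapply(grp, attr, character(1), "kind")
    amax_v <- c(); theta_v <- c(); vl_v <- c(); jm_v <- c()
    for (cv in grp[kinds == "light_curve"]) {
      lf <- fit_light_curve(cv)
      if (isTRUE(lf$amax$converged)) {
        amax_v <- c(amax_v, lf$amax$estimate)
        theta_v <- c(theta_v, lf$theta$estimate)
      }
    }
    theta_ly <- if (length(theta_v)) mean(theta_v) else 0.75
    for (cv in grp[kinds == "aci_curve"]) {
      vf <- fit_vl(cv, resp_rule = resp_rule, constants = constants)
      vl_v <- c(vl_v, vf$estimate)
      rl <- leaf_respiration(vf$estimate, resp_rule, constants)
      jf <- tryCatch(
        fit_jm(cv, rl = rl, theta = theta_ly,
               measurement_ppfd = cv$ppfd[1], constants = constants),
        error = function(e) NULL)
      if (!is.null(jf)) jm_v <- c(jm_v, jf$estimate)
    }
    se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    mn <- function(x) if (length(x)) mean(x) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      layer = ly, vlo = mn(vl_v), vlo_se = se(vl_v),
      jmo = mn(jm_v), jmo_se = se(jm_v),
      amax = mn(amax_v), amax_se = se(amax_v),
      theta = theta_ly, n = length(grp))
  }
  profile <- do.call(rbind, rows)
  trend <- do.call(rbind, lapply(c("vlo", "jmo", "amax"), function(p) {
    y <- profile[[p]]
    ok <- is.finite(y)
    if (sum(ok) < 2) {
      return(data.frame(parameter = p, slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_))
    }
    fit <- stats::lm(y[ok] ~ profile$layer[ok])
    data.frame(parameter = p,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = suppressWarnings(summary(fit))$r.squared)
  }))
  list(profile = profile, trend = trend)
}
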