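# Synthetic-data generators with known ground truth for every pipeline
# input: gas-exchange curves, weather days, and closed-chamber CO2 logs.
# All generators are seed-deterministic and attach their generating truth
# as a "truth" attribute.

#' Generate a synthetic A/Ci curve
#'
#' Emulates the 20-point A/Ci protocol: external CO2 stepped over
#' `ca_range` at fixed PPFD, internal CO2 a fixed ratio of external, net
#' assimilation from the FvCB model plus Gaussian measurement noise.
#'
#' @param params [fvcb_params()] ground truth.
#' @param n_points Points on the curve (default 20).
#' @param ca_range External CO2 span in Pa (default 0-120).
#' @param ppfd Measurement PPFD (default 1000 umol m-2 s-1).
#' @param ci_ratio ci/ca ratio (default 0.7).
#' @param noise_sd Gaussian noise on A (umol m-2 s-1; default 0.5, set 0
#'   for noiseless curves).
#' @param limitation `"min"` uses the full model; `"rubisco"` or `"rubp"`
#'   force one gross branch (minus respiration), for curves that isolate a
#'   single limitation the way the partitioned fitting windows assume.
#' @param seed Integer seed.
#' @param layer,replicate Labels carried on the curve.
#' @param constants An [fvcb_constants()].
#' @return A [gas_exchange_curve()] with a `truth` attribute.
#' @export
#' @examples
#' cv <- gen_aci_curve(fvcb_params(88.62, 175.42), noise_sd = 0)
#' fit_vl(cv)
gen_aci_curve <- function(params, n_points = 20, ca_range = c(0, 120),
                          ppfd = 1000, ci_ratio = 0.7, noise_sd = 0.5,
                          limitation = c("min", "rubisco", "rubp"),
                          seed = 1L, layer = NA, replicate = NA,
                          constants = fvcb_constants()) {
  limitation <- match.arg(limitation)
  stopifnot(noise_sd >= 0, n_points >= 4)
  ca <- seq(ca_range[1], ca_range[2], length.out = n_points)
  ci <- ci_ratio * ca
  comp <- net_assimilation(ppfd, ci, params, constants)
  a <- switch(limitation,
              min = comp$al,
              rubisco = comp$av - comp$rl,
              rubp = comp$aj - comp$rl)
  if (noise_sd > 0) a <- a + rng_stream(seed, n_points, rnorm_sd = noise_sd)
  cv <- gas_exchange_curve(ppfd, ca, ci, a, kind = "aci_curve",
                           layer = layer, replicate = replicate)
  attr(cv, "truth") <- list(params = params, ci_ratio = ci_ratio,
                            ppfd = ppfd, noise_sd = noise_sd,
                            limitation = limitation, seed = seed)
  cv
}

#' Generate a synthetic light-response curve
#'
#' PPFD stepped over `ppfd_range` at fixed external CO2 (default 100 Pa),
#' net assimilation from the non-rectangular hyperbola plus Gaussian noise.
#'
#' @param amax,phi,theta,rd Ground-truth NRH parameters (see
#'   [nrh_light_response()]).
#' @param n_points Points (default 20).
#' @param ppfd_range PPFD span (default 50-1000 umol m-2 s-1).
#' @param ca_pa External CO2 (default 100 Pa).
#' @param ci_ratio ci/ca ratio used to fill the ci column.
#' @param noise_sd Gaussian noise on A (default 0.5).
#' @param seed Integer seed.
#' @param layer,replicate Labels.
#' @return A [gas_exchange_curve()] with a `truth` attribute.
#' @export
gen_light_curve <- function(amax, phi = 0.06, theta = 0.75, rd = 1.0,
                            n_points = 20, ppfd_range = c(50, 1000),
                            ca_pa = 100, ci_ratio = 0.7, noise_sd = 0.5,
                            seed = 1L, layer = NA, replicate = NA) {
  stopifnot(noise_sd >= 0, n_points >= 4)
  i <- seq(ppfd_range[1], ppfd_range[2], length.out = n_points)
  a <- nrh_light_response(i, amax, phi, theta, rd)
  if (noise_sd > 0) a <- a + rng_stream(seed, n_points, rnorm_sd = noise_sd)
  cv <- gas_exchange_curve(i, ca_pa, ci_ratio * ca_pa, a,
                           kind = "light_curve",
                           layer = layer, replicate = replicate)
  attr(cv, "truth") <- list(amax = amax, phi = phi, theta = theta, rd = rd,
                            noise_sd = noise_sd, seed = seed)
  cv
}

#' Generate a half-sine weather day
#'
#' Global PPFD follows a half-sine from `start` to `end` peaking at the
#' midpoint, with a constant (or supplied) diffuse fraction; 30-min steps
#' give 19 records for the default 09:00-18:00 span.
#'
#' @param date Date string `"YYYY-MM-DD"`.
#' @param peak_ppfd Peak global PPFD (umol m-2 s-1).
#' @param diffuse_fraction Scalar or per-step vector in \[0, 1\].
#' @param start_hour,end_hour Day span in local hours.
#' @param step_min Step in minutes (default 30).
#' @param tz Time zone of the timestamps (default `"UTC"`, paired with an
#'   explicit `utc_offset` at the solar-geometry boundary).
#' @return A data frame `timestamp`, `ppfd`, `diffuse_fraction`.
#' @export
gen_weather_day <- function(date = "2014-10-15", peak_ppfd = 1000,
                            diffuse_fraction = 0.3, start_hour = 9,
                            end_hour = 18, step_min = 30, tz = "UTC") {
  stopifnot(peak_ppfd >= 0, end_hour > start_hour)
  t0 <- as.POSIXct(paste0(date, " 00:00:00"), tz = tz)
  hours <- seq(start_hour, end_hour, by = step_min / 60)
  frac <- (hours - start_hour) / (end_hour - start_hour)
  ppfd <- peak_ppfd * sin(pi * frac)
  ppfd[ppfd < 0] <- 0
  data.frame(timestamp = t0 + hours * 3600, ppfd = ppfd,
             diffuse_fraction = rep_len(diffuse_fraction, length(hours)))
}

#' Generate a closed-chamber CO2 log with injections
#'
#' Forward-Euler integration of the chamber CO2 mass balance at the logging
#' interval: uptake and leak draw CO2 down, and whenever the partial
#' pressure falls to `trigger_pa` an injection refills it toward
#' `refill_pa` as a first-order ramp (time constant `ramp_tau_s`), so the
#' log is the characteristic sawtooth. Optional Gaussian sensor noise.
#'
#' @param true_rates Data frame `window_start` (s), `rate_umol_s` of plant
#'   uptake, piecewise-constant per window — or a single constant rate.
#' @param geometry A [chamber_geometry()]; its `leak_rate` is applied.
#' @param duration_s Log length in seconds (default spans `true_rates`).
#' @param sampling_s Logging interval (default 10 s).
#' @param start_pa Initial CO2 partial pressure (default 200 Pa).
#' @param trigger_pa Injection trigger (default 100 Pa).
#' @param refill_pa Injection target (default 200 Pa).
#' @param ramp_tau_s Injection ramp time constant (default 60 s).
#' @param noise_sd Sensor noise on the logged pressure (Pa; default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A data frame `timestamp` (s), `co2_pa`, `injecting`, with a
#'   `truth` attribute recording the inputs.
#' @export
gen_chamber_log <- function(true_rates, geometry = chamber_geometry(),
                            duration_s = NULL, sampling_s = 10,
                            start_pa = 200, trigger_pa = 100,
                            refill_pa = 200, ramp_tau_s = 60,
                            noise_sd = 0, seed = 1L) {
  if (is.numeric(true_rates) && length(true_rates) == 1) {
    true_rates <- data.frame(window_start = 0, rate_umol_s = true_rates)
  }
  if (is.null(duration_s)) {
    duration_s <- max(true_rates$window_start) + 1800
  }
  t_k <- geometry$temperature_c + 273.15
  pa_per_umol <- GAS_CONSTANT * t_k / geometry$volume_m3 * 1e-6
  times <- seq(0, duration_s, by = sampling_s)
  n <- length(times)
  p <- numeric(n)
  injecting <- logical(n)
  p[1] <- start_pa
  active <- FALSE
  for (i in 2:n) {
    idx <- findInterval(times[i - 1], true_rates$window_start)
    uptake <- true_rates$rate_umol_s[max(idx, 1)]
    dp <- -(uptake + geometry$leak_rate) * pa_per_umol * sampling_s
    if (!active && p[i - 1] <= trigger_pa) active <- TRUE
    if (active) {
      # first-order pull toward slightly above the target so the setpoint
      # is reached in finite time
      dp <- dp + (refill_pa + 5 - p[i - 1]) *
        (1 - exp(-sampling_s / ramp_tau_s))
      if (p[i - 1] + dp >= refill_pa) active <- FALSE
    }
    p[i] <- p[i - 1] + dp
    injecting[i] <- active
  }
  if (noise_sd > 0) p <- p + rng_stream(seed, n, rnorm_sd = noise_sd)
  out <- data.frame(timestamp = times, co2_pa = p, injecting = injecting)
  attr(out, "truth") <- list(true_rates = true_rates,
                             leak_rate = geometry$leak_rate,
                             trigger_pa = trigger_pa, refill_pa = refill_pa,
                             ramp_tau_s = ramp_tau_s, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Packaged measurement tables
#'
#' Returns the bundled fixtures: the per-layer structural table, the FvCB
#' constants, and the per-layer photosynthetic parameter profile.
#'
#' @return A list `layer_structure` (data frame), `constants`
#'   ([fvcb_constants()]), `photo_profile` (data frame).
#' @export
table_fixtures <- function() {
  list(layer_structure = read_layer_spec(),
       constants = fvcb_constants(),
       photo_profile = read_photo_profile())
}
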