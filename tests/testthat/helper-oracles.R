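# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# Solar position by the Michalsky / Astronomical Almanac approximation
# (ecliptic coordinates + sidereal time), independent of the package's
# Fourier-series declination route. Accuracy ~0.01 deg for 1950-2050.
oracle_solar <- function(lat_deg, lon_deg, local_datetime, utc_offset) {
  lt <- as.POSIXct(local_datetime, tz = "UTC") - utc_offset * 3600
  jd <- as.numeric(lt) / 86400 + 2440587.5
  n <- jd - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lam <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 4e-7 * n) * pi / 180
  dec <- asin(sin(eps) * sin(lam))
  ra <- atan2(cos(eps) * sin(lam), cos(lam))
  ut_h <- (jd + 0.5 - floor(jd + 0.5)) * 24
  gmst <- (6.697375 + 0.0657098242 * n + 1.00273790935 * 0) %% 24
  # sidereal time: 6.697375 + 0.0657098242*n0 + 1.0027379*UT; the n above
  # already contains the UT fraction, so use the standard single-line form
  gmst <- (6.697375 + 0.0657098242 * (n - ut_h / 24) +
             1.00273790935 * ut_h) %% 24
  lmst <- (gmst + lon_deg / 15) %% 24
  ha <- lmst * 15 * pi / 180 - ra
  ha <- atan2(sin(ha), cos(ha))
  lat <- lat_deg * pi / 180
  sin_el <- sin(dec) * sin(lat) + cos(dec) * cos(lat) * cos(ha)
  el <- asin(pmin(1, pmax(-1, sin_el)))
  az <- atan2(-cos(dec) * sin(ha),
              (sin(dec) - sin(lat) * sin_el) / cos(lat)) * 180 / pi
  list(zenith = 90 - el * 180 / pi, azimuth = az %% 360)
}

# Two stacked horizontal Lambertian leaves under a vertical beam: absorbed
# irradiance on the lower leaf from the infinite inter-reflection series,
# D = tau I0 / (1 - rho^2), absorbed = (1 - rho - tau) D.
oracle_two_layer_lower <- function(i0, rho, tau) {
  (1 - rho - tau) * tau * i0 / (1 - rho * rho)
}

# Rectangular hyperbola: the theta -> 0 limit of the NRH light response.
oracle_rectangular_hyperbola <- function(i, amax, phi, rd) {
  phi * i * amax / (phi * i + amax) - rd
}

# Build a flattened one-surface scene from an explicit mesh, for tracer
# tests with hand-placed geometry.
flat_scene <- function(meshes, kinds = rep("leaf", length(meshes)),
                       rho = NULL, tau = NULL) {
  if (!length(meshes)) {
    surfaces <- data.frame(name = character(0), kind = character(0),
                           plant = integer(0), stem = integer(0),
                           node = integer(0), leaf_k = integer(0),
                           leaf_id = integer(0), area_m2 = numeric(0),
                           surface_id = integer(0), rho = numeric(0),
                           tau = numeric(0))
    return(list(meshes = list(), surfaces = surfaces,
                center_plant_id = 1L))
  }
  areas <- vapply(meshes, canopyray::mesh_area, numeric(1))
  surfaces <- data.frame(
    name = sprintf("%s_%d", kinds, seq_along(meshes)), kind = kinds,
    plant = 1L, stem = 1L, node = seq_along(meshes),
    leaf_k = 1L, leaf_id = seq_along(meshes), area_m2 = areas,
    surface_id = seq_along(meshes), stringsAsFactors = FALSE)
  if (!is.null(rho)) {
    surfaces$rho <- rep_len(rho, length(meshes))
    surfaces$tau <- rep_len(tau, length(meshes))
  }
  list(meshes = meshes, surfaces = surfaces, center_plant_id = 1L)
}

square_mesh <- function(cx, cy, z, side = 1, tilt_deg = 0) {
  h <- side / 2
  v <- matrix(c(-h, -h, 0, h, -h, 0, h, h, 0, -h, h, 0), 4, 3, byrow = TRUE)
  if (tilt_deg != 0) {
    a <- tilt_deg * pi / 180
    rot <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
                  byrow = TRUE)
    v <- v %*% t(rot)
  }
  v <- sweep(v, 2, c(cx, cy, z), "+")
  list(vertices = v, faces = matrix(c(1L, 2L, 3L, 1L, 3L, 4L), 2, 3,
                                    byrow = TRUE))
}

overhead_sun <- function() {
  structure(list(zenith = 0, azimuth = 0, above_horizon = TRUE),
            class = "sun_position")
}
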