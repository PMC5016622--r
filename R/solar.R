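#' Solar position from site coordinates and local time
#'
#' Zenith and azimuth of the sun via the standard low-cost solar geometry:
#' Spencer's Fourier series for declination and the equation of time, the
#' local hour angle from true solar time, then the spherical triangle for
#' zenith and azimuth. Accuracy is a few hundredths of a degree, well inside
#' the half-degree needed for canopy light interception.
#'
#' @param latitude_deg Site latitude (degrees, north positive), in
#'   \[-90, 90\].
#' @param longitude_deg Site longitude (degrees, east positive).
#' @param local_datetime A `POSIXct`/`POSIXlt` time, or a string
#'   `"YYYY-MM-DD HH:MM(:SS)"`, interpreted in the zone given by
#'   `utc_offset`.
#' @param utc_offset Hours ahead of UTC of `local_datetime` (e.g. 9 for
#'   Korea Standard Time).
#' @param north_offset_deg Rotation of the scene's +y axis away from true
#'   north (degrees clockwise); added to the azimuth so scene coordinates
#'   can be misaligned with the compass.
#' @return A list of class `sun_position`: `zenith`, `azimuth` (degrees
#'   clockwise from north), `above_horizon`, `declination`,
#'   `equation_of_time_min`.
#' @export
#' @examples
#' solar_position(37.3, 127.0, "2014-10-15 12:00", utc_offset = 9)
solar_position <- function(latitude_deg, longitude_deg, local_datetime,
                           utc_offset = 0, north_offset_deg = 0) {
  if (latitude_deg < -90 || latitude_deg > 90) {
    stop("latitude must lie in [-90, 90]")
  }
  lt <- tryCatch(as.POSIXlt(local_datetime, tz = "UTC"),
                 error = function(e) NA)
  if (anyNA(lt)) stop("invalid timestamp: ", format(local_datetime))
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  n_year <- if ((lt$year + 1900) %% 4 == 0) 366 else 365
  g <- 2 * pi / n_year * (doy - 1 + (hour - 12) / 24)

  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))

  tst <- hour * 60 + eqtime + 4 * longitude_deg - 60 * utc_offset
  ha <- (tst / 4 - 180) * pi / 180

  lat <- latitude_deg * pi / 180
  cos_zen <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cos_zen <- min(1, max(-1, cos_zen))
  zenith <- acos(cos_zen) * 180 / pi

  # azimuth from south, westward positive, then to clockwise-from-north
  az_s <- atan2(sin(ha), cos(ha) * sin(lat) - tan(decl) * cos(lat))
  azimuth <- (az_s * 180 / pi + 180 + north_offset_deg) %% 360

  structure(list(zenith = zenith, azimuth = azimuth,
                 above_horizon = zenith < 90,
                 declination = decl * 180 / pi,
                 equation_of_time_min = eqtime),
            class = "sun_position")
}

#' @export
print.sun_position <- function(x, ...) {
  cat(sprintf("<sun_position> zenith %.2f deg, azimuth %.2f deg (%s)\n",
              x$zenith, x$azimuth,
              if (x$above_horizon) "above horizon" else "below horizon"))
  invisible(x)
}

# Unit vector pointing from the scene toward the sun (x east, y north, z up).
sun_vector <- function(sun) {
  z <- sun$zenith * pi / 180
  a <- sun$azimuth * pi / 180
  c(sin(z) * sin(a), sin(z) * cos(a), cos(z))
}
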