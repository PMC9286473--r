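# Synthetic seasonal surface shortwave forcing.
#
# The ecosystem only needs the shape and phase of the seasonal light cycle
# (it phases the bloom against the seasonal attenuation cycle), so a
# clear-sky daily-integrated astronomical insolation is used: solar
# declination from obliquity on the 360-day year, sunrise hour angle, no
# clouds or albedo. Day 0 is 1 January and the Southern-Hemisphere summer
# solstice sits on the day 360/0 boundary, so maximum SH radiation aligns
# with the theta = 0 phase convention of the seasonal attenuation cycle.

#' Forcing parameters
#'
#' @param solar_constant total solar irradiance, W m^-2.
#' @param obliquity axial tilt in degrees.
#' @param attenuation_water light attenuation in the water column, m^-1.
#' @param parfrac fraction of shortwave usable for photosynthesis, in (0, 1].
#' @return An object of class `forcing_params`.
#' @export
forcing_params <- function(solar_constant = 1361, obliquity = 23.44,
                           attenuation_water = 0.04, parfrac = 0.4) {
  stopifnot(solar_constant > 0, obliquity > 0, attenuation_water >= 0,
            parfrac > 0, parfrac <= 1)
  structure(list(solar_constant = solar_constant, obliquity = obliquity,
                 attenuation_water = attenuation_water, parfrac = parfrac),
            class = "forcing_params")
}

#' Daily-mean shortwave radiation at the sea surface
#'
#' Standard daily-integrated insolation for a circular orbit:
#' `Q = (S0/pi) (h0 sin(phi) sin(delta) + cos(phi) cos(delta) sin(h0))`
#' with declination `delta = -obliquity * cos(2 pi day / 360)` and sunrise
#' hour angle `cos(h0) = -tan(phi) tan(delta)` (clamped for polar day and
#' night). Vectorised over `day` and `lat`.
#'
#' @param day day of year in [0, 360).
#' @param lat latitude in degrees North, |lat| <= 90.
#' @param params a `forcing_params`.
#' @return daily-mean shortwave at the surface, W m^-2 (>= 0).
#' @export
surface_radiation <- function(day, lat, params = forcing_params()) {
  if (any(abs(lat) > 90)) stop("|lat| must be <= 90")
  day <- day %% 360
  decl <- -params$obliquity * pi / 180 * cos(2 * pi * day / 360)
  phi <- lat * pi / 180
  cos_h0 <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  h0 <- acos(cos_h0)
  q <- params$solar_constant / pi *
    (h0 * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(h0))
  pmax(q, 0)
}

#' Photosynthetically available light at depth
#'
#' Exponential decay of the photosynthetically usable fraction of surface
#' shortwave: `I0 * parfrac * exp(-k z)`.
#'
#' @param I0 surface shortwave, W m^-2.
#' @param z depth in m (>= 0).
#' @param params a `forcing_params`.
#' @return light at depth, W m^-2.
#' @export
light_at_depth <- function(I0, z, params = forcing_params()) {
  if (any(z < 0)) stop("`z` must be >= 0")
  I0 * params$parfrac * exp(-params$attenuation_water * z)
}

#' Dump the forcing field to a CSV table
#'
#' Writes daily-mean surface radiation as a long table (day, lat, swrad) for
#' inspection; units recorded in header comments.
#'
#' @param path output file.
#' @param lats latitudes to tabulate.
#' @param params a `forcing_params`.
#' @param days days of year to tabulate.
#' @return the data frame, invisibly.
#' @export
write_forcing <- function(path, lats = seq(-85, 85, by = 10),
                          params = forcing_params(), days = 0:359) {
  tab <- expand.grid(day = days, lat = lats)
  tab$swrad <- surface_radiation(tab$day, tab$lat, params)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# seapump surface forcing",
               "# day: day of 360-day year; lat: degrees North; swrad: W m-2"), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(tab)
}
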