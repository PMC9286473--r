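# Grid, calendar, tracer state and unit conversions shared by all stages.

#' Model calendar
#'
#' The model year is an idealised 360-day year of twelve 30-day months, the
#' convention used by offline transport-matrix circulations. The time step
#' must divide a month exactly so that monthly operators and monthly output
#' line up with step boundaries.
#'
#' @param dt time step in days (default 0.5). Must divide 30 exactly.
#' @return An object of class `bgc_calendar`.
#' @export
bgc_calendar <- function(dt = 0.5) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  n <- 30 / dt
  if (abs(n - round(n)) > 1e-9) {
    stop("`dt` must divide the 30-day month exactly (got dt = ", dt, ")")
  }
  structure(
    list(year_length = 360L, n_months = 12L, month_length = 30L, dt = dt,
         steps_per_year = as.integer(round(360 / dt))),
    class = "bgc_calendar"
  )
}

#' Default layer interfaces (m)
#'
#' Fifteen layers with interfaces chosen so that 120 m (export depth, bottom
#' of the 2-layer euphotic zone) and 1080 m (transfer depth) are exact layer
#' interfaces, with roughly geometric spacing below the euphotic zone.
#' @export
default_interfaces <- function() {
  c(0, 50, 120, 220, 360, 550, 790, 1080,
    1420, 1810, 2250, 2740, 3280, 3870, 4510, 5200)
}

EARTH_RADIUS_M <- 6371000

#' Build a coarse global latitude-longitude-depth grid
#'
#' Columns are regular latitude-longitude cells on the sphere; the vertical
#' is a fixed 15-layer stack. `bathymetry` is either `"flat"` (all columns
#' reach the deepest interface), or a numeric vector/matrix of bottom depths
#' (m) per column (recycled across longitude if a vector of length `n_lat`),
#' or `"shelf"`, a synthetic one-band shallow shelf used to exercise the
#' 1080-m diagnostic mask.
#'
#' @param n_lat number of latitude bands (even, >= 4).
#' @param n_lon number of longitude columns per band.
#' @param interfaces strictly increasing layer interfaces in m, length 16,
#'   starting at 0 and containing both 120 and 1080.
#' @param bathymetry `"flat"`, `"shelf"`, or numeric bottom depths (m).
#' @param lat_range latitudinal extent in degrees North (default full globe).
#' @return An object of class `bgc_grid`.
#' @export
make_grid <- function(n_lat = 18L, n_lon = 36L,
                      interfaces = default_interfaces(),
                      bathymetry = "flat",
                      lat_range = c(-90, 90)) {
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  if (n_lat < 4L || n_lat %% 2L != 0L) stop("`n_lat` must be an even integer >= 4")
  if (n_lon < 1L) stop("`n_lon` must be >= 1")
  interfaces <- as.numeric(interfaces)
  if (length(interfaces) != 16L) {
    stop("`interfaces` must have length 16 (15 layers), got ", length(interfaces))
  }
  if (interfaces[1] != 0 || any(diff(interfaces) <= 0)) {
    stop("`interfaces` must start at 0 and be strictly increasing")
  }
  if (!any(interfaces == 120) || !any(interfaces == 1080)) {
    stop("`interfaces` must contain both the 120 m and 1080 m horizons")
  }

  n_layer <- 15L
  lat_edges <- seq(lat_range[1], lat_range[2], length.out = n_lat + 1L)
  lat_centers <- (lat_edges[-1] + lat_edges[-(n_lat + 1L)]) / 2
  lon_edges <- seq(0, 360, length.out = n_lon + 1L)
  lon_centers <- (lon_edges[-1] + lon_edges[-(n_lon + 1L)]) / 2

  thickness <- diff(interfaces)
  centers <- (interfaces[-1] + interfaces[-16L]) / 2

  # exact spherical band areas, split evenly in longitude
  band_area <- 2 * pi * EARTH_RADIUS_M^2 *
    (sin(lat_edges[-1] * pi / 180) - sin(lat_edges[-(n_lat + 1L)] * pi / 180))
  n_col <- n_lat * n_lon
  col_lat <- rep(seq_len(n_lat), times = n_lon)   # latitude index per column
  col_lon <- rep(seq_len(n_lon), each = n_lat)
  area <- band_area[col_lat] / n_lon              # m^2 per column

  bottom <- if (identical(bathymetry, "flat")) {
    rep(interfaces[16L], n_col)
  } else if (identical(bathymetry, "shelf")) {
    # shallow shelf (just above 1080 m) on the northernmost band
    b <- rep(interfaces[16L], n_col)
    b[col_lat == n_lat] <- interfaces[which(interfaces == 1080) - 1L]
    b
  } else if (is.numeric(bathymetry)) {
    b <- as.numeric(bathymetry)
    if (length(b) == n_lat) b <- b[col_lat]
    if (length(b) != n_col) stop("numeric `bathymetry` must have length n_lat or n_lat*n_lon")
    b
  } else {
    stop("unknown `bathymetry` specification")
  }
  if (any(bottom < interfaces[2])) stop("bathymetry shallower than the first layer is not supported")

  # wet layers per column: layer k is wet if its bottom interface <= bottom depth
  n_wet <- vapply(bottom, function(b) sum(interfaces[-1] <= b + 1e-9), integer(1))
  wet <- outer(seq_len(n_layer), n_wet, FUN = "<=")
  volume <- matrix(0, n_layer, n_col)
  for (k in seq_len(n_layer)) volume[k, ] <- ifelse(wet[k, ], area * thickness[k], 0)

  grid <- structure(list(
    n_lat = n_lat, n_lon = n_lon, n_layer = n_layer, n_col = n_col,
    lat_edges = lat_edges, lat_centers = lat_centers,
    lon_edges = lon_edges, lon_centers = lon_centers,
    interfaces = interfaces, centers = centers, thickness = thickness,
    area = area, volume = volume, wet = wet, n_wet = n_wet,
    col_lat = col_lat, col_lon = col_lon, bottom = bottom,
    depth_mask = bottom >= 1080,
    i120 = which(interfaces == 120), i1080 = which(interfaces == 1080),
    n_euphotic = sum(interfaces[-1] <= 120 + 1e-9)
  ), class = "bgc_grid")
  stopifnot(grid$n_euphotic == 2L)
  grid
}

#' @export
print.bgc_grid <- function(x, ...) {
  cat("<bgc_grid> ", x$n_lat, "x", x$n_lon, " columns, ", x$n_layer,
      " layers (0-", max(x$interfaces), " m), ",
      sum(x$depth_mask), "/", x$n_col, " columns deeper than 1080 m\n", sep = "")
  invisible(x)
}

#' Tracer state container
#'
#' Five phosphorus-based tracers (mmol P m^-3) on the grid: phosphate (PO4),
#' phytoplankton (PHY), zooplankton (ZOO), detritus (DET) and dissolved
#' organic phosphorus (DOP). Fields are `n_layer x n_col` matrices; dry
#' cells are held at NA.
#'
#' @param grid a `bgc_grid`.
#' @param PO4,PHY,ZOO,DET,DOP scalar or matrix initial concentrations.
#' @param time simulation time in days.
#' @return An object of class `tracer_state`.
#' @export
tracer_state <- function(grid, PO4 = 0, PHY = 0, ZOO = 0, DET = 0, DOP = 0,
                         time = 0) {
  as_field <- function(x) {
    m <- matrix(0, grid$n_layer, grid$n_col)
    m[] <- x
    if (any(m[grid$wet] < 0)) stop("tracer concentrations must be >= 0")
    m[!grid$wet] <- NA_real_
    m
  }
  structure(list(PO4 = as_field(PO4), PHY = as_field(PHY), ZOO = as_field(ZOO),
                 DET = as_field(DET), DOP = as_field(DOP), time = time),
            class = "tracer_state")
}

tracer_names <- function() c("PO4", "PHY", "ZOO", "DET", "DOP")

#' Convert phosphorus to carbon mass
#'
#' Uses the Redfield ratio C:N:P = 106:16:1 and a carbon molar mass of
#' 12.011 g mol^-1: 1 mmol P corresponds to 106 mmol C = 1.273 g C.
#'
#' @param x phosphorus amount in mmol P (any shape).
#' @return carbon mass in g C.
#' @export
phosphorus_to_carbon <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("phosphorus amounts must be >= 0")
  x * 106 * 12.011 * 1e-3
}

#' Total phosphorus inventory
#'
#' Volume-weighted sum of all five tracers over all wet cells (mmol P).
#' A plain volume integral: invariant under permutation of tracer labels.
#'
#' @param state a `tracer_state`.
#' @param grid the `bgc_grid` the state lives on.
#' @return total phosphorus in mmol P.
#' @export
total_phosphorus <- function(state, grid) {
  tot <- 0
  for (nm in tracer_names()) {
    f <- state[[nm]]
    tot <- tot + sum(f[grid$wet] * grid$volume[grid$wet])
  }
  tot
}
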