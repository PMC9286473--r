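# Flux-attenuation mathematics: Martin curve, transfer efficiency,
# attenuation <-> sinking-speed conversions, the seasonal cosine
# parameterisation and its closed-form annual means.
#
# The particle flux profile is F(z) = F(z0) (z/z0)^-b.  With a first-order
# remineralisation rate lambda and a sinking speed increasing linearly with
# depth, w(z) = a z, the no-circulation steady state is exactly this power
# law with b = lambda / a.  Seasonality enters as a cosine perturbation of
# the model-imposed exponent,
#   b_season(t, phi, theta) = b_ref -/+ delta_b cos(2 pi t/T + theta pi/6)
# (minus in the Northern Hemisphere, plus in the Southern, unperturbed on
# the equator), which makes the sinking-speed coefficient
# A(t) = lambda / b_season time dependent and, because 1/b is convex,
# biases its annual mean fast: mean(A) = lambda / sqrt(b_ref^2 - delta_b^2).

#' Seasonal attenuation parameter bundle
#'
#' @param b_ref reference (annual-mean) attenuation exponent, dimensionless.
#' @param delta_b_frac seasonal amplitude as a fraction of `b_ref` (the
#'   notation delta_b = 0.6 b_ref); ignored when `delta_b` is given.
#' @param delta_b absolute seasonal amplitude, 0 <= delta_b <= b_ref.
#' @param theta seasonal phase in months: the time of the Northern-Hemisphere
#'   minimum of b relative to 1 January. Any real value; 12 months is a full
#'   cycle (theta enters as theta * pi / 6).
#' @param lam detritus remineralisation rate lambda, day^-1.
#' @param period length of the seasonal cycle T in days.
#' @param lambda_variant optional seasonal-remineralisation variant:
#'   `"none"` (default, constant lambda), `"lambda_only"` (lambda varies with
#'   the same cosine and relative amplitude while b stays at `b_ref`) or
#'   `"constant_a"` (lambda and b vary in proportion so the sinking
#'   coefficient a = lambda/b stays constant).
#' @return An object of class `seasonal_attenuation`.
#' @export
seasonal_attenuation <- function(b_ref = 1.388, delta_b_frac = 0.6,
                                 delta_b = NULL, theta = 0, lam = 0.05,
                                 period = 360,
                                 lambda_variant = c("none", "lambda_only",
                                                    "constant_a")) {
  lambda_variant <- match.arg(lambda_variant)
  stopifnot(b_ref > 0, lam > 0, period > 0, is.numeric(theta))
  if (is.null(delta_b)) delta_b <- delta_b_frac * b_ref
  if (delta_b < 0 || delta_b > b_ref) {
    stop("`delta_b` must satisfy 0 <= delta_b <= b_ref")
  }
  structure(list(b_ref = b_ref, delta_b = delta_b, theta = theta, lam = lam,
                 period = period, lambda_variant = lambda_variant),
            class = "seasonal_attenuation")
}

#' @export
print.seasonal_attenuation <- function(x, ...) {
  cat(sprintf(
    "<seasonal_attenuation> b_ref=%.4g delta_b=%.4g (%.0f%%) theta=%g months lambda=%.3g/d%s\n",
    x$b_ref, x$delta_b, 100 * x$delta_b / x$b_ref, x$theta, x$lam,
    if (x$lambda_variant == "none") "" else paste0(" [", x$lambda_variant, "]")))
  invisible(x)
}

#' Martin-curve flux at depth
#'
#' `F(z) = F(z0) * (z/z0)^-b`.
#'
#' @param F_z0 flux at the reference depth.
#' @param z0 reference depth in m (> 0).
#' @param z target depth in m (>= z0).
#' @param b attenuation exponent (>= 0).
#' @return flux at depth `z`, same units as `F_z0`.
#' @export
martin_flux <- function(F_z0, z0, z, b) {
  if (any(z0 <= 0)) stop("`z0` must be > 0")
  if (any(z < z0)) stop("`z` must be >= `z0`")
  if (any(b < 0)) stop("`b` must be >= 0")
  F_z0 * (z / z0)^(-b)
}

#' Martin-curve transfer efficiency
#'
#' Fraction of the export flux at `z0` surviving to `z1`:
#' `TE = (z1/z0)^-b`. Defaults to the 120 m export and 1080 m transfer
#' horizons used by the diagnostics.
#'
#' @param b attenuation exponent.
#' @param z0 export depth in m.
#' @param z1 transfer depth in m (> z0).
#' @return transfer efficiency in (0, 1] for b >= 0.
#' @export
martin_te <- function(b, z0 = 120, z1 = 1080) {
  if (any(z0 <= 0) || any(z1 <= z0)) stop("need z1 > z0 > 0")
  (z1 / z0)^(-b)
}

#' Sinking-speed coefficient from the attenuation exponent
#'
#' `a = lambda / b`: the slope of the depth-linear sinking speed w(z) = a z
#' that yields a Martin exponent `b` in the no-circulation steady state.
#'
#' @param lam remineralisation rate, day^-1.
#' @param b attenuation exponent (> 0).
#' @return a in day^-1.
#' @export
sinking_coefficient <- function(lam, b) {
  if (any(b <= 0)) stop("`b` must be > 0")
  lam / b
}

#' Seasonally varying attenuation exponent
#'
#' Cosine seasonality with opposite sign in the two hemispheres (the cycle
#' is tied to local seasons) and no seasonality on the equator:
#' `b_ref - delta_b cos(2 pi t/T + theta pi/6)` for `phi > 0`,
#' `b_ref + delta_b cos(...)` for `phi < 0`, `b_ref` for `phi = 0`.
#'
#' @param t time in days (any real; periodic).
#' @param phi latitude in degrees North.
#' @param params a `seasonal_attenuation`.
#' @return exponent value(s) in `[b_ref - delta_b, b_ref + delta_b]`.
#' @export
seasonal_b <- function(t, phi, params) {
  if (params$lambda_variant == "lambda_only") {
    return(rep(params$b_ref, length.out = max(length(t), length(phi))))
  }
  osc <- params$delta_b * cos(2 * pi * t / params$period + params$theta * pi / 6)
  params$b_ref - sign(phi) * osc
}

# Seasonal remineralisation rate lambda(t, phi); constant unless a
# lambda_variant is selected.
#' Seasonal remineralisation rate
#'
#' Constant `lam` by default. Under `lambda_variant = "lambda_only"` lambda
#' carries the cosine seasonality (relative amplitude delta_b/b_ref, same
#' phase and hemisphere flip) while b stays constant; under `"constant_a"`
#' lambda varies in proportion to the seasonal b so that a = lambda/b is
#' constant in time.
#'
#' @inheritParams seasonal_b
#' @return lambda in day^-1.
#' @export
seasonal_lambda <- function(t, phi, params) {
  n <- max(length(t), length(phi))
  if (params$lambda_variant == "none") return(rep(params$lam, length.out = n))
  rel <- (params$delta_b / params$b_ref) *
    cos(2 * pi * t / params$period + params$theta * pi / 6)
  params$lam * (1 - sign(phi) * rel)
}

#' Seasonally varying sinking-speed coefficient
#'
#' `A(t) = lambda(t) / b_season(t)`. Requires `delta_b < b_ref` strictly so
#' that A stays finite.
#'
#' @inheritParams seasonal_b
#' @return A in day^-1.
#' @export
seasonal_A <- function(t, phi, params) {
  if (params$delta_b >= params$b_ref && params$lambda_variant != "lambda_only") {
    stop("`delta_b` must be < `b_ref` for the sinking coefficient A(t) to stay finite")
  }
  seasonal_lambda(t, phi, params) / seasonal_b(t, phi, params)
}

#' Annual mean of the seasonal sinking coefficient
#'
#' Closed form `lambda / sqrt(b_ref^2 - delta_b^2)` for the cosine
#' parameterisation with constant lambda (the mean of 1/b over a full cosine
#' cycle). For the seasonal-lambda variants the mean is computed by
#' quadrature.
#'
#' @param params a `seasonal_attenuation` with `delta_b < b_ref`.
#' @return mean A in day^-1.
#' @export
mean_A <- function(params) {
  if (params$lambda_variant == "none") {
    if (params$delta_b >= params$b_ref) {
      stop("`delta_b` must be < `b_ref` for mean_A")
    }
    return(params$lam / sqrt(params$b_ref^2 - params$delta_b^2))
  }
  stats::integrate(function(t) seasonal_A(t, phi = 45, params = params),
                   0, params$period, rel.tol = 1e-12)$value / params$period
}

#' Equivalent constant attenuation exponent
#'
#' The constant exponent with the same annual-mean sinking coefficient:
#' `lambda / mean_A = sqrt(b_ref^2 - delta_b^2)` for constant lambda. The
#' seasonal cycle in b therefore behaves, on annual average, like a
#' *smaller* constant exponent (faster mean sinking).
#'
#' @inheritParams mean_A
#' @return dimensionless exponent.
#' @export
equivalent_b <- function(params) {
  params$lam / mean_A(params)
}

#' Seasonal sinking speed at depth
#'
#' `W(z, t) = A(t, phi) * z`, m day^-1.
#'
#' @param z depth in m (>= 0).
#' @inheritParams seasonal_b
#' @return sinking speed in m day^-1.
#' @export
sinking_speed <- function(z, t, phi, params) {
  if (any(z < 0)) stop("`z` must be >= 0")
  seasonal_A(t, phi, params) * z
}

#' Transit time between two depths under w = a z
#'
#' Solving dz/dt = a z gives t = ln(z2/z1) / a. A particle starting at
#' exactly z = 0 never reaches depth, so z1 must be positive.
#'
#' @param z1 start depth in m (> 0).
#' @param z2 end depth in m (> z1).
#' @param a sinking-speed coefficient in day^-1 (> 0).
#' @return transit time in days.
#' @export
transit_time <- function(z1, z2, a) {
  if (any(z1 <= 0)) stop("`z1` must be > 0 (a particle at exactly 0 m never sinks)")
  if (any(z2 <= z1)) stop("`z2` must be > `z1`")
  if (any(a <= 0)) stop("`a` must be > 0")
  log(z2 / z1) / a
}
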