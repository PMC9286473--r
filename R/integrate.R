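# Time stepping, spin-up to a quasi-repeating annual cycle, run management.
#
# Operator splitting per step, in order: transport (incremental monthly
# operators, linearly interpolated between the two nearest mid-months),
# ecosystem tendencies (with the current insolation and a conservative
# positivity limiter), then detritus sinking.  The phosphorus budget is
# closed at every stage; sinking last makes the diagnosed interface fluxes
# consistent with the end-of-step detritus field.

#' Run configuration
#'
#' Bundles everything a run needs. `transport` is either a scheme name
#' (`"off"`, `"mixing_only"`, `"overturning"`) with operators built on
#' demand, or a prebuilt list of 12 operators.
#'
#' @param grid a `bgc_grid` (default desk-scale 18 x 36).
#' @param calendar a `bgc_calendar`.
#' @param att a `seasonal_attenuation`.
#' @param eco an `ecosystem_params`.
#' @param forcing a `forcing_params`.
#' @param transport scheme name or list of 12 `transport_operator`s.
#' @param transport_args named list passed to [build_transport()].
#' @param po4_init initial uniform phosphate, mmol P m^-3.
#' @param bio_seed tiny initial phytoplankton/zooplankton seed, mmol P m^-3.
#' @param perturb amplitude of a random multiplicative perturbation of the
#'   initial phosphate (0 disables; uses `seed`).
#' @param n_years_max spin-up cap in years.
#' @param convergence_tol relative per-year drift of annual-mean tracer
#'   inventories below which the cycle counts as converged.
#' @param seed RNG seed (only used when `perturb > 0`).
#' @param restore_po4 optional surface-nutrient restoring,
#'   `list(rate = <day^-1>, target = <mmol P m^-3>, layers = <indices>)`.
#'   A closed column with circulation off exports phosphorus irreversibly
#'   and runs down to extinction; restoring stands in for the missing
#'   resupply so a sustained annual cycle exists. It deliberately breaks
#'   phosphorus conservation and is off by default (used by
#'   [column_config()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(grid = make_grid(), calendar = bgc_calendar(),
                       att = seasonal_attenuation(), eco = ecosystem_params(),
                       forcing = forcing_params(), transport = "off",
                       transport_args = list(), po4_init = 2.17,
                       bio_seed = 1e-3, perturb = 0, n_years_max = 50L,
                       convergence_tol = 1e-4, seed = 1L,
                       restore_po4 = NULL) {
  stopifnot(n_years_max >= 1L, convergence_tol > 0, po4_init >= 0)
  if (!is.null(restore_po4)) {
    stopifnot(restore_po4$rate > 0, restore_po4$target >= 0)
    if (is.null(restore_po4$layers)) restore_po4$layers <- 1L
  }
  structure(list(grid = grid, calendar = calendar, att = att, eco = eco,
                 forcing = forcing, transport = transport,
                 transport_args = transport_args, po4_init = po4_init,
                 bio_seed = bio_seed, perturb = perturb,
                 n_years_max = as.integer(n_years_max),
                 convergence_tol = convergence_tol, seed = as.integer(seed),
                 restore_po4 = restore_po4),
            class = "run_config")
}

#' Smoke-scale configuration for directional experiments
#'
#' A hemisphere-symmetric 8-band meridional world (the synthetic
#' circulation and forcing are zonally uniform, so one longitude column
#' loses nothing) with the calibrated overturning-plus-mixing circulation.
#' This is the scaled-down stand-in for the global experiment grid: the
#' directions of the seasonal effects are meaningful here, the magnitudes
#' are not.
#'
#' @param att a `seasonal_attenuation` for the variant.
#' @param n_years_max spin-up cap.
#' @param ... further arguments passed to [run_config()].
#' @return a `run_config`.
#' @export
smoke_config <- function(att = seasonal_attenuation(), n_years_max = 60L,
                         ...) {
  run_config(grid = make_grid(n_lat = 8, n_lon = 1), att = att,
             transport = "overturning", n_years_max = n_years_max,
             convergence_tol = 1e-4, ...)
}

#' Single-column configuration for the no-circulation limit
#'
#' A thin meridional strip of independent columns with circulation off and
#' surface-nutrient restoring, the configuration in which the model's
#' annual-mean flux profile must converge to the Martin power law with
#' exponent `b` and transfer efficiency `(1080/120)^-b`.
#'
#' @param b the (constant) imposed attenuation exponent.
#' @param n_years_max spin-up cap.
#' @param restore_rate restoring rate for surface phosphate, day^-1.
#' @param ... further arguments passed to [run_config()].
#' @return a `run_config`.
#' @export
column_config <- function(b = 1.388, n_years_max = 40L, restore_rate = 1 / 50,
                          restore_target = 0.5, ...) {
  # restoring acts on the whole column: at the surface it resupplies the
  # nutrient (a gentle, oligotrophic supply so biomass stays realistic), at
  # depth it absorbs the rained-out phosphorus that a closed column would
  # otherwise accumulate without bound
  run_config(grid = make_grid(n_lat = 4, n_lon = 1),
             att = seasonal_attenuation(b_ref = b, delta_b = 0),
             transport = "off", n_years_max = n_years_max,
             restore_po4 = list(rate = restore_rate, target = restore_target,
                                layers = seq_len(15L)),
             ...)
}

resolve_transport <- function(config) {
  if (is.character(config$transport)) {
    do.call(build_transport, c(list(scheme = config$transport,
                                    grid = config$grid),
                               config$transport_args))
  } else {
    config$transport
  }
}

#' Initial tracer state for a run configuration
#'
#' Uniform phosphate at `po4_init`, a small phytoplankton/zooplankton seed
#' confined to the euphotic layers, and empty detritus and DOP pools; an
#' optional random multiplicative perturbation of phosphate (seeded) can
#' break symmetry.
#'
#' @param config a `run_config`.
#' @return a `tracer_state`.
#' @export
initial_state <- function(config) {
  grid <- config$grid
  st <- tracer_state(grid, PO4 = config$po4_init, PHY = config$bio_seed,
                     ZOO = config$bio_seed / 10)
  # biomass seed only where there is light to use it
  st$PHY[-seq_len(grid$n_euphotic), ] <- 0
  st$ZOO[-seq_len(grid$n_euphotic), ] <- 0
  if (config$perturb > 0) {
    set.seed(config$seed)
    pert <- 1 + config$perturb * (stats::runif(grid$n_col) - 0.5)
    st$PO4 <- sweep(st$PO4, 2, pert, `*`)
  }
  for (nm in tracer_names()) st[[nm]][!grid$wet] <- NA_real_
  st
}

# incremental transport: c += dt * (w1 R1 + w2 R2) c, with R = M - I
transport_rates <- function(ops) {
  lapply(ops, function(op) op$M - Matrix::Diagonal(nrow(op$M)))
}

month_weights <- function(t) {
  # linear interpolation between mid-months on the 360-day year
  tm <- (t %% 360) / 30                          # in months
  m_lo <- floor(tm - 0.5)
  w_hi <- (tm - 0.5) - m_lo
  lo <- (as.integer(m_lo) %% 12L) + 1L
  hi <- (lo %% 12L) + 1L
  list(lo = lo, hi = hi, w_lo = 1 - w_hi, w_hi = w_hi)
}

#' Advance the model state by one time step
#'
#' Applies transport, ecosystem tendencies and detritus sinking in that
#' order, advancing `state$time` by `calendar$dt`. Positivity is enforced by
#' a conservative per-cell limiter (the whole tendency vector of a cell is
#' scaled down when a pool would go negative, so the phosphorus budget
#' stays closed). NaN or negative concentrations abort with a diagnostic.
#'
#' @param state a `tracer_state`.
#' @param config a `run_config`.
#' @param rates precomputed list of 12 incremental transport matrices
#'   (`M - I`); see [build_transport()].
#' @param rad optional precomputed 360 x n_col daily surface radiation table.
#' @return list with `state`, `interface_flux` (16 x n_col, mmol P m^-2
#'   day^-1) and `PP` (mmol P m^-3 day^-1).
#' @export
step_state <- function(state, config, rates = NULL, rad = NULL) {
  grid <- config$grid; dt <- config$calendar$dt
  t <- state$time

  if (is.null(rates)) rates <- transport_rates(resolve_transport(config))
  mw <- month_weights(t)
  R_lo <- rates[[mw$lo]]; R_hi <- rates[[mw$hi]]
  for (nm in tracer_names()) {
    f <- state[[nm]]
    v <- f[grid$wet]
    dv <- mw$w_lo * as.numeric(R_lo %*% v) + mw$w_hi * as.numeric(R_hi %*% v)
    f[grid$wet] <- v + dt * dv
    state[[nm]] <- f
  }

  day <- floor(t) %% 360
  I_surf <- if (is.null(rad)) {
    surface_radiation(day, grid$lat_centers[grid$col_lat], config$forcing)
  } else {
    rad[day + 1L, ]
  }
  tend <- ecosystem_tendencies(state, I_surf, config$eco, grid,
                               config$forcing, config$att, t)
  # sinking increments computed from the same state, so decay and sinking
  # act simultaneously: the fixed point then satisfies the exact rate
  # balance and the no-circulation steady flux profile is Martin at any dt
  sk <- sink_detritus(state$DET, t, config$att, grid, dt)
  sink_inc <- sk$DET - state$DET

  # conservative positivity limiter: scale a cell's whole tendency vector.
  # The sinking removal is bounded away from the full inventory, so only
  # the ecosystem tendencies need limiting; headroom for the sinking
  # increment is reserved by limiting against the post-sinking detritus.
  avail <- state
  avail$DET <- sk$DET
  scale <- matrix(Inf, grid$n_layer, grid$n_col)
  for (nm in tracer_names()) {
    tn <- tend[[nm]]
    neg <- which(tn < 0)
    if (length(neg)) {
      scale[neg] <- pmin(scale[neg], avail[[nm]][neg] / (-tn[neg] * dt))
    }
  }
  scale <- pmin(1, 0.99 * scale)
  for (nm in tracer_names()) {
    state[[nm]] <- state[[nm]] + dt * tend[[nm]] * scale
  }
  state$DET <- state$DET + sink_inc
  bottom_cells <- cbind(grid$n_wet, seq_len(grid$n_col))
  state$PO4[bottom_cells] <- state$PO4[bottom_cells] +
    sk$seafloor_flux * dt / grid$thickness[grid$n_wet]

  if (!is.null(config$restore_po4)) {
    rp <- config$restore_po4
    k <- rp$layers
    state$PO4[k, ] <- state$PO4[k, ] +
      dt * rp$rate * (rp$target - state$PO4[k, , drop = FALSE])
  }

  state$time <- t + dt
  wetv <- unlist(lapply(tracer_names(), function(nm) state[[nm]][grid$wet]))
  if (anyNA(wetv) || any(wetv < 0)) {
    bad <- tracer_names()[vapply(tracer_names(), function(nm)
      anyNA(state[[nm]][grid$wet]) || any(state[[nm]][grid$wet] < 0), logical(1))]
    stop("step_state: invalid state (NaN/negative) at t = ", t,
         " in tracer(s): ", paste(bad, collapse = ", "))
  }
  list(state = state, interface_flux = sk$interface_flux,
       PP = tend$PP * scale)
}

#' Integrate to a quasi-repeating annual cycle
#'
#' Runs year by year until the maximum relative change of any tracer's
#' global mean between consecutive years drops below `convergence_tol`, or
#' `n_years_max` is reached (non-convergence is flagged in the output, not
#' an error). The final year's monthly climatology of tracers, interface
#' fluxes and primary production is recorded. Deterministic given the
#' configuration.
#'
#' @param config a `run_config`.
#' @param verbose print per-decade drift.
#' @return An object of class `annual_cycle`: monthly tracer climatology
#'   (`n_layer x n_col x 12` per tracer), monthly interface fluxes
#'   (`16 x n_col x 12`), monthly PP, convergence history, flags.
#' @export
run_to_cycle <- function(config, verbose = FALSE) {
  grid <- config$grid; cal <- config$calendar
  ops <- resolve_transport(config)
  for (op in ops) validate_transport(op, grid)
  rates <- transport_rates(ops)
  rad <- t(vapply(0:359, function(d)
    surface_radiation(d, grid$lat_centers[grid$col_lat], config$forcing),
    numeric(grid$n_col)))

  state <- initial_state(config)
  steps_year <- cal$steps_per_year
  steps_month <- as.integer(round(cal$month_length / cal$dt))

  mean_prev <- NULL
  history <- data.frame(year = integer(0), drift = numeric(0))
  converged <- FALSE
  vol <- grid$volume[grid$wet]; vtot <- sum(vol)

  monthly <- NULL
  for (year in seq_len(config$n_years_max)) {
    acc_tr <- lapply(tracer_names(), function(nm)
      array(0, c(grid$n_layer, grid$n_col, 12L)))
    names(acc_tr) <- tracer_names()
    acc_fl <- array(0, c(grid$n_layer + 1L, grid$n_col, 12L))
    acc_pp <- array(0, c(grid$n_layer, grid$n_col, 12L))
    for (s in seq_len(steps_year)) {
      m <- ((s - 1L) %/% steps_month) + 1L
      out <- step_state(state, config, rates, rad)
      state <- out$state
      for (nm in tracer_names()) {
        acc_tr[[nm]][, , m] <- acc_tr[[nm]][, , m] + state[[nm]]
      }
      acc_fl[, , m] <- acc_fl[, , m] + out$interface_flux
      acc_pp[, , m] <- acc_pp[, , m] + out$PP
    }
    for (nm in tracer_names()) acc_tr[[nm]] <- acc_tr[[nm]] / steps_month
    acc_fl <- acc_fl / steps_month
    acc_pp <- acc_pp / steps_month
    monthly <- list(tracers = acc_tr, flux = acc_fl, PP = acc_pp)

    mean_now <- vapply(tracer_names(), function(nm) {
      yr <- apply(acc_tr[[nm]], 1:2, mean)
      sum(yr[grid$wet] * vol) / vtot
    }, numeric(1))
    if (!is.null(mean_prev)) {
      # common scale: the global-mean total-phosphorus concentration, so a
      # vanishing pool cannot stall convergence with a large relative drift
      scale <- max(sum(mean_now), 1e-8)
      drift <- max(abs(mean_now - mean_prev)) / scale
      history <- rbind(history, data.frame(year = year, drift = drift))
      if (verbose && (year %% 10L == 0L)) {
        message(sprintf("year %d: drift %.3e", year, drift))
      }
      if (drift < config$convergence_tol) { converged <- TRUE }
    }
    mean_prev <- mean_now
    if (converged) break
  }

  structure(list(
    monthly_tracers = monthly$tracers, monthly_flux = monthly$flux,
    monthly_PP = monthly$PP, convergence = history, converged = converged,
    years_run = if (nrow(history)) max(history$year) else 1L,
    grid = grid, config = config, final_state = state
  ), class = "annual_cycle")
}

#' @export
print.annual_cycle <- function(x, ...) {
  cat("<annual_cycle> ", x$years_run, " years, ",
      if (x$converged) "converged" else "NOT converged",
      if (nrow(x$convergence))
        sprintf(" (final drift %.2e)", utils::tail(x$convergence$drift, 1)) else "",
      "\n", sep = "")
  invisible(x)
}
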