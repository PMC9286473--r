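# NPZD-DOP biogeochemical tendencies and explicit detritus sinking.
#
# Five phosphorus pools: PO4 (nutrient), PHY, ZOO, DET (sinking detritus)
# and DOP (slowly remineralising dissolved organic phosphorus).  Growth is
# light x nutrient limited (Smith P-I curve, Monod nutrient term) and
# confined to the euphotic zone (top 2 layers); grazing is Holling-III;
# phytoplankton has linear + quadratic losses and zooplankton a quadratic
# closure.  A fraction sigma_DOP of all non-grazing losses and egestion is
# routed to DOP, the remainder to DET.  DET remineralises at lambda
# (0.05 day^-1, shared with the attenuation module) and DOP at a slow rate.
# The five tendencies sum to zero in every cell: phosphorus is only moved
# between pools, never created.

#' Ecosystem parameters
#'
#' Only `lambda_DET` (= the attenuation module's lambda) and the
#' depth-linear sinking law are fixed by the flux-attenuation analysis; the
#' remaining values are conventional NPZD-DOP calibrations and are exposed
#' here so sensitivity is cheap.
#'
#' @param mu_max maximum phytoplankton growth rate, day^-1.
#' @param alpha initial slope of the P-I curve, (W m^-2)^-1 day^-1.
#' @param K_N half-saturation for nutrient uptake, mmol P m^-3.
#' @param g_max maximum grazing rate, day^-1.
#' @param K_P grazing half-saturation, mmol P m^-3.
#' @param m_P linear phytoplankton loss, day^-1.
#' @param m_P2 quadratic phytoplankton mortality, (mmol P m^-3)^-1 day^-1.
#' @param m_Z2 quadratic zooplankton mortality, (mmol P m^-3)^-1 day^-1.
#' @param gamma_Z zooplankton assimilation efficiency, in [0, 1].
#' @param sigma_DOP fraction of non-grazing losses routed to DOP, in [0, 1].
#' @param lambda_DET detritus remineralisation rate, day^-1 (the Martin
#'   lambda; keep equal to the attenuation bundle's `lam`).
#' @param lambda_DOP DOP remineralisation rate, day^-1.
#' @return An object of class `ecosystem_params`.
#' @export
ecosystem_params <- function(mu_max = 2, alpha = 0.025, K_N = 0.03,
                             g_max = 2, K_P = 0.1, m_P = 0.03, m_P2 = 0.05,
                             m_Z2 = 3, gamma_Z = 0.75, sigma_DOP = 0.15,
                             lambda_DET = 0.05, lambda_DOP = 1 / 360) {
  p <- list(mu_max = mu_max, alpha = alpha, K_N = K_N, g_max = g_max,
            K_P = K_P, m_P = m_P, m_P2 = m_P2, m_Z2 = m_Z2,
            gamma_Z = gamma_Z, sigma_DOP = sigma_DOP,
            lambda_DET = lambda_DET, lambda_DOP = lambda_DOP)
  if (any(unlist(p) < 0)) stop("ecosystem parameters must be >= 0")
  if (gamma_Z > 1 || sigma_DOP > 1) stop("gamma_Z and sigma_DOP must be in [0, 1]")
  structure(p, class = "ecosystem_params")
}

#' Ecosystem source-minus-sink tendencies
#'
#' Computes per-cell tendencies (mmol P m^-3 day^-1) for the five tracers.
#' The sum over tracers is exactly zero in every cell. Growth is confined to
#' the euphotic layers; remineralisation acts everywhere. When `att` uses a
#' seasonal-lambda variant, the detritus remineralisation rate follows
#' `seasonal_lambda(t, phi, att)`; otherwise `eco$lambda_DET` is used.
#'
#' @param state a `tracer_state` (nonnegative).
#' @param I_surface surface shortwave per column, W m^-2 (length `n_col`).
#' @param eco an `ecosystem_params`.
#' @param grid the `bgc_grid`.
#' @param forcing a `forcing_params` (for light attenuation in water).
#' @param att optional `seasonal_attenuation` driving a time-varying lambda.
#' @param t time in days (used only with seasonal-lambda variants).
#' @return list with one tendency matrix per tracer plus `PP`, the gross
#'   primary production field (mmol P m^-3 day^-1).
#' @export
ecosystem_tendencies <- function(state, I_surface, eco, grid,
                                 forcing = forcing_params(), att = NULL,
                                 t = state$time) {
  if (any(I_surface < 0)) stop("`I_surface` must be >= 0")
  for (nm in tracer_names()) {
    f <- state[[nm]][grid$wet]
    if (anyNA(f) || any(f < 0)) stop("negative or NaN ", nm, " in state")
  }
  PO4 <- state$PO4; PHY <- state$PHY; ZOO <- state$ZOO
  DET <- state$DET; DOP <- state$DOP
  nl <- grid$n_layer; nc <- grid$n_col

  lam_det <- if (!is.null(att) && att$lambda_variant != "none") {
    matrix(rep(seasonal_lambda(t, grid$lat_centers[grid$col_lat], att),
               each = nl), nl, nc)
  } else eco$lambda_DET

  # light-and-nutrient limited growth in the euphotic layers
  G <- matrix(0, nl, nc)
  for (k in seq_len(grid$n_euphotic)) {
    Ik <- light_at_depth(I_surface, grid$centers[k], forcing)
    f_I <- eco$alpha * Ik / sqrt(eco$mu_max^2 + (eco$alpha * Ik)^2)
    G[k, ] <- eco$mu_max * f_I * PO4[k, ] / (eco$K_N + PO4[k, ]) * PHY[k, ]
  }

  graz <- eco$g_max * PHY^2 / (eco$K_P^2 + PHY^2) * ZOO
  loss_P <- eco$m_P * PHY + eco$m_P2 * PHY^2
  loss_Z <- eco$m_Z2 * ZOO^2
  egest <- (1 - eco$gamma_Z) * graz
  L <- loss_P + loss_Z + egest

  remin_det <- lam_det * DET
  remin_dop <- eco$lambda_DOP * DOP

  tend <- list(
    PO4 = -G + remin_det + remin_dop,
    PHY = G - graz - loss_P,
    ZOO = eco$gamma_Z * graz - loss_Z,
    DET = (1 - eco$sigma_DOP) * L - remin_det,
    DOP = eco$sigma_DOP * L - remin_dop,
    PP = G
  )
  for (nm in tracer_names()) tend[[nm]][!grid$wet] <- NA_real_
  tend$PP[!grid$wet] <- NA_real_
  tend
}

# Reconstruction factor for the sinking flux: ratio of the concentration at
# a layer's bottom interface to the layer mean, assuming the within-layer
# steady power-law shape c(z) ~ z^-(b+1) implied by w = A z and decay
# lambda (b = lambda/A).  With this factor the discrete no-circulation
# steady state reproduces the Martin profile exactly, layer by layer; a
# plain upwind evaluation at the interface overestimates the flux on coarse
# layers.  Layers whose top is the surface (z_top = 0) fall back to plain
# upwind (factor 1): the power-law shape does not apply in the production
# zone and the integral would diverge.
sinking_recon_factor <- function(z_top, z_bot, b) {
  p <- b + 1
  h <- z_bot - z_top
  if (z_top <= 0) return(rep(1, length.out = length(b)))
  ifelse(abs(p - 1) < 1e-12,
         z_bot^(-1) * h / log(z_bot / z_top),
         z_bot^(-p) * h * (p - 1) / (z_top^(1 - p) - z_bot^(1 - p)))
}

#' Sink detritus through the water column
#'
#' Conservative flux-form transport of detritus with the depth-linear,
#' seasonally varying sinking speed `W(z, t) = A(t, phi) z`, evaluated at
#' layer interfaces with a power-law within-layer reconstruction (see
#' Details). The update is explicit with automatic sub-stepping so that no
#' layer exports more detritus than it holds. Flux through the seafloor is
#' returned separately and is expected to be remineralised into the bottom
#' cell's phosphate by the caller (no burial), which closes the phosphorus
#' budget.
#'
#' @details The flux at a layer's bottom interface is
#' `A z_bot * DET_layer * f`, where `f` rescales the layer-mean
#' concentration to its value at the interface under the steady shape
#' `c(z) ~ z^-(b+1)` with `b = lambda/A` the instantaneous exponent. This
#' choice makes the scheme's no-circulation steady state match the Martin
#' power law exactly at every interface, which is the analytic limit the
#' model must honour.
#'
#' @param DET detritus field, mmol P m^-3 (`n_layer x n_col`, NA on dry cells).
#' @param t time in days.
#' @param att a `seasonal_attenuation`.
#' @param grid the `bgc_grid`.
#' @param dt time step in days.
#' @return list with `DET` (updated field), `interface_flux` (a
#'   `16 x n_col` matrix of time-mean fluxes through each interface,
#'   mmol P m^-2 day^-1; the 120 m and 1080 m horizons are rows
#'   `grid$i120` and `grid$i1080`) and `seafloor_flux` (mmol P m^-2 day^-1
#'   per column).
#' @export
sink_detritus <- function(DET, t, att, grid, dt) {
  if (any(DET[grid$wet] < 0)) stop("`DET` must be >= 0")
  nl <- grid$n_layer; nc <- grid$n_col
  phi <- grid$lat_centers[grid$col_lat]
  A <- seasonal_A(t, phi, att)                 # day^-1 per column
  b <- seasonal_lambda(t, phi, att) / A        # instantaneous exponent

  # per-layer export rate r_k = A z_bot f_k / h_k (day^-1), limited by
  # sub-stepping to keep the explicit update positive
  f <- matrix(0, nl, nc)
  for (k in seq_len(nl)) {
    f[k, ] <- sinking_recon_factor(grid$interfaces[k], grid$interfaces[k + 1], b)
  }
  r <- sweep(f, 2, A, `*`) * grid$interfaces[-1] / grid$thickness
  r[!grid$wet] <- 0
  n_sub <- max(1L, ceiling(dt * max(r) / 0.9))
  dts <- dt / n_sub

  flux_acc <- matrix(0, nl + 1L, nc)
  floor_acc <- numeric(nc)
  is_bottom <- outer(seq_len(nl), grid$n_wet, FUN = "==")
  h <- matrix(grid$thickness, nl, nc)
  DET[!grid$wet] <- 0
  for (s in seq_len(n_sub)) {
    Fout <- r * DET * h                        # flux through each layer's bottom
    DET <- DET - r * DET * dts                 # interface, mmol P m^-2 day^-1
    gain <- rbind(0, Fout[-nl, , drop = FALSE]) * dts / h
    gain[!grid$wet] <- 0                       # flux out of a bottom layer hits
    DET <- DET + gain                          # the seafloor, not a dry cell
    flux_acc[-1L, ] <- flux_acc[-1L, ] + Fout * dts
    floor_acc <- floor_acc + colSums(Fout * is_bottom) * dts
  }
  DET[!grid$wet] <- NA_real_
  list(DET = DET, interface_flux = flux_acc / dt, seafloor_flux = floor_acc / dt)
}
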