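# Diagnostics: export flux, transfer-efficiency maps, global metrics,
# emergent-b fits, layer-wise fractional transfer, run comparisons.
#
# Conventions: export depth 120 m, transfer depth 1080 m; global integrals
# use only columns at least 1080 m deep (shallow shelves would bias PP and
# export relative to the 1080 m flux); annual means are over the final
# model year; carbon via the Redfield conversion.

PG_PER_G <- 1e-15

#' Annual-mean interface flux map
#'
#' @param output an `annual_cycle`.
#' @param depth interface depth in m (must be one of the grid interfaces).
#' @return per-column annual-mean flux, mmol P m^-2 day^-1.
#' @export
annual_flux_at <- function(output, depth) {
  i <- which(output$grid$interfaces == depth)
  if (length(i) != 1L) stop("`depth` is not a grid interface")
  apply(output$monthly_flux[i, , , drop = FALSE], 2, mean)
}

#' Local transfer efficiency map
#'
#' Elementwise `TE(x, y) = F1080(x, y) / F120(x, y)`, masked (NA) where the
#' export flux is vanishingly small (below `mask_frac` of its global mean)
#' to avoid meaningless near-zero ratios.
#'
#' @param F120 annual-mean export flux map (per column).
#' @param F1080 annual-mean transfer flux map (per column).
#' @param mask_frac masking threshold as a fraction of the global-mean F120.
#' @return TE per column, NA where masked.
#' @export
te_local <- function(F120, F1080, mask_frac = 1e-12) {
  if (length(F120) != length(F1080)) stop("flux maps must be on the same grid")
  thresh <- mask_frac * mean(F120, na.rm = TRUE)
  te <- ifelse(is.na(F120) | F120 <= thresh, NA_real_, F1080 / F120)
  te
}

#' Fit the emergent attenuation exponent to a flux profile
#'
#' Unweighted least-squares slope of ln F versus ln z over the interfaces
#' in `[z0, z1]` (inclusive), negated. This is the exponent the Martin
#' curve would need to explain the modelled fluxes; under circulation it is
#' an emergent property and differs from the imposed exponent.
#'
#' @param depths interface depths, m.
#' @param fluxes fluxes at those interfaces (same length).
#' @param z0,z1 fit range in m.
#' @return list with `b` (fitted exponent), `residual` (root-mean-square
#'   log-space residual) and `n` (points used).
#' @export
fit_emergent_b <- function(depths, fluxes, z0 = 120, z1 = 1080) {
  sel <- depths >= z0 & depths <= z1
  d <- depths[sel]; f <- fluxes[sel]
  pos <- is.finite(f) & f > 0
  if (sum(pos) < length(f)) {
    warning("nonpositive fluxes in fit range; fitting the positive subset")
  }
  d <- d[pos]; f <- f[pos]
  if (length(d) < 3L) stop("need at least 3 interfaces with positive flux in [z0, z1]")
  fit <- stats::lm.fit(cbind(1, log(d)), log(f))
  list(b = -unname(fit$coefficients[2]),
       residual = sqrt(mean(fit$residuals^2)), n = length(d))
}

#' Layer-wise fractional transfer: diagnosed versus expected
#'
#' For layers k = 3..14, the fraction of flux entering layer k from layer
#' k-1, `F(z_k)/F(z_{k-1})` (interface depths z), compared with the
#' Martin-curve expectation `(z_k/z_{k-1})^-b`. Under circulation the
#' power law systematically underestimates the diagnosed transfer in the
#' upper mesopelagic.
#'
#' @param depths interface depths, m (length 16).
#' @param fluxes interface fluxes (same length).
#' @param b_model the imposed attenuation exponent.
#' @return data frame with columns `k`, `z_upper`, `z_lower`, `diagnosed`,
#'   `expected` (NA where the denominator vanishes).
#' @export
fractional_transfer <- function(depths, fluxes, b_model) {
  ks <- 3:14
  z_up <- depths[ks - 1L]; z_lo <- depths[ks]
  f_up <- fluxes[ks - 1L]; f_lo <- fluxes[ks]
  diagnosed <- ifelse(is.finite(f_up) & f_up > 0, f_lo / f_up, NA_real_)
  data.frame(k = ks, z_upper = z_up, z_lower = z_lo,
             diagnosed = diagnosed,
             expected = (z_lo / z_up)^(-b_model))
}

#' Global annual diagnostics
#'
#' Area/volume-weighted annual integrals over columns at least 1080 m deep,
#' converted to Pg C yr^-1 with the Redfield ratio: global primary
#' production, export flux at 120 m, transfer flux at 1080 m, global and
#' local transfer efficiency, the emergent-b fit of the globally averaged
#' flux profile, and the layer-wise fractional transfer table.
#'
#' @param output an `annual_cycle`.
#' @param grid the grid (defaults to the run's own).
#' @return An object of class `annual_diagnostics`.
#' @export
global_metrics <- function(output, grid = output$grid) {
  mask <- grid$depth_mask
  F120_map <- annual_flux_at(output, 120)
  F1080_map <- annual_flux_at(output, 1080)
  ppbar <- apply(output$monthly_PP, 1:2, mean)     # mmol P m^-3 day^-1

  to_pg <- function(x) phosphorus_to_carbon(x) * PG_PER_G
  days <- 360

  PP_global <- to_pg(sum((ppbar * grid$volume)[, mask], na.rm = TRUE) * days)
  F120 <- to_pg(sum(F120_map[mask] * grid$area[mask]) * days)
  F1080 <- to_pg(sum(F1080_map[mask] * grid$area[mask]) * days)

  te_map <- te_local(F120_map, F1080_map)
  te_map[!mask] <- NA_real_

  prof <- apply(output$monthly_flux, 1, function(fl)
    sum(fl[mask, ] * grid$area[mask]) / 12 / sum(grid$area[mask]))
  b_model <- output$config$att$b_ref
  emergent <- tryCatch(fit_emergent_b(grid$interfaces, prof),
                       error = function(e) list(b = NA_real_,
                                                residual = NA_real_, n = 0L))
  emergent_b_map <- rep(NA_real_, grid$n_col)
  for (c in which(mask)) {
    fl <- rowMeans(output$monthly_flux[, c, ])
    fit <- tryCatch(fit_emergent_b(grid$interfaces, fl),
                    error = function(e) NULL)
    if (!is.null(fit)) emergent_b_map[c] <- fit$b
  }

  structure(list(
    PP_global = PP_global, F120 = F120, F1080 = F1080,
    TE_global = if (F120 > 0) F1080 / F120 else NA_real_,
    TE_map = te_map, emergent_b = emergent$b,
    emergent_b_map = emergent_b_map,
    flux_profile = data.frame(depth = grid$interfaces, flux = prof),
    fractional_transfer = fractional_transfer(grid$interfaces, prof, b_model),
    b_model = b_model, mask = mask, grid_sig = grid_signature(grid)
  ), class = "annual_diagnostics")
}

#' @export
print.annual_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<annual_diagnostics> PP %.3g Pg C/yr | F120 %.3g | F1080 %.3g | TE_global %.3g | emergent b %.3g (imposed %.3g)\n",
    x$PP_global, x$F120, x$F1080, x$TE_global, x$emergent_b, x$b_model))
  invisible(x)
}

#' Compare two runs
#'
#' Percent changes of the global scalars of run `a` relative to run `b`
#' (`100 * (a - b) / b`), plus the TE-map percent-change field. Reported to
#' two significant figures in the printed table.
#'
#' @param a,b `annual_diagnostics` objects on the same grid.
#' @return An object of class `run_comparison`: data frame `table` and
#'   per-column `TE_change_map` (percent).
#' @export
compare_runs <- function(a, b) {
  if (!identical(a$grid_sig, b$grid_sig)) stop("runs are on different grids")
  pct <- function(x, y) 100 * (x - y) / y
  tab <- data.frame(
    metric = c("TE_global", "PP_global", "F120", "F1080"),
    a = c(a$TE_global, a$PP_global, a$F120, a$F1080),
    b = c(b$TE_global, b$PP_global, b$F120, b$F1080))
  tab$pct_change <- pct(tab$a, tab$b)
  structure(list(table = tab,
                 TE_change_map = pct(a$TE_map, b$TE_map)),
            class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  tab <- x$table
  tab$pct_change <- signif(tab$pct_change, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
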