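# Experiment grid, attenuation tables, fixtures and report generation.
#
# The experiment design: a reference set of non-seasonal exponents
# b in {0.555, 1.110, 1.388, 2.221} (delta_b = 0) and a seasonal set
# crossing delta_b/b_ref in {0.2, 0.4, 0.6} with phase theta in
# {0, 3, 6, 9} months, all sharing one base configuration.

#' Build the experiment grid
#'
#' Returns a named list of `run_config`s: 4 non-seasonal references plus
#' 12 seasonal variants (3 amplitudes x 4 phases), each differing from
#' `base` only in its attenuation parameters.
#'
#' @param base a `run_config` providing everything except the attenuation.
#' @param b_nonseasonal constant exponents for the reference runs.
#' @param delta_b_fracs seasonal amplitudes as fractions of `b_ref`.
#' @param thetas seasonal phases in months.
#' @param b_ref reference exponent for the seasonal runs.
#' @return named list of `run_config`s.
#' @export
experiment_grid <- function(base = run_config(),
                            b_nonseasonal = c(0.555, 1.110, 1.388, 2.221),
                            delta_b_fracs = c(0.2, 0.4, 0.6),
                            thetas = c(0, 3, 6, 9), b_ref = 1.388) {
  out <- list()
  for (b in b_nonseasonal) {
    cfg <- base
    cfg$att <- seasonal_attenuation(b_ref = b, delta_b = 0, lam = base$att$lam)
    out[[sprintf("b%.3f", b)]] <- cfg
  }
  for (db in delta_b_fracs) {
    for (th in thetas) {
      cfg <- base
      cfg$att <- seasonal_attenuation(b_ref = b_ref, delta_b_frac = db,
                                      theta = th, lam = base$att$lam)
      out[[sprintf("db%.1f_th%d", db, th)]] <- cfg
    }
  }
  out
}

#' Seasonal-attenuation summary tables
#'
#' One row per parameter variant with the quantities the experiment design
#' is stated in: extrema and annual means of the seasonal exponent and of
#' the sinking coefficient A(t) (closed form and quadrature), sinking-speed
#' extrema at 120 m and 1080 m, the equivalent constant exponent, and the
#' 120-1080 m transit time at the mean coefficient.
#'
#' @param variants list of `seasonal_attenuation` objects (default: the
#'   experiment-grid attenuation set).
#' @param path optional CSV output path.
#' @return the data frame, invisibly if `path` is given.
#' @export
attenuation_tables <- function(variants = NULL, path = NULL) {
  if (is.null(variants)) {
    variants <- c(
      lapply(c(0.555, 1.110, 1.388, 2.221), function(b)
        seasonal_attenuation(b_ref = b, delta_b = 0)),
      lapply(c(0.2, 0.4, 0.6), function(db)
        seasonal_attenuation(delta_b_frac = db)))
  }
  rows <- lapply(variants, function(p) {
    b_min <- p$b_ref - p$delta_b
    b_max <- p$b_ref + p$delta_b
    A_max <- if (b_min > 0) p$lam / b_min else Inf
    A_min <- p$lam / b_max
    Abar <- if (p$delta_b < p$b_ref) mean_A(p) else NA_real_
    quad <- stats::integrate(function(t) seasonal_A(t, -45, p), 0, p$period,
                             rel.tol = 1e-12)$value / p$period
    data.frame(
      b_ref = p$b_ref, delta_b = p$delta_b, theta = p$theta, lambda = p$lam,
      b_min = b_min, b_max = b_max,
      A_min = A_min, A_max = A_max, A_mean = Abar, A_mean_quadrature = quad,
      equivalent_b = if (is.na(Abar)) NA_real_ else p$lam / Abar,
      W120_min = A_min * 120, W120_max = A_max * 120,
      W1080_min = A_min * 1080, W1080_max = A_max * 1080,
      transit_120_1080 = if (is.na(Abar)) NA_real_ else
        transit_time(120, 1080, p$lam / p$b_ref))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# seapump attenuation tables",
                 "# rates day-1, speeds m day-1, transit days, b dimensionless"),
               con)
    utils::write.csv(tab, con, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Run one configuration and write its outputs
#'
#' Executes `run_to_cycle`, writes the annual diagnostics as JSON and the
#' annual-mean fields as CSV next to it, and returns the diagnostics.
#' Skips the run when the JSON already exists (resumable), unless `force`.
#'
#' @param config a `run_config`.
#' @param name variant name (used for file names).
#' @param out_dir output directory (created if needed).
#' @param force rerun even if output exists.
#' @return the `annual_diagnostics`.
#' @export
run_experiment <- function(config, name, out_dir = NULL, force = FALSE) {
  json_path <- if (!is.null(out_dir)) file.path(out_dir, paste0(name, ".json"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (!is.null(json_path) && file.exists(json_path) && !force) {
    return(invisible(jsonlite::read_json(json_path, simplifyVector = TRUE)))
  }
  out <- run_to_cycle(config)
  diag <- global_metrics(out)
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(
      name = name, converged = out$converged, years = out$years_run,
      PP_global = diag$PP_global, F120 = diag$F120, F1080 = diag$F1080,
      TE_global = diag$TE_global, emergent_b = diag$emergent_b,
      b_ref = config$att$b_ref, delta_b = config$att$delta_b,
      theta = config$att$theta), json_path, auto_unbox = TRUE, digits = NA)
    write_annual_fields(out, file.path(out_dir, paste0(name, "_fields.csv")))
  }
  diag
}

#' Write annual-mean fields to CSV
#'
#' Long-format table (tracer, layer, depth, lat, lon, value) of annual-mean
#' tracer concentrations, with units in header comments.
#'
#' @param output an `annual_cycle`.
#' @param path output file.
#' @export
write_annual_fields <- function(output, path) {
  grid <- output$grid
  recs <- lapply(tracer_names(), function(nm) {
    ann <- apply(output$monthly_tracers[[nm]], 1:2, mean)
    data.frame(tracer = nm,
               layer = rep(seq_len(grid$n_layer), grid$n_col),
               depth = rep(grid$centers, grid$n_col),
               lat = rep(grid$lat_centers[grid$col_lat], each = grid$n_layer),
               lon = rep(grid$lon_centers[grid$col_lon], each = grid$n_layer),
               value = as.numeric(ann))
  })
  tab <- do.call(rbind, recs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# seapump annual-mean tracer fields",
               "# value: mmol P m-3; depth: m (layer centre); lat/lon: degrees"),
             con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Write synthetic fixtures to disk
#'
#' Emits the synthetic forcing table and a set of monthly transport
#' matrices for a given grid, for inspection or reuse.
#'
#' @param dir output directory.
#' @param grid grid for the transport matrices.
#' @param scheme transport scheme for the fixture operators.
#' @return paths written, invisibly.
#' @export
write_fixtures <- function(dir, grid = make_grid(n_lat = 8, n_lon = 4),
                           scheme = "overturning") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- file.path(dir, "forcing.csv")
  write_forcing(fp)
  tp <- file.path(dir, "transport.txt")
  write_transport_matrices(build_transport(scheme, grid), tp)
  invisible(c(fp, tp))
}

#' Comparison report across an experiment set
#'
#' Builds the seasonal-versus-reference comparison table: for each seasonal
#' diagnostics entry, percent changes of TE_global, PP_global, F120 and
#' F1080 relative to the named reference entries.
#'
#' @param diags named list of `annual_diagnostics`.
#' @param references names of reference entries within `diags`.
#' @param path optional CSV path.
#' @return data frame of comparisons.
#' @export
experiment_report <- function(diags, references, path = NULL) {
  for (r in references) {
    if (!r %in% names(diags)) {
      stop("missing reference run `", r, "`; run it before requesting a report")
    }
  }
  rows <- list()
  for (nm in setdiff(names(diags), references)) {
    for (r in references) {
      cmp <- compare_runs(diags[[nm]], diags[[r]])
      w <- cmp$table
      rows[[paste(nm, r)]] <- data.frame(
        run = nm, reference = r,
        metric = w$metric, value = w$a, pct_change = signif(w$pct_change, 2))
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
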