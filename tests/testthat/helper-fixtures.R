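# Shared fixtures: small grids and memoised expensive runs.

# one printed-digit comparison: reference values are printed to a fixed number
# of decimals, so agreement is asserted to one unit in the last printed digit
ulp <- function(computed, printed, digit) {
  expect_lt(abs(computed - printed), 1.000001 * digit)
}

.run_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, make(), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

small_grid <- function() make_grid(n_lat = 6, n_lon = 2)

# layer-mean of the Martin steady detritus shape c(z) = z^-(b+1), the
# analytic no-circulation profile the sinking scheme must preserve
martin_layer_means <- function(grid, b, c0 = 1) {
  zt <- grid$interfaces[-16]
  zb <- grid$interfaces[-1]
  p <- b + 1
  means <- c0 * (zt^(1 - p) - zb^(1 - p)) / ((p - 1) * (zb - zt))
  means[1] <- 0   # surface layer diverges (z_top = 0); not part of the profile
  means
}

# converged single-column run, shared by test-integrate and test-acceptance
column_run <- function() {
  cache_get("column", function() run_to_cycle(column_config(b = 1.388)))
}

# calibrated smoke-world runs: non-seasonal reference plus four phases,
# shared by test-acceptance (criterion 4)
smoke_runs <- function() {
  cache_get("smoke", function() {
    atts <- c(list(ref = seasonal_attenuation(delta_b = 0)),
              setNames(lapply(c(0, 3, 6, 9), function(th)
                seasonal_attenuation(delta_b_frac = 0.6, theta = th)),
                paste0("th", c(0, 3, 6, 9))))
    lapply(atts, function(a) {
      out <- run_to_cycle(smoke_config(att = a))
      list(output = out, diag = global_metrics(out))
    })
  })
}
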