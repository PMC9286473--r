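test_that("Martin curve, TE and sinking-coefficient closed forms match the printed values", {
  expect_equal(martin_flux(3.2, 120, 120, 1.4), 3.2)
  expect_equal(martin_flux(3.2, 120, 900, 0), 3.2)
  ulp(martin_flux(1, 120, 1080, 1.388), 0.047, 1e-3)
  expect_error(martin_flux(1, 120, 80, 1), ">=")

  expect_equal(martin_te(0), 1)
  ulp(martin_te(1.388), 0.047, 1e-3)
  ulp(martin_te(1.110), 0.088, 1e-3)   # computed 0.0873; paper prints 0.088
  ulp(martin_te(2.221), 0.0076, 1e-4)

  ulp(sinking_coefficient(0.05, 1.388), 0.036, 1e-3)
  ulp(sinking_coefficient(0.05, 2.221), 0.023, 1e-3)
  ulp(sinking_coefficient(0.05, 0.555), 0.090, 1e-3)
  expect_error(sinking_coefficient(0.05, 0), "> 0")
})

test_that("seasonal exponent follows the cosine parameterisation with hemisphere flip", {
  p <- seasonal_attenuation(b_ref = 1.388, delta_b_frac = 0.6, theta = 0)
  # equator unperturbed, for any time and phase
  for (th in c(0, 3, 6, 9, 4.5)) {
    pt <- seasonal_attenuation(delta_b_frac = 0.6, theta = th)
    expect_equal(seasonal_b(c(0, 33, 200), 0, pt), rep(1.388, 3))
  }
  # no-seasonality degenerate case
  p0 <- seasonal_attenuation(delta_b = 0)
  expect_equal(seasonal_b(seq(0, 359), 47, p0), rep(1.388, 360))

  # range endpoints 0.555 and 2.221 at 60 percent amplitude
  t <- seq(0, 360, by = 0.25)
  b <- seasonal_b(t, -50, p)
  ulp(min(b), 0.555, 1e-3)
  ulp(max(b), 2.221, 1e-3)

  # NH minimum sits a quarter period after theta = 3 sign convention
  expect_equal(seasonal_b(0, 60, p), 1.388 - 0.6 * 1.388)
  expect_equal(seasonal_b(0, -60, p), 1.388 + 0.6 * 1.388)

  expect_error(seasonal_attenuation(delta_b = 1.5), "delta_b")
})

test_that("seasonal A(t) spans the printed extrema for each amplitude", {
  t <- seq(0, 360, by = 0.25)
  for (case in list(list(f = 0.6, lo = 0.023, hi = 0.090),
                    list(f = 0.2, lo = 0.030, hi = 0.045),
                    list(f = 0.4, lo = 0.026, hi = 0.060))) {
    p <- seasonal_attenuation(delta_b_frac = case$f)
    A <- seasonal_A(t, 40, p)
    ulp(min(A), case$lo, 1e-3)
    ulp(max(A), case$hi, 1e-3)
  }
  p0 <- seasonal_attenuation(delta_b = 0)
  expect_equal(seasonal_A(t, 40, p0), rep(0.05 / 1.388, length(t)))
  expect_error(seasonal_A(0, 40, seasonal_attenuation(delta_b_frac = 1)),
               "finite")
})

test_that("annual-mean A and the equivalent exponent match quadrature and the printed values", {
  p <- seasonal_attenuation(delta_b_frac = 0.6)
  ulp(mean_A(p), 0.045, 1e-3)
  ulp(equivalent_b(p), 1.110, 1e-3)
  expect_equal(mean_A(seasonal_attenuation(delta_b = 0)), 0.05 / 1.388)
  expect_equal(equivalent_b(seasonal_attenuation(delta_b = 0)), 1.388)

  # quadrature oracle across random parameter bundles
  set.seed(7)
  for (i in 1:12) {
    b_ref <- runif(1, 0.5, 2.5)
    p <- seasonal_attenuation(b_ref = b_ref, delta_b_frac = runif(1, 0, 0.9),
                              theta = runif(1, 0, 12), lam = runif(1, 0.01, 0.1))
    quad <- stats::integrate(function(t) seasonal_A(t, 35, p), 0, 360,
                             rel.tol = 1e-13)$value / 360
    expect_equal(mean_A(p), quad, tolerance = 1e-10)
    # Jensen: the mean sinking coefficient is never slower than lam/b_ref
    expect_gte(mean_A(p), p$lam / p$b_ref - 1e-14)
    if (p$delta_b > 1e-3) expect_gt(mean_A(p), p$lam / p$b_ref)
  }
})

test_that("annual mean of the seasonal exponent is b_ref for every latitude and phase", {
  set.seed(11)
  for (i in 1:10) {
    p <- seasonal_attenuation(b_ref = runif(1, 0.5, 2.5),
                              delta_b_frac = runif(1, 0, 1),
                              theta = runif(1, 0, 12))
    phi <- runif(1, -90, 90)
    m <- stats::integrate(function(t) seasonal_b(t, phi, p), 0, 360,
                          rel.tol = 1e-13)$value / 360
    expect_lt(abs(m - p$b_ref) / p$b_ref, 1e-10)
  }
})

test_that("hemisphere flip equals a six-month phase shift", {
  set.seed(3)
  t <- seq(0, 359.5, by = 0.5)
  for (th in c(0, 3, 6, 9, 2.2)) {
    p <- seasonal_attenuation(delta_b_frac = 0.6, theta = th)
    p6 <- seasonal_attenuation(delta_b_frac = 0.6, theta = th + 6)
    phi <- runif(1, 1, 90)
    expect_equal(seasonal_b(t, phi, p), seasonal_b(t, -phi, p6), tolerance = 1e-12)
  }
})

test_that("TE and flux are strictly monotone in b and depth", {
  b <- seq(0, 3, by = 0.1)
  expect_true(all(diff(martin_te(b)) < 0))
  z <- seq(120, 5000, by = 20)
  expect_true(all(diff(martin_flux(1, 120, z, 1.388)) < 0))
  expect_true(all(martin_flux(1, 120, z, 0) == 1))
})

test_that("seasonal sinking speed covers the printed ranges at 120 m and 1080 m", {
  p <- seasonal_attenuation(delta_b_frac = 0.6)
  t <- seq(0, 360, by = 0.25)
  w120 <- sinking_speed(120, t, 40, p)
  ulp(min(w120), 2.70, 1e-2)
  ulp(max(w120), 10.81, 1e-2)
  w1080 <- sinking_speed(1080, t, 40, p)
  ulp(min(w1080), 24.31, 1e-2)
  # the printed 97.30 is 1080 * lambda / 0.555 with the exponent rounded to
  # its printed extremum; the exact seasonal maximum is 97.26
  ulp(max(w1080), 97.26, 1e-2)
  ulp(sinking_coefficient(0.05, 0.555) * 1080, 97.30, 1e-2)
  # non-seasonal reference speed at the export depth
  p0 <- seasonal_attenuation(delta_b = 0)
  ulp(sinking_speed(120, 0, 40, p0), 4.32, 1e-2)
  expect_error(sinking_speed(-1, 0, 40, p0), ">= 0")
})

test_that("transit times under w = az reproduce the printed day counts", {
  ulp(transit_time(120, 1080, 0.05 / 1.388), 61, 1)
  ulp(transit_time(1080, 5000, 0.05 / 1.388), 43, 1)
  ulp(transit_time(120, 1080, 0.05 / 0.555), 24, 1)
  ulp(transit_time(120, 1080, 0.05 / 2.221), 97, 1)
  expect_error(transit_time(0, 1080, 0.05), "> 0")
})

test_that("seasonal-lambda variants behave as documented", {
  t <- seq(0, 360, by = 0.5)
  # lambda varies, b constant
  p1 <- seasonal_attenuation(delta_b_frac = 0.6, lambda_variant = "lambda_only")
  expect_equal(seasonal_b(t, 50, p1), rep(1.388, length(t)))
  lam <- seasonal_lambda(t, 50, p1)
  expect_equal(range(lam), 0.05 * c(0.4, 1.6), tolerance = 1e-10)
  # lambda and b vary in proportion: a = lambda/b constant in time
  p2 <- seasonal_attenuation(delta_b_frac = 0.6, lambda_variant = "constant_a")
  A <- seasonal_A(t, 50, p2)
  expect_equal(A, rep(0.05 / 1.388, length(t)), tolerance = 1e-12)
  expect_gt(diff(range(seasonal_b(t, 50, p2))), 1)
})
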