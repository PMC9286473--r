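test_that("the off scheme is exactly the identity", {
  g <- small_grid()
  ops <- build_transport("off", g)
  expect_length(ops, 12L)
  set.seed(8)
  st <- tracer_state(g, PO4 = matrix(runif(15 * g$n_col), 15))
  st2 <- apply_transport(st, ops[[4]], g)
  expect_identical(st2$PO4, st$PO4)
  expect_error(build_transport("geostrophic", g))
})

test_that("every scheme satisfies the operator contracts", {
  g <- small_grid()
  for (scheme in c("off", "mixing_only", "overturning")) {
    ops <- build_transport(scheme, g)
    for (op in ops) expect_true(validate_transport(op, g))
    # uniform fields are fixed points
    st <- tracer_state(g, PO4 = 1.7, DET = 0.3)
    st2 <- apply_transport(st, ops[[1]], g)
    expect_equal(st2$PO4[g$wet], rep(1.7, sum(g$wet)), tolerance = 1e-12)
    expect_equal(st2$DET[g$wet], rep(0.3, sum(g$wet)), tolerance = 1e-12)
  }
})

test_that("repeated application conserves mass and positivity", {
  g <- small_grid()
  set.seed(13)
  st <- tracer_state(g, PO4 = matrix(runif(15 * g$n_col, 0, 3), 15))
  m0 <- total_phosphorus(st, g)
  ops <- build_transport("overturning", g)
  for (i in 1:1000) {
    st <- apply_transport(st, ops[[(i %% 12) + 1L]], g)
  }
  expect_lt(abs(total_phosphorus(st, g) - m0) / m0, 1e-9)
  expect_true(all(st$PO4[g$wet] >= 0))
  # the field has actually been redistributed
  expect_gt(max(abs(st$PO4[g$wet] - 1.5)), 0)
})

test_that("a delta of mass spreads only through hydrodynamically connected cells", {
  g <- small_grid()
  ops <- build_transport("overturning", g, kappa_mix = 0)  # pure loop
  M <- ops[[1]]$M
  idx <- seapump:::wet_index(g)
  src <- idx[8, 1]                     # a deep cell in the southernmost band
  v <- numeric(nrow(M)); v[src] <- 1
  mass0 <- g$volume[g$wet][src]
  v1 <- as.numeric(M %*% v)
  expect_equal(sum(v1 * g$volume[g$wet]), mass0, tolerance = 1e-12)
  # support = source plus its upwind-connected neighbours, all nonnegative
  expect_true(all(v1 >= 0))
  reach <- which(v1 > 0)
  expect_true(src %in% reach)
  expect_lt(length(reach), 6L)
})

test_that("mixing homogenises the seasonal mixed layer", {
  g <- small_grid()
  ops <- build_transport("mixing_only", g, kappa_mix = 0.5)
  # winter operator at a high-latitude column: strong vertical exchange
  st <- tracer_state(g, PO4 = matrix(seq(3, 0.2, length.out = 15), 15))
  col <- which(g$col_lat == 1L)[1]     # southern band, local winter ~ July
  mld <- mixed_layer_depth(195, g$lat_centers[1])
  kml <- sum(g$interfaces[-1] <= mld)
  expect_gt(kml, 1L)
  before <- stats::var(st$PO4[1:kml, col])
  after <- stats::var(apply_transport(st, ops[[7]], g)$PO4[1:kml, col])
  expect_lt(after, before)
})

test_that("transport matrices round-trip bit-exactly through the text format", {
  g <- small_grid()
  ops <- build_transport("overturning", g)
  path <- withr::local_tempfile(fileext = ".txt")
  write_transport_matrices(ops, path)
  got <- read_transport_matrices(path, g)
  for (m in 1:12) {
    expect_identical(max(abs(got[[m]]$M - ops[[m]]$M)), 0)
    expect_identical(got[[m]]$dt_matrix, ops[[m]]$dt_matrix)
  }
})

test_that("malformed transport files are reported with their location", {
  g <- small_grid()
  ops <- build_transport("mixing_only", g)
  path <- withr::local_tempfile(fileext = ".txt")
  write_transport_matrices(ops, path)
  lines <- readLines(path)

  trunc <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines[1:(length(lines) - 5)], trunc)
  expect_error(read_transport_matrices(trunc, g), "truncated")

  bad <- withr::local_tempfile(fileext = ".txt")
  lines2 <- lines
  lines2[length(lines2)] <- "1 2"      # short record
  writeLines(lines2, bad)
  expect_error(read_transport_matrices(bad, g), "line")
})

test_that("operators violating the mass-conservation contract fail validation on load", {
  g <- small_grid()
  ops <- build_transport("mixing_only", g)
  M <- ops[[1]]$M
  M[1, 2] <- M[1, 2] + 0.05            # break the volume-weighted column sum
  ops[[1]] <- seapump:::new_transport_operator(M, 1, "mixing_only", g)
  path <- withr::local_tempfile(fileext = ".txt")
  write_transport_matrices(ops, path)
  expect_error(read_transport_matrices(path, g), "conservation|uniform")
})

test_that("grid mismatch is rejected", {
  g <- small_grid()
  g2 <- make_grid(n_lat = 4, n_lon = 2)
  ops <- build_transport("off", g)
  st <- tracer_state(g2, PO4 = 1)
  expect_error(apply_transport(st, ops[[1]], g2), "different grid")
})
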