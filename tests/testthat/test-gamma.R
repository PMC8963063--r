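test_that("gamma of a volume against itself is zero with full passing", {
  v <- rand_volume(seed = 3)
  g <- gamma_map(v, v, gamma_config(dd = 1, dta = 0.5))
  expect_equal(max(g), 0)
  expect_equal(passing_rate(g), 100)
})

test_that("uniform dose offsets probe the pure dose term", {
  v <- rand_volume(seed = 4, scale = 0)  # zeros
  v$values[] <- 2
  # DD_abs = 12.5% of 2 = 0.25, exactly representable in binary
  cfg <- gamma_config(dd = 12.5, dta = 0.5, interp_step = NULL)
  shift <- function(d) {
    w <- v; w$values <- v$values + d; w
  }
  # offset exactly DD_abs -> gamma = 1 everywhere; the pass convention
  # is gamma <= 1, so boundary voxels pass
  g1 <- gamma_map(v, shift(0.25), cfg)
  expect_equal(max(abs(g1 - 1)), 0)
  expect_equal(passing_rate(g1), 100)
  g2 <- gamma_map(v, shift(0.5), cfg)
  expect_equal(passing_rate(g2), 0)
})

test_that("gamma matches the exhaustive brute-force oracle exactly", {
  ref <- rand_volume(n = 9, seed = 11)
  evl <- rand_volume(n = 9, seed = 12)
  cfg <- gamma_config(dd = 1, dta = 0.5, search_radius = 2,
                      interp_step = NULL)
  g <- gamma_map(ref, evl, cfg)
  dd_abs <- 0.01 * max(ref$values)
  gb <- gamma_brute(ref, evl, dd_abs, 0.5, 2)
  expect_equal(g, gb, tolerance = 1e-12)
})

test_that("passing rate counts VOI voxels with gamma <= 1", {
  g <- array(c(rep(0.5, 4), rep(1.5, 4)), dim = c(2, 2, 2))
  expect_equal(passing_rate(g), 50)
  voi <- array(c(rep(TRUE, 4), rep(FALSE, 4)), dim = c(2, 2, 2))
  expect_equal(passing_rate(g, voi), 100)
  expect_equal(passing_rate(array(2, dim = c(2, 2, 2))), 0)
})

test_that("accuracy and bias measure MAE/ME as % of max reference SAR", {
  v <- rand_volume(seed = 5)
  expect_equal(accuracy_bias(v, v), c(accuracy = 0, bias = 0))
  up <- v; up$values <- v$values + 0.01 * max(v$values)
  ab <- accuracy_bias(v, up)
  expect_equal(unname(ab["accuracy"]), 1, tolerance = 1e-9)
  expect_equal(unname(ab["bias"]), 1, tolerance = 1e-9)
  alt <- v
  sgn <- array(rep_len(c(1, -1), length(v$values)), dim = dim(v$values))
  alt$values <- v$values + 0.01 * max(v$values) * sgn
  ab2 <- accuracy_bias(v, alt)
  expect_equal(unname(ab2["accuracy"]), 1, tolerance = 1e-9)
  expect_lt(abs(ab2["bias"]), 0.01)
})

test_that("loosening DD or DTA never lowers a passing rate", {
  for (seed in c(21, 22, 23)) {
    ref <- rand_volume(n = 7, seed = seed)
    evl <- rand_volume(n = 7, seed = seed + 100)
    evl$values <- 0.8 * ref$values + 0.2 * evl$values
    base <- passing_rate(gamma_map(ref, evl,
      gamma_config(dd = 2, dta = 0.5, interp_step = NULL)))
    more_dd <- passing_rate(gamma_map(ref, evl,
      gamma_config(dd = 4, dta = 0.5, interp_step = NULL)))
    more_dta <- passing_rate(gamma_map(ref, evl,
      gamma_config(dd = 2, dta = 1, search_radius = 3, interp_step = NULL)))
    expect_gte(more_dd, base)
    expect_gte(more_dta, base)
  }
})

test_that("limit behavior: huge DTA reduces gamma to the dose search", {
  ref <- rand_volume(n = 7, seed = 31)
  evl <- rand_volume(n = 7, seed = 32)
  cfg <- gamma_config(dd = 10, dta = 1e4, search_radius = 1e4,
                      interp_step = NULL)
  g <- gamma_map(ref, evl, cfg)
  dd_abs <- 0.1 * max(ref$values)
  # every voxel can reach the globally closest dose value
  best <- vapply(as.vector(ref$values), function(r)
    min(abs(r - as.vector(evl$values))) / dd_abs, numeric(1))
  expect_lt(max(abs(as.vector(g) - best)), 1e-3)
})

test_that("gamma handles cross-grid comparison by resampling", {
  # same smooth field sampled on two different grids
  f <- function(x, y, z) {
    outer(outer(sin(x / 3), cos(y / 3)), sin(z / 6) + 1.5)
  }
  x1 <- seq(0.25, 9.75, by = 0.5)
  fine <- sar_volume(f(x1, x1, x1), x = x1, y = x1, z = x1)
  x2 <- seq(0.125, 9.875, by = 0.25)
  finer <- sar_volume(f(x2, x2, x2), x = x2, y = x2, z = x2)
  # sampling step aligned with the reference lattice so identical
  # underlying fields interpolate onto matching positions
  res <- gamma_analysis(fine, finer,
                        gamma_config(dd = 2, dta = 1, interp_step = 0.125))
  expect_gt(res$passing_rate, 99)
  expect_lt(res$accuracy, 0.5)
})

test_that("local normalization judges low-dose voxels by their own level", {
  co <- (1:6 - 0.5) * 0.5
  vals <- array(2, dim = c(6, 6, 6))
  vals[, , 4:6] <- 0.04                   # low-dose half
  ref <- sar_volume(vals, x = co, y = co, z = co)
  evl <- ref
  evl$values <- ref$values + 0.1          # 5% of max everywhere
  # tiny DTA so only the voxel's own position is searched
  base <- gamma_config(dd = 10, dta = 0.01, search_radius = 0.01,
                       interp_step = NULL)
  g_global <- gamma_map(ref, evl, base)
  loc <- base; loc$local <- TRUE
  g_local <- gamma_map(ref, evl, loc)
  # global: 0.1 offset is half of DD_abs = 0.2 -> passes everywhere
  expect_true(all(g_global <= 1))
  # local: low-dose voxels are judged against 10% of their own 0.04
  expect_true(all(g_local[, , 4:6] > 1))
  expect_true(all(g_local[, , 1:3] <= 1))
})

test_that("degenerate inputs are rejected", {
  v <- rand_volume(seed = 6)
  zero <- v; zero$values[] <- 0
  expect_error(gamma_map(zero, v, gamma_config()), "zero")
  expect_error(gamma_map(v, v, gamma_config(),
                         voi = array(FALSE, dim = dim(v$values))), "empty")
  expect_error(gamma_config(dd = 0, dta = 1), "dd")
  expect_error(gamma_config(dd = 1, dta = 2, search_radius = 1),
               "search_radius")
})
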