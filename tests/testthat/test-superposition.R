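# basis + superposition on the coarse two-applicator phantom; solved
# tightly so linearity can be asserted at the 1e-8 level
tiny <- tiny_phantom("simplified")
basis <- compute_basis(tiny, reference_voltage = 13, tol = 1e-12)

test_that("basis has one tightly-solved field per electrode", {
  expect_s3_class(basis, "field_basis")
  expect_length(basis$fields, 4L)
  expect_equal(dim(basis$currents), c(4L, 4L))
  # each basis field is strongest near its own electrode
  g <- tiny$grid
  for (i in 1:2) {
    app <- tiny$applicators[[ceiling(i / 2)]]
    near <- which.min(abs(g$cx - app$tip_position[1] - 1.5))
    far <- which.min(abs(g$cx - app$tip_position[1] - 7))
    kz <- which.min(abs(g$cz + 12))  # proximal electrode band
    jy <- which.min(abs(g$cy))
    Em <- Mod(basis$fields[[i]]$Ex) + Mod(basis$fields[[i]]$Ey)
    expect_gt(Em[near, jy, kz], Em[far, jy, kz])
  }
})

test_that("combining with a unit weight returns that basis field exactly", {
  exc <- excitation(4, amplitude = c(13, 0, 0, 0))
  E <- combine_fields(basis, exc)
  expect_identical(E$Ex, basis$fields[[1]]$Ex)
  exc0 <- excitation(4, amplitude = 0)
  E0 <- combine_fields(basis, exc0)
  expect_equal(max(Mod(E0$Ex)), 0)
  expect_error(combine_fields(basis, excitation(3)), "electrodes")
})

test_that("superposed field equals the direct multi-electrode solve", {
  exc <- excitation(4, amplitude = 13)
  Esup <- combine_fields(basis, exc)
  sol <- solve_electrodes(tiny, drive_voltages(exc), tol = 1e-12)
  scale <- max(Mod(sol$E$Ex) + Mod(sol$E$Ey) + Mod(sol$E$Ez))
  dev <- max(Mod(Esup$Ex - sol$E$Ex), Mod(Esup$Ey - sol$E$Ey),
             Mod(Esup$Ez - sol$E$Ez))
  expect_lt(dev / scale, 1e-8)
  # SAR from the superposed field matches the direct SAR
  sar_sup <- total_sar(Esup, tiny)
  reldiff <- abs(sar_sup$sar - sol$sar$sar) / max(sol$sar$sar)
  expect_lt(max(reldiff), 1e-6)
  # agreement metrics between the two routes are exact; compare on a
  # uniform grid over the VOI (exact-position gamma, no interpolation)
  b <- tiny$voi
  qs <- lapply(1:3, function(a)
    seq(b$lo[a] + 0.25, b$hi[a] - 0.25, by = 0.5))
  vs <- resample_volume(sar_volume(sar_sup$sar, grid = tiny$grid),
                        qs[[1]], qs[[2]], qs[[3]])
  vd <- resample_volume(sar_volume(sol$sar$sar, grid = tiny$grid),
                        qs[[1]], qs[[2]], qs[[3]])
  res <- gamma_analysis(vd, vs,
                        gamma_config(dd = 1, dta = 0.5, interp_step = NULL))
  expect_equal(res$passing_rate, 100)
  expect_equal(res$accuracy, 0, tolerance = 1e-6)
  expect_equal(res$bias, 0, tolerance = 1e-6)
})

test_that("superposition with mixed amplitudes matches a direct solve", {
  exc <- excitation(4, amplitude = c(13, 6.5, 9.1, 2.6),
                    polarity = c(1, -1, 1, 1))
  Esup <- combine_fields(basis, exc)
  sol <- solve_electrodes(tiny, drive_voltages(exc), tol = 1e-12)
  scale <- max(Mod(sol$E$Ex) + Mod(sol$E$Ey) + Mod(sol$E$Ez))
  dev <- max(Mod(Esup$Ex - sol$E$Ex), Mod(Esup$Ey - sol$E$Ey),
             Mod(Esup$Ez - sol$E$Ez))
  expect_lt(dev / scale, 1e-8)
})

test_that("flipping one polarity changes the field shape, not its scale", {
  Epp <- combine_fields(basis, excitation(4, polarity = c(1, 1, 1, 1)))
  Epm <- combine_fields(basis, excitation(4, polarity = c(1, 1, -1, -1)))
  sar_pp <- total_sar(Epp, tiny)$sar
  sar_pm <- total_sar(Epm, tiny)$sar
  ratio <- sar_pm[sar_pp > 1e-8 * max(sar_pp)] /
    sar_pp[sar_pp > 1e-8 * max(sar_pp)]
  expect_gt(max(ratio) / min(ratio), 1.5)
})

test_that("power normalization hits the per-electrode target", {
  exc <- normalize_power(basis, excitation(4), target_power = 0.7)
  P <- basis_powers(basis, exc)
  expect_true(all(abs(P - 0.7) <= 0.007))
  # symmetric phantom: equal amplitudes, polarities untouched
  expect_equal(exc$amplitude[1], exc$amplitude[3], tolerance = 1e-6)
  expect_identical(exc$polarity, rep(1L, 4))
  # normalized powers agree with a direct solve at those voltages
  sol <- solve_electrodes(tiny, drive_voltages(exc), tol = 1e-11)
  expect_equal(sol$power, P, tolerance = 1e-4)
  # zero target zeroes the drive
  exc0 <- normalize_power(basis, excitation(4), target_power = 0)
  expect_equal(exc0$amplitude, rep(0, 4))
})
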