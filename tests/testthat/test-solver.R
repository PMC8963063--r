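test_that("edge conductances reproduce a hand-assembled layered stack", {
  # two cells along x (materials Muscle | Fat), one cell in y and z;
  # each x-edge collects kappa * dy*dz/4 from the single adjacent cell
  g <- rectilinear_grid(c(0, 2, 5), c(0, 3), c(0, 4))
  m <- voxel_model(g, background = "Muscle")
  m$material[2, 1, 1] <- match("Fat", names(m$materials))
  kap <- ihtplan:::model_kappa(m, 27e6)
  sys <- ihtplan:::stencil_conductances(g, kap)
  k1 <- admittivity(tissue_table()[["Muscle"]], 27e6)
  k2 <- admittivity(tissue_table()[["Fat"]], 27e6)
  # mm -> m: area (3*4)/4 mm^2 per quadrant, length 2 and 3 mm
  expect_equal(sys$gx[1, 1, 1], k1 * (3 * 4 / 4) / 2 * 1e-3, tolerance = 1e-14)
  expect_equal(sys$gx[2, 2, 2], k2 * (3 * 4 / 4) / 3 * 1e-3, tolerance = 1e-14)
  # series composition through the stack equals the harmonic combination
  G1 <- k1 * (3 * 4 * 1e-6) / 2e-3
  G2 <- k2 * (3 * 4 * 1e-6) / 3e-3
  Gtot_nodes <- 1 / (1 / sum(sys$gx[1, , ]) + 1 / sum(sys$gx[2, , ]))
  expect_equal(Gtot_nodes, 1 / (1 / G1 + 1 / G2), tolerance = 1e-12)
})

test_that("parallel-plate solve gives the exact 1D ramp and circuit power", {
  m <- plate_model()
  sys <- assemble_system(m, c(10, 0),
                         boundary = c("dirichlet", "neumann", "neumann"))
  V <- solve_potential(sys, tol = 1e-12)
  # Dirichlet values exact
  expect_equal(max(abs(V[1, , ] - 10)), 0)
  expect_equal(max(abs(V[21, , ])), 0)
  # linear ramp between the plate faces (x = 1 .. 19 mm)
  ramp <- 10 * (19 - seq(1, 19)) / 18
  expect_equal(Re(V[2:20, 6, 6]), ramp, tolerance = 1e-10)
  E <- efield_from_potential(V, m$grid)
  expect_equal(Re(E$Ex[5, 5, 5]), 10 / 18e-3, tolerance = 1e-10)
  expect_lt(max(Mod(E$Ey)), 1e-6)
  # slab of admittance G: P = Re(V^2 conj(G))/2 through 18 mm of muscle
  kap <- admittivity(tissue_table()[["Muscle"]], 27e6)
  G <- kap * (10 * 10 * 1e-6) / 18e-3
  P <- electrode_power(V, sys)
  expect_equal(P[1], 0.5 * Re(10 * Conj(10 * G)), tolerance = 1e-9)
  expect_equal(P[2], 0)  # grounded plate
  # energy balance: deposited power equals driven power
  sar <- sar_from_field(E, m)
  expect_equal(sum(P), sar$total_power, tolerance = 1e-9)
})

test_that("zero excitation and grounded systems give a null field", {
  m <- plate_model()
  sol <- solve_electrodes(m, c(0, 0))
  expect_equal(max(Mod(sol$V)), 0)
  expect_equal(max(Mod(sol$E$Ex)), 0)
  expect_equal(sol$sar$total_power, 0)
  expect_equal(sol$power, c(0, 0))
})

test_that("fields scale linearly and SAR quadratically with voltage", {
  m <- plate_model()
  s1 <- solve_electrodes(m, c(5, 0), tol = 1e-11)
  s2 <- solve_electrodes(m, c(10, 0), tol = 1e-11)
  expect_lt(max(Mod(2 * s1$V - s2$V)) / max(Mod(s2$V)), 1e-10)
  expect_lt(max(abs(4 * s1$sar$sar - s2$sar$sar)) / max(s2$sar$sar), 1e-10)
})

test_that("discrete conservation holds at every free node", {
  m <- cylinder_model(0.4)
  sys <- assemble_system(m, c(10, 0),
                         boundary = c("neumann", "neumann", "neumann"))
  V <- solve_potential(sys, tol = 1e-11)
  y <- ihtplan:::eqs_apply_cpp(sys$gx, sys$gy, sys$gz, sys$extra,
                               as.complex(V), as.integer(sys$nn))
  free <- sys$dmask == 0L
  scale <- max(Mod(y))  # electrode currents set the scale
  expect_lt(max(Mod(y[free])) / scale, 1e-9)
})

test_that("concentric-cylinder solution follows the analytic log profile", {
  m <- cylinder_model(0.1)
  sys <- assemble_system(m, c(10, 0),
                         boundary = c("neumann", "neumann", "neumann"))
  V <- solve_potential(sys, tol = 1e-11)
  g <- m$grid
  rn <- sqrt(outer(g$x^2, g$y^2, `+`))
  band <- rn > 3 & rn < 7
  fit <- stats::lm(Re(V[, , 2])[band] ~ log(rn[band]))
  # potential proportional to log(r) within 1% of the drive voltage
  expect_lt(max(abs(stats::resid(fit))) / 10, 0.01)
  # field magnitude proportional to 1/r within 2% off the shells
  E <- efield_from_potential(V, g)
  rc <- sqrt(outer(g$cx^2, g$cy^2, `+`))
  bandc <- rc > 3 & rc < 7
  er <- (sqrt(Mod(E$Ex[, , 2])^2 + Mod(E$Ey[, , 2])^2) * rc)[bandc]
  expect_lt((max(er) - min(er)) / mean(er), 0.02)
})

test_that("stencil truncation error converges at second order", {
  # harmonic Dirichlet problem with grid-aligned boundary data, so the
  # measured error isolates the interior discretization
  err_at <- function(h) {
    n <- round(10 / h)
    xs <- seq(0, 10, length.out = n + 1)
    g <- rectilinear_grid(xs, xs, c(0, 0.5, 1))
    m <- voxel_model(g, background = "Muscle")
    kap <- ihtplan:::model_kappa(m, 27e6)
    sys <- ihtplan:::stencil_conductances(g, kap)
    nn <- g$nn
    kx <- pi / 10
    ana <- outer(sin(kx * g$x), sinh(kx * g$y)) / sinh(kx * 10)
    dmask <- array(0L, dim = nn)
    dmask[c(1, nn[1]), , ] <- 1L
    dmask[, c(1, nn[2]), ] <- 1L
    dvals <- array(0 + 0i, dim = nn)
    for (k in seq_len(nn[3])) dvals[, , k] <- ana
    res <- ihtplan:::eqs_bicgstab_cpp(sys$gx, sys$gy, sys$gz,
                                      array(0 + 0i, dim = nn),
                                      array(0 + 0i, dim = nn), dmask, dvals,
                                      array(0 + 0i, dim = nn),
                                      as.integer(nn), 1e-12, 10000L, 1.5)
    max(abs(Re(array(res$x, dim = nn))[, , 2] - ana))
  }
  e <- vapply(c(0.5, 0.25, 0.125), err_at, numeric(1))
  orders <- log2(e[-3] / e[-1])
  expect_gt(min(orders), 1.8)
  expect_lt(max(orders), 2.2)
})

test_that("SAR follows sigma |E|^2 / (2 rho) with complex magnitudes", {
  g <- rectilinear_grid(0:2, 0:2, 0:2)
  m <- voxel_model(g, background = "Muscle")
  mk <- function(v) array(as.complex(v), dim = g$nc)
  # |E| = 100 V/m split over components with phases
  E <- list(Ex = mk(60), Ey = mk(80i), Ez = mk(0))
  sar <- sar_from_field(E, m)
  expect_equal(sar$sar[1, 1, 1], 2.99889948642700, tolerance = 1e-12)
  # sigma = 0 materials deposit nothing
  m$material[] <- match("Air", names(m$materials))
  expect_equal(max(sar_from_field(E, m)$sar), 0)
  # quadratic scaling
  E2 <- list(Ex = mk(120), Ey = mk(160i), Ez = mk(0))
  m$material[] <- match("Muscle", names(m$materials))
  expect_equal(sar_from_field(E2, m)$sar, 4 * sar_from_field(E, m)$sar)
})

test_that("solver reports non-convergence instead of returning garbage", {
  m <- plate_model()
  sys <- assemble_system(m, c(10, 0))
  expect_error(solve_potential(sys, tol = 1e-14, maxit = 0L),
               "did not converge")
})
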