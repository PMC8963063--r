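# expected values frozen from an independent 30-digit evaluation of the
# closed forms (see the corresponding test for each)

test_that("coaxial capacitance matches the closed-form oracle", {
  eps <- 2.4 * EPS0
  C <- coaxial_capacitance(2.12, 2.06, 20, eps)
  expect_equal(C, 9.30111558630290e-11, tolerance = 1e-12)
  # linear in length, dependent only on the diameter ratio
  expect_equal(coaxial_capacitance(2.12, 2.06, 40, eps), 2 * C)
  expect_equal(coaxial_capacitance(4.24, 4.12, 20, eps), C)
  # thin-gap divergence
  expect_gt(coaxial_capacitance(2.06 * (1 + 1e-9), 2.06, 20, eps), 1e-3)
  expect_error(coaxial_capacitance(2.0, 2.06, 20, eps), "outer")
})

test_that("coaxial impedance matches the oracle and the capacitive limit", {
  eps <- 2.4 * EPS0
  Z <- coaxial_impedance(2.12, 2.06, 20, 1e-5, eps, frequency = 27e6)
  expect_equal(Re(Z), 0.175798182247910, tolerance = 1e-10)
  expect_equal(Im(Z), -63.3750017411500, tolerance = 1e-10)
  # sigma = 0 reduces to 1/(i omega C) for many geometries
  for (d in list(c(2.12, 2.06), c(3, 1), c(10, 9.5))) {
    Z0 <- coaxial_impedance(d[1], d[2], 20, 0, eps, frequency = 27e6)
    C <- coaxial_capacitance(d[1], d[2], 20, eps)
    expect_equal(Z0, 1 / (2i * pi * 27e6 * C), tolerance = 1e-12)
  }
  # resistive limit is purely real
  Zr <- coaxial_impedance(2.12, 2.06, 20, 0.5, 0, frequency = 27e6)
  expect_equal(Im(Zr), 0)
  expect_equal(Re(Zr), log(2.12 / 2.06) / (2 * pi * 0.02 * 0.5))
  # degenerate gap
  expect_lt(Mod(coaxial_impedance(2.06 * (1 + 1e-12), 2.06, 20, 0.5, eps)),
            1e-9)
  expect_error(coaxial_impedance(2.12, 2.06, 20, 0, 0), "zero")
})

test_that("cuboid capacitance relates to the coaxial form by 2/pi", {
  eps <- 2.4 * EPS0
  Ccoax <- coaxial_capacitance(2.12, 2.06, 20, eps)
  Ccub <- cuboid_capacitance(2.12, 2.06, 20, eps)
  expect_equal(Ccub / Ccoax, 2 / pi, tolerance = 1e-14)
  # depends only on the edge ratio
  expect_equal(cuboid_capacitance(3.6, 2.4, 20, eps),
               cuboid_capacitance(1.8, 1.2, 20, eps))
  expect_error(cuboid_capacitance(1.4, 1.8, 20, eps), "outer")
})

test_that("adapted permittivity preserves capacitance exactly", {
  eps <- 2.4 * EPS0
  # edges of the surface-equivalent cuboid keep the diameter ratio
  a_i <- cuboid_edge_from_cylinder(2.06)
  a_o <- cuboid_edge_from_cylinder(2.12)
  expect_equal(a_i, pi * 2.06 / 4)
  expect_equal(a_o / a_i, 2.12 / 2.06, tolerance = 1e-15)
  ep <- equivalent_permittivity(eps, a_o, a_i, 1.8, 1.4)
  expect_equal(ep / EPS0, 21.0084431713386, tolerance = 1e-12)
  # exact identity for arbitrary geometries and lengths
  set.seed(7)
  for (i in 1:20) {
    ai <- runif(1, 0.5, 3); ao <- ai * runif(1, 1.001, 3)
    aip <- runif(1, 0.5, 3); aop <- aip * runif(1, 1.001, 3)
    l <- runif(1, 1, 50)
    e2 <- equivalent_permittivity(eps, ao, ai, aop, aip)
    expect_equal(cuboid_capacitance(aop, aip, l, e2),
                 cuboid_capacitance(ao, ai, l, eps), tolerance = 1e-12)
  }
  # identity ratio and monotonicity in the adapted thickness
  expect_equal(equivalent_permittivity(eps, 1.8, 1.4, 1.8, 1.4), eps)
  expect_gt(equivalent_permittivity(eps, a_o, a_i, 2.0, 1.4), ep)
  expect_error(equivalent_permittivity(eps, 1.4, 1.8, 1.8, 1.4), "outer")
})

test_that("equivalence report combines the pieces consistently", {
  rep <- equivalence_report(applicator_spec(c(0, 0, 0)))
  expect_equal(rep$eps_prime_r, 21.0084431713386, tolerance = 1e-10)
  expect_equal(rep$C_simplified, rep$C_cuboid, tolerance = 1e-14)
  expect_equal(rep$C_coaxial / rep$C_cuboid, pi / 2, tolerance = 1e-12)
  # coaxial-matched option reproduces the coaxial capacitance value
  repc <- equivalence_report(applicator_spec(c(0, 0, 0)), match = "coaxial")
  expect_equal(repc$C_simplified, rep$C_coaxial, tolerance = 1e-14)
  expect_equal(repc$eps_prime_r / rep$eps_prime_r, pi / 2, tolerance = 1e-12)
})
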