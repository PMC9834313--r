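test_that("size parameter and truncation order follow their definitions", {
  expect_equal(size_parameter(10, 1000), 2 * pi, tolerance = 1e-12)
  expect_equal(size_parameter(10, 4000), 8 * pi, tolerance = 1e-12)
  expect_equal(size_parameter(0, 1000), 0)
  expect_error(size_parameter(-1, 1000), "radius")
  expect_equal(truncation_order(2 * pi), 16L)
  expect_equal(truncation_order(0.01), 3L)
  x <- seq(0.1, 60, length.out = 200)
  expect_true(all(diff(truncation_order(x)) >= 0L))
})

test_that("a sphere with vacuum index does not extinguish", {
  res <- qext_homogeneous(1 + 0i, 10, seq(500, 4000, by = 100))
  expect_lt(max(abs(res$q_ext)), 1e-12)
  expect_lt(max(abs(res$q_sca)), 1e-12)
})

test_that("Rayleigh limit matches the closed-form scattering efficiency", {
  m <- 1.5 + 0i
  x <- 0.01
  res <- qext_homogeneous(m, radius_for_x(x, 1000), 1000)
  exact <- 8 / 3 * x^4 * Mod((m^2 - 1) / (m^2 + 2))^2
  expect_equal(res$q_sca, exact, tolerance = 0.01)
})

test_that("extinction approaches the extinction-paradox limit of 2", {
  q100 <- qext_homogeneous(1.5 + 0i, radius_for_x(100, 1000), 1000)$q_ext
  q400 <- qext_homogeneous(1.5 + 0i, radius_for_x(400, 1000), 1000)$q_ext
  expect_lt(abs(q100 - 2), 0.2)
  expect_lt(abs(q400 - 2), abs(q100 - 2))
})

test_that("extinction splits exactly into scattering plus absorption", {
  nu <- seq(500, 4000, by = 8)
  m <- complex_index(random_dispersion(5, seed = 3), nu)
  res <- qext_homogeneous(m, 10, nu)
  expect_lt(max(abs(res$q_ext - res$q_sca - res$q_abs)), 1e-8)
  expect_true(all(res$q_abs > 0))          # absorbing index
  real_only <- qext_homogeneous(1.4 + 0i, 10, nu)
  expect_lt(max(abs(real_only$q_abs)), 1e-8)
  expect_equal(res$geometric_cross_section, pi * 100)
})

test_that("homogeneous efficiencies match an independently coded series", {
  set.seed(42)
  for (rep in 1:25) {
    x <- runif(1, 0.1, 30)
    m <- complex(real = runif(1, 1.1, 1.8), imaginary = runif(1, 0, 0.5))
    impl <- qext_homogeneous(m, radius_for_x(x, 1000), 1000)
    orc <- oracle_mie_homog(m, x)
    expect_equal(impl$q_ext, orc$q_ext, tolerance = 1e-7)
    expect_equal(impl$q_sca, orc$q_sca, tolerance = 1e-7)
  }
})

test_that("coated solution matches a direct boundary-condition solve", {
  set.seed(7)
  for (rep in 1:12) {
    x2 <- runif(1, 1, 28); x1 <- runif(1, 0.2, 0.95) * x2
    m1 <- complex(real = runif(1, 1.1, 1.8), imaginary = runif(1, 0, 0.4))
    m2 <- complex(real = runif(1, 1.1, 1.8), imaginary = runif(1, 0, 0.4))
    geo <- sphere_geometry(radius_for_x(x2, 1000), radius_for_x(x1, 1000))
    impl <- qext_coated(m1, m2, geo, 1000)
    orc <- oracle_mie_coated(m1, m2, x1, x2)
    expect_equal(impl$q_ext, orc$q_ext, tolerance = 1e-7)
    expect_equal(impl$q_sca, orc$q_sca, tolerance = 1e-7)
  }
})

test_that("coated sphere degenerates to homogeneous in all three limits", {
  nu <- seq(500, 4000, by = 20)
  mc <- 1.5 + 0.1i; ms <- 1.4 + 0.02i
  hom_core <- qext_homogeneous(mc, 10, nu)
  hom_shell <- qext_homogeneous(ms, 10, nu)
  same <- qext_coated(mc, mc, sphere_geometry(10, 8), nu)
  expect_lt(max(abs(same$q_ext - hom_core$q_ext)), 1e-8)
  thin_shell <- qext_coated(mc, ms, sphere_geometry(10, 10 * (1 - 1e-6)), nu)
  expect_lt(max(abs(thin_shell$q_ext - hom_core$q_ext)), 1e-4)
  tiny_core <- qext_coated(mc, ms, sphere_geometry(10, 1e-4), nu)
  expect_lt(max(abs(tiny_core$q_ext - hom_shell$q_ext)), 1e-4)
})

test_that("coated efficiencies conserve energy and reference the outer section", {
  nu <- seq(500, 4000, by = 16)
  geo <- sphere_geometry(10, 8)
  m1 <- complex_index(random_dispersion(3, seed = 5), nu)
  m2 <- complex_index(random_dispersion(3, seed = 6), nu)
  res <- qext_coated(m1, m2, geo, nu)
  expect_lt(max(abs(res$q_ext - res$q_sca - res$q_abs)), 1e-8)
  expect_true(all(res$q_abs >= 0))
  expect_equal(res$geometric_cross_section, pi * 100)
})

test_that("efficiencies are continuous under tiny radius perturbations", {
  nu <- seq(500, 4000, by = 16)
  m <- complex_index(random_dispersion(4, seed = 9), nu)
  base <- qext_homogeneous(m, 10, nu)
  pert <- qext_homogeneous(m, 10 * (1 + 1e-6), nu)
  expect_lt(max(abs(base$q_ext - pert$q_ext)), 1e-3)
})

test_that("forward map composes dispersion models with the right solver", {
  nu <- seq(500, 4000, by = 50)
  vac <- voxel_dispersion(list(), n_infinity = 1, allow_empty = TRUE)
  sp <- qext_from_dispersion(vac, sphere_geometry(10), nu)
  expect_s3_class(sp, "spectrum")
  expect_equal(sp$kind, "qext")
  expect_lt(max(abs(sp$value)), 1e-12)
  m <- random_dispersion(3, seed = 12)
  one <- qext_from_dispersion(m, sphere_geometry(10), nu)
  two <- qext_from_dispersion(list(m, m), sphere_geometry(10, 6), nu)
  expect_equal(two$value, one$value, tolerance = 1e-8)
  expect_error(qext_from_dispersion(list(m, m), sphere_geometry(10), nu), "J = 1")
  expect_error(qext_coated(1.5 + 0.1i, 1.4 + 0i, sphere_geometry(10), nu), "core")
  expect_error(sphere_geometry(10, 12), "core")
  expect_error(qext_homogeneous(1.5 - 0.1i, 10, nu), "imaginary")
})
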