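test_that("anti-symmetrized Lorentzian evaluates to its closed-form values", {
  m <- voxel_dispersion(lorentzian_band(1000, 0.1, 50), n_infinity = 1.5)
  # at resonance the mirror term leaves 0.1 - 0.1/(1 + 40^2)
  expect_equal(imag_index(m, 1000), 0.1 - 0.1 / (1 + 40^2), tolerance = 1e-12)
  expect_equal(imag_index(m, 1000), 0.0999375, tolerance = 1e-6)
  # the first bracket of the real part vanishes at resonance
  expect_equal(real_index(m, 1000), 1.5 + 0.1 * 40 / (1 + 40^2), tolerance = 1e-12)
  expect_equal(real_index(m, 1000), 1.5024984, tolerance = 1e-6)
  z <- complex_index(m, 1000)
  expect_equal(Re(z), real_index(m, 1000))
  expect_equal(Im(z), imag_index(m, 1000))
})

test_that("imaginary part is odd and real increment even in wavenumber", {
  set.seed(11)
  for (rep in 1:5) {
    m <- random_dispersion(4, seed = rep)
    nu <- sort(runif(40, 10, 5000))
    expect_equal(imag_index(m, -nu, .formal = TRUE),
                 -imag_index(m, nu, .formal = TRUE), tolerance = 1e-14)
    expect_equal(real_index(m, -nu, .formal = TRUE) - m$n_infinity,
                 real_index(m, nu, .formal = TRUE) - m$n_infinity,
                 tolerance = 1e-14)
  }
  # the two mirror terms cancel exactly in the zero-wavenumber limit
  m <- random_dispersion(3, seed = 99)
  expect_equal(imag_index(m, 0, .formal = TRUE), 0)
})

test_that("model is linear in band heights", {
  b <- lorentzian_band(1200, 0.2, 30)
  half <- lorentzian_band(1200, 0.1, 30)
  nu <- seq(500, 4000, by = 25)
  one <- voxel_dispersion(list(b), 1.4)
  two <- voxel_dispersion(list(half, half), 1.4)
  expect_equal(imag_index(two, nu), imag_index(one, nu), tolerance = 1e-14)
  expect_equal(real_index(two, nu), real_index(one, nu), tolerance = 1e-14)
})

test_that("index tends to its baseline far from all bands", {
  m <- random_dispersion(5, seed = 7, n_infinity = 1.45)
  expect_equal(real_index(m, 1e6), 1.45, tolerance = 1e-3)
  expect_lt(abs(imag_index(m, 1e6)), 1e-3)
  # decay of both parts bounded by C / nu at large nu
  nus <- c(1e5, 2e5, 4e5, 8e5)
  dev <- abs(real_index(m, nus) - 1.45)
  expect_true(all(dev <= 10 * sum(vapply(m$bands, `[[`, numeric(1), "height")) *
                    max(vapply(m$bands, `[[`, numeric(1), "width")) / nus))
})

test_that("numerical Kramers-Kronig oracle confirms the analytic real part", {
  nu_wide <- seq(0, 20000, by = 1)
  nu_eval <- seq(600, 3600, by = 150)
  single <- voxel_dispersion(lorentzian_band(1000, 0.1, 50), 1.5)
  inc <- kk_numeric_transform(nu_wide, imag_index(single, nu_wide, .formal = TRUE),
                              nu_eval)
  expect_lt(max(abs(real_index(single, nu_eval) - (1.5 + inc))), 1e-3)
  # zero imaginary part transforms to zero
  expect_equal(kk_numeric_transform(nu_wide, rep(0, length(nu_wide)), nu_eval),
               rep(0, length(nu_eval)))
})

test_that("Kramers-Kronig oracle agrees for random band sets and is linear", {
  nu_wide <- seq(0, 72000, by = 2)
  nu_eval <- seq(700, 3500, by = 350)
  for (seed in 1:4) {
    m <- random_dispersion(3, center_range = c(600, 3600), seed = seed)
    inc <- kk_numeric_transform(nu_wide, imag_index(m, nu_wide, .formal = TRUE),
                                nu_eval)
    expect_lt(max(abs(real_index(m, nu_eval) - (m$n_infinity + inc))), 1e-3)
    # transform of the sum equals the sum of single-band transforms
    parts <- Reduce(`+`, lapply(m$bands, function(b) {
      mb <- voxel_dispersion(list(b), 1)
      kk_numeric_transform(nu_wide, imag_index(mb, nu_wide, .formal = TRUE),
                           nu_eval)
    }))
    expect_equal(inc, parts, tolerance = 1e-10)
  }
})

test_that("Kramers-Kronig oracle refuses edge-truncated evaluation points", {
  nu_wide <- seq(0, 10000, by = 1)
  k <- rep(0, length(nu_wide))
  expect_error(kk_numeric_transform(nu_wide, k, 6000), "truncation")
  expect_error(kk_numeric_transform(nu_wide, k[1:50], 100))
})

test_that("band and model constructors enforce their invariants", {
  expect_error(lorentzian_band(-5, 0.1, 10), "center")
  expect_error(lorentzian_band(100, -0.1, 10), "height")
  expect_error(lorentzian_band(100, 0.1, 0), "width")
  expect_error(voxel_dispersion(list(), 1.5), "at least one band")
  expect_silent(voxel_dispersion(list(), 1.5, allow_empty = TRUE))
  expect_error(voxel_dispersion(lorentzian_band(100, 0.1, 10), 0.9), "n_infinity")
  expect_error(voxel_dispersion(lorentzian_band(100, 0.1, 10), basis = "gaussian"),
               "lorentzian")
  expect_error(imag_index(random_dispersion(2, seed = 1), numeric(0)))
  expect_error(imag_index(random_dispersion(2, seed = 1), c(-5, 10)))
})

test_that("bands are kept in canonical order and serialize losslessly", {
  m <- voxel_dispersion(list(lorentzian_band(3000, 0.1, 20),
                             lorentzian_band(800, 0.3, 40),
                             lorentzian_band(800, 0.5, 15)),
                        n_infinity = 1.52)
  ctrs <- vapply(m$bands, `[[`, numeric(1), "center")
  expect_equal(ctrs, sort(ctrs))
  # tie at 800 broken by descending height
  expect_equal(vapply(m$bands, `[[`, numeric(1), "height")[1:2], c(0.5, 0.3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_dispersion(m, path)
  m2 <- read_dispersion(path)
  expect_equal(band_table(m2), band_table(m), tolerance = 1e-12)
  expect_equal(m2$n_infinity, m$n_infinity, tolerance = 1e-12)
})
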