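test_that("initial band centres are equi-spaced at mid-bin positions", {
  nu <- seq(500, 4000, by = 4)
  cfg <- fit_config(bands_per_voxel = 18, seed = 1)
  init <- init_parameters(cfg, nu, 1L, sphere_geometry(10))
  centers <- init$par[grepl("^v1_center", names(init$par))]
  expect_equal(unname(centers[1]), 500 + 3500 / 36, tolerance = 1e-9)
  expect_equal(unname(diff(centers)), rep(3500 / 18, 17), tolerance = 1e-9)

  cfg2 <- fit_config(bands_per_voxel = 2, seed = 1)
  init2 <- init_parameters(cfg2, seq(1000, 2000, by = 10), 1L, sphere_geometry(10))
  expect_equal(unname(init2$par[1:2]), c(1250, 1750))
  # heights and widths drawn within the configured ranges, n_inf at 1.5
  h <- init2$par[grepl("height", names(init2$par))]
  w <- init2$par[grepl("width", names(init2$par))]
  expect_true(all(h >= 0.001 & h <= 0.1))
  expect_true(all(w >= 5 & w <= 50))
  expect_equal(unname(init2$par["v1_ninf"]), 1.5)
})

test_that("initialization is deterministic per seed and warns when crowded", {
  nu <- seq(500, 4000, by = 4)
  cfg <- fit_config(bands_per_voxel = 6, seed = 77)
  a <- init_parameters(cfg, nu, 1L, sphere_geometry(10))
  b <- init_parameters(cfg, nu, 1L, sphere_geometry(10))
  expect_identical(a$par, b$par)
  cfg2 <- fit_config(bands_per_voxel = 5, seed = 77)
  expect_warning(init_parameters(cfg2, seq(1000, 1052, by = 4), 1L,
                                 sphere_geometry(10)), "over-parameterized")
})

test_that("target function is the sum of squared residuals", {
  expect_equal(target_s(c(1.5, 2.5), c(1, 2)), 0.5)
  expect_equal(target_s(c(1, 2), c(1, 2)), 0)
  truth <- random_dispersion(3, seed = 55)
  geo <- sphere_geometry(10)
  nu <- seq(500, 4000, by = 16)
  given <- qext_from_dispersion(truth, geo, nu)
  cfg <- fit_config(bands_per_voxel = 3, seed = 1)
  bt <- band_table(truth)
  par <- c(bt$center, bt$height, bt$width, truth$n_infinity)
  names(par) <- mierecon:::param_layout(cfg, 1L)
  obj <- objective_s(par, given, geo, cfg)
  expect_lte(obj$s, 1e-16 * sum(given$value^2))
  # permuting band labels leaves S unchanged
  perm <- c(bt$center[c(2, 3, 1)], bt$height[c(2, 3, 1)], bt$width[c(2, 3, 1)],
            truth$n_infinity)
  names(perm) <- names(par)
  expect_equal(objective_s(perm, given, geo, cfg)$s, obj$s, tolerance = 1e-12)
  # out-of-bounds parameters are clamped with a warning
  bad <- par; bad["v1_ninf"] <- 5
  expect_warning(res <- objective_s(bad, given, geo, cfg), "clamp")
  expect_gt(res$s, 0)
})

test_that("identifiability guard trips and can be relaxed", {
  truth <- random_dispersion(2, seed = 66)
  geo <- sphere_geometry(10)
  nu <- seq(1000, 1240, by = 8)     # 31 points for 7 parameters
  given <- qext_from_dispersion(truth, geo, nu)
  cfg <- fit_config(bands_per_voxel = 2, seed = 1, n_starts = 1)
  expect_error(fit_dispersion(given, geo, cfg), "10 per parameter")
})

test_that("noiseless two-band spectra are recovered to the generating truth", {
  truth <- voxel_dispersion(list(lorentzian_band(1200, 0.15, 35),
                                 lorentzian_band(2600, 0.25, 50)),
                            n_infinity = 1.48)
  geo <- sphere_geometry(10)
  nu <- seq(500, 4000, by = 8)
  given <- qext_from_dispersion(truth, geo, nu)
  cfg <- fit_config(bands_per_voxel = 2, seed = 13, n_starts = 2)
  fit <- fit_dispersion(given, geo, cfg, reference = truth)
  expect_true(fit$converged)
  bt <- band_table(fit$dispersions[[1]])
  expect_equal(bt$center, c(1200, 2600), tolerance = 1 / 1200)
  expect_gte(fit$scores[[1]]$r2_real, 0.99)
  expect_gte(fit$scores[[1]]$r2_imag, 0.99)
  expect_equal(fit$dispersions[[1]]$n_infinity, 1.48, tolerance = 1e-3)
})

test_that("fits are bit-reproducible and multi-start best is monotone", {
  truth <- voxel_dispersion(lorentzian_band(1800, 0.2, 40), n_infinity = 1.5)
  geo <- sphere_geometry(10)
  nu <- seq(500, 4000, by = 16)
  given <- qext_from_dispersion(truth, geo, nu)
  cfg <- fit_config(bands_per_voxel = 1, seed = 31, n_starts = 2)
  f1 <- fit_dispersion(given, geo, cfg)
  f2 <- fit_dispersion(given, geo, cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$objective, f2$objective)
  best <- vapply(1:3, function(ns) {
    cfg_ns <- fit_config(bands_per_voxel = 1, seed = 31, n_starts = ns)
    fit_dispersion(given, geo, cfg_ns)$objective
  }, numeric(1))
  expect_true(all(diff(best) <= 1e-12))
})

test_that("known distortions are unfolded together with the index", {
  truth <- voxel_dispersion(list(lorentzian_band(1300, 0.18, 40),
                                 lorentzian_band(2700, 0.22, 55)),
                            n_infinity = 1.5)
  geo <- sphere_geometry(10)
  nu <- seq(500, 4000, by = 8)
  d_true <- distortion_params(scale = 1.15, shift = 0.12, tilt = 0.08,
                              curvature = -0.06)
  bundle <- make_observation(truth, geo, nu = nu, distortion = d_true,
                             g_ratio = 100, seed = 17)
  cfg <- fit_config(bands_per_voxel = 2, seed = 19, n_starts = 2,
                    fit_distortion = TRUE, g_ratio = 100)
  fit <- fit_dispersion(bundle$observed, geo, cfg, reference = truth)
  expect_equal(fit$distortion$scale, 1.15, tolerance = 0.05)
  expect_equal(fit$distortion$shift, 0.12, tolerance = 0.05 * 0.12 + 1e-3)
  expect_equal(fit$distortion$tilt, 0.08, tolerance = 0.05 * 0.08 + 1e-3)
  expect_equal(fit$distortion$curvature, -0.06, tolerance = 0.05 * 0.06 + 1e-3)
  expect_gte(fit$scores[[1]]$r2_real, 0.99)
  expect_gte(fit$scores[[1]]$r2_imag, 0.99)
})

test_that("fit results serialize with bands, geometry and scores", {
  truth <- voxel_dispersion(lorentzian_band(2000, 0.2, 40), n_infinity = 1.5)
  geo <- sphere_geometry(10)
  nu <- seq(500, 4000, by = 16)
  given <- qext_from_dispersion(truth, geo, nu)
  cfg <- fit_config(bands_per_voxel = 1, seed = 23, n_starts = 1)
  fit <- fit_dispersion(given, geo, cfg, reference = truth)
  txt <- write_fit_result(fit)
  doc <- yaml::yaml.load(txt)
  expect_equal(doc$geometry$outer_radius_um, 10)
  expect_length(doc$dispersions, 1)
  expect_gte(doc$scores[[1]]$r2_real, 0.99)
  expect_true(is.numeric(doc$objective))
})
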