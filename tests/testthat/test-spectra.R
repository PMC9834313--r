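test_that("absorbance-extinction conversion follows the detector relation", {
  nu <- seq(500, 4000, by = 50)
  zero <- spectrum(nu, rep(0, length(nu)), kind = "absorbance")
  expect_equal(absorbance_to_qext(zero, 100)$value, rep(0, length(nu)))
  # saturation: very large absorbance approaches G/g
  sat <- spectrum(nu, rep(30, length(nu)), kind = "absorbance")
  expect_equal(absorbance_to_qext(sat, 100)$value, rep(100, length(nu)),
               tolerance = 1e-12)
  a <- spectrum(nu, rep(0.0132, length(nu)), kind = "absorbance")
  expect_equal(absorbance_to_qext(a, 100)$value[1], 2.99369, tolerance = 1e-5)
  q <- spectrum(nu, rep(2.99369, length(nu)), kind = "qext")
  expect_equal(qext_to_absorbance(q, 100)$value[1], 0.0132, tolerance = 1e-4)
})

test_that("conversion pair is a bijection on its valid domain", {
  set.seed(21)
  nu <- seq(500, 4000, by = 10)
  for (g_ratio in c(5, 100, 1000)) {
    a <- spectrum(nu, runif(length(nu), -0.05, 2), kind = "absorbance")
    back <- qext_to_absorbance(absorbance_to_qext(a, g_ratio), g_ratio)
    expect_equal(back$value, a$value, tolerance = 1e-12)
  }
  q_bad <- spectrum(nu, rep(6, length(nu)), kind = "qext")
  expect_error(qext_to_absorbance(q_bad, 5), "too small")
  expect_error(absorbance_to_qext(q_bad, 100), "absorbance")
  expect_error(absorbance_to_qext(spectrum(nu, rep(0, length(nu)),
                                           kind = "absorbance"), 0.5), "G/g")
})

test_that("distortion model is affine, exact at the worked example, invertible", {
  nu <- seq(500, 4000, by = 10)
  flat <- spectrum(nu, rep(0.5, length(nu)), kind = "absorbance")
  ident <- distortion_params()
  expect_equal(apply_distortion(flat, ident)$value, flat$value)
  shift <- distortion_params(shift = 0.2)
  expect_equal(apply_distortion(flat, shift)$value, flat$value + 0.2)
  d <- distortion_params(scale = 2, tilt = 0.1)
  out <- apply_distortion(flat, d)
  expect_equal(out$value[length(nu)], 2 * 0.5 + 0.1 * 0.5, tolerance = 1e-12)
  expect_equal(out$value[1], 2 * 0.5 - 0.1 * 0.5, tolerance = 1e-12)
  set.seed(4)
  rough <- spectrum(nu, runif(length(nu), 0, 1), kind = "absorbance")
  d2 <- distortion_params(scale = 1.3, shift = -0.1, tilt = 0.2, curvature = 0.4)
  expect_equal(remove_distortion(apply_distortion(rough, d2), d2)$value,
               rough$value, tolerance = 1e-12)
  # affine: distortion of a sum relates linearly
  expect_error(apply_distortion(spectrum(1000, 0.3, kind = "absorbance"), d2),
               "2 points")
  expect_error(distortion_params(scale = 0), "scale")
})

test_that("spectrum files round-trip losslessly and reject bad input", {
  nu <- seq(500, 4000, by = 7)
  sp <- spectrum(nu, sin(nu / 300) + 2, kind = "qext")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  back <- read_spectrum(path, kind = "qext")
  expect_equal(back$nu, sp$nu, tolerance = 1e-12)
  expect_equal(back$value, sp$value, tolerance = 1e-12)

  desc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# header", "2000 1.5", "1000 2.5"), desc)
  expect_warning(rs <- read_spectrum(desc, "qext"), "re-sorting")
  expect_equal(rs$nu, c(1000, 2000))
  expect_equal(rs$value, c(2.5, 1.5))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("# only a comment", empty)
  expect_error(read_spectrum(empty, "qext"), "no data")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000 1.5", "1500 oops"), bad)
  expect_error(read_spectrum(bad, "qext"), "line 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000 1.5", "1000 2.0"), dup)
  expect_error(read_spectrum(dup, "qext"), "duplicate")
})

test_that("index tables interpolate linearly and refuse extrapolation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# nu n k", "1000 1.50 0.10", "1200 1.54 0.30", "1400 1.52 0.20"),
             path)
  tab <- read_index_table(path)
  expect_equal(interpolate_index(tab, c(1000, 1200, 1400)), tab$index)
  mid <- interpolate_index(tab, 1100)
  expect_equal(mid, (tab$index[1] + tab$index[2]) / 2)
  expect_error(interpolate_index(tab, 900), "extrapolate")
  expect_error(interpolate_index(tab, 1500), "extrapolate")
  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000 1.5 -0.1"), neg)
  expect_error(read_index_table(neg), "negative")
  # write/read round trip
  out <- withr::local_tempfile(fileext = ".csv")
  write_index_table(tab$nu, tab$index, out)
  tab2 <- read_index_table(out)
  expect_equal(tab2$index, tab$index, tolerance = 1e-12)
})
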