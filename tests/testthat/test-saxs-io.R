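test_that("read_profile parses 3-column ASCII, skips headers, drops bad sigma", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# a header line",
               "q I err",
               "0.010 10.0 0.10",
               "0.020  9.5 0.10",
               "0.030  9.0 0.10",
               "0.040  8.4 0.10",
               "0.050  7.9 0.10"), f)
  p <- read_profile(f)
  expect_s3_class(p, "saxs_profile")
  expect_length(p$q, 5)
  expect_equal(p$intensity[1], 10)

  # a sigma <= 0 row is dropped with a warning, not an error
  writeLines(c("0.010 10.0 0.10", "0.015 -0.2 0.0", "0.020 9.5 0.10",
               "0.030 9.0 0.10", "0.040 8.4 0.10", "0.050 7.9 0.10"), f)
  expect_warning(p2 <- read_profile(f), "sigma")
  expect_length(p2$q, 5)

  # fewer than 5 valid rows is a format error
  writeLines(c("0.01 1 0.1", "0.02 1 0.1", "0.03 1 0.1", "0.04 1 0.1"), f)
  expect_error(read_profile(f), "fewer than 5")
  expect_error(read_profile(file.path(tempdir(), "no-such-file.dat")),
               "no such file")
})

test_that("profile invariants are enforced with the offending index named", {
  expect_error(saxs_profile(c(0.01, 0.03, 0.02, 0.04, 0.05), rep(1, 5),
                            rep(0.1, 5)),
               "index: 3")
  expect_error(saxs_profile(c(0.01, 0.02, 0.03, 0.04, 0.05), rep(1, 5),
                            c(0.1, 0.1, 0, 0.1, 0.1)),
               "sigma")
})

test_that("write_profile / read_profile round trip is lossless to 6 digits", {
  p <- sphere_profile(50, n = 60, rel_sigma = 0.01)
  f <- withr::local_tempfile(fileext = ".dat")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$q, p$q, tolerance = 1e-6)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-6)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-6)
})

test_that("rebin_log compresses onto log bins with inverse-variance stats", {
  p <- sphere_profile(50, n = 800, rel_sigma = 0.02)
  r <- rebin_log(p, 180)
  expect_lte(length(r$q), 180)
  expect_gt(length(r$q), 100)   # low-q log bins are sparser than the grid
  expect_true(all(diff(r$q) > 0))

  # identity case
  expect_identical(rebin_log(p, 1000), p)

  # hand-computed inverse-variance combination of two points in one bin:
  # I = (I1/1 + I2/4) / (1 + 1/4), sigma = 1/sqrt(1 + 1/4)
  p2 <- saxs_profile(c(0.01, 0.0101, 0.03, 0.05, 0.1, 0.2, 0.4),
                     c(2, 4, 1, 1, 1, 1, 1), c(1, 2, 1, 1, 1, 1, 1))
  r2 <- rebin_log(p2, 5)
  expect_length(r2$q, 5)
  expect_equal(r2$intensity[1], (2 / 1 + 4 / 4) / (1 + 1 / 4))
  expect_equal(r2$sigma[1], 1 / sqrt(1 + 1 / 4))

  # combined sigma never exceeds the best member sigma in any bin
  edges <- exp(seq(log(p$q[1]), log(p$q[length(p$q)]), length.out = 181))
  idx <- findInterval(p$q, edges, rightmost.closed = TRUE, all.inside = TRUE)
  best <- tapply(p$sigma, idx, min)
  expect_true(all(r$sigma <= best + 1e-12))
})

test_that("Guinier Rg matches sqrt(3/5) R within 1% on noise-free spheres", {
  for (R in c(20, 50, 100)) {
    g <- guinier_fit(sphere_profile(R))
    expect_lt(abs(g$rg - sqrt(3 / 5) * R) / (sqrt(3 / 5) * R), 0.01)
    expect_equal(g$i0, 1, tolerance = 0.01)
    expect_gte(g$n_points, 5)
  }
})

test_that("Guinier handles two-point scatterers and degenerate input", {
  q <- seq(0.002, 0.1, length.out = 200)
  d <- 60
  I <- 2 * (1 + sin(q * d) / (q * d))
  g <- guinier_fit(saxs_profile(q, I, 1e-6 * I))
  expect_equal(g$rg, d / 2, tolerance = 0.02)

  flat <- saxs_profile(q, rep(1, 200), rep(0.01, 200))
  expect_error(guinier_fit(flat), "degenerate")
})
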