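test_that("Debye intensity matches closed forms", {
  one <- bead_model(matrix(0, 1, 3))
  expect_equal(debye_intensity(one, c(0.01, 0.1, 0.3)), rep(1, 3))

  two <- bead_model(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(debye_intensity(two, 0.1), 2 * (1 + sin(5) / 5),
               tolerance = 1e-12)
  # I(0) = (sum w)^2
  w <- bead_model(rbind(c(0, 0, 0), c(30, 0, 0)), weight = c(1, 1.4))
  expect_equal(debye_intensity(w, 1e-6), (1 + 1.4)^2, tolerance = 1e-6)
})

test_that("bead-filled sphere reproduces the analytic form factor", {
  set.seed(1)
  n <- 2000
  pts <- matrix(runif(3 * 4 * n, -1, 1), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 1, ][1:n, ] * 50
  m <- bead_model(pts)
  q <- seq(0.005, 5 / 50, length.out = 40)   # q R <= 5
  x <- q * 50
  analytic <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  calc <- debye_intensity(m, q)
  expect_equal(calc / calc[1], analytic / analytic[1], tolerance = 0.02)
})

test_that("Debye sum is invariant under rigid motion; histogram mode close", {
  set.seed(2)
  X <- matrix(rnorm(300), 100, 3) * 30
  m1 <- bead_model(X)
  R <- random_rotation()
  m2 <- bead_model(sweep(X %*% t(R), 2, c(10, -4, 7), "+"))
  q <- seq(0.01, 0.3, length.out = 30)
  expect_equal(debye_intensity(m1, q), debye_intensity(m2, q),
               tolerance = 1e-10)
  hist <- debye_intensity(m1, q, method = "histogram", bin_width = 0.25)
  expect_lt(max(abs(hist / debye_intensity(m1, q) - 1)), 1e-3)
})

test_that("profile fitting recovers scale and constant", {
  q <- seq(0.01, 0.3, length.out = 100)
  calc <- exp(-q * 10)
  exp_prof <- saxs_profile(q, 2 * calc + 0.5, rep(1, 100))
  f <- fit_profile(calc, exp_prof)
  expect_equal(f$scale, 2, tolerance = 1e-10)
  expect_equal(f$constant, 0.5, tolerance = 1e-10)
  expect_equal(f$chi2, 0, tolerance = 1e-20)

  # chi2 invariant to common rescaling of I and sigma
  s <- saxs_profile(q, 2 * calc + 0.1 * sin(20 * q), rep(0.05, 100))
  s10 <- saxs_profile(q, s$intensity * 10, s$sigma * 10)
  expect_equal(fit_profile(calc, s)$chi2, fit_profile(calc, s10)$chi2)

  # constant calc curve with fit_constant is rank-degenerate
  expect_error(fit_profile(rep(1, 100), s, fit_constant = TRUE), "rank")
  # without the constant the offset cannot be absorbed
  off <- saxs_profile(q, rep(1.5, 100), rep(0.01, 100))
  f2 <- fit_profile(rep(1, 100), off, fit_constant = FALSE)
  expect_equal(f2$scale, 1.5, tolerance = 1e-10)
})

test_that("reduced chi2 of the true curve against its own noise is ~1", {
  truth <- small_truth("fp3")
  q <- seq(0.005, 0.3, length.out = 200)
  truecurve <- debye_intensity(truth$model, q)
  chi2 <- vapply(1:30, function(s) {
    p <- simulate_profile(truth$model, noise_level = 0.01, seed = s)
    fit_profile(truecurve, p)$chi2
  }, numeric(1))
  expect_equal(mean(chi2), 1, tolerance = 0.2)
})
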