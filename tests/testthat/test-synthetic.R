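test_that("spec validation rejects infeasible geometry", {
  expect_error(synthetic_spec(9, 180, 120), "1..8")
  expect_error(synthetic_spec(3, 30, 120, eye_extent = 40), "eye_sep")
  expect_error(synthetic_spec(3, 180, 80), "alpha_true")
})

test_that("presets carry the dimer/trimer/tetramer study geometry", {
  fp <- list(fp2 = c(2, 165, 150), fp3 = c(3, 180, 128),
             fp4 = c(4, 195, 109))
  for (nm in names(fp)) {
    s <- synthetic_preset(nm)
    expect_equal(c(s$n, s$eye_sep, s$alpha_true), fp[[nm]])
  }
})

test_that("realized models hit their designed geometry", {
  for (nm in c("fp2", "fp3", "fp4")) {
    truth <- small_truth(nm)
    s <- truth$spec
    expect_equal(eye_separation(truth$model), s$eye_sep,
                 tolerance = 0.01)
    expect_equal(alpha_angle(truth$model)$mean_alpha, s$alpha_true,
                 tolerance = 1 / s$alpha_true)
  }
  # n = 1: single protomer, no symmetry copies
  t1 <- make_oligomer(synthetic_spec(1, 110, 150, eye_beads = 24,
                                     arm_cluster_beads = 6))
  expect_equal(unique(t1$model$protomer_id), 1L)

  # the generator is deterministic (no RNG consumed)
  set.seed(99); a <- small_truth("fp3")
  set.seed(1);  b <- small_truth("fp3")
  expect_identical(a$model$xyz, b$model$xyz)
})

test_that("n = 2 D_max is close to eye_sep + eye_extent", {
  truth <- small_truth("fp2")
  expect_equal(model_dmax(truth$model), 165 + 40, tolerance = 10 / 205)
})

test_that("planar C4 model shows inter-eye peaks in the sqrt(2) ratio", {
  truth <- make_oligomer(synthetic_spec(4, eye_sep = 190, alpha_true = 90,
                                        eye_beads = 100,
                                        arm_cluster_beads = 0))
  pk <- find_peaks(model_pr(truth$model, bin_width = 2))
  inter <- pk[pk$position > 100, ]
  expect_equal(max(inter$position) / min(inter$position), sqrt(2),
               tolerance = 0.03)
  expect_equal(min(inter$position), 190, tolerance = 0.03)
})

test_that("noise-free simulation equals the Debye curve with a sigma floor", {
  truth <- small_truth("fp3")
  p0 <- simulate_profile(truth$model, noise_level = 0, seed = 1)
  expect_equal(p0$intensity, debye_intensity(truth$model, p0$q))
  expect_true(all(p0$sigma > 0))
  # and does not consume the RNG stream
  set.seed(5); u1 <- runif(1)
  simulate_profile(truth$model, noise_level = 0, seed = 1)
  set.seed(5); expect_identical(runif(1), u1)
})

test_that("simulated noise is unbiased and carries the stated sigma", {
  truth <- small_truth("fp3")
  q <- seq(0.005, 0.3, length.out = 60)
  Iq <- debye_intensity(truth$model, q)
  reps <- vapply(1:200, function(s)
    simulate_profile(truth$model, n_q = 60, noise_level = 0.02,
                     seed = s)$intensity, numeric(60))
  sig <- simulate_profile(truth$model, n_q = 60, noise_level = 0.02,
                          seed = 1)$sigma
  z <- abs(rowMeans(reps) - Iq) / (sig / sqrt(200))
  expect_lt(max(z), 4)           # law-of-large-numbers envelope
  zs <- apply(reps, 1, sd) / sig
  expect_equal(mean(zs), 1, tolerance = 0.05)
})
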