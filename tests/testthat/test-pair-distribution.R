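nrms <- function(a, b) {
  a <- a / sum(a); b <- b / sum(b)
  sqrt(mean((a - b)^2)) / max(b)
}

test_that("IFT of a sphere curve reproduces the closed-form p(r)", {
  p <- sphere_profile(50, rel_sigma = 0.005)
  pr <- ift_pr(p, dmax = 100)
  oracle <- sphere_pr_oracle(pr$r, 50)
  expect_lt(nrms(pr$p, oracle), 0.02)
  # real-space Rg and I(0) from the moments
  expect_equal(pr$rg_real, sqrt(3 / 5) * 50, tolerance = 0.01)
  g <- guinier_fit(p)
  expect_equal(pr$rg_real, g$rg, tolerance = 0.03)
  expect_equal(pr$i0 / g$i0, 1, tolerance = 0.01)
})

test_that("IFT of two point scatterers peaks at their separation", {
  pr <- suppressWarnings(ift_pr(two_point_profile(100), dmax = 120))
  pk <- find_peaks(pr)
  inter <- pk[pk$position > 50, ]
  expect_equal(inter$position[which.max(inter$height)], 100, tolerance = 0.02)
})

test_that("dmax scan selects the true support", {
  # sphere: 2R within 5%
  sc <- scan_dmax(sphere_profile(50, rel_sigma = 0.005), seq(60, 160, 5))
  expect_true(any(sc$selected))
  expect_equal(sc$dmax[sc$selected], 100, tolerance = 0.05)

  # two-point d = 100: stated rule lands in [100, 115]
  sc2 <- suppressWarnings(scan_dmax(two_point_profile(100), seq(80, 150, 5)))
  expect_gte(sc2$dmax[sc2$selected], 100)
  expect_lte(sc2$dmax[sc2$selected], 115)

  # degenerate single-value grid
  sc3 <- scan_dmax(sphere_profile(50, rel_sigma = 0.005), 100)
  expect_true(sc3$selected[1])
})

test_that("peak detection: sphere maximum near 1.05 R, empty for flat p", {
  pr <- ift_pr(sphere_profile(50, rel_sigma = 0.005), dmax = 100)
  pk <- find_peaks(pr)
  expect_equal(nrow(pk), 1)
  # numeric maximum of r^2 gamma(r) for a sphere sits at ~1.05 R
  r <- seq(0, 100, 0.01)
  expect_equal(pk$position, r[which.max(sphere_pr_oracle(r, 50))],
               tolerance = 0.02)

  flat <- pair_distribution(seq(0, 10, 1), rep(0, 11), dmax = 10)
  expect_equal(nrow(find_peaks(flat)), 0)
})

test_that("square of four eye clusters shows the sqrt(2) diagonal peak", {
  truth <- make_oligomer(synthetic_spec(4, eye_sep = 190, alpha_true = 90,
                                        eye_beads = 100,
                                        arm_cluster_beads = 0))
  pk <- find_peaks(model_pr(truth$model, bin_width = 2))
  inter <- pk[pk$position > 100, ]
  expect_equal(nrow(inter), 2)
  expect_equal(max(inter$position) / min(inter$position), sqrt(2),
               tolerance = 0.03)
})

test_that("round trip: IFT of a model's Debye curve matches its direct p(r)", {
  truth <- small_truth("fp3")
  q <- seq(0.005, 0.3, length.out = 250)    # q_max * dmax ~ 70 >> 25
  I <- debye_intensity(truth$model, q)
  prof <- saxs_profile(q, I, 1e-4 * max(I) + 1e-4 * I)
  pr <- suppressWarnings(ift_pr(prof, dmax = 250, qmax = 0.3))
  dr <- pr$r[2] - pr$r[1]                   # commensurate grids (2.5 A)
  direct <- model_pr(truth$model, bin_width = dr)
  onto <- approx(direct$r, direct$p, xout = pr$r, rule = 2)$y
  # compare at the resolution the q range supports (pi/q_max ~ 10 A): the
  # direct histogram carries sub-resolution intra-cluster spikes that no
  # regularized inversion of this data can or should reproduce
  agg <- function(p) tapply(p, floor(pr$r / 10), sum)
  a <- agg(pmax(pr$p, 0)); b <- agg(onto)
  expect_lt(nrms(a, b), 0.03)
  expect_equal(pr$i0 / sum(truth$model$weight)^2, 1, tolerance = 0.02)
})
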