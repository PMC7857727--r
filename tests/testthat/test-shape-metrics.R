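test_that("principal axes identify the thin direction and degeneracy", {
  # planar square in xy: smallest axis is z
  sq <- bead_model(rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0)))
  ax <- principal_axes(sq)
  expect_equal(abs(ax$axes[3, 1]), 1, tolerance = 1e-12)
  expect_true(all(abs(crossprod(ax$axes) - diag(3)) < 1e-10))
  expect_gt(det(ax$axes), 0)

  # collinear beads: rank warning, two degenerate eigenvalues
  line <- bead_model(cbind(seq(0, 10, 1), 0, 0))
  expect_warning(axl <- principal_axes(line), "collinear|degenerate")
  expect_equal(abs(axl$axes[1, 3]), 1, tolerance = 1e-12)
})

test_that("principal axes are equivariant under rotation", {
  set.seed(7)
  X <- matrix(rnorm(300), 100, 3) %*% diag(c(30, 12, 4))  # distinct spectrum
  m <- bead_model(X)
  ax <- principal_axes(m)
  for (rep in 1:5) {
    R <- random_rotation()
    ax2 <- principal_axes(bead_model(X %*% t(R)))
    for (k in 1:3) {
      ang <- acos(min(1, abs(sum((R %*% ax$axes[, k]) * ax2$axes[, k]))))
      expect_lt(ang, 1e-6)
    }
  }
})

test_that("alpha angle hits its extremes and obeys the flip rule", {
  mk <- function(vdir, n = 4) {
    set.seed(1)
    pts <- NULL; anchors <- integer(); pid <- integer()
    for (k in 1:n) {
      phi <- 2 * pi * (k - 1) / n
      c0 <- c(100 * cos(phi), 100 * sin(phi), 0)
      blob <- sweep(matrix(rnorm(90, 0, 6), 30, 3), 2, c0, "+")
      blob[, 3] <- blob[, 3] * 0.3
      pts <- rbind(pts, blob, c0 - 10 * vdir, c0 + 10 * vdir)
      anchors <- c(anchors, setNames(c(nrow(pts) - 1, nrow(pts)),
                                     paste0(c("S345_", "A402_"), k)))
      pid <- c(pid, rep(k, 32))
    }
    bead_model(pts, protomer_id = pid, anchors = anchors)
  }
  up <- alpha_angle(mk(c(0, 0, 1)))
  expect_equal(up$mean_alpha, 180, tolerance = 1)
  flat <- alpha_angle(mk(c(1, 0, 0)))
  expect_equal(flat$mean_alpha, 90, tolerance = 1)
  expect_gte(flat$mean_alpha, 90)

  # a 30-degree construction flips to 150
  v30 <- c(sin(pi / 6), 0, cos(pi / 6))
  a30 <- alpha_angle(mk(v30))
  expect_true(a30$flipped)
  expect_equal(a30$mean_alpha, 150, tolerance = 1)

  expect_error(alpha_angle(mk(c(0, 0, 1)), anchor_from = "missing"),
               "configuration error")
})

test_that("alpha is invariant under global motion and protomer relabeling", {
  truth <- small_truth("fp3")
  a0 <- alpha_angle(truth$model)
  m <- truth$model
  set.seed(3)
  R <- ringfit:::rot_z(runif(1, 0, 2 * pi))
  m2 <- bead_model(sweep(m$xyz %*% t(R), 2, c(0, 0, 50), "+"),
                   body_id = m$body_id, protomer_id = m$protomer_id,
                   anchors = m$anchors)
  expect_equal(alpha_angle(m2)$mean_alpha, a0$mean_alpha, tolerance = 1e-6)

  relab <- c(2L, 3L, 1L)
  base <- sub("_(\\d+)$", "", names(m$anchors))
  prot <- as.integer(sub("^.*_(\\d+)$", "\\1", names(m$anchors)))
  m3 <- bead_model(m$xyz, body_id = m$body_id,
                   protomer_id = relab[m$protomer_id],
                   anchors = setNames(m$anchors,
                                      paste0(base, "_", relab[prot])))
  expect_equal(alpha_angle(m3)$mean_alpha, a0$mean_alpha, tolerance = 1e-6)
})

test_that("generator tilt is recovered within 2 degrees across [95, 175]", {
  for (al in c(95, 120, 150, 175)) {
    truth <- make_oligomer(synthetic_spec(3, 180, al, eye_beads = 24,
                                          arm_cluster_beads = 6))
    a <- alpha_angle(truth$model)
    expect_equal(a$mean_alpha, al, tolerance = 2 / al)
    expect_gte(a$mean_alpha, 90)
    expect_lte(a$mean_alpha, 180)
  }
})

test_that("model_dmax and model_pr are consistent", {
  two <- bead_model(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(model_dmax(two), 100)
  cube <- bead_model(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(model_dmax(cube), sqrt(3))

  # two-bead histogram: one occupied bin at r = 100 carrying mass 2
  pr2 <- model_pr(two, bin_width = 1)
  expect_equal(pr2$r[which.max(pr2$p)], 100)
  expect_equal(sum(pr2$p) * 1, 2, tolerance = 1e-12)  # (sum w)^2 - sum w^2

  truth <- small_truth("fp3")
  pr <- model_pr(truth$model, bin_width = 1)
  d <- model_dmax(truth$model)
  expect_equal(pr$dmax, d)
  support <- max(pr$r[pr$p > 0])
  expect_lt(abs(support - d), 1.5)           # within one bin width
  expect_gte(d, max(find_peaks(pr)$position) - 1)

  # invariant under rigid motion
  R <- random_rotation()
  moved <- bead_model(sweep(truth$model$xyz %*% t(R), 2, c(5, 6, 7), "+"),
                      weight = truth$model$weight)
  prm <- model_pr(moved, bin_width = 1)
  nr <- min(length(prm$p), length(pr$p))
  expect_equal(prm$p[1:nr], pr$p[1:nr], tolerance = 1e-8)
})

test_that("uniform sphere sampling matches the closed-form p(r)", {
  set.seed(4)
  pts <- matrix(runif(24000, -1, 1), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 1, ][1:1500, ] * 50
  pr <- model_pr(bead_model(pts), bin_width = 2)
  oracle <- sphere_pr_oracle(pr$r, 50)
  a <- pr$p / sum(pr$p); b <- oracle / sum(oracle)
  expect_lt(sqrt(mean((a - b)^2)) / max(b), 0.02)
})
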