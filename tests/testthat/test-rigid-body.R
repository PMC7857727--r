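one_bead_assembly <- function(n, at = c(100, 0, 0)) {
  assembly_spec(list(list(spec = rigid_body_spec("b", matrix(at, 1, 3)),
                          placement = placement())), symmetry_n = n)
}

test_that("apply_cn realizes the expected symmetry geometry", {
  # identity for n = 1
  truth <- small_truth("fp3")
  protomer <- assembly_spec(truth$assembly$bodies, symmetry_n = 1)
  m1 <- apply_cn(protomer)
  m3 <- apply_cn(truth$assembly)
  expect_equal(m1$xyz, m3$xyz[m3$protomer_id == 1, ])

  # C4 of a single bead at (100, 0, 0)
  m <- apply_cn(one_bead_assembly(4))
  expect_equal(m$xyz,
               rbind(c(100, 0, 0), c(0, 100, 0), c(-100, 0, 0),
                     c(0, -100, 0)),
               tolerance = 1e-12)
  d12 <- sqrt(sum((m$xyz[1, ] - m$xyz[2, ])^2))
  expect_equal(d12, 100 * sqrt(2), tolerance = 1e-12)

  # per-protomer Rg identical across copies (isometry)
  rgs <- vapply(1:3, function(k) {
    sub <- m3$xyz[m3$protomer_id == k, ]
    sqrt(mean(rowSums(sweep(sub, 2, colMeans(sub))^2)))
  }, numeric(1))
  expect_lt(max(rgs) - min(rgs), 1e-10)
})

test_that("penalty energies follow the flat-bottom and clash forms", {
  truth <- small_truth("fp3")
  rs <- synthetic_restraints(truth)
  pe <- penalty_energy(truth$model, rs)
  expect_equal(pe$restraint_energy, 0)      # truth satisfies its restraints

  # single restraint violated by 2 A beyond tolerance, k = 1 -> 4.0
  m <- bead_model(rbind(c(0, 0, 0), c(12, 0, 0)),
                  body_id = c("a", "b"),
                  anchors = c(p = 1L, q = 2L))
  r1 <- restraint_set("p", "q", target = 8, tolerance = 2, k = 1)
  expect_equal(penalty_energy(m, r1)$restraint_energy, 4)
  # inside the flat bottom: zero
  r2 <- restraint_set("p", "q", target = 11, tolerance = 1.5, k = 1)
  expect_equal(penalty_energy(m, r2)$restraint_energy, 0)

  # clash: two beads of different bodies at 2.0 A, clash_dist 3.8 -> 3.24
  mc <- bead_model(rbind(c(0, 0, 0), c(2, 0, 0)), body_id = c("a", "b"))
  expect_equal(penalty_energy(mc, NULL, clash_dist = 3.8,
                              k_clash = 1)$clash_energy,
               (3.8 - 2)^2, tolerance = 1e-12)

  expect_error(penalty_energy(m, restraint_set("p", "nope", 5)),
               "unresolvable.*nope")
})

test_that("refine with zero moves is a scored no-op", {
  truth <- small_truth("fp3")
  prof <- simulate_profile(truth$model, noise_level = 0.01, seed = 3)
  r <- refine(truth$assembly, synthetic_restraints(truth), prof,
              refine_config(n_moves = 0), seed = 1)
  expect_equal(r$model$xyz, truth$model$xyz)
  expect_lt(r$chi2, 1.5)   # truth scores at the noise floor
})

test_that("refined models stay exactly C_n symmetric", {
  truth <- small_truth("fp3")
  prof <- simulate_profile(truth$model, noise_level = 0.01, seed = 3)
  cfg <- refine_config(n_moves = 60, polish_sweeps = 1, polish_maxit = 20,
                       basin_hops = 0, joint_maxit = 5)
  r <- refine(truth$assembly, synthetic_restraints(truth), prof, cfg,
              seed = 5)
  m <- r$model
  p1 <- m$xyz[m$protomer_id == 1, ]
  for (k in 2:3) {
    rot <- p1 %*% t(ringfit:::rot_z(2 * pi * (k - 1) / 3))
    expect_lt(max(abs(rot - m$xyz[m$protomer_id == k, ])), 1e-6)
  }
  # score trace is non-increasing at best-so-far checkpoints
  expect_true(all(diff(r$trace) <= 1e-9))
  # reproducible given the seed
  r2 <- refine(truth$assembly, synthetic_restraints(truth), prof, cfg,
               seed = 5)
  expect_equal(r$total_score, r2$total_score)
  expect_equal(r$model$xyz, r2$model$xyz)
})

test_that("objective is invariant to global rotation about z", {
  truth <- small_truth("fp3")
  prof <- simulate_profile(truth$model, noise_level = 0.01, seed = 3)
  rs <- synthetic_restraints(truth)
  cfg <- refine_config()
  keep <- prof$q <= cfg$qmax
  pf <- saxs_profile(prof$q[keep], prof$intensity[keep], prof$sigma[keep])
  s0 <- ringfit:::assembly_score(truth$assembly, rs, pf, cfg)$total
  rot <- truth$assembly
  Rz <- ringfit:::rot_z(0.7)
  for (j in seq_along(rot$bodies)) {
    pl <- rot$bodies[[j]]$placement
    rot$bodies[[j]]$placement <- placement(Rz %*% pl$rotation,
                                           as.numeric(Rz %*% pl$translation))
  }
  s1 <- ringfit:::assembly_score(rot, rs, pf, cfg)$total
  expect_equal(s0, s1, tolerance = 1e-6)
})

test_that("C1 refinement of a symmetric target scores no worse than C3", {
  truth <- small_truth("fp3")
  prof <- simulate_profile(truth$model, noise_level = 0.01, seed = 3)
  rs3 <- synthetic_restraints(truth)
  cfg <- refine_config(n_moves = 150, polish_sweeps = 1, polish_maxit = 30,
                       basin_hops = 0, joint_maxit = 10, fit_stride = 3)
  r3 <- refine(truth$assembly, rs3, prof, cfg, seed = 2)

  # the same target rebuilt as an explicit C1 assembly (all bodies free)
  bodies1 <- list()
  for (k in 0:2) {
    Rz <- ringfit:::rot_z(2 * pi * k / 3)
    for (b in truth$assembly$bodies) {
      b$spec$body_id <- paste0(b$spec$body_id, "_p", k + 1)
      names(b$spec$anchors) <- paste0(names(b$spec$anchors), "_p", k + 1)
      b$placement <- placement(Rz %*% b$placement$rotation,
                               as.numeric(Rz %*% b$placement$translation))
      bodies1 <- c(bodies1, list(b))
    }
  }
  asm1 <- assembly_spec(bodies1, symmetry_n = 1)
  map <- function(a) {  # eyeC_2 -> eyeC_p2_1 style renaming
    parts <- sub("_(\\d+)$", "", a)
    prot <- sub("^.*_(\\d+)$", "\\1", a)
    paste0(parts, "_p", prot, "_1")
  }
  rs1 <- restraint_set(map(rs3$anchor_a), map(rs3$anchor_b), rs3$target,
                       rs3$tolerance, rs3$k)
  r1 <- refine(asm1, rs1, prof, cfg, seed = 2)
  expect_lte(r1$chi2, r3$chi2 * 1.1 + 0.1)
})

test_that("run_batch clusters, picks a medoid and flags outliers", {
  truth <- small_truth("fp3")
  prof <- simulate_profile(truth$model, noise_level = 0.01, seed = 3)
  rs <- synthetic_restraints(truth)
  cfg <- refine_config(n_moves = 120, polish_sweeps = 1, polish_maxit = 25,
                       basin_hops = 0, joint_maxit = 8, fit_stride = 3)
  b1 <- run_batch(truth$assembly, rs, prof, cfg, n_runs = 1, seed = 4)
  expect_equal(b1$representative, 1L)

  b3 <- run_batch(truth$assembly, rs, prof, cfg, n_runs = 3, seed = 4,
                  perturb_rot = 10, perturb_trans = 5)
  expect_s3_class(b3$summary, "data.frame")
  expect_true(b3$summary$representative[b3$representative])
  expect_false(any(b3$summary$outlier[b3$representative]))
})
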