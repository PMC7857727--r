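`%||%` <- function(a, b) if (is.null(a)) b else a

# --- rotation helpers -------------------------------------------------------

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# rotation about an arbitrary unit axis (Rodrigues)
rot_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# nearest proper rotation (guards against drift from accumulated products)
orthonormalize <- function(R) {
  s <- svd(R)
  Q <- s$u %*% t(s$v)
  if (det(Q) < 0) Q <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  Q
}

# --- rigid-body containers --------------------------------------------------

#' Define a rigid body
#'
#' @param body_id label.
#' @param xyz beads in the body frame (N x 3).
#' @param weight per-bead scattering weight (recycled).
#' @param anchors named integer vector of anchor bead rows, local to the body.
#' @return An object of class `rigid_body_spec`.
#' @export
rigid_body_spec <- function(body_id, xyz, weight = 1, anchors = integer()) {
  xyz <- as.matrix(xyz); storage.mode(xyz) <- "double"
  if (nrow(xyz) < 1) stop("a rigid body needs at least one bead")
  anchors <- vapply(anchors, as.integer, integer(1))
  if (length(anchors) && (any(anchors < 1) || any(anchors > nrow(xyz))))
    stop("anchor index not resolvable in body ", body_id)
  structure(list(body_id = as.character(body_id), xyz = xyz,
                 weight = rep_len(as.numeric(weight), nrow(xyz)),
                 anchors = anchors), class = "rigid_body_spec")
}

#' Define a body placement (proper rotation + translation)
#'
#' @param rotation 3 x 3 proper orthonormal matrix (checked to 1e-8).
#' @param translation length-3 vector \[Angstrom\].
#' @return An object of class `placement`.
#' @export
placement <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper orthonormal (det = +1) within 1e-8")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "placement")
}

#' Define a C_n assembly: one protomer's bodies plus a symmetry order
#'
#' The symmetry axis is fixed to z (models are assumed pre-oriented, e.g. by
#' principal-axis alignment).
#'
#' @param bodies list of `list(spec = rigid_body_spec, placement = placement)`.
#' @param symmetry_n integer >= 1.
#' @return An object of class `assembly_spec`.
#' @export
assembly_spec <- function(bodies, symmetry_n = 1L) {
  symmetry_n <- as.integer(symmetry_n)
  if (symmetry_n < 1) stop("symmetry_n must be >= 1")
  for (b in bodies) {
    stopifnot(inherits(b$spec, "rigid_body_spec"),
              inherits(b$placement, "placement"))
  }
  ids <- vapply(bodies, function(b) b$spec$body_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate body_id in assembly")
  structure(list(bodies = bodies, symmetry_n = symmetry_n),
            class = "assembly_spec")
}

#' Realize a C_n assembly as a bead model
#'
#' Places each body (local coordinates through its placement), concatenates
#' the protomer, then applies rotations by 2*pi*k/n about z for
#' k = 0..n-1. Protomer ids are set per copy and every anchor is replicated
#' with a `_k` protomer suffix.
#'
#' @param assembly an [assembly_spec].
#' @return A realized [bead_model].
#' @export
apply_cn <- function(assembly) {
  stopifnot(inherits(assembly, "assembly_spec"))
  xyz <- NULL; weight <- NULL; body_id <- NULL; anchors <- integer()
  off <- 0L
  for (b in assembly$bodies) {
    co <- b$spec$xyz %*% t(b$placement$rotation)
    co <- sweep(co, 2, b$placement$translation, "+")
    xyz <- rbind(xyz, co)
    weight <- c(weight, b$spec$weight)
    body_id <- c(body_id, rep(b$spec$body_id, nrow(co)))
    if (length(b$spec$anchors))
      anchors <- c(anchors, setNames(b$spec$anchors + off,
                                     names(b$spec$anchors)))
    off <- off + nrow(co)
  }
  n <- assembly$symmetry_n
  np <- nrow(xyz)
  all_xyz <- do.call(rbind, lapply(0:(n - 1L), function(k)
    xyz %*% t(rot_z(2 * pi * k / n))))
  all_anchors <- integer()
  if (length(anchors))
    for (k in seq_len(n))
      all_anchors <- c(all_anchors,
                       setNames(anchors + (k - 1L) * np,
                                paste0(names(anchors), "_", k)))
  bead_model(all_xyz,
             weight = rep(weight, n),
             body_id = rep(body_id, n),
             protomer_id = rep(seq_len(n), each = np),
             anchors = all_anchors)
}

# --- restraints and penalties -----------------------------------------------

#' Build a restraint table
#'
#' Flat-bottom quadratic distance restraints between named anchors of a
#' realized model: zero inside `|d - target| <= tolerance`, else
#' `k * (|d - target| - tolerance)^2`.
#'
#' @param anchor_a,anchor_b protomer-qualified anchor names.
#' @param target target distances \[Angstrom\], > 0.
#' @param tolerance flat-bottom half-widths \[Angstrom\], >= 0.
#' @param k force constants \[score units / Angstrom^2\], > 0.
#' @return A data.frame of class `restraint_set`.
#' @export
restraint_set <- function(anchor_a, anchor_b, target, tolerance = 0, k = 10) {
  out <- data.frame(anchor_a = as.character(anchor_a),
                    anchor_b = as.character(anchor_b),
                    target = as.numeric(target),
                    tolerance = as.numeric(tolerance),
                    k = as.numeric(k))
  if (any(out$target <= 0) || any(out$tolerance < 0) || any(out$k <= 0))
    stop("restraints require target > 0, tolerance >= 0, k > 0")
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Restraint and clash penalty energies of a realized model
#'
#' @param model a realized [bead_model].
#' @param restraints a [restraint_set] (may have zero rows).
#' @param clash_dist beads of different bodies closer than this
#'   \[Angstrom\] are penalized `k_clash * (clash_dist - d)^2` (default 3.8).
#' @param k_clash clash force constant (default 1).
#' @return A list: `restraint_energy`, `clash_energy`, `table` (per-restraint
#'   distances, violations, energies).
#' @export
penalty_energy <- function(model, restraints, clash_dist = 3.8, k_clash = 1) {
  stopifnot(inherits(model, "bead_model"))
  tab <- NULL
  e_r <- 0
  if (!is.null(restraints) && nrow(restraints)) {
    ia <- model$anchors[restraints$anchor_a]
    ib <- model$anchors[restraints$anchor_b]
    miss <- is.na(ia) | is.na(ib)
    if (any(miss))
      stop("configuration error: unresolvable anchor(s): ",
           paste(unique(c(restraints$anchor_a[is.na(ia)],
                          restraints$anchor_b[is.na(ib)])), collapse = ", "))
    d <- sqrt(rowSums((model$xyz[ia, , drop = FALSE] -
                         model$xyz[ib, , drop = FALSE])^2))
    viol <- pmax(abs(d - restraints$target) - restraints$tolerance, 0)
    e <- restraints$k * viol^2
    e_r <- sum(e)
    tab <- data.frame(anchor_a = restraints$anchor_a,
                      anchor_b = restraints$anchor_b,
                      target = restraints$target, distance = d,
                      violation = viol, energy = e)
  }
  group <- as.integer(factor(paste(model$body_id, model$protomer_id)))
  e_c <- cpp_clash_energy(model$xyz, group, clash_dist, k_clash)
  list(restraint_energy = e_r, clash_energy = e_c, table = tab)
}

# --- refinement -------------------------------------------------------------

#' Refinement configuration
#'
#' @param n_moves number of Metropolis moves (default 20000).
#' @param cool geometric cooling factor applied every `cool_every` moves;
#'   `NULL` (default) derives it so the temperature falls by `t_end_ratio`
#'   over the whole run regardless of `n_moves`.
#' @param cool_every moves per cooling step.
#' @param t_end_ratio target final/initial temperature ratio for the
#'   auto-derived schedule (default 1e-7).
#' @param sigma_trans base translation move size \[Angstrom\].
#' @param sigma_rot base rotation move size \[degrees\].
#' @param t_start starting temperature; `NULL` = auto-set so the initial
#'   acceptance rate is about 50%.
#' @param w_restraint,w_clash penalty weights in units of reduced chi2.
#' @param clash_dist,k_clash clash term parameters (see [penalty_energy()]).
#' @param qmax fit range \[1/Angstrom\].
#' @param fit_constant fit an additive constant in the profile fit?
#' @param debye_method intensity evaluation inside the annealing loop:
#'   `"histogram"` (pair-distance histogram at `debye_bin`, relative error
#'   below 1e-3 — the default, an order of magnitude faster) or `"exact"`.
#' @param debye_bin histogram bin width \[Angstrom\].
#' @param polish_sweeps derivative-free local polish after annealing: number
#'   of Nelder-Mead sweeps over the bodies (0 disables).
#' @param polish_maxit Nelder-Mead iterations per body per sweep.
#' @param basin_hops after polishing, number of escape attempts: one body is
#'   kicked by a random rotation, locally re-polished and the move kept only
#'   if the total score improves (0 disables). Helps leave shallow
#'   orientation minima of individual bodies.
#' @param hop_angle kick rotation magnitude \[degrees\].
#' @param fit_stride use every `fit_stride`-th point of the profile in the
#'   optimization objective (default 1 = all). SAXS grids typically
#'   oversample the Shannon spacing pi/D_max several-fold, so a stride of
#'   2-3 speeds refinement up without information loss; the reported chi2 is
#'   always computed on the full fitted range.
#' @param joint_maxit iterations of the final quasi-Newton (numerical
#'   gradient BFGS) refinement over all bodies jointly (0 disables). This
#'   stage removes the zigzag limit of per-body coordinate descent and
#'   brings every run in the same basin to the same score floor.
#' @return A list of class `refine_config`.
#' @export
refine_config <- function(n_moves = 20000L, cool = NULL, cool_every = 100L,
                          t_end_ratio = 1e-7,
                          sigma_trans = 5, sigma_rot = 10, t_start = NULL,
                          w_restraint = 1, w_clash = 1, clash_dist = 3.8,
                          k_clash = 1, qmax = 0.27, fit_constant = TRUE,
                          debye_method = c("histogram", "exact"),
                          debye_bin = 0.25, polish_sweeps = 2L,
                          polish_maxit = 150L, basin_hops = 6L,
                          hop_angle = 25, fit_stride = 1L,
                          joint_maxit = 60L) {
  if (is.null(cool))
    cool <- exp(log(t_end_ratio) / max(1, n_moves / cool_every))
  structure(list(n_moves = as.integer(n_moves), cool = cool,
                 cool_every = as.integer(cool_every),
                 sigma_trans = sigma_trans, sigma_rot = sigma_rot,
                 t_start = t_start, w_restraint = w_restraint,
                 w_clash = w_clash, clash_dist = clash_dist,
                 k_clash = k_clash, qmax = qmax,
                 fit_constant = fit_constant,
                 debye_method = match.arg(debye_method),
                 debye_bin = debye_bin,
                 polish_sweeps = as.integer(polish_sweeps),
                 polish_maxit = as.integer(polish_maxit),
                 basin_hops = as.integer(basin_hops),
                 hop_angle = hop_angle,
                 fit_stride = as.integer(fit_stride),
                 joint_maxit = as.integer(joint_maxit)),
            class = "refine_config")
}

# total score of an assembly state; returns parts for diagnostics
assembly_score <- function(assembly, restraints, prof, config) {
  model <- apply_cn(assembly)
  calc <- debye_intensity(model, prof$q,
                          method = config$debye_method %||% "exact",
                          bin_width = config$debye_bin %||% 0.25)
  fit <- fit_profile(calc, prof, fit_constant = config$fit_constant)
  pen <- penalty_energy(model, restraints, clash_dist = config$clash_dist,
                        k_clash = config$k_clash)
  total <- fit$chi2 + config$w_restraint * pen$restraint_energy +
    config$w_clash * pen$clash_energy
  list(total = total, chi2 = fit$chi2,
       restraint_energy = pen$restraint_energy,
       clash_energy = pen$clash_energy, model = model, fit = fit)
}

# derivative-free local polish: Nelder-Mead over one body's 6 rigid DOFs at
# a time, sweeping the bodies; robust to the small steps the histogram
# intensity introduces
move_body_par <- function(b, par) {
  ang <- sqrt(sum(par[1:3]^2))
  R <- if (ang > 1e-12)
    rot_axis(par[1:3] / ang, ang) %*% b$placement$rotation
  else b$placement$rotation
  b$placement <- placement(orthonormalize(R),
                           b$placement$translation + par[4:6])
  b
}

polish_body <- function(asm, j, restraints, prof, config) {
  b0 <- asm$bodies[[j]]
  f <- function(par) {
    asm$bodies[[j]] <- move_body_par(b0, par)
    assembly_score(asm, restraints, prof, config)$total
  }
  o <- optim(rep(0, 6), f, method = "Nelder-Mead",
             control = list(maxit = config$polish_maxit, reltol = 1e-10,
                            parscale = c(rep(0.05, 3), rep(1, 3))))
  asm$bodies[[j]] <- move_body_par(b0, o$par)
  asm
}

# final joint refinement: BFGS with numerical gradients over the stacked
# (rotation vector, translation) parameters of all bodies
polish_joint <- function(asm, restraints, prof, config) {
  nb <- length(asm$bodies)
  f <- function(par) {
    for (j in seq_len(nb))
      asm$bodies[[j]] <- move_body_par(asm$bodies[[j]],
                                       par[(6 * (j - 1) + 1):(6 * j)])
    assembly_score(asm, restraints, prof, config)$total
  }
  o <- optim(rep(0, 6 * nb), f, method = "BFGS",
             control = list(maxit = config$joint_maxit, reltol = 1e-12,
                            parscale = rep(c(rep(0.03, 3), rep(0.6, 3)), nb)))
  for (j in seq_len(nb))
    asm$bodies[[j]] <- move_body_par(asm$bodies[[j]],
                                     o$par[(6 * (j - 1) + 1):(6 * j)])
  asm
}

polish_assembly <- function(asm, restraints, prof, config) {
  prev <- assembly_score(asm, restraints, prof, config)$total
  for (s in seq_len(config$polish_sweeps)) {
    for (j in seq_along(asm$bodies))
      asm <- polish_body(asm, j, restraints, prof, config)
    cur <- assembly_score(asm, restraints, prof, config)$total
    if (prev - cur < 1e-3 * abs(prev)) break   # sweep no longer productive
    prev <- cur
  }
  asm
}

perturb_body <- function(b, sigma_trans, sigma_rot_deg) {
  ang <- rnorm(1, 0, sigma_rot_deg * pi / 180)
  R <- rot_axis(random_unit_vector(), ang) %*% b$placement$rotation
  t <- b$placement$translation + rnorm(3, 0, sigma_trans)
  b$placement <- placement(orthonormalize(R), t)
  b
}

#' Restrained rigid-body refinement by simulated annealing
#'
#' Metropolis simulated annealing over per-body rotation/translation moves
#' applied to the protomer; symmetry copies are regenerated every step. The
#' objective is
#' `chi2 + w_restraint * restraint_energy + w_clash * clash_energy`, with
#' chi2 from a free-scale (+ constant) fit of the Debye curve of the realized
#' model to the profile. Geometric cooling; move sizes shrink with the
#' square root of the temperature ratio. Fully reproducible given `seed`.
#'
#' @param start an [assembly_spec] (bodies with starting placements).
#' @param restraints a [restraint_set] (or NULL).
#' @param profile a [saxs_profile].
#' @param config a [refine_config].
#' @param seed integer RNG seed.
#' @return A list of class `refinement_result`: `assembly`, `model`
#'   (realized best state), `chi2`, `restraint_energy`, `clash_energy`,
#'   `total_score`, `trace` (best-so-far score at checkpoints), `accept_rate`,
#'   `seed`, `config`.
#' @export
refine <- function(start, restraints, profile, config = refine_config(),
                   seed = 1L) {
  stopifnot(inherits(start, "assembly_spec"))
  validate_profile(profile)
  keep <- profile$q <= config$qmax
  prof_full <- saxs_profile(profile$q[keep], profile$intensity[keep],
                            profile$sigma[keep], label = profile$label)
  stride <- max(1L, config$fit_stride %||% 1L)
  prof <- if (stride > 1L) {
    i <- seq(1L, length(prof_full$q), by = stride)
    saxs_profile(prof_full$q[i], prof_full$intensity[i], prof_full$sigma[i],
                 label = prof_full$label)
  } else prof_full
  set.seed(seed)
  cur <- start
  sc <- assembly_score(cur, restraints, prof, config)
  if (!is.finite(sc$total)) {
    bad <- c(chi2 = sc$chi2, restraint = sc$restraint_energy,
             clash = sc$clash_energy)
    stop("non-finite objective at start; offending term(s): ",
         paste(names(bad)[!is.finite(bad)], collapse = ", "))
  }
  best <- cur; best_sc <- sc
  trace <- sc$total
  nb <- length(cur$bodies)

  if (config$n_moves < 1L) {
    return(structure(list(assembly = best, model = best_sc$model,
                          chi2 = best_sc$chi2,
                          restraint_energy = best_sc$restraint_energy,
                          clash_energy = best_sc$clash_energy,
                          total_score = best_sc$total, trace = trace,
                          accept_rate = NA_real_, seed = seed,
                          config = config), class = "refinement_result"))
  }

  t0 <- config$t_start
  if (is.null(t0)) {
    # probe: set T0 so ~half of uphill probe moves would be accepted
    deltas <- replicate(40, {
      trial <- cur
      j <- sample.int(nb, 1)
      trial$bodies[[j]] <- perturb_body(trial$bodies[[j]], config$sigma_trans,
                                        config$sigma_rot)
      assembly_score(trial, restraints, prof, config)$total - sc$total
    })
    up <- deltas[deltas > 0]
    t0 <- if (length(up)) stats::median(up) / log(2) else 1
    t0 <- max(t0, 1e-6)
  }
  temp <- t0
  n_acc <- 0L
  for (m in seq_len(config$n_moves)) {
    f <- max(0.05, sqrt(temp / t0))
    trial <- cur
    j <- sample.int(nb, 1)
    trial$bodies[[j]] <- perturb_body(trial$bodies[[j]],
                                      config$sigma_trans * f,
                                      config$sigma_rot * f)
    sc_t <- assembly_score(trial, restraints, prof, config)
    d <- sc_t$total - sc$total
    if (d <= 0 || runif(1) < exp(-d / temp)) {
      cur <- trial; sc <- sc_t; n_acc <- n_acc + 1L
      if (sc$total < best_sc$total) {
        best <- cur; best_sc <- sc
      }
    }
    if (m %% config$cool_every == 0L) {
      temp <- temp * config$cool
      trace <- c(trace, best_sc$total)
    }
  }
  if (config$polish_sweeps > 0L) {
    polished <- polish_assembly(best, restraints, prof, config)
    sc_p <- assembly_score(polished, restraints, prof, config)
    if (sc_p$total <= best_sc$total) {
      best <- polished; best_sc <- sc_p
      trace <- c(trace, best_sc$total)
    }
  }
  if (config$basin_hops > 0L && config$polish_sweeps > 0L) {
    nb <- length(best$bodies)
    for (h in seq_len(config$basin_hops)) {
      trial <- best
      j <- ((h - 1L) %% nb) + 1L
      ang <- rnorm(1, 0, config$hop_angle * pi / 180)
      b <- trial$bodies[[j]]
      b$placement <- placement(
        orthonormalize(rot_axis(random_unit_vector(), ang) %*%
                         b$placement$rotation),
        b$placement$translation)
      trial$bodies[[j]] <- b
      trial <- polish_body(trial, j, restraints, prof, config)
      sc_t <- assembly_score(trial, restraints, prof, config)
      if (sc_t$total < best_sc$total) {
        best <- trial; best_sc <- sc_t
        trace <- c(trace, best_sc$total)
      }
    }
    polished <- polish_assembly(best, restraints, prof, config)
    sc_p <- assembly_score(polished, restraints, prof, config)
    if (sc_p$total <= best_sc$total) {
      best <- polished; best_sc <- sc_p
      trace <- c(trace, best_sc$total)
    }
  }
  if ((config$joint_maxit %||% 0L) > 0L && config$n_moves > 0L) {
    refined <- polish_joint(best, restraints, prof, config)
    sc_j <- assembly_score(refined, restraints, prof, config)
    if (sc_j$total <= best_sc$total) {
      best <- refined; best_sc <- sc_j
      trace <- c(trace, best_sc$total)
    }
  }
  if (stride > 1L)  # report scores on the full fitted range
    best_sc <- assembly_score(best, restraints, prof_full, config)
  structure(list(assembly = best, model = best_sc$model, chi2 = best_sc$chi2,
                 restraint_energy = best_sc$restraint_energy,
                 clash_energy = best_sc$clash_energy,
                 total_score = best_sc$total, trace = trace,
                 accept_rate = n_acc / config$n_moves, seed = seed,
                 config = config), class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf(
    "<refinement_result> chi2 = %.3f, E_restraint = %.3g, E_clash = %.3g, score = %.3f\n",
    x$chi2, x$restraint_energy, x$clash_energy, x$total_score))
  invisible(x)
}

# anchor-anchor internal distance vector, the rotation-invariant feature used
# for clustering
anchor_distance_vector <- function(model) {
  nm <- sort(names(model$anchors))
  X <- model$xyz[model$anchors[nm], , drop = FALSE]
  as.numeric(dist(X))
}

#' Batch refinement with randomized starts and clustering
#'
#' Runs `n_runs` independent refinements from perturbed copies of `start`
#' (uniform body rotations up to `perturb_rot` degrees and translations up to
#' `perturb_trans` Angstrom; clashing starts are rejected and redrawn). Runs
#' whose chi2 exceeds twice the best run's chi2 are discarded as outliers;
#' the remainder are clustered by pairwise anchor-distance RMSD with single
#' linkage, and the largest cluster's medoid (ties broken by lower chi2) is
#' flagged representative.
#'
#' @param start an [assembly_spec].
#' @param restraints a [restraint_set] (or NULL).
#' @param profile a [saxs_profile].
#' @param config a [refine_config].
#' @param n_runs number of independent runs.
#' @param seed master seed; run k uses `seed + k - 1`.
#' @param perturb_rot,perturb_trans start randomization amplitudes.
#' @param cluster_cutoff single-linkage height \[Angstrom\] (default 15).
#' @return A list of class `batch_result`: `runs` (list of
#'   `refinement_result`), `representative` (index), `clusters` (assignment,
#'   NA for outliers), `summary` (per-run data.frame).
#' @export
run_batch <- function(start, restraints, profile, config = refine_config(),
                      n_runs = 10L, seed = 1L, perturb_rot = 60,
                      perturb_trans = 30, cluster_cutoff = 15) {
  stopifnot(n_runs >= 1)
  base_pen <- penalty_energy(apply_cn(start), restraints,
                             clash_dist = config$clash_dist,
                             k_clash = config$k_clash)$clash_energy
  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(seed + k - 1L)
    for (try in 1:50) {
      pert <- start
      for (j in seq_along(pert$bodies)) {
        ang <- runif(1, 0, perturb_rot) * pi / 180
        R <- rot_axis(random_unit_vector(), ang) %*%
          pert$bodies[[j]]$placement$rotation
        shift <- random_unit_vector() * runif(1, 0, perturb_trans)
        pert$bodies[[j]]$placement <- placement(
          orthonormalize(R),
          pert$bodies[[j]]$placement$translation + shift)
      }
      ec <- penalty_energy(apply_cn(pert), restraints,
                           clash_dist = config$clash_dist,
                           k_clash = config$k_clash)$clash_energy
      if (ec <= base_pen + 10) break
    }
    runs[[k]] <- refine(pert, restraints, profile, config,
                        seed = seed + 1000L * k)
  }
  chi2 <- vapply(runs, function(r) r$chi2, numeric(1))
  ok <- chi2 <= 2 * min(chi2)
  clusters <- rep(NA_integer_, n_runs)
  if (sum(ok) == 1L) {
    clusters[ok] <- 1L
  } else {
    feats <- lapply(runs[ok], function(r) anchor_distance_vector(r$model))
    Fm <- do.call(rbind, feats)
    D <- as.dist(sqrt(outer(seq_len(nrow(Fm)), seq_len(nrow(Fm)),
                            Vectorize(function(i, j)
                              mean((Fm[i, ] - Fm[j, ])^2)))))
    clusters[ok] <- if (nrow(Fm) == 2L) {
      if (as.matrix(D)[1, 2] <= cluster_cutoff) c(1L, 1L) else c(1L, 2L)
    } else {
      cutree(hclust(D, method = "single"), h = cluster_cutoff)
    }
  }
  sizes <- table(clusters)
  big <- as.integer(names(sizes)[which.max(sizes)])
  members <- which(!is.na(clusters) & clusters == big)
  rep_idx <- if (length(members) == 1L) members else {
    Fm <- do.call(rbind, lapply(runs[members], function(r)
      anchor_distance_vector(r$model)))
    Dm <- as.matrix(dist(Fm))
    tot <- rowSums(Dm)
    cand <- members[tot == min(tot)]
    cand[which.min(chi2[cand])]
  }
  structure(list(
    runs = runs, representative = rep_idx, clusters = clusters,
    summary = data.frame(run = seq_len(n_runs), chi2 = chi2,
                         outlier = !ok, cluster = clusters,
                         representative = seq_len(n_runs) == rep_idx)),
    class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d runs, largest cluster %d member(s), representative run %d (chi2 = %.3f)\n",
              nrow(x$summary), sum(x$clusters == x$clusters[x$representative],
                                   na.rm = TRUE),
              x$representative, x$summary$chi2[x$representative]))
  invisible(x)
}
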