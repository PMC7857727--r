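# Halton low-discrepancy sequence (radical inverse); deterministic fill so
# noise-free pipelines are bit-reproducible without touching the RNG stream.
radical_inverse <- function(i, b) {
  f <- 1; r <- 0
  while (i > 0) {
    f <- f / b
    r <- r + f * (i %% b)
    i <- i %/% b
  }
  r
}

halton_block <- function(from, to, bases = c(2, 3, 5)) {
  sapply(bases, function(b)
    vapply(from:to, radical_inverse, numeric(1), b = b))
}

# quasi-random fill of an axis-aligned ellipsoid with semi-axes `semi`
fill_ellipsoid <- function(n_beads, semi) {
  if (n_beads <= 0) return(matrix(numeric(0), 0, 3))
  pts <- matrix(numeric(0), 0, 3)
  idx <- 0L
  while (nrow(pts) < n_beads) {
    m <- 2L * (n_beads - nrow(pts)) + 16L
    u <- halton_block(idx + 1L, idx + m)
    idx <- idx + m
    x <- 2 * u - 1
    keep <- rowSums(x^2) <= 1
    pts <- rbind(pts, x[keep, , drop = FALSE])
  }
  sweep(pts[seq_len(n_beads), , drop = FALSE], 2, semi, "*")
}

#' Specify a synthetic "eye + arm" cyclic oligomer
#'
#' Describes a flat C_n ring of compact ellipsoidal "eye" vertices joined by
#' arms of three compact sub-clusters tracing the arc to the next vertex —
#' the coarse architecture of properdin oligomers. The binding-site vector of
#' each eye (anchors `S345` -> `A402`) lies along the eye's long axis, tilted
#' by `alpha_true` degrees from the ring normal (+z).
#'
#' @param n oligomer order, 1-8.
#' @param eye_sep neighbor eye-eye centroid distance \[Angstrom\].
#' @param alpha_true designed eye tilt \[degrees, 90-180\].
#' @param eye_extent eye diameter along its long axis \[Angstrom\], default 40.
#' @param eye_beads beads in the eye fill (default 160, roughly residue
#'   level; reduce for fast refinement tests).
#' @param arm_cluster_beads beads per arm sub-cluster (default 55; 0 drops
#'   the arms entirely, leaving bare vertices).
#' @param out_of_plane vertical bowing of the arm mid-arc \[Angstrom\].
#' @param noise_level relative noise scale passed to [simulate_profile()].
#' @param seed RNG seed for profile simulation (the geometry itself is
#'   deterministic).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, eye_sep, alpha_true, eye_extent = 40,
                           eye_beads = 160L, arm_cluster_beads = 55L,
                           out_of_plane = 0, noise_level = 0.01, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L || n > 8L) stop("n must be in 1..8")
  if (eye_sep <= eye_extent)
    stop("infeasible geometry: eye_sep must exceed eye_extent")
  if (alpha_true < 90 || alpha_true > 180)
    stop("alpha_true must lie in [90, 180] degrees")
  structure(list(n = n, eye_sep = eye_sep, alpha_true = alpha_true,
                 eye_extent = eye_extent, eye_beads = as.integer(eye_beads),
                 arm_cluster_beads = as.integer(arm_cluster_beads),
                 out_of_plane = out_of_plane, noise_level = noise_level,
                 seed = as.integer(seed)), class = "synthetic_spec")
}

#' Named presets mirroring the properdin dimer/trimer/tetramer
#'
#' `fp2`, `fp3`, `fp4`: n = 2/3/4, eye separation 165/180/195 Angstrom and
#' eye tilt 150/128/109 degrees.
#'
#' @param name one of `"fp2"`, `"fp3"`, `"fp4"`.
#' @param ... overrides passed to [synthetic_spec()] (e.g. bead counts,
#'   `noise_level`, `seed`).
#' @return A `synthetic_spec`.
#' @export
synthetic_preset <- function(name = c("fp2", "fp3", "fp4"), ...) {
  name <- match.arg(name)
  par <- switch(name,
                fp2 = list(n = 2, eye_sep = 165, alpha_true = 150),
                fp3 = list(n = 3, eye_sep = 180, alpha_true = 128),
                fp4 = list(n = 4, eye_sep = 195, alpha_true = 109))
  do.call(synthetic_spec, utils::modifyList(par, list(...)))
}

#' Build the ground-truth oligomer for a synthetic spec
#'
#' One protomer is built as rigid bodies — an eye (prolate ellipsoid,
#' semi-axes `(eye_extent/2, 0.35 eye_extent, 0.35 eye_extent)`, long axis
#' along the binding-site vector, plus deterministic axis-tip cap beads and
#' the `S345`/`A402`/`eyeN`/`eyeC` anchor beads) and three arm sub-clusters
#' (spheres of radius 9 Angstrom) placed on the arc towards the next vertex
#' at fractions 1/4, 1/2, 3/4 — then realized with C_n symmetry about z.
#' Entirely deterministic: the quasi-random fill does not consume the RNG
#' stream.
#'
#' @param spec a [synthetic_spec].
#' @return A list of class `synthetic_truth`: `model` (realized
#'   [bead_model]), `assembly` (the truth [assembly_spec], reusable as a
#'   refinement start), `spec`.
#' @export
make_oligomer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n
  a <- spec$eye_extent / 2
  bc <- 0.35 * spec$eye_extent
  r_ring <- if (n >= 2) spec$eye_sep / (2 * sin(pi / n)) else spec$eye_sep / 2
  alpha <- spec$alpha_true * pi / 180

  # eye local frame: x = binding-site vector v, y = ring-tangential, z = x cross y
  eye_local <- fill_ellipsoid(spec$eye_beads, c(a, bc, bc))
  # deterministic rim: surface ring in the tilt-sensitive x-z plane plus the
  # tangential axis tips, so the realized eye reaches its designed extent
  phi <- 2 * pi * (0:11) / 12
  caps <- rbind(cbind(a * cos(phi), 0, bc * sin(phi)),
                c(0, bc, 0), c(0, -bc, 0))
  anchor_xyz <- rbind(S345 = c(-0.6 * a, 0, 0), A402 = c(0.6 * a, 0, 0),
                      eyeN = c(0, -bc, 0), eyeC = c(0, bc, 0))
  eye_xyz <- rbind(eye_local, caps, anchor_xyz)
  eye_anchors <- setNames(nrow(eye_local) + nrow(caps) + 1:4,
                          rownames(anchor_xyz))
  eye_spec <- rigid_body_spec("eye", eye_xyz, anchors = eye_anchors)

  # truth placement of the eye at ring angle 0
  v <- c(sin(alpha), 0, cos(alpha))      # angle(v, +z) = alpha_true
  t_hat <- c(0, 1, 0)
  R_eye <- cbind(v, t_hat, c(-cos(alpha), 0, sin(alpha)))  # v x t_hat
  eye_place <- placement(R_eye, c(r_ring, 0, 0))

  bodies <- list(list(spec = eye_spec, placement = eye_place))
  if (spec$arm_cluster_beads > 0) {
    arc <- 2 * pi / n          # angle to the next vertex (full loop for n = 1)
    if (n == 1) arc <- 2 * pi
    for (j in 1:3) {
      f <- j / 4
      blob <- fill_ellipsoid(spec$arm_cluster_beads, rep(9, 3))
      blob <- rbind(blob, c(0, 0, 0))    # explicit centre bead as anchor
      b <- rigid_body_spec(paste0("arm", j), blob,
                           anchors = setNames(nrow(blob),
                                              paste0("arm", j)))
      phi <- arc * f
      centre <- c(r_ring * cos(phi), r_ring * sin(phi),
                  spec$out_of_plane * sin(pi * f))
      bodies <- c(bodies, list(list(spec = b,
                                    placement = placement(rot_z(phi),
                                                          centre))))
    }
  }
  assembly <- assembly_spec(bodies, symmetry_n = n)
  structure(list(model = apply_cn(assembly), assembly = assembly,
                 spec = spec), class = "synthetic_truth")
}

#' Connectivity restraints for a synthetic oligomer
#'
#' Chains each eye to its arm and the arm to the next protomer's eye:
#' `eyeC(k) - arm1(k) - arm2(k) - arm3(k) - eyeN(k+1)` (cyclic). Targets are
#' the designed truth distances; the flat bottom is a fraction of the target.
#'
#' @param truth a `synthetic_truth`.
#' @param tolerance_frac flat-bottom half-width as a fraction of the target
#'   (default 0.1).
#' @param k force constant (default 10).
#' @return A [restraint_set].
#' @export
synthetic_restraints <- function(truth, tolerance_frac = 0.1, k = 10) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- truth$spec$n
  if (truth$spec$arm_cluster_beads <= 0)
    stop("the spec has no arms; nothing to restrain")
  pairs <- NULL
  for (kk in seq_len(n)) {
    nxt <- if (kk == n) 1L else kk + 1L
    pairs <- rbind(pairs,
                   c(paste0("eyeC_", kk), paste0("arm1_", kk)),
                   c(paste0("arm1_", kk), paste0("arm2_", kk)),
                   c(paste0("arm2_", kk), paste0("arm3_", kk)),
                   c(paste0("arm3_", kk), paste0("eyeN_", nxt)))
  }
  m <- truth$model
  ia <- m$anchors[pairs[, 1]]; ib <- m$anchors[pairs[, 2]]
  d <- sqrt(rowSums((m$xyz[ia, , drop = FALSE] -
                       m$xyz[ib, , drop = FALSE])^2))
  restraint_set(pairs[, 1], pairs[, 2], target = d,
                tolerance = tolerance_frac * d, k = k)
}

#' Simulate a noisy SAXS profile from a bead model
#'
#' Debye intensity on a linear q grid starting at 0.005 1/Angstrom, with a
#' q-dependent Gaussian noise model mimicking beamline statistics:
#' \deqn{\sigma(q) = \nu I(0)(0.001 + 0.02 (q/q_{max})^2) + 0.01 \nu I(q)}
#' where \eqn{\nu} is `noise_level`. Intensities are perturbed by
#' `rnorm(0, sigma)`; deterministic given `seed`. With `noise_level = 0` no
#' noise is added and sigma is evaluated at a reference level of 0.01 so the
#' profile still carries positive uncertainties.
#'
#' @param model a [bead_model].
#' @param qmax top of the q grid \[1/Angstrom\] (default 0.3).
#' @param n_q number of grid points (>= 50; default 200).
#' @param noise_level relative noise scale (default 0.01).
#' @param seed RNG seed.
#' @return A [saxs_profile].
#' @export
simulate_profile <- function(model, qmax = 0.3, n_q = 200L,
                             noise_level = 0.01, seed = 1L) {
  stopifnot(qmax > 0, n_q >= 50)
  q <- seq(0.005, qmax, length.out = n_q)
  I <- debye_intensity(model, q)
  i0 <- sum(model$weight)^2
  nl <- if (noise_level > 0) noise_level else 0.01
  sig <- nl * i0 * (0.001 + 0.02 * (q / qmax)^2) + nl * 0.01 * I
  if (noise_level > 0) {
    set.seed(seed)
    I <- I + rnorm(n_q, 0, sig)
  }
  saxs_profile(q, I, sig, label = "simulated")
}
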