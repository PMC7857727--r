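# analytic fixtures used across the suite -----------------------------------

# homogeneous sphere form factor on a q grid; rel_sigma sets nominal errors
sphere_profile <- function(R, qmax = 0.3, n = 400, rel_sigma = 1e-6,
                           qmin = 0.0023) {
  q <- seq(qmin, qmax, length.out = n)
  x <- q * R
  I <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  saxs_profile(q, I, rel_sigma * I + 1e-4 * rel_sigma,
               label = sprintf("sphere R=%g", R))
}

# closed-form sphere distance distribution (unnormalized r^2 * gamma(r))
sphere_pr_oracle <- function(r, R) {
  x <- r / (2 * R)
  p <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  p[r > 2 * R] <- 0
  p
}

# two equal point scatterers separated by d
two_point_profile <- function(d = 100, qmax = 0.3, n = 400,
                              rel_sigma = 0.005) {
  q <- seq(0.0023, qmax, length.out = n)
  I <- 2 * (1 + sin(q * d) / (q * d))
  saxs_profile(q, I, rel_sigma * I + 1e-5)
}

# small, fast ground-truth oligomers (reduced bead counts)
small_truth <- function(preset = "fp3", ...) {
  make_oligomer(synthetic_preset(preset, eye_beads = 24,
                                 arm_cluster_beads = 6, ...))
}

# seeded random proper rotation
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
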