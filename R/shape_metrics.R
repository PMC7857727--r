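#' Principal axes of a bead model
#'
#' Eigendecomposition of the unweighted gyration tensor about the centroid.
#' Eigenvalues are returned ascending, so `axes[, 1]` is the smallest
#' principal axis — the thinnest direction of a flat molecule and, for planar
#' ring oligomers, the (pseudo) C_n rotation axis. Each axis sign is
#' canonicalized so its largest-magnitude component is positive; if the
#' resulting set is left-handed the largest axis is negated to restore a
#' right-handed frame.
#'
#' @param model a [bead_model] with at least 3 non-collinear beads.
#' @return A list of class `principal_axes`: `eigenvalues` (ascending,
#'   Angstrom^2), `axes` (3 x 3, columns = unit axes), `degenerate` (logical
#'   per axis).
#' @export
principal_axes <- function(model) {
  stopifnot(inherits(model, "bead_model"))
  X <- model$xyz
  if (nrow(X) < 3) stop("need at least 3 beads")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / nrow(X)
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values)            # ascending
  vals <- e$values[ord]
  axes <- e$vectors[, ord, drop = FALSE]
  for (k in 1:3) {
    j <- which.max(abs(axes[, k]))
    if (axes[j, k] < 0) axes[, k] <- -axes[, k]
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  rel <- vals / max(vals, .Machine$double.eps)
  degen <- c(rel[1] < 1e-8 || (vals[2] - vals[1]) < 0.01 * vals[2],
             (vals[2] - vals[1]) < 0.01 * vals[2] ||
               (vals[3] - vals[2]) < 0.01 * vals[3],
             (vals[3] - vals[2]) < 0.01 * vals[3])
  if (rel[2] < 1e-8)
    warning("rank-deficient bead set (collinear); principal axes degenerate")
  structure(list(eigenvalues = vals, axes = axes, degenerate = degen),
            class = "principal_axes")
}

#' Binding-site orientation angle alpha
#'
#' For each protomer, the angle between the anchor vector
#' (`anchor_from` -> `anchor_to`; the stand-in for the Ser345 -> Ala402
#' C-alpha vector lying in the plane of each eye) and the smallest principal
#' axis of the whole model. The per-protomer angles are averaged; if the mean
#' is below 90 degrees the axis is negated and the angles recomputed
#' (`flipped = TRUE`), so the mean always lies in \[90, 180\]. alpha = 180
#' means all binding sites point the same way along the ring normal; 90 means
#' they lie in the ring plane.
#'
#' @param model a realized [bead_model] (anchors carry protomer suffixes
#'   `_1`, `_2`, ...).
#' @param anchor_from,anchor_to base anchor names present in every protomer.
#' @return A list of class `alpha_result`: `per_protomer_alpha` (degrees),
#'   `mean_alpha`, `flipped`.
#' @export
alpha_angle <- function(model, anchor_from = "S345", anchor_to = "A402") {
  stopifnot(inherits(model, "bead_model"))
  prot <- sort(unique(model$protomer_id))
  ax <- principal_axes(model)
  if (ax$degenerate[1])
    warning("smallest principal axis nearly degenerate; alpha ill-defined")
  z <- ax$axes[, 1]
  ang <- vapply(prot, function(k) {
    nm_f <- anchor_name(anchor_from, k)
    nm_t <- anchor_name(anchor_to, k)
    if (is.na(model$anchors[nm_f]) || is.na(model$anchors[nm_t]))
      stop("configuration error: anchor ", nm_f, " or ", nm_t,
           " missing in protomer ", k)
    v <- model$xyz[model$anchors[[nm_t]], ] - model$xyz[model$anchors[[nm_f]], ]
    v <- v / sqrt(sum(v^2))
    acos(max(-1, min(1, sum(v * z)))) * 180 / pi
  }, numeric(1))
  flipped <- FALSE
  if (mean(ang) < 90) {
    ang <- 180 - ang
    flipped <- TRUE
  }
  structure(list(per_protomer_alpha = ang, mean_alpha = mean(ang),
                 flipped = flipped), class = "alpha_result")
}

# protomer-qualified anchor name; bare names (single-protomer models read
# from PDB) are tried as a fallback for protomer 1
anchor_name <- function(base, k) {
  paste0(base, "_", k)
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("<alpha_result> mean alpha = %.1f deg over %d protomer(s)%s\n",
              x$mean_alpha, length(x$per_protomer_alpha),
              if (x$flipped) " (axis flipped)" else ""))
  invisible(x)
}

#' Maximum intramolecular distance of a model
#'
#' @param model a [bead_model] with at least 2 beads.
#' @return The exact maximum pairwise bead distance \[Angstrom\].
#' @export
model_dmax <- function(model) {
  stopifnot(inherits(model, "bead_model"), nrow(model$xyz) >= 2)
  cpp_max_dist(model$xyz)
}

#' Direct pair distance distribution of a model
#'
#' Weight-product-weighted histogram of all pairwise distances (each
#' unordered pair counted twice), zero-padded at both ends and normalized so
#' \eqn{\int p\,dr = (\sum w)^2 - \sum w^2}. This is the direct-space oracle
#' for [ift_pr()].
#'
#' @param model a [bead_model].
#' @param bin_width histogram bin width \[Angstrom\] (default 1).
#' @return A [pair_distribution]; `i0` is the Debye \eqn{I(0) = (\sum w)^2}.
#' @export
model_pr <- function(model, bin_width = 1) {
  stopifnot(inherits(model, "bead_model"), bin_width > 0)
  h <- cpp_pair_hist(model$xyz, model$weight, bin_width)
  nb <- length(h$mass)
  r <- c((seq_len(nb) - 1) * bin_width, nb * bin_width)
  p <- c(h$mass / bin_width, 0)
  mom <- pr_moments(r, p)
  pair_distribution(r, p, dmax = h$dmax,
                    rg_real = mom$rg, i0 = sum(model$weight)^2)
}

#' Model radius of gyration
#'
#' @param model a [bead_model].
#' @return Weighted Rg \[Angstrom\].
#' @export
model_rg <- function(model) {
  w <- model$weight / sum(model$weight)
  c0 <- colSums(model$xyz * w)
  sqrt(sum(w * rowSums(sweep(model$xyz, 2, c0)^2)))
}

#' Mean neighbor eye-to-eye separation of a realized ring model
#'
#' Distance between centroids of the `eye` body in adjacent protomers
#' (protomers ordered by index, cyclically for n >= 3).
#'
#' @param model a realized [bead_model] with an `"eye"` body per protomer.
#' @param body body label of the vertex (default `"eye"`).
#' @return Mean neighbor eye-eye centroid distance \[Angstrom\].
#' @export
eye_separation <- function(model, body = "eye") {
  prot <- sort(unique(model$protomer_id))
  n <- length(prot)
  cent <- t(vapply(prot, function(k) {
    i <- model$protomer_id == k & model$body_id == body
    if (!any(i)) stop("no '", body, "' beads in protomer ", k)
    colMeans(model$xyz[i, , drop = FALSE])
  }, numeric(3)))
  if (n < 2) stop("need at least 2 protomers")
  pairs <- if (n == 2) cbind(1, 2) else cbind(1:n, c(2:n, 1))
  mean(sqrt(rowSums((cent[pairs[, 1], , drop = FALSE] -
                       cent[pairs[, 2], , drop = FALSE])^2)))
}
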