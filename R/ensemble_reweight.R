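#' Construct a conformational ensemble of calculated SAXS curves
#'
#' @param member_intensities M x Nq matrix: one calculated curve per ensemble
#'   member, on the experimental q grid.
#' @param prior_weights length-M prior (default uniform); normalized to sum 1.
#' @param labels member labels.
#' @return An object of class `saxs_ensemble`.
#' @export
saxs_ensemble <- function(member_intensities, prior_weights = NULL,
                          labels = NULL) {
  X <- as.matrix(member_intensities)
  m <- nrow(X)
  if (m < 2) stop("an ensemble needs at least 2 members")
  if (is.null(prior_weights)) prior_weights <- rep(1 / m, m)
  prior_weights <- as.numeric(prior_weights)
  if (length(prior_weights) != m || any(prior_weights < 0))
    stop("prior weights must be non-negative, one per member")
  prior_weights <- prior_weights / sum(prior_weights)
  if (is.null(labels)) labels <- paste0("member_", seq_len(m))
  structure(list(member_intensities = X, prior_weights = prior_weights,
                 labels = labels), class = "saxs_ensemble")
}

#' Bayesian maximum entropy reweighting of an ensemble
#'
#' Minimally perturbs the ensemble weights away from the prior to improve
#' agreement with an experimental profile, minimizing
#' \deqn{\chi^2(w)/2 - \theta S_{rel}(w), \quad
#'   S_{rel}(w) = -\sum_i w_i \ln(w_i/w_i^0)}
#' solved in the dual: \eqn{w_i \propto w_i^0 \exp(-\sum_q \lambda_q I_i(q))}
#' with the multipliers \eqn{\lambda} found by gradient-based minimization of
#' the convex dual function. A free scale factor (and optional constant) for
#' the ensemble-average curve is refit between dual solves, since calculated
#' and experimental curves are on different scales. chi2 uses the n_points
#' divisor (the common BME convention).
#'
#' @param ensemble a [saxs_ensemble] with curves on the experimental grid.
#' @param profile a [saxs_profile].
#' @param theta_reg regularization parameter theta > 0; large values pin the
#'   prior, small values chase the data.
#' @param fit_constant also fit an additive constant? Default `FALSE`.
#' @param max_outer maximum scale-refit iterations.
#' @param lambda_init optional starting multipliers (length Nq); defaults to
#'   zero. [scan_theta()] uses this to warm-start each theta from the
#'   previous solution, which keeps the L-curve numerically monotone.
#' @param weights_init optional starting weights matching `lambda_init`, so
#'   the first scale refit is consistent with the warm start.
#' @return A list of class `bme_result`: `weights`, `chi2`, `s_rel` (<= 0),
#'   `phi_eff` = exp(s_rel), `theta_reg`, `scale`, `constant`, `converged`.
#' @export
bme_reweight <- function(ensemble, profile, theta_reg,
                         fit_constant = FALSE, max_outer = 30L,
                         lambda_init = NULL, weights_init = NULL) {
  stopifnot(inherits(ensemble, "saxs_ensemble"), theta_reg > 0)
  validate_profile(profile)
  X0 <- ensemble$member_intensities
  if (ncol(X0) != length(profile$q))
    stop("ensemble curves are not on the experimental q grid")
  w0 <- ensemble$prior_weights
  y <- profile$intensity; s <- profile$sigma
  nq <- length(y)
  # internal normalization for conditioning; undone through the free scale
  u <- max(abs(y))
  y <- y / u; s <- s / u

  w <- if (is.null(weights_init)) w0 else as.numeric(weights_init)
  scale <- 1; constant <- 0
  converged <- FALSE
  lam <- if (is.null(lambda_init)) rep(0, nq) else as.numeric(lambda_init)
  s2 <- nq * s^2             # chi2 uses the nq divisor
  chi2_of <- function(w, scale, constant) {
    avg <- as.numeric(crossprod(X0, w)) * scale / u + constant
    sum(((avg - y) / s)^2) / nq
  }
  primal <- function(w, scale, constant)
    chi2_of(w, scale, constant) / 2 +
      theta_reg * sum(w[w > 0] * log(w[w > 0] / w0[w > 0]))
  best <- list(val = primal(w0, 1, 0), w = w0, scale = 1, constant = 0)
  for (outer in seq_len(max_outer)) {
    # 1) refit scale (+ constant) of the current weighted average
    avg0 <- as.numeric(crossprod(X0, w)) / u
    Xd <- if (fit_constant) cbind(avg0 / s, 1 / s) else cbind(avg0 / s)
    beta <- qr.coef(qr(Xd), y / s)
    scale <- beta[1]; constant <- if (fit_constant) beta[2] else 0
    Xs <- (scale * X0 / u + constant)    # M x Nq scaled member curves
    # 2) convex dual in the theta-scaled multipliers:
    # w_i propto w0_i exp(-(Xs lam)_i); objective G = logZ + lam.y +
    # (theta/2) lam^2 s2 is well conditioned across the whole theta range
    dual <- function(lam) {
      ex <- -as.numeric(Xs %*% lam)
      mx <- max(ex)
      # keep the primal-best point ever visited: at small theta the dual is
      # nearly flat (or unbounded along unfittable directions) and the
      # optimizer can overshoot past the useful region
      wl <- w0 * exp(ex - mx); wl <- wl / sum(wl)
      pv <- primal(wl, scale, constant)
      if (pv < best$val)
        best <<- list(val = pv, w = wl, scale = scale, constant = constant)
      log(sum(w0 * exp(ex - mx))) + mx + sum(lam * y) +
        0.5 * theta_reg * sum(lam^2 * s2)
    }
    grad <- function(lam) {
      ex <- -as.numeric(Xs %*% lam)
      ex <- ex - max(ex)
      wl <- w0 * exp(ex); wl <- wl / sum(wl)
      -as.numeric(crossprod(Xs, wl)) + y + theta_reg * lam * s2
    }
    opt <- optim(lam, dual, grad, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-15))
    lam <- opt$par
    ex <- -as.numeric(Xs %*% lam)
    ex <- ex - max(ex)
    w_new <- w0 * exp(ex); w_new <- w_new / sum(w_new)
    gnorm <- sqrt(sum(grad(lam)^2)) / max(1, sqrt(sum(y^2)))
    moved <- max(abs(w_new - w))
    w <- w_new
    pv <- primal(w, scale, constant)
    if (pv < best$val)
      best <- list(val = pv, w = w, scale = scale, constant = constant)
    if (moved < 1e-10 && gnorm < 1e-6) { converged <- TRUE; break }
  }
  w <- best$w; scale <- best$scale; constant <- best$constant
  s_rel <- -sum(w[w > 0] * log(w[w > 0] / w0[w > 0]))
  out <- structure(list(weights = w, chi2 = chi2_of(w, scale, constant),
                        s_rel = s_rel,
                        phi_eff = exp(s_rel), theta_reg = theta_reg,
                        scale = scale, constant = constant * u,
                        converged = converged), class = "bme_result")
  attr(out, "lambda") <- lam
  out
}

#' @export
print.bme_result <- function(x, ...) {
  cat(sprintf("<bme_result> theta = %.3g: chi2 = %.3f, phi_eff = %.3f%s\n",
              x$theta_reg, x$chi2, x$phi_eff,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Scan the BME regularization parameter
#'
#' One [bme_reweight()] per theta on a decreasing grid, emitting the L-curve
#' of chi2 against the effective fraction of frames phi_eff. The elbow
#' (maximum discrete curvature of chi2 vs phi_eff) is flagged as the
#' suggested choice.
#'
#' @param ensemble a [saxs_ensemble].
#' @param profile a [saxs_profile].
#' @param theta_grid positive, decreasing theta values.
#' @param ... passed to [bme_reweight()].
#' @return A data.frame (theta_reg, chi2, phi_eff, s_rel, elbow) with the
#'   per-theta `bme_result`s attached as attribute `results`.
#' @export
scan_theta <- function(ensemble, profile, theta_grid, ...) {
  theta_grid <- as.numeric(theta_grid)
  if (any(theta_grid <= 0)) stop("theta grid must be positive")
  if (is.unsorted(rev(theta_grid), strictly = FALSE) && length(theta_grid) > 1)
    stop("theta grid must be decreasing")
  res <- vector("list", length(theta_grid))
  lam <- NULL
  for (i in seq_along(theta_grid)) {
    res[[i]] <- bme_reweight(ensemble, profile, theta_reg = theta_grid[i],
                             lambda_init = lam,
                             weights_init = if (i > 1) res[[i - 1]]$weights,
                             ...)
    lam <- attr(res[[i]], "lambda")
  }
  chi2 <- vapply(res, `[[`, numeric(1), "chi2")
  phi <- vapply(res, `[[`, numeric(1), "phi_eff")
  srel <- vapply(res, `[[`, numeric(1), "s_rel")
  m <- length(theta_grid)
  elbow <- rep(FALSE, m)
  if (m == 1L) {
    elbow[1] <- TRUE
  } else if (m == 2L) {
    elbow[which.max(chi2 - min(chi2))] <- TRUE
  } else {
    # curvature of the (phi_eff, chi2) polyline
    kappa <- rep(NA_real_, m)
    for (i in 2:(m - 1)) {
      x1 <- phi[i] - phi[i - 1]; y1 <- chi2[i] - chi2[i - 1]
      x2 <- phi[i + 1] - phi[i]; y2 <- chi2[i + 1] - chi2[i]
      cross <- x1 * y2 - y1 * x2
      denom <- sqrt((x1^2 + y1^2) * (x2^2 + y2^2) *
                      ((x1 + x2)^2 + (y1 + y2)^2))
      kappa[i] <- if (denom > 0) abs(cross) / denom else 0
    }
    elbow[which.max(kappa)] <- TRUE
  }
  out <- data.frame(theta_reg = theta_grid, chi2 = chi2, phi_eff = phi,
                    s_rel = srel, elbow = elbow)
  attr(out, "results") <- res
  out
}
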