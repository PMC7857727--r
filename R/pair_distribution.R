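#' Construct a pair distance distribution object
#'
#' @param r equally spaced distance grid from 0 to `dmax` \[Angstrom\].
#' @param p p(r) values on `r`.
#' @param dmax maximum intramolecular distance \[Angstrom\].
#' @param rg_real real-space radius of gyration from p(r) moments.
#' @param i0 forward scattering from the p(r) zeroth moment.
#' @param reg_alpha regularization weight used (NA for direct model p(r)).
#' @param chi2 fit quality of the regularized curve against the data, if any.
#' @return An object of class `pair_distribution`.
#' @export
pair_distribution <- function(r, p, dmax, rg_real = NA_real_, i0 = NA_real_,
                              reg_alpha = NA_real_, chi2 = NA_real_) {
  r <- as.numeric(r); p <- as.numeric(p)
  stopifnot(length(r) == length(p), length(r) >= 3)
  dr <- diff(r)
  if (max(abs(dr - dr[1])) > 1e-6 * dr[1] + 1e-12)
    stop("r grid must be equally spaced")
  if (min(p) < -0.01 * max(p) - 1e-12)
    warning("p(r) has negative excursions beyond the 1% ripple tolerance")
  structure(list(r = r, p = p, dmax = dmax, rg_real = rg_real, i0 = i0,
                 reg_alpha = reg_alpha, chi2 = chi2),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair_distribution> dmax = %.1f A, Rg = %.2f A, I0 = %.4g (%d r bins)\n",
              x$dmax, x$rg_real, x$i0, length(x$r)))
  invisible(x)
}

# Moments of p(r): I0 (zeroth, with the 4*pi transform convention) and the
# real-space Rg, Rg^2 = integral(r^2 p) / (2 integral(p)).
pr_moments <- function(r, p) {
  dr <- r[2] - r[1]
  m0 <- sum(p) * dr
  m2 <- sum(r^2 * p) * dr
  list(i0 = 4 * pi * m0, rg = sqrt(max(m2 / (2 * m0), 0)))
}

#' Indirect Fourier transformation to p(r)
#'
#' Solves the linear inverse problem
#' \deqn{I(q) = 4\pi \int_0^{D_{max}} p(r) \frac{\sin(qr)}{qr} dr}
#' by expanding p(r) on `n_r` equally spaced histogram bins with a
#' second-derivative (Tikhonov) smoothness penalty of weight `reg_alpha`,
#' endpoints pinned to zero, and data weighted by \eqn{1/\sigma^2}. When
#' `reg_alpha = "auto"` the weight is chosen by generalized cross-validation
#' over a log-spaced grid.
#'
#' @param profile a [saxs_profile].
#' @param dmax assumed maximum distance \[Angstrom\].
#' @param n_r number of r grid points including the pinned endpoints.
#' @param reg_alpha numeric smoothness weight, or `"auto"` (GCV).
#' @param qmax use only data with `q <= qmax` (default 0.27 1/Angstrom).
#' @return A [pair_distribution] with `rg_real`, `i0` and the data-fit `chi2`;
#'   the regularized fit is attached as attribute `fit` (q, i_fit).
#' @export
ift_pr <- function(profile, dmax, n_r = 101L, reg_alpha = "auto",
                   qmax = 0.27) {
  validate_profile(profile)
  if (dmax <= 0) stop("dmax must be positive")
  keep <- profile$q <= qmax
  q <- profile$q[keep]; I <- profile$intensity[keep]; s <- profile$sigma[keep]
  nq <- length(q)
  if (nq < 10) stop("too few data points below qmax for IFT")
  if (dmax < pi / max(q) )
    warning("dmax below the resolution support pi/q_max; result ill-posed")
  if (pi / q[1] < dmax)
    warning(sprintf(
      "q_min too high to support dmax = %.0f A (pi/q_min = %.0f A)",
      dmax, pi / q[1]))

  r <- seq(0, dmax, length.out = n_r)
  dr <- r[2] - r[1]
  # kernel on interior bins (endpoints pinned to zero)
  ri <- r[2:(n_r - 1L)]
  Qr <- outer(q, ri)
  K <- 4 * pi * dr * sin(Qr) / Qr          # q > 0 so Qr > 0
  Wh <- 1 / s                              # sqrt of the weight
  A <- K * Wh                              # weighted design
  y <- I * Wh
  # second-difference operator on the full grid incl. pinned zeros
  ni <- n_r - 2L
  L <- matrix(0, ni, ni)
  for (i in seq_len(ni)) {
    L[i, i] <- -2
    if (i > 1) L[i, i - 1] <- 1
    if (i < ni) L[i, i + 1] <- 1
  }
  AtA <- crossprod(A); Aty <- crossprod(A, y); LtL <- crossprod(L)
  base <- sum(diag(AtA)) / sum(diag(LtL))  # dimensionally neutral alpha unit

  solve_alpha <- function(alpha) {
    M <- AtA + alpha * LtL
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch))
      stop("numerical error: singular IFT system; raise reg_alpha")
    p <- backsolve(ch, forwardsolve(t(ch), Aty))
    fitted <- as.numeric(A %*% p)
    rss <- sum((y - fitted)^2)
    # effective dof: trace of the hat matrix
    Minv_At <- backsolve(ch, forwardsolve(t(ch), t(A)))
    edf <- sum(A * t(Minv_At))
    list(p = as.numeric(p), rss = rss, edf = edf, fitted = fitted)
  }

  if (identical(reg_alpha, "auto")) {
    alphas <- base * 10^seq(-6, 4, by = 0.5)
    gcv <- vapply(alphas, function(a) {
      sol <- solve_alpha(a)
      nq * sol$rss / (nq - sol$edf)^2
    }, numeric(1))
    reg_alpha <- alphas[which.min(gcv)]
  }
  sol <- solve_alpha(reg_alpha)
  p_full <- c(0, sol$p, 0)
  mom <- pr_moments(r, p_full)
  out <- pair_distribution(r, p_full, dmax = dmax, rg_real = mom$rg,
                           i0 = mom$i0, reg_alpha = reg_alpha,
                           chi2 = sol$rss / (nq - sol$edf))
  attr(out, "fit") <- list(q = q, i_exp = I, sigma = s,
                           i_fit = sol$fitted / Wh)
  out
}

#' Scan candidate D_max values
#'
#' Runs [ift_pr()] for each grid value and selects the smallest `dmax` whose
#' data-fit chi2 is on the plateau — within `max(0.05, 2 sqrt(2/n) chi2_min)`
#' of the minimum, the second term being twice the statistical spread of a
#' reduced chi2 with n fitted points (extra `dmax` freedom always absorbs a
#' little noise, so the raw minimum overshoots) — and whose p(r) decays
#' cleanly at the tail. A `dmax`
#' below the true maximum distance forces the distance mass against the
#' pinned endpoint — a pile-up or negative dip in the last bins — so the tail
#' is flagged clean only when |p| over the last three interior bins stays
#' below 5% of max p.
#'
#' @param profile a [saxs_profile].
#' @param dmax_grid increasing vector of candidate D_max \[Angstrom\], >= 1
#'   value (a single value is trivially selected).
#' @param ... passed to [ift_pr()].
#' @return A data.frame (dmax, chi2, smoothness, tail_ok, selected) with the
#'   chosen `pair_distribution` attached as attribute `pr`.
#' @export
scan_dmax <- function(profile, dmax_grid, ...) {
  dmax_grid <- sort(as.numeric(dmax_grid))
  prs <- lapply(dmax_grid, function(d)
    suppressWarnings(ift_pr(profile, dmax = d, ...)))
  chi2 <- vapply(prs, function(x) x$chi2, numeric(1))
  smooth <- vapply(prs, function(x) sum(diff(x$p, differences = 2)^2),
                   numeric(1))
  tail_ok <- vapply(prs, function(x) {
    n <- length(x$p)
    max(abs(x$p[(n - 3):(n - 1)])) <= 0.05 * max(x$p)
  }, logical(1))
  sel <- rep(FALSE, length(dmax_grid))
  nq <- length(attr(prs[[1]], "fit")$q)
  slack <- max(0.05, 2 * sqrt(2 / nq) * min(chi2))
  cand <- which(chi2 <= min(chi2) + slack & tail_ok)
  if (length(cand)) {
    sel[cand[1]] <- TRUE
  } else {
    warning("no chi2 plateau with a clean tail found; no dmax selected")
  }
  out <- data.frame(dmax = dmax_grid, chi2 = chi2, smoothness = smooth,
                    tail_ok = tail_ok, selected = sel)
  if (any(sel)) attr(out, "pr") <- prs[[which(sel)]]
  out
}

#' Detect peaks (and optionally shoulders) in a p(r) curve
#'
#' Local maxima with prominence at least `min_prominence` of max(p) are
#' reported as peaks; positions are refined by quadratic interpolation of the
#' three points around each maximum. Shoulders (inflection plateaus: a zero
#' crossing of the second derivative without a sign change of the first) are
#' reported when `shoulders = TRUE`.
#'
#' @param pr a [pair_distribution].
#' @param min_prominence prominence threshold as a fraction of max(p)
#'   (default 0.02).
#' @param shoulders also report shoulders? Default `FALSE`.
#' @return A data.frame (position, height, kind) ordered by position.
#' @export
find_peaks <- function(pr, min_prominence = 0.02, shoulders = FALSE) {
  stopifnot(inherits(pr, "pair_distribution"))
  r <- pr$r; p <- pr$p
  n <- length(p)
  pmax <- max(p)
  if (pmax <= 0) return(data.frame(position = numeric(0), height = numeric(0),
                                   kind = character(0)))
  is_max <- which(vapply(2:(n - 1), function(i)
    p[i] > p[i - 1] && p[i] >= p[i + 1], logical(1))) + 1L
  # prominence = height - max(left base, right base), bases being the lowest
  # points between the peak and the nearest higher ground on each side

  prominence <- vapply(is_max, function(i) {
    left <- p[1:i]
    hi_l <- which(left > p[i])
    base_l <- min(left[if (length(hi_l)) max(hi_l):i else 1:i])
    right <- p[i:n]
    hi_r <- which(right > p[i])
    base_r <- min(right[1:if (length(hi_r)) hi_r[1] else length(right)])
    p[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- is_max[prominence >= min_prominence * pmax]
  refine <- function(i) {
    # quadratic through (i-1, i, i+1)
    y1 <- p[i - 1]; y2 <- p[i]; y3 <- p[i + 1]
    denom <- y1 - 2 * y2 + y3
    off <- if (abs(denom) < 1e-300) 0 else 0.5 * (y1 - y3) / denom
    off <- max(min(off, 0.5), -0.5)
    c(pos = r[i] + off * (r[2] - r[1]),
      h = y2 - 0.25 * (y1 - y3) * off)
  }
  pk <- t(vapply(keep, refine, numeric(2)))
  out <- data.frame(position = if (length(keep)) pk[, 1] else numeric(0),
                    height = if (length(keep)) pk[, 2] else numeric(0),
                    kind = rep("peak", length(keep)))
  if (shoulders) {
    d1 <- diff(p); d2 <- diff(p, differences = 2)
    sh <- integer(0)
    for (i in 2:(length(d2) - 1)) {
      if (sign(d2[i]) != sign(d2[i + 1]) && d2[i] != 0 &&
          sign(d1[i]) == sign(d1[i + 1]) && d1[i] != 0) {
        j <- i + 1L  # grid index of the inflection
        if (!any(abs(r[j] - out$position) < 3 * (r[2] - r[1])))
          sh <- c(sh, j)
      }
    }
    if (length(sh))
      out <- rbind(out, data.frame(position = r[sh], height = p[sh],
                                   kind = "shoulder"))
  }
  out <- out[out$height > 0, , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}

#' Write a p(r) result as two-block text (GNOM-style)
#'
#' First block: the data and regularized fit (q, I_exp, sigma, I_fit), when
#' available; second block: r, p(r).
#'
#' @param pr a [pair_distribution].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pr <- function(pr, path) {
  con <- file(path, "w"); on.exit(close(con))
  fit <- attr(pr, "fit")
  writeLines(sprintf("# ringfit p(r): dmax = %.2f A, Rg = %.3f A, I0 = %.6g",
                     pr$dmax, pr$rg_real, pr$i0), con)
  if (!is.null(fit)) {
    writeLines("# q I_exp sigma I_fit", con)
    writeLines(sprintf("%.6e %.6e %.6e %.6e", fit$q, fit$i_exp, fit$sigma,
                       fit$i_fit), con)
    writeLines("", con)
  }
  writeLines("# r p(r)", con)
  writeLines(sprintf("%.4f %.8e", pr$r, pr$p), con)
  invisible(path)
}
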