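#' Construct a 1D SAXS scattering profile
#'
#' The basic container of the package: a momentum-transfer grid `q`
#' (\eqn{q = 4\pi\sin\theta/\lambda}, in inverse Angstrom), intensities and
#' per-point 1-sigma uncertainties.
#'
#' @param q numeric vector, strictly increasing, all > 0 \[1/Angstrom\].
#' @param intensity numeric vector, same length as `q`.
#' @param sigma numeric vector of positive 1-sigma uncertainties.
#' @param label character tag carried through the pipeline.
#' @param absolute_scale logical metadata flag; `TRUE` when the curve is on an
#'   absolute cm^-1 scale. Pass-through only: all fits in the package include
#'   a free scale factor, so no unit conversion is performed.
#' @return An object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma, label = "",
                         absolute_scale = FALSE) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  sigma <- as.numeric(sigma)
  obj <- structure(
    list(q = q, intensity = intensity, sigma = sigma,
         label = as.character(label)[1],
         absolute_scale = isTRUE(absolute_scale)),
    class = "saxs_profile")
  validate_profile(obj)
  obj
}

#' Validate a scattering profile's invariants
#'
#' @param profile a `saxs_profile`.
#' @return The profile, invisibly; errors describe the first violation.
#' @export
validate_profile <- function(profile) {
  stopifnot(inherits(profile, "saxs_profile"))
  q <- profile$q
  n <- length(q)
  if (n < 5L)
    stop("profile must contain at least 5 points, got ", n)
  if (length(profile$intensity) != n || length(profile$sigma) != n)
    stop("q, intensity and sigma must have equal length")
  if (!all(is.finite(q)) || !all(is.finite(profile$intensity)) ||
      !all(is.finite(profile$sigma)))
    stop("profile contains non-finite values")
  if (any(q <= 0))
    stop("q must be positive; first offending index: ", which(q <= 0)[1])
  dq <- diff(q)
  if (any(dq <= 0))
    stop("q must be strictly increasing; first offending index: ",
         which(dq <= 0)[1] + 1L)
  if (any(profile$sigma <= 0))
    stop("sigma must be positive; first offending index: ",
         which(profile$sigma <= 0)[1])
  invisible(profile)
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %s: %d points, q in [%.4g, %.4g] 1/A%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), min(x$q), max(x$q),
              if (x$absolute_scale) ", absolute scale" else ""))
  invisible(x)
}

#' Read a 3-column ASCII SAXS profile
#'
#' Parses the standard whitespace-delimited `q I sigma` format (ATSAS-style
#' `.dat`). Lines starting with `#` and lines whose first three fields do not
#' parse as numbers are skipped as headers/comments. Rows with `sigma <= 0`
#' are dropped with a warning, mirroring common beamline output quirks.
#'
#' @param path file path.
#' @param format dialect tag; currently only `"dat"` (3-column ASCII).
#' @param label profile label; defaults to the file name.
#' @return A validated [saxs_profile].
#' @export
read_profile <- function(path, format = "dat", label = basename(path)) {
  format <- match.arg(format, "dat")
  if (!file.exists(path)) stop("cannot read profile: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, function(ln) {
    ln <- sub("#.*$", "", ln)
    f <- strsplit(trimws(ln), "[ \t,;]+")[[1]]
    if (length(f) < 3) return(NULL)
    v <- suppressWarnings(as.numeric(f[1:3]))
    if (any(is.na(v))) return(NULL)
    v
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) < 5L)
    stop("format error: fewer than 5 parseable data rows in ", path)
  bad <- rows[, 3] <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with sigma <= 0 dropped from ", basename(path))
    rows <- rows[!bad, , drop = FALSE]
  }
  if (nrow(rows) < 5L)
    stop("format error: fewer than 5 valid rows after sigma filtering in ",
         path)
  saxs_profile(rows[, 1], rows[, 2], rows[, 3], label = label)
}

#' Write a profile as 3-column ASCII
#'
#' @param profile a [saxs_profile].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  hdr <- sprintf("# ringfit profile '%s' (%d points)%s", profile$label,
                 length(profile$q),
                 if (profile$absolute_scale) " [absolute scale, cm^-1]" else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.8e %.8e %.8e", profile$q, profile$intensity,
                     profile$sigma), con)
  invisible(path)
}

#' Logarithmic rebinning of a profile
#'
#' Compresses an oversampled curve onto logarithmically spaced q bins (the
#' usual ~800 -> ~180 point reduction applied to synchrotron data, which
#' equalizes statistics across decades of q). Within each bin the intensity
#' is the inverse-variance-weighted mean, the combined uncertainty is
#' \eqn{1/\sqrt{\sum \sigma_i^{-2}}} and q is the same weighted mean of the
#' member q values. Empty bins are omitted.
#'
#' @param profile a [saxs_profile].
#' @param n_bins target number of bins (>= 2). If `n_bins >=` the number of
#'   points the input is returned unchanged.
#' @return A rebinned [saxs_profile].
#' @export
rebin_log <- function(profile, n_bins = 180L) {
  validate_profile(profile)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  n <- length(profile$q)
  if (n_bins >= n) return(profile)
  edges <- exp(seq(log(profile$q[1]), log(profile$q[n]), length.out = n_bins + 1L))
  idx <- findInterval(profile$q, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  wt <- 1 / profile$sigma^2
  sw  <- tapply(wt, idx, sum)
  qb  <- tapply(wt * profile$q, idx, sum) / sw
  ib  <- tapply(wt * profile$intensity, idx, sum) / sw
  sb  <- 1 / sqrt(sw)
  ord <- order(qb)
  saxs_profile(qb[ord], ib[ord], sb[ord], label = profile$label,
               absolute_scale = profile$absolute_scale)
}

#' Guinier analysis of the low-q region
#'
#' Weighted linear fit of \eqn{\ln I} against \eqn{q^2} over the largest
#' low-q window satisfying \eqn{q \cdot R_g \le} `qrg_limit`, found by
#' iterating the window to self-consistency in Rg. Returns
#' \eqn{R_g = \sqrt{-3 \cdot slope}} and \eqn{I_0 = e^{intercept}}, plus a
#' flag for systematic positive low-q residuals, the classic signature of
#' aggregation.
#'
#' After the window converges, it is shrunk further while the reduced chi2 of
#' the linear fit exceeds `chi2_max`: the Guinier law is only quadratic to
#' O((qRg)^4), and for data whose uncertainties are small compared to that
#' truncation error a full qRg <= 1.3 window biases Rg upward by 1-2%.
#' Shrinking until the fit is adequate relative to the stated sigmas removes
#' the bias on precise data while leaving noisy data fitted over the whole
#' conventional window.
#'
#' @param profile a [saxs_profile].
#' @param qrg_limit upper limit on q*Rg for the fitted window (default 1.3,
#'   the standard compact-particle convention).
#' @param min_points minimum number of points required in the window.
#' @param chi2_max adequacy threshold for the linear fit (default 2).
#' @return A list of class `guinier_result` with elements `rg`, `i0`,
#'   `q_min`, `q_max`, `n_points`, `aggregation_flag`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 5L,
                        chi2_max = 2) {
  validate_profile(profile)
  keep <- profile$intensity > 0
  q <- profile$q[keep]; I <- profile$intensity[keep]
  s <- profile$sigma[keep]
  if (length(q) < min_points) stop("range error: too few positive-I points")
  x <- q^2; y <- log(I); w <- (I / s)^2  # sigma_lnI = sigma/I

  fit_window <- function(m) {
    xm <- x[1:m]; ym <- y[1:m]; wm <- w[1:m]
    sw <- sum(wm); mx <- sum(wm * xm) / sw; my <- sum(wm * ym) / sw
    sxx <- sum(wm * (xm - mx)^2)
    if (sxx <= 0) return(NULL)
    b <- sum(wm * (xm - mx) * (ym - my)) / sxx
    list(slope = b, intercept = my - b * mx)
  }

  m <- length(q)   # start from the full curve; the window iterates downward
  rg <- NA_real_
  for (it in 1:50) {
    f <- fit_window(m)
    if (is.null(f) || f$slope >= 0)
      stop("degenerate fit: non-positive Guinier slope (flat or rising curve)")
    rg_new <- sqrt(-3 * f$slope)
    m_new <- max(min_points, findInterval(qrg_limit / rg_new, q))
    m_new <- min(m_new, length(q))
    done <- !is.na(rg) && abs(rg_new - rg) < 1e-3 && m_new == m
    rg <- rg_new
    if (done) break
    m <- m_new
  }
  if (m < min_points) stop("range error: fewer than ", min_points,
                           " points in the Guinier window")
  # adequacy shrinkage: retreat while the quadratic law is violated
  # relative to the stated uncertainties
  chi2_lin <- function(m, f) {
    r <- (y[1:m] - (f$intercept + f$slope * x[1:m])) * sqrt(w[1:m])
    sum(r^2) / (m - 2)
  }
  f <- fit_window(m)
  while (m > min_points && chi2_lin(m, f) > chi2_max) {
    m <- m - 1L
    f <- fit_window(m)
    if (is.null(f) || f$slope >= 0)
      stop("degenerate fit: non-positive Guinier slope")
  }
  rg <- sqrt(-3 * f$slope)
  resid_std <- (y[1:m] - (f$intercept + f$slope * x[1:m])) * sqrt(w[1:m])
  nlow <- min(5L, m)
  structure(list(
    rg = rg, i0 = exp(f$intercept), q_min = q[1], q_max = q[m],
    n_points = m, aggregation_flag = mean(resid_std[1:nlow]) > 1,
    qrg_limit = qrg_limit), class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "<guinier_result> Rg = %.2f A, I0 = %.4g, %d pts (q %.4g..%.4g, qRg <= %.2f)%s\n",
    x$rg, x$i0, x$n_points, x$q_min, x$q_max, x$qrg_limit,
    if (x$aggregation_flag) " [aggregation suspected]" else ""))
  invisible(x)
}
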