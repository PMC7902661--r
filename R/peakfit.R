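#' Define a spectral fit window
#'
#' A wavenumber window over which a sum of Gaussians plus a local linear
#' baseline is least-squares fitted. Fitted centers are allowed to drift at
#' most `centerTolerance` from their initial guesses.
#'
#' @param lo,hi window bounds, cm-1 (`lo < hi`).
#' @param peaks data.frame of initial guesses with columns `center`, `width`,
#'   `amplitude`; every center must lie inside `(lo, hi)`.
#' @param centerTolerance allowed center drift, cm-1 (default 5, larger than
#'   the ~3 cm-1 spectral resolution but below typical band separations).
#' @return A `fitWindowSpec` (named list).
#' @export
fitWindowSpec <- function(lo, hi, peaks, centerTolerance = 5) {
  stopifnot(lo < hi, is.data.frame(peaks),
            all(c("center", "width", "amplitude") %in% names(peaks)),
            all(peaks$center > lo & peaks$center < hi),
            centerTolerance > 0)
  structure(list(lo = lo, hi = hi, peaks = peaks,
                 centerTolerance = centerTolerance),
            class = "fitWindowSpec")
}

#' Default fingerprint-region fit windows
#'
#' Groups the eleven default bands into seven windows so that overlapping
#' neighbours (932/971/999, 1060/1085, 1445/1473) are fitted jointly while
#' isolated bands get their own local baseline.
#'
#' @param bands band table as from [fingerprintBands()]; initial amplitudes
#'   are taken from it but only seed the optimiser.
#' @param centerTolerance allowed center drift, cm-1.
#' @return list of [fitWindowSpec()] objects.
#' @export
defaultFitWindows <- function(bands = fingerprintBands(), centerTolerance = 5) {
  ranges <- list(c(605, 675), c(745, 815), c(895, 1032), c(1028, 1130),
                 c(1405, 1515), c(1535, 1612), c(1612, 1700))
  out <- list()
  for (rg in ranges) {
    pk <- bands[bands$center > rg[1] & bands$center < rg[2], , drop = FALSE]
    if (nrow(pk))
      out[[length(out) + 1L]] <- fitWindowSpec(rg[1], rg[2], pk,
                                               centerTolerance)
  }
  out
}

# Sum-of-Gaussians + local linear baseline model over a window.
# p = (A_1..A_k, c_1..c_k, s_1..s_k, b0, b1); baseline is b0 + b1*(x - lo).
peakModel <- function(p, x, k, lo) {
  y <- p[3 * k + 1] + p[3 * k + 2] * (x - lo)
  for (i in seq_len(k))
    y <- y + p[i] * exp(-(x - p[k + i])^2 / (2 * p[2 * k + i]^2))
  y
}

# analytic Jacobian of peakModel; rows = x, cols = parameters
peakJacobian <- function(p, x, k, lo) {
  J <- matrix(0, length(x), 3L * k + 2L)
  for (i in seq_len(k)) {
    A <- p[i]; ctr <- p[k + i]; s <- p[2 * k + i]
    g <- exp(-(x - ctr)^2 / (2 * s^2))
    J[, i] <- g
    J[, k + i] <- A * g * (x - ctr) / s^2
    J[, 2 * k + i] <- A * g * (x - ctr)^2 / s^3
  }
  J[, 3 * k + 1] <- 1
  J[, 3 * k + 2] <- x - lo
  J
}

#' Fit Gaussian peaks in a window
#'
#' Bounded Levenberg-Marquardt least squares of a sum of Gaussians plus a
#' local linear baseline within `[lo, hi]`. For an [AverageSpectrum-class]
#' input the per-channel SE values act as inverse-variance fit weights and
#' the amplitude uncertainty is the known-variance covariance
#' `(J'WJ)^-1`, so the channel SE envelope propagates into `intensity_se`.
#' For a plain [RamanSpectrum-class] the covariance is scaled by the residual
#' variance in the usual way.
#'
#' Results are never silently dropped: fits that do not converge, hit a
#' parameter bound (amplitudes are bounded below at 0), or collapse two
#' centers to within 2 cm-1 are returned flagged.
#'
#' @param s a [RamanSpectrum-class] or [AverageSpectrum-class].
#' @param window a [fitWindowSpec()].
#' @return data.frame, one row per peak: `band` (initial center label),
#'   `center`, `sigma`, `intensity`, `intensity_se`, `converged`,
#'   `degenerate`, `window_lo`, `window_hi`.
#' @export
fitWindow <- function(s, window) {
  stopifnot(inherits(window, "fitWindowSpec"))
  if (is(s, "AverageSpectrum")) {
    w <- s@wavenumbers; y <- s@mean; se <- s@se
  } else {
    stopifnot(is(s, "RamanSpectrum"))
    w <- wavenumbers(s); y <- intensities(s); se <- NULL
  }
  if (window$lo < min(w) || window$hi > max(w))
    stop("fit window extends beyond the spectrum range")
  idx <- which(w >= window$lo & w <= window$hi)
  x <- w[idx]; yy <- y[idx]
  k <- nrow(window$peaks)
  npar <- 3L * k + 2L
  if (length(x) < 3L * npar)
    stop(sprintf("window has %d points for %d parameters; need >= %d",
                 length(x), npar, 3L * npar))

  weights <- NULL
  if (!is.null(se)) {
    sew <- se[idx]
    if (max(sew) > 0) {
      floorSE <- max(sew) * 1e-6
      weights <- 1 / pmax(sew, floorSE)^2
    }
  }
  sw <- if (is.null(weights)) rep(1, length(x)) else sqrt(weights)

  p0 <- c(pmax(window$peaks$amplitude, 1e-3), window$peaks$center,
          window$peaks$width, min(yy), 0)
  tol <- window$centerTolerance
  lower <- c(rep(0, k), window$peaks$center - tol,
             pmax(0.5, window$peaks$width / 3), -Inf, -Inf)
  upper <- c(rep(Inf, k), window$peaks$center + tol,
             window$peaks$width * 3, Inf, Inf)

  res <- tryCatch(
    minpack.lm::nls.lm(
      par = p0,
      fn = function(p) sw * (peakModel(p, x, k, window$lo) - yy),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  out <- data.frame(band = window$peaks$center,
                    center = NA_real_, sigma = NA_real_,
                    intensity = NA_real_, intensity_se = NA_real_,
                    converged = FALSE, degenerate = FALSE,
                    window_lo = window$lo, window_hi = window$hi)
  if (is.null(res)) return(out)

  p <- res$par
  ok <- res$info %in% 1:4
  # parameter-at-bound checks (amplitude floor, center drift limit)
  atBound <- (p[seq_len(k)] <= lower[seq_len(k)] + 1e-9) |
    (abs(p[k + seq_len(k)] - lower[k + seq_len(k)]) < 1e-9) |
    (abs(p[k + seq_len(k)] - upper[k + seq_len(k)]) < 1e-9)

  covm <- tryCatch({
    J <- sw * peakJacobian(p, x, k, window$lo)
    ih <- chol2inv(chol(crossprod(J)))
    if (is.null(weights)) {
      dof <- max(length(x) - npar, 1L)
      ih * (res$deviance / dof)
    } else ih
  }, error = function(e) NULL)
  pse <- if (is.null(covm)) rep(NA_real_, npar) else sqrt(pmax(diag(covm), 0))

  centers <- p[k + seq_len(k)]
  degen <- rep(FALSE, k)
  if (k > 1L)
    for (i in seq_len(k - 1L))
      for (j in seq(i + 1L, k))
        if (abs(centers[i] - centers[j]) < 2) degen[c(i, j)] <- TRUE

  out$center <- centers
  out$sigma <- p[2 * k + seq_len(k)]
  out$intensity <- p[seq_len(k)]
  out$intensity_se <- pse[seq_len(k)]
  out$converged <- ok & !atBound & !is.na(pse[seq_len(k)])
  out$degenerate <- degen
  out
}

#' Fit all default windows and collect band intensities
#'
#' Convenience wrapper running [fitWindow()] over a window list and
#' row-binding the per-peak results.
#'
#' @param s a [RamanSpectrum-class] or [AverageSpectrum-class].
#' @param windows list of [fitWindowSpec()]; default [defaultFitWindows()].
#' @return data.frame as from [fitWindow()], one row per band.
#' @export
fitBands <- function(s, windows = defaultFitWindows()) {
  do.call(rbind, lapply(windows, function(w) fitWindow(s, w)))
}

#' Robust two-band auto-fit for single (noisy) spectra
#'
#' Fits each of the two bands alone in a fixed narrow window with bounded
#' center drift — designed to succeed on low signal-to-noise single map
#' pixels where the full multipeak fit would not. The pair defaults to
#' (1085, 1654), the two strong bands that remain resolvable at
#' single-spectrum level.
#'
#' @param s a [RamanSpectrum-class].
#' @param bands length-2 numeric, (numerator, denominator) band centers.
#' @param halfWidth window half width, cm-1.
#' @param widths initial Gaussian sigmas for the two bands.
#' @param centerTolerance allowed center drift, cm-1.
#' @return list with elements `numerator` and `denominator` (one-row
#'   data.frames as from [fitWindow()]) and `valid` (both fits converged
#'   with intensity above twice its SE).
#' @export
autoFitPair <- function(s, bands = c(1654, 1085), halfWidth = 30,
                        widths = c(11, 8), centerTolerance = 5) {
  stopifnot(length(bands) == 2L, bands[1] != bands[2])
  w <- wavenumbers(s); y <- intensities(s)
  fitOne <- function(ctr, wd) {
    sel <- w >= ctr - halfWidth & w <= ctr + halfWidth
    amp0 <- max(diff(range(y[sel])), 1e-3)
    win <- fitWindowSpec(ctr - halfWidth, ctr + halfWidth,
                         data.frame(center = ctr, width = wd,
                                    amplitude = amp0),
                         centerTolerance)
    fitWindow(s, win)
  }
  num <- fitOne(bands[1], widths[1])
  den <- fitOne(bands[2], widths[2])
  signalOK <- function(r) {
    isTRUE(r$converged) && is.finite(r$intensity_se) &&
      (r$intensity_se == 0 || r$intensity > 2 * r$intensity_se)
  }
  list(numerator = num, denominator = den,
       valid = signalOK(num) && signalOK(den))
}
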