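#' Read a spectrum from two-column delimited text
#'
#' Accepts comma-, semicolon-, tab- or whitespace-delimited numeric text with
#' optional `#` comment lines and an optional single header line. A
#' descending axis is sorted ascending.
#'
#' @param source file path (or connection readable by [readLines()]).
#' @param metadata named list attached to the spectrum.
#' @return A [RamanSpectrum-class].
#' @export
readSpectrum <- function(source, metadata = list()) {
  lines <- readLines(source)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data lines in ", source)
  parseLine <- function(ln) {
    parts <- strsplit(trimws(ln), "[,;\t ]+")[[1L]]
    suppressWarnings(as.numeric(parts))
  }
  vals <- lapply(lines[keep], parseLine)
  bad <- vapply(vals, function(v) length(v) < 2L || anyNA(v[1:2]), logical(1))
  # tolerate one header line at the top, nothing else
  if (bad[1L] && length(bad) > 1L) {
    vals <- vals[-1L]; keep <- keep[-1L]; bad <- bad[-1L]
  }
  if (any(bad))
    stop(sprintf("non-numeric data at line %d: '%s'",
                 keep[which(bad)[1L]], lines[keep[which(bad)[1L]]]))
  w <- vapply(vals, `[`, numeric(1), 1L)
  y <- vapply(vals, `[`, numeric(1), 2L)
  if (length(w) < 2L) stop("spectrum needs at least 2 points")
  if (anyDuplicated(w))
    stop("duplicate wavenumber at line ", keep[which(duplicated(w))[1L]])
  ramanSpectrum(w, y, metadata = metadata)
}

#' Linearly interpolate a spectrum onto a new grid
#'
#' Exact at shared nodes; no extrapolation (the grid must lie within the
#' spectrum's wavenumber range). Used to put all spectra on identical
#' channels before multivariate analysis.
#'
#' @param s a [RamanSpectrum-class].
#' @param grid target wavenumber axis.
#' @return A [RamanSpectrum-class] on `grid`.
#' @export
interpolateToGrid <- function(s, grid) {
  stopifnot(is(s, "RamanSpectrum"))
  w <- wavenumbers(s)
  if (min(grid) < min(w) || max(grid) > max(w))
    stop(sprintf("grid [%g, %g] extends beyond data range [%g, %g]; no extrapolation",
                 min(grid), max(grid), min(w), max(w)))
  y <- stats::approx(w, intensities(s), xout = grid)$y
  ramanSpectrum(grid, y, metadata = spectrumMeta(s))
}

#' Linear baseline correction from first to last spectral point
#'
#' Subtracts the straight line through the first and last (wavenumber,
#' intensity) points; the corrected endpoints are exactly zero. Idempotent.
#'
#' @param s a [RamanSpectrum-class] or [RamanSpectrumSet-class] (applied
#'   spectrum-wise).
#' @return Same class as the input.
#' @export
linearBaseline <- function(s) {
  if (is(s, "RamanSpectrumSet")) {
    m <- s@intensities
    w <- s@wavenumbers
    n <- nrow(m)
    slope <- (m[n, ] - m[1L, ]) / (w[n] - w[1L])
    base <- outer(w - w[1L], slope) + rep(m[1L, ], each = n)
    return(ramanSpectrumSet(w, m - base, s@spectrumData))
  }
  stopifnot(is(s, "RamanSpectrum"))
  w <- wavenumbers(s); y <- intensities(s)
  n <- length(w)
  base <- y[1L] + (y[n] - y[1L]) / (w[n] - w[1L]) * (w - w[1L])
  ramanSpectrum(w, y - base, metadata = spectrumMeta(s))
}

#' Area-normalize a spectrum
#'
#' Scales the intensities so that the trapezoidal integral over the axis is
#' exactly 1. Errors when the total area is zero or negative.
#'
#' @param s a [RamanSpectrum-class].
#' @return A [RamanSpectrum-class].
#' @export
areaNormalize <- function(s) {
  stopifnot(is(s, "RamanSpectrum"))
  a <- trapezoidArea(wavenumbers(s), intensities(s))
  if (!is.finite(a) || a <= 0)
    stop("cannot area-normalize: trapezoidal area is ", format(a))
  ramanSpectrum(wavenumbers(s), intensities(s) / a, metadata = spectrumMeta(s))
}

trapezoidArea <- function(x, y) {
  sum(diff(x) * (y[-1L] + y[-length(y)])) / 2
}

#' Cubic smoothing spline on the original axis
#'
#' Smoothing parameter on a package-defined \[0, 1\] scale: 0 returns the
#' input unchanged (interpolating limit) and larger values give smoother
#' output (the value is passed as `spar` to [stats::smooth.spline()]). This
#' scale is not portable to other software's smoothing conventions.
#'
#' @param s a [RamanSpectrum-class].
#' @param smoothing numeric in \[0, 1\]; default 0.65.
#' @return A [RamanSpectrum-class], same length as the input.
#' @export
splineSmooth <- function(s, smoothing = 0.65) {
  stopifnot(is(s, "RamanSpectrum"))
  if (smoothing < 0 || smoothing > 1)
    stop("smoothing must be in [0, 1], got ", smoothing)
  w <- wavenumbers(s); y <- intensities(s)
  if (smoothing == 0 || stats::sd(y) == 0) return(s)
  fit <- stats::smooth.spline(w, y, spar = smoothing)
  ramanSpectrum(w, stats::predict(fit, w)$y, metadata = spectrumMeta(s))
}

#' Average spectra with SD and SE envelopes
#'
#' Channel-wise mean, sample standard deviation (n-1 denominator) and
#' standard error of the mean SE = SD/sqrt(n) over a set of spectra on a
#' common axis. `subset` restricts the average to an ordering prefix — the
#' primitive behind the convergence tests.
#'
#' @param spectra a [RamanSpectrumSet-class], or list of
#'   [RamanSpectrum-class] on identical axes.
#' @param subset optional integer vector of spectrum indices (e.g. the first
#'   N of a random ordering).
#' @return An [AverageSpectrum-class].
#' @export
averageSpectra <- function(spectra, subset = NULL) {
  if (is.list(spectra)) {
    w <- wavenumbers(spectra[[1L]])
    for (sp in spectra)
      if (!isTRUE(all.equal(wavenumbers(sp), w)))
        stop("spectra are not on a common wavenumber axis")
    mat <- vapply(spectra, intensities, numeric(length(w)))
    md <- spectrumMeta(spectra[[1L]])
  } else {
    stopifnot(is(spectra, "RamanSpectrumSet"))
    w <- spectra@wavenumbers
    mat <- spectra@intensities
    md <- as.list(spectra@spectrumData[1L, intersect("population",
                                                     names(spectra@spectrumData)),
                                       drop = FALSE])
  }
  if (!is.null(subset)) mat <- mat[, subset, drop = FALSE]
  n <- ncol(mat)
  if (n < 1L) stop("need at least one spectrum")
  mu <- rowMeans(mat)
  if (n == 1L) {
    warning("single spectrum: SD and SE reported as 0")
    sdv <- numeric(length(w))
  } else {
    sdv <- sqrt(rowSums((mat - mu)^2) / (n - 1L))
  }
  new("AverageSpectrum", wavenumbers = w, mean = mu, sd = sdv,
      se = sdv / sqrt(n), n = as.integer(n), metadata = md)
}

#' Average the repeat spectra of one cell
#'
#' Channel-wise mean of all spectra sharing one cell id; errors if the input
#' mixes cells.
#'
#' @param set a [RamanSpectrumSet-class] whose spectra all carry the same
#'   `cell` metadata value.
#' @return A [RamanSpectrum-class] carrying the cell id.
#' @export
perCellAverage <- function(set) {
  stopifnot(is(set, "RamanSpectrumSet"))
  cells <- unique(set@spectrumData$cell)
  if (length(cells) != 1L)
    stop("perCellAverage expects spectra of a single cell; got ",
         length(cells), " cell ids")
  md <- as.list(set@spectrumData[1L, , drop = FALSE])
  ramanSpectrum(set@wavenumbers, rowMeans(set@intensities), metadata = md)
}

#' Per-cell averages across a population
#'
#' Splits a population by cell id and averages each cell's repeat spectra,
#' giving one spectrum per cell (the sampling unit of the multivariate
#' analysis).
#'
#' @param set a [RamanSpectrumSet-class] with a `cell` metadata column.
#' @return A [RamanSpectrumSet-class] with one column per cell.
#' @export
averageByCell <- function(set) {
  stopifnot(is(set, "RamanSpectrumSet"),
            "cell" %in% names(set@spectrumData))
  cells <- unique(set@spectrumData$cell)
  mat <- vapply(cells, function(cid) {
    rowMeans(set@intensities[, set@spectrumData$cell == cid, drop = FALSE])
  }, numeric(length(set@wavenumbers)))
  sd1 <- set@spectrumData[match(cells, set@spectrumData$cell), , drop = FALSE]
  rownames(sd1) <- NULL
  ramanSpectrumSet(set@wavenumbers, mat, sd1)
}

#' Univariate (PIR-path) preprocessing
#'
#' Linear baseline correction of every raw spectrum, the only preprocessing
#' applied before averaging and peak fitting on the ratiometric path.
#'
#' @param set a [RamanSpectrumSet-class].
#' @return A [RamanSpectrumSet-class].
#' @export
pirPreprocess <- function(set) linearBaseline(set)

#' Multivariate-path preprocessing
#'
#' The chain used before PCA-LDA: interpolate to a common grid, minimal
#' linear baselining, per-cell averaging, area normalization, cubic spline
#' smoothing (default parameter 0.65).
#'
#' @param set a [RamanSpectrumSet-class] with a `cell` column.
#' @param grid target axis; default keeps the set's own axis.
#' @param smoothing spline smoothing parameter in \[0, 1\].
#' @return A [RamanSpectrumSet-class], one preprocessed spectrum per cell.
#' @export
multivariatePreprocess <- function(set, grid = NULL, smoothing = 0.65) {
  stopifnot(is(set, "RamanSpectrumSet"))
  if (!is.null(grid)) {
    specs <- lapply(seq_len(nSpectra(set)), function(i)
      interpolateToGrid(getSpectrum(set, i), grid))
    mat <- vapply(specs, intensities, numeric(length(grid)))
    set <- ramanSpectrumSet(grid, mat, set@spectrumData)
  }
  set <- linearBaseline(set)
  percell <- averageByCell(set)
  out <- vapply(seq_len(nSpectra(percell)), function(i) {
    s <- getSpectrum(percell, i)
    intensities(splineSmooth(areaNormalize(s), smoothing))
  }, numeric(length(percell@wavenumbers)))
  ramanSpectrumSet(percell@wavenumbers, out, percell@spectrumData)
}

#' Write an AverageSpectrum as CSV plus JSON sidecar
#'
#' CSV columns: wavenumber, mean, sd, se; the sidecar records n and any
#' provenance.
#'
#' @param avg an [AverageSpectrum-class].
#' @param path CSV output path (sidecar written as `<path>.json`).
#' @param provenance optional named list.
#' @return `path`, invisibly.
#' @export
writeAverageSpectrum <- function(avg, path, provenance = list()) {
  stopifnot(is(avg, "AverageSpectrum"))
  utils::write.csv(data.frame(wavenumber = avg@wavenumbers, mean = avg@mean,
                              sd = avg@sd, se = avg@se),
                   path, row.names = FALSE)
  jsonlite::write_json(c(list(n = avg@n), provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
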