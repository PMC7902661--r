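#' Build a spatially-resolved PIR map
#'
#' Runs the robust two-band auto-fit ([autoFitPair()]) on every map pixel
#' and assembles the per-pixel ratio into a grid. Pixels whose fits fail (or
#' whose fitted amplitude is indistinguishable from zero) are masked as NA —
#' never silently filled.
#'
#' @param set a [RamanSpectrumSet-class] with unique (`row`, `col`) metadata
#'   per spectrum (as produced by [sampleMap()]); baseline the spectra first
#'   if the acquisition added one.
#' @param bands length-2 numeric (numerator, denominator); default the
#'   1654/1085 marker used for nucleolus hot-spot imaging.
#' @param ... passed to [autoFitPair()].
#' @return A [PIRMap-class].
#' @export
computePIRMap <- function(set, bands = c(1654, 1085), ...) {
  stopifnot(is(set, "RamanSpectrumSet"),
            all(c("row", "col") %in% names(set@spectrumData)))
  sd <- set@spectrumData
  if (anyDuplicated(sd[, c("row", "col")]))
    stop("duplicate map positions")
  nr <- max(sd$row); nc <- max(sd$col)
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nSpectra(set))) {
    fit <- autoFitPair(getSpectrum(set, i), bands = bands, ...)
    if (fit$valid && fit$denominator$intensity > 0) {
      v <- fit$numerator$intensity / fit$denominator$intensity
      if (is.finite(v) && v > 0) vals[sd$row[i], sd$col[i]] <- v
    }
  }
  new("PIRMap", values = vals, numeratorBand = bands[1L],
      denominatorBand = bands[2L], nValid = sum(!is.na(vals)),
      metadata = list(population = if ("population" %in% names(sd))
        sd$population[1L] else NA_character_,
        nPixels = nrow(sd)))
}

#' Percentage frequency-of-occurrence histogram of a PIR map
#'
#' Bins the valid pixel values and normalises counts to percentages of the
#' valid-pixel count N, so maps of different sizes are comparable. Values
#' outside the edge range are clipped into the end bins (with a message).
#' Percentages sum to 100 over valid pixels; both the valid-pixel and
#' total-pixel denominators are reported.
#'
#' @param map a [PIRMap-class].
#' @param edges strictly increasing bin edges; default 20 equal-width bins
#'   over the map's own value range.
#' @return list of class `pirHistogram`: `edges`, `mid`, `percent`,
#'   `nValid`, `nTotal`.
#' @export
frequencyHistogram <- function(map, edges = NULL) {
  stopifnot(is(map, "PIRMap"))
  v <- map@values[!is.na(map@values)]
  if (!length(v)) stop("no valid pixels to histogram")
  if (is.null(edges)) {
    rg <- range(v)
    if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
    edges <- seq(rg[1L], rg[2L], length.out = 21L)
  }
  stopifnot(length(edges) >= 2L, all(diff(edges) > 0))
  nClip <- sum(v < edges[1L] | v > edges[length(edges)])
  if (nClip > 0) {
    message(nClip, " value(s) outside the bin range clipped into end bins")
    v <- pmin(pmax(v, edges[1L]), edges[length(edges)])
  }
  cnt <- graphics::hist(v, breaks = edges, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)$counts
  structure(list(edges = edges,
                 mid = (edges[-1L] + edges[-length(edges)]) / 2,
                 percent = 100 * cnt / length(v),
                 nValid = length(v), nTotal = length(map@values)),
            class = "pirHistogram")
}

#' @export
print.pirHistogram <- function(x, ...) {
  cat(sprintf("pirHistogram: %d bins over [%.3g, %.3g], N = %d valid (%d total) pixels\n",
              length(x$percent), min(x$edges), max(x$edges),
              x$nValid, x$nTotal))
  invisible(x)
}

#' Shared fixed-width bin edges over several maps
#'
#' Fixed-width bins spanning the pooled min-max of all maps being compared,
#' so their frequency curves share an axis.
#'
#' @param maps list of [PIRMap-class].
#' @param nBins number of bins.
#' @return numeric edges of length `nBins + 1`.
#' @export
pooledBinEdges <- function(maps, nBins = 20L) {
  vals <- unlist(lapply(maps, function(m) m@values[!is.na(m@values)]))
  stopifnot(length(vals) > 0L)
  rg <- range(vals)
  if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
  seq(rg[1L], rg[2L], length.out = nBins + 1L)
}

#' Write a PIR map as a CSV matrix
#'
#' @param map a [PIRMap-class].
#' @param path output path (invalid pixels written as NA).
#' @return `path`, invisibly.
#' @export
writePIRMap <- function(map, path) {
  utils::write.csv(map@values, path, row.names = FALSE)
  invisible(path)
}

#' Plot a PIR map
#'
#' @param x a [PIRMap-class].
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @export
setMethod("plot", signature(x = "PIRMap", y = "missing"), function(x, y, ...) {
  graphics::image(t(x@values[nrow(x@values):1, , drop = FALSE]),
                  axes = FALSE, useRaster = TRUE,
                  main = sprintf("%g/%g PIR map", x@numeratorBand,
                                 x@denominatorBand), ...)
})

#' Plot a convergence curve
#'
#' @param x a [ConvergenceCurve-class].
#' @param y optional [TauFit-class] overlaid as the fitted exponential.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "ConvergenceCurve"), function(x, y, ...) {
  graphics::plot(x@n, x@values, xlab = "spectra in average (N)",
                 ylab = x@statistic, ...)
  if (!missing(y) && is(y, "TauFit") && y@converged) {
    nn <- seq(min(x@n), max(x@n), length.out = 200)
    graphics::lines(nn, y@amplitude * exp(-nn / y@tau) + y@offset,
                    col = "red")
  }
})
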