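#' @name accessors
#' @title Accessors for RamanPIR containers
#'
#' @description Slot accessors shared by the spectral containers:
#' `wavenumbers()` returns the Raman shift axis, `intensities()` the
#' intensity vector/matrix, `spectrumMeta()` per-spectrum metadata,
#' `nSpectra()` the number of contributing spectra.
#'
#' @param object a RamanPIR object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))

#' @rdname accessors
#' @export
setGeneric("nSpectra", function(object) standardGeneric("nSpectra"))

#' @rdname accessors
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(object) object@wavenumbers)

#' @rdname accessors
#' @export
setMethod("wavenumbers", "RamanSpectrumSet", function(object) object@wavenumbers)

#' @rdname accessors
#' @export
setMethod("wavenumbers", "AverageSpectrum", function(object) object@wavenumbers)

#' @rdname accessors
#' @export
setMethod("intensities", "RamanSpectrum", function(object) object@intensities)

#' @rdname accessors
#' @export
setMethod("intensities", "RamanSpectrumSet", function(object) object@intensities)

#' @rdname accessors
#' @export
setMethod("spectrumMeta", "RamanSpectrum", function(object) object@metadata)

#' @rdname accessors
#' @export
setMethod("spectrumMeta", "RamanSpectrumSet", function(object) object@spectrumData)

#' @rdname accessors
#' @export
setMethod("nSpectra", "RamanSpectrumSet", function(object) ncol(object@intensities))

#' @rdname accessors
#' @export
setMethod("nSpectra", "AverageSpectrum", function(object) object@n)

#' @name averageAccessors
#' @title Accessors for AverageSpectrum envelopes
#' @param object an [AverageSpectrum-class] object.
#' @return numeric vector (per-channel mean, SD or SE).
NULL

#' @rdname averageAccessors
#' @export
setGeneric("meanIntensity", function(object) standardGeneric("meanIntensity"))

#' @rdname averageAccessors
#' @export
setGeneric("sdEnvelope", function(object) standardGeneric("sdEnvelope"))

#' @rdname averageAccessors
#' @export
setGeneric("seEnvelope", function(object) standardGeneric("seEnvelope"))

#' @rdname averageAccessors
#' @export
setMethod("meanIntensity", "AverageSpectrum", function(object) object@mean)

#' @rdname averageAccessors
#' @export
setMethod("sdEnvelope", "AverageSpectrum", function(object) object@sd)

#' @rdname averageAccessors
#' @export
setMethod("seEnvelope", "AverageSpectrum", function(object) object@se)

#' @name panelAccessors
#' @title Accessors for PIR panels and maps
#' @param object a [PIRPanel-class] or [PIRMap-class] object.
#' @return See the individual accessor.
NULL

#' @rdname panelAccessors
#' @export
setGeneric("referenceBand", function(object) standardGeneric("referenceBand"))

#' @rdname panelAccessors
#' @export
setGeneric("panelEntries", function(object) standardGeneric("panelEntries"))

#' @rdname panelAccessors
#' @export
setGeneric("panelLines", function(object) standardGeneric("panelLines"))

#' @rdname panelAccessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname panelAccessors
#' @export
setMethod("referenceBand", "PIRPanel", function(object) object@referenceBand)

#' @rdname panelAccessors
#' @export
setMethod("panelEntries", "PIRPanel", function(object) object@entries)

#' @rdname panelAccessors
#' @export
setMethod("panelLines", "PIRPanel", function(object) object@lines)

#' @rdname panelAccessors
#' @export
setMethod("mapValues", "PIRMap", function(object) object@values)

#' @name tauAccessors
#' @title Accessors for convergence curves and tau fits
#' @param object a [ConvergenceCurve-class] or [TauFit-class] object.
#' @return See the individual accessor.
NULL

#' @rdname tauAccessors
#' @export
setGeneric("curveN", function(object) standardGeneric("curveN"))

#' @rdname tauAccessors
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))

#' @rdname tauAccessors
#' @export
setGeneric("tau", function(object) standardGeneric("tau"))

#' @rdname tauAccessors
#' @export
setGeneric("tauSD", function(object) standardGeneric("tauSD"))

#' @rdname tauAccessors
#' @export
setMethod("curveN", "ConvergenceCurve", function(object) object@n)

#' @rdname tauAccessors
#' @export
setMethod("curveValues", "ConvergenceCurve", function(object) object@values)

#' @rdname tauAccessors
#' @export
setMethod("tau", "TauFit", function(object) object@tau)

#' @rdname tauAccessors
#' @export
setMethod("tauSD", "TauFit", function(object) object@tauSD)

setMethod("show", "RamanSpectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf("RamanSpectrum: %d channels, %.1f-%.1f cm-1\n",
              length(w), min(w), max(w)))
  md <- object@metadata
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "RamanSpectrumSet", function(object) {
  w <- object@wavenumbers
  cat(sprintf("RamanSpectrumSet: %d spectra x %d channels, %.1f-%.1f cm-1\n",
              ncol(object@intensities), length(w), min(w), max(w)))
  sd <- object@spectrumData
  if ("cell" %in% names(sd))
    cat(sprintf("  %d distinct cells\n", length(unique(sd$cell))))
  if (all(c("row", "col") %in% names(sd)))
    cat(sprintf("  map positions: %d x %d grid\n",
                max(sd$row), max(sd$col)))
})

setMethod("show", "AverageSpectrum", function(object) {
  cat(sprintf("AverageSpectrum: N = %d spectra, %d channels\n",
              object@n, length(object@wavenumbers)))
  cat(sprintf("  mean SE envelope: %.4g\n", mean(object@se)))
})

setMethod("show", "PIRPanel", function(object) {
  e <- object@entries
  cat(sprintf("PIRPanel: reference band %g cm-1, %d marker(s)\n",
              object@referenceBand, nrow(e)))
  if (nrow(e))
    cat(sprintf("  classes: %d full, %d group\n",
                sum(e$class == "full"), sum(e$class == "group")))
})

setMethod("show", "PIRMap", function(object) {
  v <- object@values
  cat(sprintf("PIRMap: %g/%g PIR on a %d x %d grid, %d/%d valid pixels\n",
              object@numeratorBand, object@denominatorBand,
              nrow(v), ncol(v), object@nValid, length(v)))
})

setMethod("show", "ConvergenceCurve", function(object) {
  cat(sprintf("ConvergenceCurve [%s]: %d points, N = %d..%d%s\n",
              object@statistic, length(object@n),
              min(object@n), max(object@n),
              if (object@flagged) " (FLAGGED: >20% fit failures)" else ""))
})

setMethod("show", "TauFit", function(object) {
  if (object@converged)
    cat(sprintf("TauFit: tau = %.3g +/- %.2g spectra (A = %.3g, B = %.3g, R2 = %.3f)\n",
                object@tau, object@tauSD, object@amplitude, object@offset,
                object@rSquared))
  else cat("TauFit: not converged\n")
})
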