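#' @import methods
NULL

#' RamanSpectrum: a single Raman point spectrum
#'
#' One Raman measurement: a strictly increasing wavenumber axis (cm\eqn{^{-1}})
#' with matched intensities and free-form metadata (population label, cell id,
#' optional map position, passage).
#'
#' @slot wavenumbers numeric, strictly increasing Raman shift axis in
#'   cm\eqn{^{-1}}.
#' @slot intensities numeric, same length as `wavenumbers`.
#' @slot metadata named list; recognised entries are `population`, `cell`,
#'   `row`, `col`, `passage` but any entry is carried through.
#'
#' @seealso [ramanSpectrum()] for the user-facing constructor.
#' @export
setClass("RamanSpectrum",
  representation(
    wavenumbers = "numeric",
    intensities = "numeric",
    metadata    = "list"
  )
)

setValidity("RamanSpectrum", function(object) {
  w <- object@wavenumbers
  y <- object@intensities
  if (length(w) < 2L) return("spectrum needs at least 2 points")
  if (length(w) != length(y)) return("wavenumbers and intensities differ in length")
  if (anyNA(w) || anyNA(y)) return("NA values in spectrum")
  if (any(diff(w) <= 0)) return("wavenumbers must be strictly increasing")
  TRUE
})

#' RamanSpectrumSet: a collection of spectra on a common axis
#'
#' Spectra stored column-wise in a channels x spectra matrix, with one row of
#' per-spectrum metadata (`spectrumData`) per column. This is the container
#' for cell populations and for spatially-resolved maps (where `spectrumData`
#' carries `row`/`col` pixel positions).
#'
#' @slot wavenumbers numeric common axis, strictly increasing.
#' @slot intensities numeric matrix, `length(wavenumbers)` rows, one column
#'   per spectrum.
#' @slot spectrumData data.frame with one row per spectrum (columns such as
#'   `population`, `cell`, `row`, `col`).
#'
#' @seealso [ramanSpectrumSet()], [samplePopulation()], [sampleMap()]
#' @export
setClass("RamanSpectrumSet",
  representation(
    wavenumbers  = "numeric",
    intensities  = "matrix",
    spectrumData = "data.frame"
  )
)

setValidity("RamanSpectrumSet", function(object) {
  w <- object@wavenumbers
  m <- object@intensities
  if (length(w) < 2L) return("axis needs at least 2 points")
  if (any(diff(w) <= 0)) return("wavenumbers must be strictly increasing")
  if (nrow(m) != length(w)) return("intensity matrix rows must match axis length")
  if (ncol(m) < 1L) return("need at least one spectrum")
  if (nrow(object@spectrumData) != ncol(m))
    return("spectrumData must have one row per spectrum")
  TRUE
})

#' AverageSpectrum: population mean spectrum with dispersion envelopes
#'
#' A converged average over N spectra with per-channel sample standard
#' deviation and standard error of the mean (SE = SD/sqrt(N)). The SE
#' envelope is what propagates into peak-fit amplitude uncertainties and
#' hence into PIR standard errors.
#'
#' @slot wavenumbers numeric axis.
#' @slot mean numeric per-channel mean intensity.
#' @slot sd numeric per-channel sample SD (n-1 denominator; 0 when n = 1).
#' @slot se numeric per-channel standard error, `sd/sqrt(n)`.
#' @slot n integer, number of contributing spectra.
#' @slot metadata named list (population label etc.).
#'
#' @seealso [averageSpectra()]
#' @export
setClass("AverageSpectrum",
  representation(
    wavenumbers = "numeric",
    mean        = "numeric",
    sd          = "numeric",
    se          = "numeric",
    n           = "integer",
    metadata    = "list"
  )
)

setValidity("AverageSpectrum", function(object) {
  len <- length(object@wavenumbers)
  if (any(c(length(object@mean), length(object@sd), length(object@se)) != len))
    return("all channel arrays must share the axis length")
  if (object@n < 1L) return("n must be >= 1")
  if (any(object@sd < 0) || any(object@se < 0)) return("sd/se must be non-negative")
  ok <- all(abs(object@se - object@sd / sqrt(object@n)) <=
              1e-8 * pmax(object@sd, 1e-300))
  if (!ok) return("se must equal sd/sqrt(n) channel-wise")
  TRUE
})

#' PIRPanel: discriminating PIRs sharing a reference band
#'
#' One biomarker panel: all peak-intensity ratios involving a common
#' reference band that pass a discrimination rule across the reference cell
#' lines, with per-line values and propagated SEs.
#'
#' @slot referenceBand numeric, the shared band position in cm\eqn{^{-1}}.
#' @slot entries data.frame with columns `numerator`, `denominator`, `class`
#'   (`"full"` or `"group"`), then one `value_<line>` and `se_<line>` column
#'   pair per reference line.
#' @slot lines character, reference line labels in a fixed order.
#' @slot groups list of two character vectors partitioning `lines` into the
#'   biological groups used by the group-stratification rule.
#'
#' @seealso [buildPanels()], [classifyAgainstPanels()]
#' @export
setClass("PIRPanel",
  representation(
    referenceBand = "numeric",
    entries       = "data.frame",
    lines         = "character",
    groups        = "list"
  )
)

setValidity("PIRPanel", function(object) {
  if (length(object@referenceBand) != 1L) return("one reference band per panel")
  e <- object@entries
  if (nrow(e) > 0) {
    need <- c("numerator", "denominator", "class",
              paste0("value_", object@lines), paste0("se_", object@lines))
    if (!all(need %in% names(e)))
      return(paste("entries missing columns:",
                   paste(setdiff(need, names(e)), collapse = ", ")))
    involves <- e$numerator == object@referenceBand |
      e$denominator == object@referenceBand
    if (!all(involves)) return("every entry must involve the reference band")
    if (!all(e$class %in% c("full", "group"))) return("entry class must be full/group")
  }
  if (length(object@groups) != 2L) return("groups must be a list of two line sets")
  if (!setequal(unlist(object@groups), object@lines))
    return("groups must partition the reference lines")
  TRUE
})

#' PIRMap: a spatial grid of PIR values
#'
#' Per-pixel peak-intensity-ratio values from auto-fitted map spectra;
#' pixels where either band fit failed are NA (masked).
#'
#' @slot values numeric matrix (rows x cols) of PIR values; NA = invalid.
#' @slot numeratorBand,denominatorBand numeric band positions, cm\eqn{^{-1}}.
#' @slot nValid integer count of valid (fitted) pixels.
#' @slot metadata named list.
#'
#' @seealso [computePIRMap()], [frequencyHistogram()]
#' @export
setClass("PIRMap",
  representation(
    values          = "matrix",
    numeratorBand   = "numeric",
    denominatorBand = "numeric",
    nValid          = "integer",
    metadata        = "list"
  )
)

setValidity("PIRMap", function(object) {
  v <- object@values
  nv <- sum(!is.na(v))
  if (object@nValid != nv) return("nValid must equal the count of non-NA pixels")
  if (any(v[!is.na(v)] <= 0)) return("valid PIR values must be positive")
  TRUE
})

#' ConvergenceCurve: a statistic as a function of cumulative spectrum count
#'
#' Tracks a convergence statistic (the %SE of a PIR, or a channel-summarised
#' SE / 2xSD of the spectral average) as spectra are added to the average in
#' a seeded random order.
#'
#' @slot n integer vector of cumulative spectrum counts, strictly increasing.
#' @slot values numeric statistic at each N.
#' @slot statistic character label (e.g. `"%SE(971/1085)"`, `"SE"`, `"2xSD"`).
#' @slot orderingSeed integer seed of the random permutation used.
#' @slot flagged logical, TRUE when more than 20% of schedule points were
#'   dropped by failed fits.
#'
#' @seealso [pirPercentSECurve()], [spectralConvergence()], [fitTau()]
#' @export
setClass("ConvergenceCurve",
  representation(
    n            = "integer",
    values       = "numeric",
    statistic    = "character",
    orderingSeed = "integer",
    flagged      = "logical"
  )
)

setValidity("ConvergenceCurve", function(object) {
  if (length(object@n) != length(object@values))
    return("n and values must have equal length")
  if (any(diff(object@n) <= 0)) return("n must be strictly increasing")
  TRUE
})

#' TauFit: exponential decay fit of a convergence curve
#'
#' Least-squares fit of `stat(N) = A * exp(-N / tau) + B` with A, tau > 0 and
#' B >= 0. The decay constant tau (in units of spectrum count) quantifies how
#' quickly the statistic converges: smaller tau, faster convergence, more
#' homogeneous population for that marker.
#'
#' @slot tau,amplitude,offset numeric fitted parameters (tau, A, B).
#' @slot tauSD numeric standard deviation of tau from the fit covariance.
#' @slot rSquared numeric coefficient of determination of the fit.
#' @slot converged logical.
#'
#' @seealso [fitTau()], [comparePopulations()]
#' @export
setClass("TauFit",
  representation(
    tau       = "numeric",
    amplitude = "numeric",
    offset    = "numeric",
    tauSD     = "numeric",
    rSquared  = "numeric",
    converged = "logical"
  )
)

setValidity("TauFit", function(object) {
  if (object@converged && object@tau <= 0) return("converged tau must be > 0")
  if (object@tauSD < 0) return("tauSD must be >= 0")
  TRUE
})
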