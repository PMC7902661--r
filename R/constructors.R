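#' Construct a RamanSpectrum
#'
#' @param wavenumbers numeric Raman shift axis (cm-1). If supplied descending
#'   it is sorted ascending together with the intensities.
#' @param intensities numeric, same length.
#' @param metadata named list of per-spectrum metadata.
#' @return A [RamanSpectrum-class] object.
#' @examples
#' s <- ramanSpectrum(600:610, rnorm(11))
#' wavenumbers(s)
#' @export
ramanSpectrum <- function(wavenumbers, intensities, metadata = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities differ in length")
  if (is.unsorted(wavenumbers, strictly = TRUE)) {
    o <- order(wavenumbers)
    wavenumbers <- wavenumbers[o]
    intensities <- intensities[o]
  }
  new("RamanSpectrum", wavenumbers = wavenumbers, intensities = intensities,
      metadata = metadata)
}

#' Construct a RamanSpectrumSet
#'
#' @param wavenumbers numeric common axis.
#' @param intensities channels x spectra matrix.
#' @param spectrumData data.frame, one row per spectrum.
#' @return A [RamanSpectrumSet-class] object.
#' @export
ramanSpectrumSet <- function(wavenumbers, intensities,
                             spectrumData = data.frame(row.names = seq_len(ncol(intensities)))) {
  new("RamanSpectrumSet", wavenumbers = as.numeric(wavenumbers),
      intensities = as.matrix(intensities), spectrumData = spectrumData)
}

#' Extract one spectrum from a set
#'
#' @param set a [RamanSpectrumSet-class].
#' @param i column index.
#' @return A [RamanSpectrum-class] carrying that spectrum's metadata row.
#' @export
getSpectrum <- function(set, i) {
  stopifnot(is(set, "RamanSpectrumSet"), i >= 1, i <= nSpectra(set))
  md <- as.list(set@spectrumData[i, , drop = FALSE])
  ramanSpectrum(set@wavenumbers, set@intensities[, i], metadata = md)
}

#' Subset a RamanSpectrumSet by spectrum index
#'
#' @param set a [RamanSpectrumSet-class].
#' @param idx integer vector of spectrum (column) indices.
#' @return A [RamanSpectrumSet-class] with the selected spectra.
#' @export
subsetSpectra <- function(set, idx) {
  stopifnot(is(set, "RamanSpectrumSet"))
  new("RamanSpectrumSet", wavenumbers = set@wavenumbers,
      intensities = set@intensities[, idx, drop = FALSE],
      spectrumData = set@spectrumData[idx, , drop = FALSE])
}

# Evaluate code under a local, restorable RNG state so that seeded package
# functions never disturb the caller's random stream.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
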