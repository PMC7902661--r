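#' Describe one Raman band
#'
#' A Gaussian line: `amplitude * exp(-(x - center)^2 / (2 * width^2))`.
#' "Intensity" throughout the package means the Gaussian amplitude (peak
#' height), not the integrated area.
#'
#' @param center band position, cm-1.
#' @param width Gaussian sigma, cm-1; must be > 0.
#' @param amplitude peak height in arbitrary intensity units; must be >= 0.
#' @return A `bandSpec` (named list).
#' @export
bandSpec <- function(center, width, amplitude) {
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(width), width > 0,
            is.numeric(amplitude), amplitude >= 0)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "bandSpec")
}

#' Fingerprint-region band table
#'
#' The eleven bands used by the built-in profiles, spanning the main protein,
#' lipid and DNA/RNA features of the cellular fingerprint region
#' (639, 779, 932, 971, 999, 1060, 1085, 1445, 1473, 1573, 1654 cm-1).
#'
#' @return data.frame with columns `center`, `width`, `amplitude`.
#' @export
fingerprintBands <- function() {
  data.frame(
    center    = c(639, 779, 932, 971, 999, 1060, 1085, 1445, 1473, 1573, 1654),
    width     = c(  7,   7,   7,   6,   5,    8,    8,   10,    8,    8,   11),
    amplitude = c( 18,  24,  30,  36,  30,   28,   34,   80,   40,   24,   70)
  )
}

#' Define a cell-type profile for the synthetic generator
#'
#' A cell type is a set of mean band amplitudes plus two levels of
#' multiplicative log-normal variation: between cells (`interCellCV`, shared
#' by all repeat spectra of one cell) and between repeat spectra within a
#' cell (`intraCellCV`). An optional rare subpopulation replaces a cell's
#' amplitude profile with an alternative one with probability
#' `rareSubpopFraction`, which is how heterogeneous populations are emulated.
#'
#' @param name character label.
#' @param bands data.frame with columns `center`, `width`, `amplitude`.
#' @param interCellCV fractional CV of band amplitudes across cells (>= 0).
#' @param intraCellCV fractional CV across repeat spectra within a cell.
#' @param rareSubpopFraction probability in \[0, 1\] that a cell is drawn
#'   from the alternative profile.
#' @param rareSubpopBands alternative `bands` data.frame; required iff
#'   `rareSubpopFraction > 0`.
#' @return A `cellTypeProfile` (named list).
#' @export
cellTypeProfile <- function(name, bands, interCellCV = 0.10,
                            intraCellCV = 0.05, rareSubpopFraction = 0,
                            rareSubpopBands = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.data.frame(bands),
            all(c("center", "width", "amplitude") %in% names(bands)),
            all(bands$width > 0), all(bands$amplitude >= 0),
            interCellCV >= 0, intraCellCV >= 0,
            rareSubpopFraction >= 0, rareSubpopFraction <= 1)
  if (rareSubpopFraction > 0 && is.null(rareSubpopBands))
    stop("rareSubpopBands must be given when rareSubpopFraction > 0")
  if (rareSubpopFraction == 0 && !is.null(rareSubpopBands))
    stop("rareSubpopBands given but rareSubpopFraction is 0")
  structure(list(name = name, bands = bands,
                 interCellCV = interCellCV, intraCellCV = intraCellCV,
                 rareSubpopFraction = rareSubpopFraction,
                 rareSubpopBands = rareSubpopBands),
            class = "cellTypeProfile")
}

#' Define the acquisition model
#'
#' Describes how synthetic spectra are "recorded": the wavenumber grid, the
#' per-spectrum linear baseline draw, additive Gaussian detector noise, and
#' the number of repeat spectra per cell nucleus (default 5). The default
#' grid covers the fingerprint region at 1 cm-1 steps; the instrument's
#' ~3 cm-1 spectral resolution is expressed through the band widths, not the
#' grid step.
#'
#' @param gridStart,gridStop,gridStep wavenumber axis definition, cm-1.
#' @param baselineSlopeRange length-2 range for the uniform slope draw
#'   (intensity units per cm-1).
#' @param baselineOffsetRange length-2 range for the uniform offset draw.
#' @param noiseSD SD of additive Gaussian noise, intensity units (>= 0).
#' @param spectraPerCell repeat spectra per cell (>= 1).
#' @return An `acquisitionModel` (named list, including the realised `grid`).
#' @export
acquisitionModel <- function(gridStart = 600, gridStop = 1800, gridStep = 1,
                             baselineSlopeRange = c(-0.004, 0.004),
                             baselineOffsetRange = c(0, 2),
                             noiseSD = 0.5, spectraPerCell = 5L) {
  stopifnot(gridStart < gridStop, gridStep > 0, noiseSD >= 0,
            spectraPerCell >= 1,
            length(baselineSlopeRange) == 2L, length(baselineOffsetRange) == 2L,
            diff(baselineSlopeRange) >= 0, diff(baselineOffsetRange) >= 0)
  grid <- seq(gridStart, gridStop, by = gridStep)
  if (length(grid) < 2L) stop("grid must contain at least 2 points")
  structure(list(gridStart = gridStart, gridStop = gridStop,
                 gridStep = gridStep, grid = grid,
                 baselineSlopeRange = baselineSlopeRange,
                 baselineOffsetRange = baselineOffsetRange,
                 noiseSD = noiseSD, spectraPerCell = as.integer(spectraPerCell)),
            class = "acquisitionModel")
}

#' Define a spatial map layout
#'
#' A rows x cols acquisition grid over one cell nucleus with an optional
#' nucleolus-like hot-spot mask: inside the mask the designated band
#' amplitudes are multiplied by `hotspotFactor`, emulating the concentrated
#' regions of elevated 1654/1085 PIR seen in differentiation-incompetent
#' cells.
#'
#' @param rows,cols grid dimensions.
#' @param nucleolusMask logical rows x cols matrix marking hot-spot pixels;
#'   defaults to all-FALSE.
#' @param hotspotFactor multiplier (> 0) applied inside the mask.
#' @param hotspotBands band centers (cm-1) whose amplitudes are multiplied.
#' @return A `mapLayout` (named list).
#' @export
mapLayout <- function(rows, cols, nucleolusMask = NULL,
                      hotspotFactor = 1, hotspotBands = 1654) {
  stopifnot(rows >= 1, cols >= 1, hotspotFactor > 0)
  if (is.null(nucleolusMask))
    nucleolusMask <- matrix(FALSE, rows, cols)
  if (!is.logical(nucleolusMask) ||
      !all(dim(nucleolusMask) == c(rows, cols)))
    stop("nucleolusMask must be a logical rows x cols matrix")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 nucleolusMask = nucleolusMask,
                 hotspotFactor = hotspotFactor, hotspotBands = hotspotBands),
            class = "mapLayout")
}

#' Draw the per-cell amplitude state
#'
#' Draws one multiplicative log-normal factor per band (mean 1, CV =
#' `interCellCV`), optionally switching the cell to the rare subpopulation
#' profile first. The returned state is shared by all repeat spectra of that
#' cell.
#'
#' @param profile a [cellTypeProfile()].
#' @param seed integer seed.
#' @return list with `bands` (data.frame with realised amplitudes) and
#'   `subpop` (`"main"` or `"rare"`).
#' @export
drawCellState <- function(profile, seed) {
  stopifnot(inherits(profile, "cellTypeProfile"))
  withLocalSeed(seed, {
    rare <- profile$rareSubpopFraction > 0 &&
      stats::runif(1) < profile$rareSubpopFraction
    bands <- if (rare) profile$rareSubpopBands else profile$bands
    amp <- bands$amplitude * rlnormCV(nrow(bands), profile$interCellCV)
    bands$amplitude <- amp
    list(bands = bands, subpop = if (rare) "rare" else "main")
  })
}

# log-normal factors with mean 1 and coefficient of variation cv
rlnormCV <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# sum-of-Gaussians evaluated on a grid
gaussianSum <- function(grid, bands) {
  y <- numeric(length(grid))
  for (i in seq_len(nrow(bands)))
    y <- y + bands$amplitude[i] *
      exp(-(grid - bands$center[i])^2 / (2 * bands$width[i]^2))
  y
}

#' Simulate one spectrum of a cell
#'
#' Evaluates the cell's Gaussian band sum on the acquisition grid, applies
#' per-spectrum intra-cell multiplicative band noise, adds a random linear
#' baseline and additive Gaussian noise. Deterministic given `seed`.
#'
#' @param profile a [cellTypeProfile()].
#' @param acq an [acquisitionModel()].
#' @param cellState per-cell state from [drawCellState()]; `NULL` uses the
#'   profile's mean amplitudes (no inter-cell variation).
#' @param seed integer seed for the per-spectrum noise draws.
#' @return A [RamanSpectrum-class].
#' @export
sampleCellSpectrum <- function(profile, acq, cellState = NULL, seed = 1L) {
  stopifnot(inherits(profile, "cellTypeProfile"),
            inherits(acq, "acquisitionModel"))
  if (is.null(cellState))
    cellState <- list(bands = profile$bands, subpop = "main")
  withLocalSeed(seed, {
    bands <- cellState$bands
    bands$amplitude <- bands$amplitude * rlnormCV(nrow(bands), profile$intraCellCV)
    y <- gaussianSum(acq$grid, bands)
    slope <- stats::runif(1, acq$baselineSlopeRange[1], acq$baselineSlopeRange[2])
    offset <- stats::runif(1, acq$baselineOffsetRange[1], acq$baselineOffsetRange[2])
    y <- y + offset + slope * (acq$grid - acq$gridStart)
    if (acq$noiseSD > 0) y <- y + stats::rnorm(length(y), 0, acq$noiseSD)
    ramanSpectrum(acq$grid, y,
                  metadata = list(population = profile$name,
                                  subpop = cellState$subpop))
  })
}

#' Simulate a cell population
#'
#' Draws `nCells` cells (each with its own inter-cell amplitude state, and
#' with probability `rareSubpopFraction` from the rare profile) and
#' `acq$spectraPerCell` repeat spectra per cell, emulating the "five random
#' spectra per nucleus" sampling design.
#'
#' @param profile a [cellTypeProfile()].
#' @param acq an [acquisitionModel()].
#' @param nCells number of cells (>= 1).
#' @param seed integer seed; the whole population is deterministic given
#'   (profile, acq, nCells, seed).
#' @return A [RamanSpectrumSet-class] with `population`, `cell`, `subpop`
#'   metadata columns.
#' @export
samplePopulation <- function(profile, acq, nCells, seed = 1L) {
  stopifnot(nCells >= 1)
  nCells <- as.integer(nCells)
  # independent sub-seeds per cell / spectrum, derived deterministically
  seeds <- withLocalSeed(seed,
    matrix(sample.int(.Machine$integer.max, nCells * (acq$spectraPerCell + 1L)),
           nrow = nCells))
  nspec <- nCells * acq$spectraPerCell
  mat <- matrix(NA_real_, length(acq$grid), nspec)
  cellId <- character(nspec)
  subpop <- character(nspec)
  k <- 0L
  for (i in seq_len(nCells)) {
    state <- drawCellState(profile, seeds[i, 1L])
    for (j in seq_len(acq$spectraPerCell)) {
      k <- k + 1L
      sp <- sampleCellSpectrum(profile, acq, state, seeds[i, j + 1L])
      mat[, k] <- intensities(sp)
      cellId[k] <- sprintf("cell%03d", i)
      subpop[k] <- state$subpop
    }
  }
  ramanSpectrumSet(acq$grid, mat,
                   data.frame(population = profile$name, cell = cellId,
                              subpop = subpop, stringsAsFactors = FALSE))
}

#' Simulate a spatially-resolved Raman map of one cell
#'
#' One spectrum per grid pixel, sharing a single per-cell amplitude state;
#' pixels inside the nucleolus mask have the designated band amplitudes
#' multiplied by the hot-spot factor. Map sizes of ~360-484 pixels match
#' typical single-nucleus acquisitions.
#'
#' @param profile a [cellTypeProfile()].
#' @param acq an [acquisitionModel()].
#' @param layout a [mapLayout()].
#' @param seed integer seed.
#' @return A [RamanSpectrumSet-class] with `row`, `col`, `hotspot` metadata.
#' @export
sampleMap <- function(profile, acq, layout, seed = 1L) {
  stopifnot(inherits(layout, "mapLayout"))
  npix <- layout$rows * layout$cols
  seeds <- withLocalSeed(seed, sample.int(.Machine$integer.max, npix + 1L))
  state <- drawCellState(profile, seeds[1L])
  hot <- state$bands$center %in% layout$hotspotBands
  mat <- matrix(NA_real_, length(acq$grid), npix)
  rowIdx <- integer(npix); colIdx <- integer(npix); isHot <- logical(npix)
  k <- 0L
  for (r in seq_len(layout$rows)) {
    for (cc in seq_len(layout$cols)) {
      k <- k + 1L
      st <- state
      if (layout$nucleolusMask[r, cc]) {
        st$bands$amplitude[hot] <- st$bands$amplitude[hot] * layout$hotspotFactor
        isHot[k] <- TRUE
      }
      sp <- sampleCellSpectrum(profile, acq, st, seeds[k + 1L])
      mat[, k] <- intensities(sp)
      rowIdx[k] <- r; colIdx[k] <- cc
    }
  }
  ramanSpectrumSet(acq$grid, mat,
                   data.frame(population = profile$name,
                              cell = "map-cell", row = rowIdx, col = colIdx,
                              hotspot = isHot, stringsAsFactors = FALSE))
}

#' Built-in reference cell-type profiles
#'
#' Four synthetic profiles ("Y101-like" ... "Y202-like") emulating clonal
#' mesenchymal stromal cell lines: the first pair stands for
#' differentiation-competent lines, the second for incompetent ones. They
#' share the fingerprint band table but differ in the
#' 932/971/1060/1085/1445/1473/1654 amplitudes so that the 971 band
#' stratifies all four lines while the 1060/1473/1654-related ratios
#' separate the two groups. The amplitudes are fixture constants chosen to
#' realise that qualitative panel structure; they are not measured values.
#'
#' @param interCellCV,intraCellCV variation levels passed to every profile.
#' @return Named list of four [cellTypeProfile()] objects.
#' @export
referenceProfiles <- function(interCellCV = 0.10, intraCellCV = 0.05) {
  base <- fingerprintBands()
  tweak <- function(name, mult) {
    b <- base
    for (ctr in names(mult))
      b$amplitude[b$center == as.numeric(ctr)] <-
        b$amplitude[b$center == as.numeric(ctr)] * mult[[ctr]]
    cellTypeProfile(name, b, interCellCV = interCellCV,
                    intraCellCV = intraCellCV)
  }
  list(
    "Y101-like" = tweak("Y101-like", list(
      "932" = 1.25, "971" = 0.65, "1060" = 0.900, "1085" = 1.10,
      "1445" = 1.00, "1473" = 0.900, "1654" = 0.800)),
    "Y201-like" = tweak("Y201-like", list(
      "932" = 1.15, "971" = 0.85, "1060" = 0.905, "1085" = 1.05,
      "1445" = 1.04, "1473" = 0.905, "1654" = 0.810)),
    "Y102-like" = tweak("Y102-like", list(
      "932" = 0.85, "971" = 1.15, "1060" = 1.150, "1085" = 0.90,
      "1445" = 0.90, "1473" = 1.100, "1654" = 1.180)),
    "Y202-like" = tweak("Y202-like", list(
      "932" = 0.75, "971" = 1.45, "1060" = 1.155, "1085" = 0.85,
      "1445" = 0.87, "1473" = 1.105, "1654" = 1.190))
  )
}

#' Default reference-line grouping
#'
#' The biological grouping used by the group-stratification rule and the
#' classification aggregates: differentiation-competent ("Y101-like",
#' "Y201-like") vs incompetent ("Y102-like", "Y202-like").
#'
#' @param lines character vector of the four line labels.
#' @return list of two character vectors.
#' @export
defaultGroups <- function(lines = names(referenceProfiles())) {
  stopifnot(length(lines) == 4L)
  list(competent = lines[c(1L, 2L)], incompetent = lines[c(3L, 4L)])
}

#' Write a population to disk as two-column CSV spectra plus a manifest
#'
#' Each spectrum becomes `spectrum_<k>.csv` (columns wavenumber, intensity);
#' `manifest.json` records the per-spectrum metadata and provenance.
#'
#' @param set a [RamanSpectrumSet-class].
#' @param dir output directory (created if needed).
#' @param provenance optional named list stored in the manifest.
#' @return `dir`, invisibly.
#' @export
writePopulation <- function(set, dir, provenance = list()) {
  stopifnot(is(set, "RamanSpectrumSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("spectrum_%04d.csv", seq_len(nSpectra(set)))
  for (i in seq_len(nSpectra(set)))
    utils::write.csv(
      data.frame(wavenumber = set@wavenumbers,
                 intensity = set@intensities[, i]),
      file.path(dir, files[i]), row.names = FALSE)
  manifest <- list(files = files,
                   spectrumData = set@spectrumData,
                   provenance = provenance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a population written by [writePopulation()]
#'
#' @param dir directory containing `manifest.json` and spectrum CSVs.
#' @return A [RamanSpectrumSet-class].
#' @export
readPopulation <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  specs <- lapply(file.path(dir, manifest$files), readSpectrum)
  w <- wavenumbers(specs[[1L]])
  mat <- vapply(specs, intensities, numeric(length(w)))
  ramanSpectrumSet(w, mat, as.data.frame(manifest$spectrumData))
}
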