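# Shared fixture builders. Everything is generated in code; no data files.

# noise-free acquisition: no baseline draw, no detector noise
quietAcq <- function(...) {
  acquisitionModel(baselineSlopeRange = c(0, 0),
                   baselineOffsetRange = c(0, 0), noiseSD = 0, ...)
}

mkCurve <- function(n, v, seed = 1L) {
  new("ConvergenceCurve", n = as.integer(n), values = v,
      statistic = "test", orderingSeed = as.integer(seed), flagged = FALSE)
}

# a synthetic one-row peak-fit result, for PIR/matching unit tests
mkPeak <- function(band, intensity, se) {
  data.frame(band = band, center = band, sigma = 6, intensity = intensity,
             intensity_se = se, converged = TRUE, degenerate = FALSE,
             window_lo = band - 30, window_hi = band + 30)
}

mkPIR <- function(num, den, value, se) {
  data.frame(numerator = num, denominator = den, value = value, se = se,
             source = NA_character_, stringsAsFactors = FALSE)
}

# four synthetic profiles whose panel-band amplitudes are all pairwise
# separated by >= ~11% per band, with per-band line orderings permuted so
# that band ratios stay separated too; used where the property under test
# presumes distinguishable reference lines
separatedProfiles <- function(interCellCV = 0.05, intraCellCV = 0.03) {
  base <- fingerprintBands()
  mult <- list( # per band: multiplier for (line1, line2, line3, line4)
    "932"  = c(0.82, 0.94, 1.06, 1.18),
    "971"  = c(1.18, 1.06, 0.94, 0.82),
    "1060" = c(0.94, 1.18, 0.82, 1.06),
    "1085" = c(1.06, 0.82, 1.18, 0.94),
    "1445" = c(0.85, 1.05, 0.95, 1.15),
    "1473" = c(1.15, 0.95, 1.05, 0.85),
    "1654" = c(0.82, 1.06, 1.18, 0.94))
  nm <- c("lineA", "lineB", "lineC", "lineD")
  out <- lapply(seq_along(nm), function(l) {
    b <- base
    for (ctr in names(mult))
      b$amplitude[b$center == as.numeric(ctr)] <-
        b$amplitude[b$center == as.numeric(ctr)] * mult[[ctr]][l]
    cellTypeProfile(nm[l], b, interCellCV = interCellCV,
                    intraCellCV = intraCellCV)
  })
  names(out) <- nm
  out
}

# reference PIR tables and panels from a profile list
buildReferencePIRs <- function(profiles, acq = acquisitionModel(),
                               nCells = 40, seed = 101) {
  refPIRs <- list()
  for (i in seq_along(profiles)) {
    pop <- samplePopulation(profiles[[i]], acq, nCells, seed = seed + i)
    refPIRs[[names(profiles)[i]]] <-
      allPairsPIRs(fitBands(averageSpectra(pirPreprocess(pop))),
                   source = names(profiles)[i])
  }
  refPIRs
}

buildReferencePanels <- function(profiles, acq = acquisitionModel(),
                                 nCells = 40, seed = 101,
                                 groups = NULL) {
  refPIRs <- buildReferencePIRs(profiles, acq, nCells, seed)
  if (is.null(groups)) groups <- defaultGroups(names(profiles))
  suppressMessages(buildPanels(refPIRs, groups = groups))
}
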