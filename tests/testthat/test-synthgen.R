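test_that("noise-free spectra are the exact Gaussian band sum", {
  acq <- quietAcq()
  prof <- cellTypeProfile("t", fingerprintBands(),
                          interCellCV = 0, intraCellCV = 0)
  s1 <- sampleCellSpectrum(prof, acq, seed = 1)
  s2 <- sampleCellSpectrum(prof, acq, seed = 99)
  expect_identical(intensities(s1), intensities(s2))
  b <- prof$bands
  expected <- rowSums(vapply(seq_len(nrow(b)), function(i)
    b$amplitude[i] * exp(-(acq$grid - b$center[i])^2 / (2 * b$width[i]^2)),
    numeric(length(acq$grid))))
  expect_equal(intensities(s1), expected)

  # single band: apex value equals the amplitude at the band channel
  p1 <- cellTypeProfile("one", data.frame(center = 971, width = 6,
                                          amplitude = 100),
                        interCellCV = 0, intraCellCV = 0)
  sp <- sampleCellSpectrum(p1, acq, seed = 1)
  expect_equal(intensities(sp)[wavenumbers(sp) == 971], 100)
  expect_equal(max(intensities(sp)), 100)
})

test_that("seeding contract: same seed identical, different seeds differ", {
  acq <- acquisitionModel()
  prof <- referenceProfiles()[[1]]
  expect_identical(sampleCellSpectrum(prof, acq, seed = 7),
                   sampleCellSpectrum(prof, acq, seed = 7))
  expect_false(identical(intensities(sampleCellSpectrum(prof, acq, seed = 7)),
                         intensities(sampleCellSpectrum(prof, acq, seed = 8))))
  # whole populations are bit-identical under identical (config, seed)
  p1 <- samplePopulation(prof, acq, 5, seed = 3)
  p2 <- samplePopulation(prof, acq, 5, seed = 3)
  expect_identical(intensities(p1), intensities(p2))
  expect_identical(spectrumMeta(p1), spectrumMeta(p2))
})

test_that("population structure: counts, cell ids, subpopulation draws", {
  acq <- acquisitionModel()
  prof <- referenceProfiles()[[1]]
  pop <- samplePopulation(prof, acq, 20, seed = 5)
  expect_equal(nSpectra(pop), 100)
  expect_equal(length(unique(spectrumMeta(pop)$cell)), 20)
  expect_true(all(spectrumMeta(pop)$subpop == "main"))

  # rare-subpopulation cell count lands in the binomial 99% interval
  rare <- fingerprintBands()
  rare$amplitude <- rare$amplitude * 2
  het <- cellTypeProfile("h", fingerprintBands(), rareSubpopFraction = 0.1,
                         rareSubpopBands = rare)
  acq1 <- acquisitionModel(spectraPerCell = 1)
  popH <- samplePopulation(het, acq1, 1000, seed = 11)
  nRare <- sum(spectrumMeta(popH)$subpop == "rare")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(nRare, ci[1])
  expect_lte(nRare, ci[2])
})

test_that("repeat spectra of one cell share the cell state", {
  # no intra-cell or acquisition noise: repeats identical, cells differ
  acq <- quietAcq()
  prof <- cellTypeProfile("t", fingerprintBands(), interCellCV = 0.2,
                          intraCellCV = 0)
  pop <- samplePopulation(prof, acq, 3, seed = 2)
  m <- intensities(pop)
  cells <- spectrumMeta(pop)$cell
  for (cid in unique(cells)) {
    cols <- which(cells == cid)
    expect_equal(m[, cols], m[, rep(cols[1], length(cols))],
                 ignore_attr = TRUE)
  }
  expect_false(identical(m[, 1], m[, 6]))
})

test_that("maps carry positions and apply the hot-spot factor", {
  acq <- quietAcq()
  prof <- cellTypeProfile("t", fingerprintBands(),
                          interCellCV = 0, intraCellCV = 0)
  mask <- matrix(FALSE, 20, 20); mask[5:10, 5:10] <- TRUE
  lay <- mapLayout(20, 20, mask, hotspotFactor = 2, hotspotBands = 1654)
  mp <- sampleMap(prof, acq, lay, seed = 4)
  expect_equal(nSpectra(mp), 400)          # inside the 360-484 design range
  expect_gte(nSpectra(mp), 360); expect_lte(nSpectra(mp), 484)
  md <- spectrumMeta(mp)
  expect_false(anyDuplicated(md[, c("row", "col")]) > 0)

  # 1654/1085 amplitude ratio doubles inside the mask, exactly
  i1654 <- which(acq$grid == 1654); i1085 <- which(acq$grid == 1085)
  m <- intensities(mp)
  # use pure single-band channels via a 2-band profile for exactness
  p2 <- cellTypeProfile("p2", data.frame(center = c(1085, 1654),
                                         width = c(8, 11),
                                         amplitude = c(34, 70)),
                        interCellCV = 0, intraCellCV = 0)
  mp2 <- sampleMap(p2, acq, lay, seed = 4)
  m2 <- intensities(mp2)
  md2 <- spectrumMeta(mp2)
  ratio <- m2[i1654, ] / m2[i1085, ]
  expect_equal(unique(round(ratio[md2$hotspot] / ratio[!md2$hotspot][1], 9)),
               2)

  # identity factor: masked and unmasked pixels identical without noise
  lay1 <- mapLayout(20, 20, mask, hotspotFactor = 1, hotspotBands = 1654)
  mp1 <- sampleMap(p2, acq, lay1, seed = 4)
  mm <- intensities(mp1)
  expect_equal(max(abs(mm - mm[, 1])), 0)
})

test_that("population round-trips through the CSV + manifest format", {
  acq <- acquisitionModel(gridStart = 600, gridStop = 700)
  prof <- referenceProfiles()[[2]]
  pop <- samplePopulation(prof, acq, 2, seed = 9)
  dir <- withr::local_tempdir()
  writePopulation(pop, dir, provenance = list(seed = 9))
  back <- readPopulation(dir)
  expect_equal(wavenumbers(back), wavenumbers(pop))
  expect_equal(intensities(back), intensities(pop), tolerance = 1e-12)
  expect_equal(spectrumMeta(back)$cell, spectrumMeta(pop)$cell)
})

test_that("generator parameter validation rejects bad configurations", {
  expect_error(acquisitionModel(gridStart = 1800, gridStop = 600), "gridStart")
  expect_error(cellTypeProfile("x", fingerprintBands(),
                               rareSubpopFraction = 0.2), "rareSubpopBands")
  expect_error(mapLayout(3, 3, matrix(FALSE, 2, 2)), "nucleolusMask")
})
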