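test_that("readSpectrum parses delimited text and reports bad lines", {
  f <- withr::local_tempfile(lines = c("600,1", "601,2", "602,1"))
  s <- readSpectrum(f)
  expect_s4_class(s, "RamanSpectrum")
  expect_equal(wavenumbers(s), c(600, 601, 602))
  expect_equal(intensities(s), c(1, 2, 1))

  # descending axis comes back ascending
  fd <- withr::local_tempfile(lines = c("602,1", "601,2", "600,3"))
  sd <- readSpectrum(fd)
  expect_equal(wavenumbers(sd), c(600, 601, 602))
  expect_equal(intensities(sd), c(3, 2, 1))

  # header tolerated once; interior text is an error naming the line
  fh <- withr::local_tempfile(lines = c("wavenumber,intensity", "600,1",
                                        "601,2"))
  expect_equal(intensities(readSpectrum(fh)), c(1, 2))
  fb <- withr::local_tempfile(lines = c("600,1", "601,oops", "602,2"))
  expect_error(readSpectrum(fb), "line 2")
  fdup <- withr::local_tempfile(lines = c("600,1", "600,2", "601,3"))
  expect_error(readSpectrum(fdup), "duplicate")
  f1 <- withr::local_tempfile(lines = "600,1")
  expect_error(readSpectrum(f1), "at least 2")
})

test_that("grid interpolation is exact at nodes and refuses extrapolation", {
  s <- ramanSpectrum(c(600, 602, 604), c(0, 2, 0))
  expect_equal(intensities(interpolateToGrid(s, c(600, 602, 604))),
               intensities(s))
  expect_equal(intensities(interpolateToGrid(s, c(601, 603))), c(1, 1))
  expect_error(interpolateToGrid(s, c(599, 601)), "extrapolation")
})

test_that("linear baseline zeroes the endpoints and is idempotent", {
  x <- seq(600, 700, 2)
  s <- ramanSpectrum(x, 3 + 0.5 * x)           # straight line -> all zero
  expect_equal(intensities(linearBaseline(s)), rep(0, length(x)))

  s2 <- ramanSpectrum(x, sin(x / 10) + 0.01 * x)
  b <- linearBaseline(s2)
  expect_equal(intensities(b)[c(1, length(x))], c(0, 0))
  expect_equal(intensities(linearBaseline(b)), intensities(b))

  # parabola vanishing at both endpoints is untouched
  s3 <- ramanSpectrum(x, (x - 600) * (700 - x))
  expect_equal(intensities(linearBaseline(s3)), intensities(s3))

  # set-wise application matches spectrum-wise
  m <- cbind(intensities(s2), intensities(s3))
  set <- ramanSpectrumSet(x, m)
  expect_equal(intensities(linearBaseline(set))[, 1], intensities(b))
})

test_that("area normalization yields unit trapezoidal area, idempotently", {
  x <- seq(0, 10, 0.5)   # constant 2 over span 10: area 20, scales to 0.1
  s <- ramanSpectrum(x, rep(2, length(x)))
  n1 <- areaNormalize(s)
  expect_equal(intensities(n1), rep(0.1, length(x)))
  expect_equal(intensities(areaNormalize(n1)), intensities(n1),
               tolerance = 1e-12)
  area <- function(s) sum(diff(wavenumbers(s)) *
                            (intensities(s)[-1] + intensities(s)[-length(x)])) / 2
  expect_equal(area(n1), 1, tolerance = 1e-9)
  expect_error(areaNormalize(ramanSpectrum(x, rep(0, length(x)))), "area")
})

test_that("spline smoothing: limits and noise reduction at 0.65", {
  x <- seq(600, 1800, 1)
  s <- ramanSpectrum(x, rep(4, length(x)))
  expect_equal(intensities(splineSmooth(s, 0.65)), rep(4, length(x)))
  noisy <- ramanSpectrum(x, sin(x / 60))
  expect_equal(intensities(splineSmooth(noisy, 0)), intensities(noisy))
  expect_error(splineSmooth(noisy, 1.2), "smoothing")

  set.seed(42)
  truth <- 50 * exp(-(x - 1200)^2 / (2 * 80^2))
  obs <- truth + rnorm(length(x), 0, 2)
  sm <- splineSmooth(ramanSpectrum(x, obs), 0.65)
  expect_lt(mean((intensities(sm) - truth)^2), mean((obs - truth)^2))
})

test_that("averaging produces n-1 SD and SE = SD/sqrt(n) channel-wise", {
  x <- c(600, 601)
  set <- ramanSpectrumSet(x, cbind(c(1, 1), c(3, 3)))
  avg <- averageSpectra(set)
  expect_equal(meanIntensity(avg), c(2, 2))
  expect_equal(sdEnvelope(avg), c(sqrt(2), sqrt(2)))
  expect_equal(seEnvelope(avg), c(1, 1))
  expect_equal(nSpectra(avg), 2)

  same <- ramanSpectrumSet(x, cbind(c(5, 1), c(5, 1), c(5, 1)))
  avgS <- averageSpectra(same)
  expect_equal(sdEnvelope(avgS), c(0, 0))
  expect_equal(seEnvelope(avgS), c(0, 0))

  expect_warning(averageSpectra(set, subset = 1), "single spectrum")
  # subset prefix restricts the average
  expect_equal(meanIntensity(suppressWarnings(averageSpectra(set, subset = 1))),
               c(1, 1))
  # mismatched axes error (list input)
  expect_error(averageSpectra(list(ramanSpectrum(1:3, 1:3),
                                   ramanSpectrum(2:4, 1:3))), "common")
})

test_that("per-cell averaging requires one cell and averages channel-wise", {
  x <- c(600, 601)
  one <- ramanSpectrumSet(x, cbind(c(0, 0), c(4, 4)),
                          data.frame(cell = c("a", "a")))
  avg <- perCellAverage(one)
  expect_equal(intensities(avg), c(2, 2))
  expect_equal(spectrumMeta(avg)$cell, "a")
  mixed <- ramanSpectrumSet(x, cbind(c(0, 0), c(4, 4)),
                            data.frame(cell = c("a", "b")))
  expect_error(perCellAverage(mixed), "single cell")
  byc <- averageByCell(mixed)
  expect_equal(nSpectra(byc), 2)

  five <- ramanSpectrumSet(x, matrix(7, 2, 5), data.frame(cell = rep("c", 5)))
  expect_equal(intensities(perCellAverage(five)), c(7, 7))
})

test_that("SE(N) * sqrt(N) is stable for iid populations (N >= 30)", {
  set.seed(8)
  x <- seq(600, 650, 1)
  m <- matrix(rnorm(length(x) * 120, 10, 1), nrow = length(x))
  set <- ramanSpectrumSet(x, m)
  prods <- sapply(seq(30, 120, 10), function(N)
    mean(seEnvelope(averageSpectra(set, subset = seq_len(N)))) * sqrt(N))
  expect_lt((max(prods) - min(prods)) / mean(prods), 0.05)
})
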