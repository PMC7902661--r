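test_that("a noiseless Gaussian is self-fitted to machine precision", {
  x <- seq(900, 1032, 1)
  s <- ramanSpectrum(x, 50 * exp(-(x - 971)^2 / (2 * 36)))
  win <- fitWindowSpec(900, 1032, data.frame(center = 971, width = 6,
                                             amplitude = 40))
  fit <- fitWindow(s, win)
  expect_true(fit$converged)
  expect_equal(fit$intensity, 50, tolerance = 1e-8)
  expect_equal(fit$center, 971, tolerance = 1e-6)
  expect_lt(fit$intensity_se, 1e-6)
})

test_that("overlapping bands are jointly recovered within 1% at low noise", {
  x <- seq(895, 1032, 1)
  truth <- 30 * exp(-(x - 971)^2 / (2 * 49)) +
    45 * exp(-(x - 999)^2 / (2 * 49))
  set.seed(11)
  s <- ramanSpectrum(x, truth + rnorm(length(x), 0, 0.001 * 45))
  win <- fitWindowSpec(895, 1032,
                       data.frame(center = c(971, 999), width = c(7, 7),
                                  amplitude = c(20, 30)))
  fit <- fitWindow(s, win)
  expect_true(all(fit$converged))
  expect_equal(fit$intensity[fit$band == 971], 30, tolerance = 0.01)
  expect_equal(fit$intensity[fit$band == 999], 45, tolerance = 0.01)
})

test_that("a peakless window is flagged or consistent with zero", {
  set.seed(21)
  x <- seq(900, 1032, 1)
  s <- ramanSpectrum(x, rnorm(length(x), 0, 1))
  win <- fitWindowSpec(900, 1032, data.frame(center = 971, width = 6,
                                             amplitude = 5))
  fit <- fitWindow(s, win)
  expect_true(!fit$converged ||
                fit$intensity <= 2 * fit$intensity_se + 1e-9)
})

test_that("fitted intensities and SEs are scale-equivariant", {
  set.seed(31)
  x <- seq(900, 1032, 1)
  y <- 50 * exp(-(x - 971)^2 / (2 * 36)) + rnorm(length(x), 0, 0.3)
  win <- fitWindowSpec(900, 1032, data.frame(center = 971, width = 6,
                                             amplitude = 40))
  f1 <- fitWindow(ramanSpectrum(x, y), win)
  f5 <- fitWindow(ramanSpectrum(x, 5 * y), win)
  expect_equal(f5$intensity / f1$intensity, 5, tolerance = 1e-4)
  expect_equal(f5$intensity_se / f1$intensity_se, 5, tolerance = 1e-3)
})

test_that("fit matches a brute-force grid search on well-separated peaks", {
  x <- seq(1028, 1130, 1)
  truth <- 28 * exp(-(x - 1060)^2 / (2 * 64)) +
    34 * exp(-(x - 1085)^2 / (2 * 64))
  s <- ramanSpectrum(x, truth)
  win <- fitWindowSpec(1028, 1130,
                       data.frame(center = c(1060, 1085), width = c(8, 8),
                                  amplitude = c(20, 25)))
  fit <- fitWindow(s, win)

  # independent oracle: coarse grid search over (A1, A2) at known shape
  grid <- seq(20, 40, 0.25)
  sse <- outer(grid, grid, Vectorize(function(a1, a2)
    sum((a1 * exp(-(x - 1060)^2 / 128) + a2 * exp(-(x - 1085)^2 / 128) -
           truth)^2)))
  best <- which(sse == min(sse), arr.ind = TRUE)
  expect_equal(fit$intensity[fit$band == 1060], grid[best[1, 1]],
               tolerance = 0.25)
  expect_equal(fit$intensity[fit$band == 1085], grid[best[1, 2]],
               tolerance = 0.25)
})

test_that("reported intensity_se matches Monte-Carlo spread within 20%", {
  x <- seq(900, 1032, 1)
  truth <- 50 * exp(-(x - 971)^2 / (2 * 36))
  win <- fitWindowSpec(900, 1032, data.frame(center = 971, width = 6,
                                             amplitude = 40))
  set.seed(77)
  fits <- replicate(220, {
    f <- fitWindow(ramanSpectrum(x, truth + rnorm(length(x), 0, 0.5)), win)
    c(f$intensity, f$intensity_se)
  })
  empirical <- sd(fits[1, ])
  reported <- mean(fits[2, ])
  expect_lt(abs(empirical - reported) / reported, 0.20)
})

test_that("average-spectrum fits propagate the channel SE envelope", {
  # population of identical spectra: SE envelope 0 -> intensity_se ~ 0
  x <- seq(900, 1032, 1)
  y <- 50 * exp(-(x - 971)^2 / (2 * 36))
  set <- ramanSpectrumSet(x, cbind(y, y, y, y))
  avg <- averageSpectra(set)
  win <- fitWindowSpec(900, 1032, data.frame(center = 971, width = 6,
                                             amplitude = 40))
  f0 <- fitWindow(avg, win)
  expect_lt(f0$intensity_se, 1e-8)

  # iid noise: halving SE by quadrupling N halves the fitted SE
  set.seed(13)
  mk <- function(n) ramanSpectrumSet(x, vapply(seq_len(n), function(i)
    y + rnorm(length(x), 0, 1), numeric(length(x))))
  f1 <- fitWindow(averageSpectra(mk(40)), win)
  f2 <- fitWindow(averageSpectra(mk(160)), win)
  expect_equal(f2$intensity_se / f1$intensity_se, 0.5, tolerance = 0.25)
})

test_that("auto-fit pair recovers ratios and flags pure-noise pixels", {
  acq <- quietAcq()
  p2 <- cellTypeProfile("p", data.frame(center = c(1085, 1654),
                                        width = c(8, 11),
                                        amplitude = c(34, 68)),
                        interCellCV = 0, intraCellCV = 0)
  s <- sampleCellSpectrum(p2, acq, seed = 1)
  fit <- autoFitPair(s)
  expect_true(fit$valid)
  expect_equal(fit$numerator$intensity / fit$denominator$intensity, 2,
               tolerance = 1e-6)

  # doubling the 1654 amplitude doubles the fitted 1654 intensity
  p3 <- cellTypeProfile("p", data.frame(center = c(1085, 1654),
                                        width = c(8, 11),
                                        amplitude = c(34, 136)),
                        interCellCV = 0, intraCellCV = 0)
  fit3 <- autoFitPair(sampleCellSpectrum(p3, acq, seed = 1))
  expect_equal(fit3$numerator$intensity / fit$numerator$intensity, 2,
               tolerance = 1e-6)

  set.seed(5)
  noise <- ramanSpectrum(acq$grid, rnorm(length(acq$grid), 0, 1))
  expect_false(autoFitPair(noise)$valid)
})

test_that("window preconditions and degeneracy are enforced", {
  x <- seq(900, 910, 1)   # 11 points, too few for a 5-parameter fit
  s <- ramanSpectrum(x, exp(-(x - 905)^2 / 50))
  expect_error(fitWindow(s, fitWindowSpec(900, 910,
                                          data.frame(center = 905, width = 5,
                                                     amplitude = 1))),
               "points")
  expect_error(fitWindowSpec(1000, 900, data.frame(center = 950, width = 5,
                                                   amplitude = 1)))
  # two initial centers collapsing to the same position are flagged
  x2 <- seq(900, 1032, 1)
  s2 <- ramanSpectrum(x2, 40 * exp(-(x2 - 970)^2 / (2 * 36)))
  win2 <- fitWindowSpec(900, 1032,
                        data.frame(center = c(968, 972), width = c(6, 6),
                                   amplitude = c(20, 20)),
                        centerTolerance = 5)
  fit2 <- fitWindow(s2, win2)
  expect_true(any(fit2$degenerate))
})
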