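test_that("PIR value and SE follow the quadrature propagation formula", {
  p <- computePIR(mkPeak(971, 10, 1), mkPeak(1085, 5, 0.5))
  expect_equal(p$value, 2)
  expect_equal(p$se, 2 * sqrt(0.01 + 0.01), tolerance = 1e-12)

  p0 <- computePIR(mkPeak(971, 7, 0), mkPeak(1085, 7, 0))
  expect_equal(p0$value, 1)
  expect_equal(p0$se, 0)

  expect_error(computePIR(mkPeak(971, 10, 1), mkPeak(1085, 0, 0.5)),
               "denominator")
  bad <- mkPeak(971, 10, 1); bad$converged <- FALSE
  expect_error(computePIR(bad, mkPeak(1085, 5, 0.5)), "converged")
})

test_that("reciprocal PIRs multiply to 1 with identical relative SE", {
  a <- mkPeak(971, 23.7, 0.8); b <- mkPeak(1085, 41.2, 1.1)
  ab <- computePIR(a, b); ba <- computePIR(b, a)
  expect_equal(ab$value * ba$value, 1, tolerance = 1e-12)
  expect_equal(ab$se / ab$value, ba$se / ba$value, tolerance = 1e-12)
})

test_that("all-pairs enumeration gives C(k,2) canonical PIRs", {
  fits <- do.call(rbind, lapply(fingerprintBands()$center, function(b)
    mkPeak(b, 10 + b / 100, 0.1)))
  pirs <- allPairsPIRs(fits)
  expect_equal(nrow(pirs), choose(11, 2))
  expect_true(all(pirs$numerator < pirs$denominator))
  expect_false(anyDuplicated(paste(pirs$numerator, pirs$denominator)) > 0)

  two <- allPairsPIRs(rbind(mkPeak(971, 10, 0.1), mkPeak(1085, 20, 0.1)))
  expect_equal(nrow(two), 1)

  flipped <- reorientPIRs(two)
  expect_equal(flipped$value, 2)
  expect_equal(flipped$se / flipped$value, two$se / two$value,
               tolerance = 1e-12)
})

test_that("full discrimination requires strict pairwise interval separation", {
  expect_true(fullDiscrimination(1:4, rep(0.1, 4)))
  expect_false(fullDiscrimination(1:4, c(0.6, 0.6, 0.1, 0.1)))
  expect_false(fullDiscrimination(c(1, 2), c(0.5, 0.5)))  # touching fails
  # invariance under common rescaling
  v <- c(1.1, 2.3, 3.2, 4.9); s <- c(0.2, 0.3, 0.1, 0.4)
  expect_identical(fullDiscrimination(v, s),
                   fullDiscrimination(1e3 * v, 1e3 * s))
})

test_that("group stratification compares union intervals", {
  expect_true(groupStratification(c(1, 1.2, 2, 2.2), rep(0.1, 4), c(1, 2)))
  expect_false(groupStratification(c(1, 3, 2, 4), rep(0.01, 4), c(1, 2)))
  # full discrimination does not imply group stratification
  v <- c(1, 2, 1.5, 1.6); s <- c(0.1, 0.1, 0.05, 0.05)
  expect_true(fullDiscrimination(v, s))
  expect_false(groupStratification(v, s, c(1, 2)))
  expect_identical(groupStratification(7 * v, 7 * s, c(1, 2)),
                   groupStratification(v, s, c(1, 2)))
})

test_that("panels collect reference-band markers by discrimination class", {
  lines <- c("L1", "L2", "L3", "L4")
  groups <- list(g1 = c("L1", "L2"), g2 = c("L3", "L4"))
  mkRef <- function(vals, se = 0.01) {
    fits <- rbind(mkPeak(971, vals[1], se * vals[1]),
                  mkPeak(1085, vals[2], se * vals[2]),
                  mkPeak(1445, vals[3], se * vals[3]))
    allPairsPIRs(fits)
  }
  # 971 separates all lines; 1085 and 1445 are identical across lines
  refs <- list(L1 = mkRef(c(10, 50, 40)), L2 = mkRef(c(20, 50, 40)),
               L3 = mkRef(c(30, 50, 40)), L4 = mkRef(c(40, 50, 40)))
  panels <- suppressMessages(
    buildPanels(refs, referenceBands = c(971, 1085), groups = groups))
  e971 <- panelEntries(panels[["971"]])
  expect_equal(nrow(e971), 2)                  # 971/1085 and 971/1445
  expect_true(all(e971$class == "full"))
  # the 1085 panel only holds the pair involving 971
  e1085 <- panelEntries(panels[["1085"]])
  expect_equal(nrow(e1085), 1)
  expect_true(971 %in% c(e1085$numerator, e1085$denominator))

  # nothing discriminates -> empty panels
  refsNone <- list(L1 = mkRef(c(10, 50, 40), 0.5), L2 = mkRef(c(10, 50, 40), 0.5),
                   L3 = mkRef(c(10, 50, 40), 0.5), L4 = mkRef(c(10, 50, 40), 0.5))
  panels0 <- buildPanels(refsNone, referenceBands = c(971, 1085),
                         groups = groups)
  expect_equal(sum(vapply(panels0, function(p) nrow(panelEntries(p)),
                          integer(1))), 0)

  # panel entries are exactly the full+group markers involving the band
  expect_true(all(panelEntries(panels[["971"]])$class %in% c("full", "group")))
})

test_that("default reference bands give six panels that serialize losslessly", {
  profs <- referenceProfiles()
  panels <- buildReferencePanels(profs, nCells = 15, seed = 500)
  expect_length(panels, 6)
  expect_equal(as.numeric(names(panels)), c(932, 971, 1060, 1085, 1445, 1473))
  expect_true(all(vapply(panels, function(p) nrow(panelEntries(p)) > 0,
                         logical(1))))
  f <- withr::local_tempfile(fileext = ".json")
  writePanels(panels, f)
  back <- readPanels(f)
  expect_length(back, 6)
  expect_equal(panelEntries(back[[2]]), panelEntries(panels[[2]]),
               tolerance = 1e-12)
  expect_equal(panelLines(back[[1]]), panelLines(panels[[1]]))
})
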