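test_that("partition model evaluates, saturates and rejects bad input", {
  expect_equal(evaluatePartitionModel(4.6e6, 2.3, 1.0), 2.2745,
               tolerance = 1e-4)
  expect_identical(evaluatePartitionModel(4.6e6, 2.3, 0), 1)
  # monotone in lipid and in K, bounded by fMax
  lip <- c(0, 0.01, 0.1, 1, 10)
  v <- evaluatePartitionModel(4.6e6, 2.3, lip)
  expect_true(all(diff(v) > 0) && all(v <= 2.3))
  ks <- c(1e4, 1e5, 1e6, 1e7, 1e8)
  vk <- vapply(ks, evaluatePartitionModel, numeric(1), fMax = 2.3,
               lipidTotal = 0.5)
  expect_true(all(diff(vk) > 0))
  expect_error(evaluatePartitionModel(4.6e6, 1, 1), "fMax")
  expect_error(evaluatePartitionModel(NaN, 2.3, 1), "K")
})

test_that("partition fit round-trips generating parameters on noiseless data", {
  for (p in list(c(4.6e6, 2.3), c(1.1e7, 3.5), c(4.3e6, 2.7),
                 c(5e5, 1.5))) {
    f <- fitPartition(simPartitionTitration(p[1], p[2], noiseSd = 0))
    expect_equal(partitionCoef(f), p[1], tolerance = 1e-6)
    expect_equal(fMax(f), p[2], tolerance = 1e-6)
  }
})

test_that("partition fit labels model kind and flags degenerate series", {
  s <- simPartitionTitration(4.3e6, 2.7, noiseSd = 0,
                             responseKind = "max_intensity")
  expect_identical(fitPartition(s)@modelKind, "dequench")
  flat <- new("TitrationSeries",
              lipidTotal = c(0, 0.01, 0.1, 1),
              response = c(1, 1.001, 0.999, 1.002),
              responseKind = "intensity_at_320nm",
              availableFraction = 0.6, waterMolarity = 55.3)
  f <- fitPartition(flat)
  expect_true(f@degenerate)
  expect_true(is.finite(f@KLowerBound) && f@KLowerBound > 0)
  short <- new("TitrationSeries", lipidTotal = c(0, 1, 2),
               response = c(1, 2, 2.1),
               responseKind = "intensity_at_320nm",
               availableFraction = 0.6, waterMolarity = 55.3)
  expect_error(fitPartition(short), "at least 4")
  narrow <- new("TitrationSeries", lipidTotal = c(0, 0.5, 0.8, 1),
                response = c(1, 2, 2.1, 2.2),
                responseKind = "intensity_at_320nm",
                availableFraction = 0.6, waterMolarity = 55.3)
  expect_error(fitPartition(narrow), "decade")
})

test_that("estimator calibration: noisy replicates cover the generating K", {
  ks <- vapply(1:100, function(s)
    partitionCoef(fitPartition(
      simPartitionTitration(4.6e6, 2.3, noiseSd = 0.02, seed = s))),
    numeric(1))
  expect_true(abs(mean(ks) - 4.6e6) <= 2 * stats::sd(ks))
})

test_that("Stern-Volmer fit matches the closed-form least-squares slope", {
  f <- fitSternVolmer(simQuenchTitration(37.7, noiseSd = 0))
  expect_equal(quenchConstant(f), 37.7, tolerance = 1e-12)
  # normal-equations oracle on noisy data, intercept fixed at 1:
  # slope = sum(q (r - 1)) / sum(q^2)
  s <- simQuenchTitration(29.2, noiseSd = 0.05, seed = 7)
  q <- s@quencher; r <- s@ratio
  expect_equal(quenchConstant(fitSternVolmer(s)),
               sum(q * (r - 1)) / sum(q^2), tolerance = 1e-12)
  free <- fitSternVolmer(s, fixIntercept = FALSE)
  expect_false(free@interceptFixed)
  qq <- q - mean(q); rr <- r - mean(r)
  expect_equal(quenchConstant(free), sum(qq * rr) / sum(qq^2),
               tolerance = 1e-12)
  few <- new("QuenchSeries", quencher = c(0, 0.1), ratio = c(1, 2))
  expect_error(fitSternVolmer(few), "at least 3")
  offzero <- new("QuenchSeries", quencher = c(0.2, 0.25, 0.3),
                 ratio = c(2, 2.2, 2.4))
  expect_error(fitSternVolmer(offzero), "near zero")
})

test_that("blue shift detects identical, constructed and ~2 nm shifts", {
  a <- simEmissionSpectrum(lambdaMax = 350, noiseSd = 0)
  expect_equal(blueShift(a, a), 0)
  b <- simEmissionSpectrum(lambdaMax = 335, noiseSd = 0)
  expect_equal(blueShift(a, b), 15, tolerance = 1e-6)
  # weak-partitioner scenario: 2 nm maximal shift, saturating lipid
  aq <- simMembraneSpectrum(K = 4.3e6, lipidTotal = 0,
                            lambdaAqueous = 350, lambdaMembrane = 348,
                            fMax = 2.7, noiseSd = 0)
  mb <- simMembraneSpectrum(K = 4.3e6, lipidTotal = 10,
                            lambdaAqueous = 350, lambdaMembrane = 348,
                            fMax = 2.7, noiseSd = 0)
  expect_equal(blueShift(aq, mb), 2, tolerance = 0.25)
  flat <- new("EmissionSpectrum", wavelength = 300:310,
              intensity = rep(5, 11), lipidTotal = 0, quencher = 0,
              label = "")
  expect_error(blueShift(a, flat), "flat")
})

test_that("brominated-lipid quenching profile reports per-label ratios", {
  un <- simEmissionSpectrum(lambdaMax = 340, noiseSd = 0)
  same <- list("6,7-diBr" = un, "9,10-diBr" = un, "11,12-diBr" = un)
  expect_true(all(bromoQuenchProfile(un, same)@ratios == 1))

  quenchBy <- function(sp, f) new("EmissionSpectrum",
    wavelength = wavelengths(sp), intensity = intensities(sp) * f,
    lipidTotal = sp@lipidTotal, quencher = sp@quencher, label = "")
  lab <- list("6,7-diBr" = quenchBy(un, 0.8),
              "9,10-diBr" = quenchBy(un, 0.5),
              "11,12-diBr" = quenchBy(un, 0.7))
  pr <- bromoQuenchProfile(un, lab)
  expect_equal(unname(pr@ratios[["9,10-diBr"]]), 0.5)
  # strong-partitioner profile sits below a weak-partitioner profile at
  # every bromine depth
  strong <- list("6,7-diBr" = quenchBy(un, 0.45),
                 "9,10-diBr" = quenchBy(un, 0.35),
                 "11,12-diBr" = quenchBy(un, 0.5))
  weak <- list("6,7-diBr" = quenchBy(un, 0.9),
               "9,10-diBr" = quenchBy(un, 0.85),
               "11,12-diBr" = quenchBy(un, 0.95))
  expect_true(all(bromoQuenchProfile(un, strong)@ratios <
                  bromoQuenchProfile(un, weak)@ratios))
  expect_error(bromoQuenchProfile(un, lab[1:2]), "11,12-diBr")
})
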