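test_that("four-site inversion matches hand values and raises at the limits", {
  expect_equal(kdFourSite(0.0625, 224), 224, tolerance = 1e-12)
  expect_equal(kdFourSite((2 / 3)^4, 100), 200, tolerance = 1e-12)
  expect_error(kdFourSite(1, 224), "no detectable inhibition")
  expect_error(kdFourSite(0, 224), "complete block")
  expect_error(kdFourSite(0.5, 0), "positive")
})

test_that("forward and inverse occupancy models round-trip to 1e-10", {
  kds <- 10^seq(0, 6, length.out = 13)
  ts <- 10^seq(0, 5, length.out = 11)
  for (kd in kds) for (tt in ts) {
    fu <- fractionUnboundModel(kd, tt)
    expect_equal(kdFourSite(fu, tt), kd, tolerance = 1e-10)
  }
  # F_u decreases monotonically with concentration at fixed K_d
  expect_true(all(diff(fractionUnboundModel(224, ts)) < 0))
})

test_that("fraction unbound averages the weak-depolarization plateau", {
  same <- new("InhibitionSet", records = data.frame(
    cell_id = "c1", toxin_nM = 100, voltage_mV = c(-20, -10, 0, 10),
    I0_nA = 1000, I_nA = 1000))
  expect_equal(fractionUnbound(same)$F_u, 1)

  ex <- simInhibitionExperiment(224, toxinNM = 454, noiseSd = 0)
  fu <- fractionUnbound(ex)
  expect_equal(fu$F_u, (224 / 678)^4, tolerance = 1e-12)

  # a steep rise at the strongest depolarization is excluded, flagged runs
  # with increased current are reported
  steep <- new("InhibitionSet", records = data.frame(
    cell_id = "c1", toxin_nM = 100, voltage_mV = c(-20, -10, 0, 10),
    I0_nA = 1000, I_nA = c(100, 101, 102, 300)))
  out <- fractionUnbound(steep)
  expect_equal(out$n_voltages, 3L)
  expect_equal(out$F_u, mean(c(0.100, 0.101, 0.102)), tolerance = 1e-12)

  jagged <- new("InhibitionSet", records = data.frame(
    cell_id = "c1", toxin_nM = 100, voltage_mV = c(-20, -10, 0, 10),
    I0_nA = 1000, I_nA = c(100, 500, 100, 500)))
  expect_error(fractionUnbound(jagged), "plateau")

  outside <- new("InhibitionSet", records = data.frame(
    cell_id = "c1", toxin_nM = 100, voltage_mV = c(40, 60),
    I0_nA = 1000, I_nA = 500))
  expect_error(fractionUnbound(outside), "window")
})

test_that("per-cell K_d aggregation gives mean, SEM and n-of-1 flag", {
  one <- aggregateKd(224)
  expect_equal(kdNM(one), 224)
  expect_identical(kdSemNM(one), 0)
  expect_true(one@singleCell)

  two <- aggregateKd(c(200, 248))
  expect_equal(kdNM(two), 224)
  expect_equal(kdSemNM(two), 24)

  set.seed(42)
  cells <- 224 * (1 + stats::rnorm(13, sd = 0.1))
  est <- aggregateKd(cells)
  expect_lt(abs(kdNM(est) - 224), 2 * kdSemNM(est) + 1e-9)
  expect_identical(nCells(est), 13L)
})

test_that("DDG conversion reproduces published anchor values and is additive", {
  expect_equal(ddgFromKd(224, 224), 0)
  expect_equal(round(ddgFromKd(89033, 224), 2), 3.55)
  expect_equal(round(ddgFromKd(9641, 224), 2), 2.23)
  # additivity through a common reference, to machine precision
  a <- 123.4; b <- 4567.8; c <- 99.1
  expect_equal(ddgFromKd(a, b) + ddgFromKd(b, c), ddgFromKd(a, c),
               tolerance = 1e-14)
  expect_error(ddgFromKd(-1, 224), "below 0")
})

test_that("recomputing the alanine-scan table reproduces the published pairs", {
  tab <- gxtxScanTable()
  ddg <- buildDdgTable(tab, wtLabel = "GxTx-1E(Nle)")
  expect_equal(ddg@temperatureK, 298.15)
  res <- ddgValues(ddg)
  mut <- res[res$toxin != "GxTx-1E(Nle)", ]
  pub <- tab[tab$toxin != "GxTx-1E(Nle)", ]
  okRatio <- abs(mut$ratio - pub$ratio) <= 0.1 + 1e-9
  okDdg <- abs(mut$ddg_kcal_mol - pub$ddg_kcal_mol) <= 0.02 + 1e-9
  expect_identical(nrow(mut), 28L)
  expect_gte(sum(okRatio & okDdg), 25L)
})

test_that("concentration-response fit agrees with inversion and recovers K_d", {
  single <- fitConcentrationResponse(0.0625, 224)
  expect_identical(single$kd, kdFourSite(0.0625, 224))
  ts <- c(50, 150, 450, 1350, 4050)
  fu <- fractionUnboundModel(500, ts)
  f <- fitConcentrationResponse(fu, ts)
  expect_equal(f$kd, 500, tolerance = 1e-6)
  # calibration over noisy replicates
  # 5% per-current noise makes I/I0 scatter by ~7%, so the plateau filter
  # is opened to 25% to accept the full voltage set
  kds <- vapply(1:100, function(s) {
    ex <- simInhibitionExperiment(224, toxinNM = c(50, 150, 450, 1350),
                                  noiseSd = 0.05, seed = s)
    g <- fractionUnbound(ex, plateauTolerance = 0.25)
    fitConcentrationResponse(g$F_u, g$toxin_nM)$kd
  }, numeric(1))
  expect_lt(abs(mean(kds) / 224 - 1), 0.05)
  expect_error(fitConcentrationResponse(c(0.5, 1.2), c(10, 20)),
               "inside")
})

test_that("G-V normalization and Boltzmann summary behave", {
  v <- seq(-60, 60, by = 10)
  g <- 1 / (1 + exp(-(v - 0) / 10))
  gv <- gvFromTails(v, g * 3.2)  # arbitrary tail amplitude scale
  expect_equal(gv@vHalf, 0, tolerance = 1e-6)
  expect_equal(gv@slope, 10, tolerance = 1e-6)
  const <- gvFromTails(v, rep(2, length(v)))
  expect_true(const@degenerate)
  expect_true(all(const@conductance == 1))
  expect_error(gvFromTails(v, rep(0, length(v))), "zero")
  # a depolarizing-shift phenotype moves V1/2 rightward
  shifted <- gvFromTails(v, 1 / (1 + exp(-(v - 25) / 10)))
  expect_gt(shifted@vHalf, gv@vHalf)
})
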