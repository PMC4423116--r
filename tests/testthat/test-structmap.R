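test_that("Kabsch superposition recovers identity and known rigid motions", {
  set.seed(1)
  p <- matrix(rnorm(18, sd = 4), 6, 3)
  id <- kabschSuperpose(p, p)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(rotation(id$transform), diag(3), tolerance = 1e-10)

  th <- 30 * pi / 180
  R30 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  q <- p %*% t(R30) + matrix(c(5, -2, 7), 6, 3, byrow = TRUE)
  fit <- kabschSuperpose(p, q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(rotation(fit$transform), R30, tolerance = 1e-10)
  # the recovered transform inverts the constructed motion
  back <- applyTransform(invertTransform(fit$transform), q)
  expect_equal(back, p, tolerance = 1e-10)

  expect_error(kabschSuperpose(p, p[1:5, ]), "matching dimensions")
})

test_that("superposed RMSD equals brute-force rotational minimization", {
  set.seed(7)
  # six cystine-like Calpha pairs with 1 A isotropic jitter
  p <- matrix(rnorm(18, sd = 5), 6, 3)
  q <- p %*% t(randomSmallRotation(0.9)) + matrix(rnorm(18, sd = 1), 6, 3)
  fit <- kabschSuperpose(p, q)
  expect_equal(fit$rmsd, bruteForceRmsd(p, q), tolerance = 1e-3)
})

test_that("no rotation perturbation improves the superposition", {
  set.seed(11)
  p <- matrix(rnorm(15, sd = 3), 5, 3)
  q <- p %*% t(randomSmallRotation(0.5)) +
    matrix(rnorm(15, sd = 0.8), 5, 3)
  fit <- kabschSuperpose(p, q)
  base <- fit$rmsd
  cp <- colMeans(p); cq <- colMeans(q)
  Pc <- sweep(p, 2, cp); Qc <- sweep(q, 2, cq)
  R0 <- rotation(fit$transform)
  worse <- vapply(seq_len(1000), function(i) {
    Rp <- randomSmallRotation(stats::runif(1, 1e-4, 0.3)) %*% R0
    sqrt(mean(rowSums((Pc %*% t(Rp) - Qc)^2)))
  }, numeric(1))
  expect_true(all(worse >= base - 1e-12))
})

test_that("SASA quadrature matches the analytic sphere and is additive", {
  one <- carbonModel(matrix(0, 1, 3))
  s1 <- shrakeRupleySasa(one, probe = 1.4, nPoints = 960)
  expect_equal(totalSasa(s1), 4 * pi * 3.1^2, tolerance = 0.01)

  far <- carbonModel(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(totalSasa(shrakeRupleySasa(far, nPoints = 960)),
               2 * 4 * pi * 3.1^2, tolerance = 0.01)

  # coincident duplicate atoms: the later copy is fully occluded
  dup <- carbonModel(rbind(c(0, 0, 0), c(0, 0, 0)))
  sd2 <- shrakeRupleySasa(dup, nPoints = 960)
  expect_equal(totalSasa(sd2), 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(atomSasa(sd2)$sasa[2], 0)

  # per-residue sums equal per-atom sums; doubling points barely moves totals
  toy <- simToyComplex(helixLength = 8, toxinAtomCount = 12,
                       placementOffset = c(8, 0, 0))
  r1 <- shrakeRupleySasa(toy, nPoints = 480)
  expect_equal(sum(residueSasa(r1)$sasa), sum(atomSasa(r1)$sasa),
               tolerance = 1e-9)
  r2 <- shrakeRupleySasa(toy, nPoints = 960)
  expect_lt(abs(totalSasa(r2) - totalSasa(r1)) / totalSasa(r2), 0.01)
})

test_that("interface burial is zero out of contact and matches the grid oracle", {
  apart <- simToyComplex(helixLength = 8, toxinAtomCount = 12,
                         placementOffset = c(40, 0, 0))
  d0 <- deltaSasa(apart, "B", nPoints = 960)
  expect_true(all(abs(d0@residues$dsasa) < 1e-6))

  touch <- simToyComplex(helixLength = 8, toxinAtomCount = 12,
                         placementOffset = c(7, 0, 0))
  dt <- deltaSasa(touch, "B", nPoints = 960)
  expect_true(any(dt@residues$dsasa > 1))
  expect_true(all(dt@residues$dsasa > -1e-6))

  # independent latitude-longitude quadrature oracle, complex minus free
  a <- atoms(touch)
  free <- new("StructureModel", atoms = a[a$chain == "B", ])
  oracleFree <- gridResidueSasa(free)
  oracleCplx <- gridResidueSasa(touch)
  keys <- paste(dt@residues$chain, dt@residues$resno)
  oracle <- oracleFree[keys] - oracleCplx[keys]
  scale <- max(oracleFree)
  expect_lt(max(abs(dt@residues$dsasa - oracle)) / scale, 0.02)

  # both components' burials sum to the total buried area
  dh <- deltaSasa(touch, "A", nPoints = 960)
  sFree <- totalSasa(shrakeRupleySasa(free, nPoints = 960)) +
    totalSasa(shrakeRupleySasa(
      new("StructureModel", atoms = a[a$chain == "A", ]), nPoints = 960))
  sCplx <- totalSasa(shrakeRupleySasa(touch, nPoints = 960))
  expect_equal(sum(dt@residues$dsasa) + sum(dh@residues$dsasa),
               sFree - sCplx, tolerance = 1e-6)

  expect_error(deltaSasa(touch, "Z"), "not present")
  expect_error(deltaSasa(touch, character(0)), "at least one")
})

test_that("hydrophobic patch area clusters contacting residues only", {
  # three single-atom residues: two in contact, one remote
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(30, 0, 0))
  m <- carbonModel(xyz, resno = 1:3)
  sasa <- shrakeRupleySasa(m, nPoints = 960)
  res <- data.frame(chain = "A", resno = 1:3)
  area <- hydrophobicPatchArea(m, res, sasa)
  expect_equal(as.numeric(area),
               sum(residueSasa(sasa)$sasa[1:2]), tolerance = 1e-9)
  expect_setequal(attr(area, "members"), c("A 1", "A 2"))

  single <- hydrophobicPatchArea(m, data.frame(chain = "A", resno = 3),
                                 sasa)
  expect_equal(as.numeric(single), residueSasa(sasa)$sasa[3],
               tolerance = 1e-9)
  expect_error(
    hydrophobicPatchArea(m, data.frame(chain = "A", resno = 9), sasa),
    "disjoint")
})

test_that("helix axis estimation recovers the construction axis", {
  ca <- caCoords(simToyComplex(helixLength = 12), "A", 1:12)
  ax <- helixAxis(ca)
  expect_equal(abs(sum(ax$direction * c(0, 0, 1))), 1, tolerance = 1e-4)
  expect_gt(sum(ax$direction * c(0, 0, 1)), 0)  # oriented 1 -> n
  expect_error(helixAxis(ca[1:3, ]), "at least 4")
})

test_that("register grafting composes as a one-parameter screw family", {
  toxin <- simToyComplex(helixLength = 9, toxinAtomCount = 16,
                         placementOffset = c(9, 0, 0),
                         helixChain = "H", toxinChain = "X")
  target <- simToyComplex(helixLength = 15, toxinAtomCount = 4,
                          placementOffset = c(60, 0, 0),
                          helixChain = "T", toxinChain = "U")
  g0 <- graftByRegister(toxin, target, "H", 1:9, "T", 4:12, offset = 0)
  # offset 0 equals the direct superposition of the template onto the target
  direct <- kabschSuperpose(caCoords(toxin, "H", 1:9),
                            caCoords(target, "T", 4:12))$transform
  expect_equal(rotation(graftTransform(g0)), rotation(direct),
               tolerance = 1e-8)
  expect_equal(translation(graftTransform(g0)), translation(direct),
               tolerance = 1e-8)

  gp <- graftByRegister(toxin, target, "H", 1:9, "T", 4:12, offset = 1)
  gm <- graftByRegister(toxin, target, "H", 1:9, "T", 4:12, offset = -1)
  # stepping +1 then -1 returns the base placement
  ax <- helixAxis(caCoords(target, "T", 4:12))
  stepBack <- invertTransform(
    ToxinScan:::.screwTransform(ax$point, ax$direction, 100, 1.5))
  roundTrip <- composeTransforms(stepBack, graftTransform(gp))
  x <- coords(toxin)
  expect_lt(max(abs(applyTransform(roundTrip, x) -
                    applyTransform(graftTransform(g0), x))), 1e-8)

  # offset +1 equals the independently composed screw o base transform
  stepFwd <- ToxinScan:::.screwTransform(ax$point, ax$direction, 100, 1.5)
  expected <- composeTransforms(stepFwd, direct)
  expect_lt(max(abs(applyTransform(graftTransform(gp), x) -
                    applyTransform(expected, x))), 1e-8)
  # and the -1 frame is its inverse step
  expectedM <- composeTransforms(invertTransform(stepFwd), direct)
  expect_lt(max(abs(applyTransform(graftTransform(gm), x) -
                    applyTransform(expectedM, x))), 1e-8)
  # the toxin centroid moves by the screw motion between frames
  c0 <- colMeans(coords(g0@structure)[g0@structure@atoms$chain == "X", ])
  c1 <- colMeans(coords(gp@structure)[gp@structure@atoms$chain == "X", ])
  expect_equal(unname(c1), as.vector(applyTransform(stepFwd, unname(c0))),
               tolerance = 1e-8)

  expect_error(graftByRegister(toxin, target, "H", 1:9, "T", 4:11),
               "equal length")
})

test_that("clash screening counts constructed contacts deterministically", {
  sep <- simToyComplex(placementOffset = c(40, 0, 0))
  expect_identical(detectClashes(sep, "A", "B")$count, 0L)

  two <- new("StructureModel", atoms = data.frame(
    chain = c("A", "B"), resno = 1L, resid = "UNK",
    elety = "CA", element = "C",
    x = c(0, 1), y = 0, z = 0, radius = 1.7))
  hit <- detectClashes(two, "A", "B", cutoff = 2.5)
  expect_identical(hit$count, 1L)
  expect_equal(hit$pairs$distance, 1)
})

test_that("only register frames built to collide are flagged", {
  toxin <- simToyComplex(helixLength = 9, toxinAtomCount = 16,
                         placementOffset = c(9, 0, 0),
                         helixChain = "H", toxinChain = "X")
  # a 9-residue target helix that the template replaces in full, so no
  # leftover helix residues can collide with the grafted segment
  target <- simToyComplex(helixLength = 9, toxinAtomCount = 4,
                          placementOffset = c(60, 0, 0),
                          helixChain = "T", toxinChain = "U")
  # obstacle atoms exactly on a toxin atom position of frames +1 and -1
  ax <- helixAxis(caCoords(target, "T", 1:9))
  base <- kabschSuperpose(caCoords(toxin, "H", 1:9),
                          caCoords(target, "T", 1:9))$transform
  step <- ToxinScan:::.screwTransform(ax$point, ax$direction, 100, 1.5)
  firstX <- coords(toxin)[atoms(toxin)$chain == "X", ][1, ]
  obstacle <- rbind(
    applyTransform(composeTransforms(step, base), firstX),
    applyTransform(composeTransforms(invertTransform(step), base),
                   firstX))
  aug <- new("StructureModel", atoms = rbind(
    atoms(target),
    data.frame(chain = "W", resno = 1:2, resid = "OBS", elety = "CA",
               element = "C", x = obstacle[, 1], y = obstacle[, 2],
               z = obstacle[, 3], radius = 1.7)))
  flagged <- vapply(-2:2, function(k)
    clashCount(graftByRegister(toxin, aug, "H", 1:9, "T", 1:9,
                               offset = k)) > 0, logical(1))
  expect_identical(flagged, c(FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("interface residues respect and shrink with the threshold", {
  toy <- simToyComplex(helixLength = 8, toxinAtomCount = 12,
                       placementOffset = c(40, 0, 0))
  far <- interfaceResidues(toy, "A", "B", threshold = 12)
  expect_identical(nrow(far$a), 0L)
  expect_identical(nrow(far$b), 0L)

  near <- simToyComplex(helixLength = 8, toxinAtomCount = 12,
                        placementOffset = c(8, 0, 0))
  sets <- lapply(c(20, 12, 6), function(th)
    interfaceResidues(near, "A", "B", threshold = th))
  for (i in 2:3) {
    prev <- paste(sets[[i - 1]]$a$chain, sets[[i - 1]]$a$resno)
    cur <- paste(sets[[i]]$a$chain, sets[[i]]$a$resno)
    expect_true(all(cur %in% prev))
  }
  # known contacts: every helix residue within 12 A of the toxin shell
  d <- sets[[2]]
  expect_true(all(d$a$min_distance <= 12))
})
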