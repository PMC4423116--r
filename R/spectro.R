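#' @include AllClasses.R
NULL

#' Bound fraction under the mole-fraction partition equilibrium
#'
#' Fraction of peptide partitioned into the membrane,
#' \eqn{K [L] / ([W] + K [L])}, with [L] the available lipid concentration
#' in molar (\code{availableFraction} times the total) and [W] the molarity
#' of water.
#'
#' @param K Mole-fraction partition coefficient (> 0).
#' @param lipidTotal Total lipid concentration(s) in mM (>= 0).
#' @param availableFraction Fraction of total lipid available (default 0.60).
#' @param waterMolarity Molarity of water (default 55.3 M).
#' @return Bound fraction(s) in [0, 1).
#' @export
partitionBoundFraction <- function(K, lipidTotal, availableFraction = 0.60,
                                   waterMolarity = 55.3) {
  .assertNumber(K, "K", 0, strict = TRUE, upper = Inf)
  .assertNumeric(lipidTotal, "lipidTotal", lower = 0)
  .assertNumber(availableFraction, "availableFraction", 0, 1)
  if (availableFraction == 0)
    stop("'availableFraction' must be positive", call. = FALSE)
  .assertNumber(waterMolarity, "waterMolarity", 0, strict = TRUE,
                upper = Inf)
  lM <- availableFraction * lipidTotal / 1000  # mM total -> M available
  K * lM / (waterMolarity + K * lM)
}

#' Evaluate the mole-fraction partition model
#'
#' The fluorescence response to membrane partitioning,
#' \deqn{F/F_0(L) = 1 + (F/F_0^{max} - 1)\, K [L]/([W] + K [L]),}
#' where [L] is the available lipid concentration in molar and [W] the
#' molarity of water. Returns 1 at zero lipid, increases monotonically with
#' lipid and saturates at \code{fMax}.
#'
#' @inheritParams partitionBoundFraction
#' @param fMax Maximal relative fluorescence F/F0max (> 1).
#' @return F/F0 value(s).
#' @examples
#' evaluatePartitionModel(4.6e6, 2.3, 1.0)  # ~2.27 at 1 mM total lipid
#' @export
evaluatePartitionModel <- function(K, fMax, lipidTotal,
                                   availableFraction = 0.60,
                                   waterMolarity = 55.3) {
  .assertNumber(fMax, "fMax", 1, strict = TRUE, upper = Inf)
  1 + (fMax - 1) * partitionBoundFraction(K, lipidTotal,
                                          availableFraction, waterMolarity)
}

#' Fit a mole-fraction partition coefficient to a titration
#'
#' Damped least-squares (Levenberg-Marquardt) fit of the partition model to
#' an F/F0 titration, parameterized in log10(K) for conditioning, with a
#' multi-start around an initial K taken from the lipid concentration at
#' half-maximal response. The fitted constant is K_x for
#' intensity-at-320-nm series (\code{modelKind = "partition"}) and K_dx for
#' dequenching maximum-intensity series (\code{modelKind = "dequench"}).
#'
#' Titrations whose responses never leave 1 (no partitioning signal) are
#' flagged degenerate: no K is reported, only a lower bound (the K at which
#' the model would have produced a response exceeding the observed spread
#' at the largest lipid concentration).
#'
#' @param series A \linkS4class{TitrationSeries}, responses normalized so
#'   response(0) = 1; at least 4 points spanning at least one decade of
#'   non-zero lipid.
#' @param modelKind \code{"partition"} or \code{"dequench"}; defaults to
#'   the label implied by the series' response kind.
#' @param signalThreshold Minimum excess response max(F/F0) - 1 below which
#'   the fit is flagged degenerate (default 0.05).
#' @return A \linkS4class{PartitionFit}.
#' @examples
#' s <- simPartitionTitration(K = 4.6e6, fMax = 2.3, noiseSd = 0)
#' fitPartition(s)
#' @export
fitPartition <- function(series,
                         modelKind = c("partition", "dequench"),
                         signalThreshold = 0.05) {
  stopifnot(is(series, "TitrationSeries"))
  if (missing(modelKind))
    modelKind <- if (series@responseKind == "max_intensity")
      "dequench" else "partition"
  modelKind <- match.arg(modelKind, c("partition", "dequench"))
  l <- series@lipidTotal
  y <- series@response
  pos <- l[l > 0]
  if (length(l) < 4L)
    stop("need at least 4 titration points", call. = FALSE)
  if (length(pos) < 2L || max(pos) / min(pos) < 10)
    stop("titration must span at least one decade of non-zero lipid",
         call. = FALSE)
  af <- series@availableFraction
  w <- series@waterMolarity
  if (max(y) - 1 < signalThreshold) {
    # no signal: the largest K still consistent with a flat series
    lMaxM <- af * max(pos) / 1000
    kLower <- w * signalThreshold / lMaxM  # K s.t. bound fraction ~ thr
    return(new("PartitionFit", K = NA_real_, fMax = NA_real_,
               KStderr = NA_real_, fMaxStderr = NA_real_,
               rss = sum((y - 1)^2), nPoints = length(y),
               modelKind = modelKind, degenerate = TRUE,
               KLowerBound = kLower))
  }
  # initial K from the lipid concentration at half-maximal response
  half <- 1 + (max(y) - 1) / 2
  lHalf <- pos[which.min(abs(y[l > 0] - half))]
  k0 <- w / (af * lHalf / 1000)
  fm0 <- max(y)
  fits <- list()
  for (fac in c(0.1, 1, 10)) {
    st <- list(lk = log10(k0 * fac), fm = max(fm0, 1.01))
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 1 + (fm - 1) * (10^lk * af * l / 1000) /
          (w + 10^lk * af * l / 1000),
        start = st, lower = c(lk = 0, fm = 1 + 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits))
    stop("partition fit failed to converge from all starts (n = ",
         length(y), " points; response range ",
         sprintf("%.3g-%.3g", min(y), max(y)), ")", call. = FALSE)
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  co <- summary(best)$coefficients
  K <- 10^co["lk", "Estimate"]
  KSe <- log(10) * K * co["lk", "Std. Error"]  # delta method from log10 K
  new("PartitionFit", K = K, fMax = co["fm", "Estimate"],
      KStderr = KSe, fMaxStderr = co["fm", "Std. Error"],
      rss = min(rss), nPoints = length(y), modelKind = modelKind,
      degenerate = FALSE, KLowerBound = NA_real_)
}

#' Fit a Stern-Volmer quenching constant
#'
#' Linear least-squares fit of \eqn{F_0/F = 1 + K_{sv} [Q]}. By default the
#' intercept is fixed at 1, as the quenching relation requires; a
#' free-intercept mode is available as a diagnostic for offset artefacts.
#'
#' @param series A \linkS4class{QuenchSeries} with at least 3 points
#'   including a near-zero quencher concentration.
#' @param fixIntercept Fix the intercept at 1 (default TRUE).
#' @return A \linkS4class{SternVolmerFit}.
#' @examples
#' fitSternVolmer(simQuenchTitration(37.7, noiseSd = 0))
#' @export
fitSternVolmer <- function(series, fixIntercept = TRUE) {
  stopifnot(is(series, "QuenchSeries"))
  q <- series@quencher
  r <- series@ratio
  if (length(q) < 3L)
    stop("need at least 3 quenching points", call. = FALSE)
  if (min(q) > 0.25 * max(q))
    stop("series must include a quencher concentration near zero",
         call. = FALSE)
  if (fixIntercept) {
    fit <- stats::lm(I(r - 1) ~ 0 + q)
    co <- suppressWarnings(summary(fit))$coefficients
    new("SternVolmerFit", ksv = unname(co[1, 1]), intercept = 1,
        ksvStderr = unname(co[1, 2]),
        rss = sum(stats::residuals(fit)^2), interceptFixed = TRUE)
  } else {
    fit <- stats::lm(r ~ q)
    co <- suppressWarnings(summary(fit))$coefficients
    new("SternVolmerFit", ksv = unname(co["q", 1]),
        intercept = unname(co["(Intercept)", 1]),
        ksvStderr = unname(co["q", 2]),
        rss = sum(stats::residuals(fit)^2), interceptFixed = FALSE)
  }
}

#' Locate an emission peak by quadratic interpolation
#'
#' Finds the grid argmax (ties broken toward the lower wavelength) and
#' refines it with a parabola through the three surrounding points, giving
#' sub-grid resolution needed to resolve shifts of ~2 nm on a 1 nm grid.
#' Peaks at a grid boundary are returned at the boundary point.
#'
#' @param spectrum An \linkS4class{EmissionSpectrum}.
#' @return Peak wavelength in nm.
#' @export
peakWavelength <- function(spectrum) {
  stopifnot(is(spectrum, "EmissionSpectrum"))
  y <- spectrum@intensity
  x <- spectrum@wavelength
  if (length(y) < 1L || max(y) - min(y) <= 0)
    stop("spectrum is flat: no unique emission peak", call. = FALSE)
  i <- which.max(y)  # which.max takes the first (lowest-wavelength) tie
  if (i == 1L || i == length(y)) return(x[i])
  # parabola through (x[i-1], x[i], x[i+1]); vertex offset in grid units
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) return(x[i])
  d <- 0.5 * (y0 - y2) / denom
  x[i] + d * (x[i + 1L] - x[i])
}

#' Blue shift between two emission spectra
#'
#' Returns \code{peakWavelength(reference) - peakWavelength(test)}: positive
#' when the test spectrum is blue-shifted (peak at lower wavelength) relative
#' to the reference, as upon transfer of tryptophan into the membrane.
#'
#' @param reference,test \linkS4class{EmissionSpectrum} objects on
#'   overlapping grids.
#' @return Shift in nm.
#' @examples
#' aq <- simEmissionSpectrum(lambdaMax = 350, noiseSd = 0)
#' mb <- simEmissionSpectrum(lambdaMax = 335, noiseSd = 0)
#' blueShift(aq, mb)  # 15
#' @export
blueShift <- function(reference, test) {
  stopifnot(is(reference, "EmissionSpectrum"), is(test, "EmissionSpectrum"))
  if (max(reference@wavelength) < min(test@wavelength) ||
      max(test@wavelength) < min(reference@wavelength))
    stop("spectra do not share an overlapping wavelength range",
         call. = FALSE)
  peakWavelength(reference) - peakWavelength(test)
}

#' Depth-dependent quenching profile from brominated lipids
#'
#' Ratios of labeled-vesicle to unlabeled-vesicle intensity evaluated at the
#' unlabeled condition's emission maximum, one ratio per bromine position on
#' the acyl chain. Lower ratios indicate stronger quenching by the bromines
#' at that bilayer depth.
#'
#' @param unlabeled \linkS4class{EmissionSpectrum} recorded with unlabeled
#'   vesicles.
#' @param labeled Named list of \linkS4class{EmissionSpectrum} objects for
#'   labels \code{"6,7-diBr"}, \code{"9,10-diBr"} and \code{"11,12-diBr"};
#'   all on the same grid as \code{unlabeled}.
#' @return A \linkS4class{BromoQuenchProfile}.
#' @export
bromoQuenchProfile <- function(unlabeled, labeled) {
  stopifnot(is(unlabeled, "EmissionSpectrum"))
  need <- c("6,7-diBr", "9,10-diBr", "11,12-diBr")
  miss <- setdiff(need, names(labeled))
  if (length(miss))
    stop("missing labeled spectra for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (lab in need) {
    sp <- labeled[[lab]]
    stopifnot(is(sp, "EmissionSpectrum"))
    if (!isTRUE(all.equal(sp@wavelength, unlabeled@wavelength)))
      stop("labeled spectrum '", lab,
           "' is not on the unlabeled spectrum's grid", call. = FALSE)
  }
  i <- which.max(unlabeled@intensity)
  ratios <- vapply(need, function(lab)
    labeled[[lab]]@intensity[i] / unlabeled@intensity[i], numeric(1))
  new("BromoQuenchProfile", ratios = ratios,
      lambdaMax = unlabeled@wavelength[i])
}
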