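#' @include AllClasses.R
NULL

# gas constant in kcal / (mol K)
.RGAS <- 1.9872e-3

#' Fraction unbound from paired steady-state currents
#'
#' For each (cell, toxin concentration) group, computes per-voltage current
#' ratios I/I0 inside the weak-depolarization window, checks that the
#' ratios form a plateau (longest run of adjacent voltages whose relative
#' change stays below \code{plateauTolerance}), and averages the plateau
#' values into a single fraction unbound F_u. Ratios above
#' \code{1 + plateauTolerance} (current increased on toxin) are reported
#' and flagged, never silently clipped.
#'
#' @param x An \linkS4class{InhibitionSet}.
#' @param plateauTolerance Maximum relative change in I/I0 between adjacent
#'   voltages for both to count as plateau (default 0.10).
#' @param voltageWindow Weak-depolarization window in mV (default
#'   \code{c(-20, 10)}).
#' @return data.frame with one row per (cell, concentration): columns
#'   \code{cell_id}, \code{toxin_nM}, \code{F_u}, \code{n_voltages},
#'   \code{flagged}.
#' @examples
#' ex <- simInhibitionExperiment(224, toxinNM = 454, noiseSd = 0)
#' fractionUnbound(ex)
#' @export
fractionUnbound <- function(x, plateauTolerance = 0.10,
                            voltageWindow = c(-20, 10)) {
  stopifnot(is(x, "InhibitionSet"))
  .assertNumber(plateauTolerance, "plateauTolerance", 0, strict = TRUE,
                upper = Inf)
  rec <- x@records
  rec <- rec[rec$voltage_mV >= voltageWindow[1] &
             rec$voltage_mV <= voltageWindow[2], , drop = FALSE]
  if (!nrow(rec))
    stop("no records inside the weak-depolarization window", call. = FALSE)
  groups <- split(rec, list(rec$cell_id, rec$toxin_nM), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$voltage_mV), , drop = FALSE]
    fu <- g$I_nA / g$I0_nA
    flagged <- any(fu > 1 + plateauTolerance)
    keep <- .plateauRun(fu, plateauTolerance)
    if (!length(keep))
      stop(sprintf(
        "no plateau in I/I0 across voltages for cell %s at %g nM",
        g$cell_id[1], g$toxin_nM[1]), call. = FALSE)
    data.frame(cell_id = g$cell_id[1], toxin_nM = g$toxin_nM[1],
               F_u = mean(fu[keep]), n_voltages = length(keep),
               flagged = flagged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cell_id, res$toxin_nM), , drop = FALSE]
}

# indices of the longest run of adjacent values whose relative change stays
# within tol; a single measured voltage is accepted as-is, but with several
# voltages at least two must agree or there is no plateau (empty result)
.plateauRun <- function(fu, tol) {
  n <- length(fu)
  if (n == 1L) return(1L)
  ok <- abs(diff(fu)) / pmax(abs(fu[-n]), .Machine$double.eps) <= tol
  best <- integer(0)
  start <- 1L
  for (i in seq_len(n - 1L)) {
    if (!ok[i]) start <- i + 1L
    run <- start:(i + 1L)
    if (length(run) > length(best) && length(run) >= 2L) best <- run
  }
  best
}

#' Apparent K_d from fraction unbound under the independent-sites model
#'
#' Algebraic inversion of the occupancy model
#' \eqn{F_u = (K_d/(K_d+[T]))^n} (default n = 4 independent binding sites
#' per channel, single occupancy sufficient to prevent opening at weak
#' depolarizations):
#' \deqn{K_d = \left(\frac{1}{1 - F_u^{1/n}} - 1\right)[T].}
#'
#' @param fu Fraction unbound, strictly inside (0, 1).
#' @param toxinNM Toxin concentration in nM (> 0).
#' @param nSites Number of independent binding sites (default 4).
#' @return Apparent K_d in nM (vectorized over \code{fu}/\code{toxinNM}).
#' @examples
#' kdFourSite(0.0625, 224)  # 224
#' @export
kdFourSite <- function(fu, toxinNM, nSites = 4L) {
  if (any(!is.finite(fu)))
    stop("fraction unbound must be finite", call. = FALSE)
  if (any(fu >= 1))
    stop("F_u >= 1: no detectable inhibition, K_d is undefined",
         call. = FALSE)
  if (any(fu <= 0))
    stop("F_u <= 0: complete block, K_d is not identifiable",
         call. = FALSE)
  .assertNumeric(toxinNM, "toxinNM", lower = 0)
  if (any(toxinNM <= 0))
    stop("toxin concentration must be positive", call. = FALSE)
  if (nSites < 1L) stop("nSites must be >= 1", call. = FALSE)
  (1 / (1 - fu^(1 / nSites)) - 1) * toxinNM
}

#' Forward occupancy model: fraction unbound at a toxin concentration
#'
#' \eqn{F_u = (K_d/(K_d+[T]))^n}; the inverse of \code{\link{kdFourSite}}.
#'
#' @param kdNM Per-site K_d in nM (> 0).
#' @param toxinNM Toxin concentration(s) in nM (>= 0).
#' @param nSites Number of independent sites (default 4).
#' @return Fraction unbound in (0, 1].
#' @export
fractionUnboundModel <- function(kdNM, toxinNM, nSites = 4L) {
  .assertNumeric(kdNM, "kdNM", lower = 0)
  if (any(kdNM <= 0)) stop("kdNM must be positive", call. = FALSE)
  .assertNumeric(toxinNM, "toxinNM", lower = 0)
  (kdNM / (kdNM + toxinNM))^nSites
}

#' Aggregate per-cell K_d values
#'
#' Mean and standard error of the mean across cells (n - 1 denominator).
#' With a single cell the SEM is undefined; it is reported as 0 with the
#' \code{singleCell} flag set.
#'
#' @param kd Numeric vector of per-cell K_d values in nM.
#' @param label Toxin label stored on the estimate.
#' @return A \linkS4class{KdEstimate}.
#' @examples
#' aggregateKd(c(200, 248))  # mean 224, SEM 24
#' @export
aggregateKd <- function(kd, label = "") {
  .assertNumeric(kd, "kd", lower = 0)
  if (any(kd <= 0)) stop("K_d values must be positive", call. = FALSE)
  n <- length(kd)
  sem <- if (n == 1L) 0 else stats::sd(kd) / sqrt(n)
  new("KdEstimate", label = label, kdNM = mean(kd), kdSemNM = sem,
      nCells = n, singleCell = n == 1L)
}

#' Binding free-energy perturbation from a K_d ratio
#'
#' \eqn{\Delta\Delta G = R T \ln(K_d^{mut} / K_d^{wt})} in kcal/mol, with
#' R = 1.9872e-3 kcal/(mol K). The default temperature of 298.15 K is the
#' convention under which published alanine-scan tables for these toxins
#' reproduce from their K_d columns.
#'
#' @param kdMut Mutant K_d (nM), positive; vectorized.
#' @param kdWt Wild-type K_d (nM), positive.
#' @param temperatureK Temperature in K (default 298.15).
#' @return DDG in kcal/mol (same length as \code{kdMut}).
#' @examples
#' ddgFromKd(89033, 224)  # ~3.55 kcal/mol
#' @export
ddgFromKd <- function(kdMut, kdWt, temperatureK = 298.15) {
  .assertNumeric(kdMut, "kdMut", lower = 0)
  .assertNumber(kdWt, "kdWt", 0, strict = TRUE, upper = Inf)
  .assertNumber(temperatureK, "temperatureK", 0, strict = TRUE, upper = Inf)
  if (any(kdMut <= 0)) stop("kdMut must be positive", call. = FALSE)
  .RGAS * temperatureK * log(kdMut / kdWt)
}

#' Build an alanine-scan DDG table from apparent affinities
#'
#' Computes K_d ratios relative to the wild-type row and converts them to
#' binding free-energy perturbations at the given temperature.
#'
#' @param kdTable data.frame with columns \code{toxin}, \code{kd_nM} and
#'   optionally \code{kd_sem_nM}.
#' @param wtLabel Value of \code{toxin} identifying the wild-type row.
#' @param temperatureK Temperature in K (default 298.15).
#' @return A \linkS4class{DdgTable}; the wild-type row carries ratio 1 and
#'   DDG NA (the reference).
#' @export
buildDdgTable <- function(kdTable, wtLabel, temperatureK = 298.15) {
  need <- c("toxin", "kd_nM")
  miss <- setdiff(need, names(kdTable))
  if (length(miss))
    stop("kdTable is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  wi <- which(kdTable$toxin == wtLabel)
  if (length(wi) != 1L)
    stop("wild-type label '", wtLabel, "' must match exactly one row",
         call. = FALSE)
  kdWt <- kdTable$kd_nM[wi]
  tab <- data.frame(
    toxin = kdTable$toxin,
    kd_nM = kdTable$kd_nM,
    kd_sem_nM = if ("kd_sem_nM" %in% names(kdTable))
      kdTable$kd_sem_nM else NA_real_,
    ratio = kdTable$kd_nM / kdWt,
    ddg_kcal_mol = ddgFromKd(kdTable$kd_nM, kdWt, temperatureK))
  tab$ddg_kcal_mol[wi] <- NA_real_
  new("DdgTable", table = tab, wtLabel = wtLabel,
      temperatureK = temperatureK)
}

#' Fit K_d to a concentration-inhibition curve
#'
#' Least-squares fit of \eqn{F_u = (K_d/(K_d+[T]))^n} across toxin
#' concentrations. A single (F_u, [T]) point reduces exactly to the
#' algebraic inversion \code{\link{kdFourSite}}.
#'
#' @param fu Fractions unbound in (0, 1).
#' @param toxinNM Matching toxin concentrations in nM.
#' @param nSites Number of independent sites (default 4).
#' @return list with \code{kd} (nM), \code{stderr}, \code{rss} and
#'   \code{n}.
#' @examples
#' fitConcentrationResponse(c(0.32, 0.062, 0.0025),
#'                          c(100, 224, 1000))
#' @export
fitConcentrationResponse <- function(fu, toxinNM, nSites = 4L) {
  if (length(fu) != length(toxinNM))
    stop("fu and toxinNM must have equal length", call. = FALSE)
  if (any(fu <= 0 | fu >= 1))
    stop("F_u values must lie strictly inside (0, 1)", call. = FALSE)
  if (length(fu) == 1L)
    return(list(kd = kdFourSite(fu, toxinNM, nSites), stderr = NA_real_,
                rss = 0, n = 1L))
  # start at the geometric mean of per-point algebraic inversions
  kd0 <- exp(mean(log(kdFourSite(fu, toxinNM, nSites))))
  fit <- tryCatch(
    minpack.lm::nlsLM(fu ~ (kd / (kd + toxinNM))^nSites,
                      start = list(kd = kd0), lower = c(kd = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("concentration-response fit failed: ", conditionMessage(e),
           call. = FALSE))
  co <- summary(fit)$coefficients
  list(kd = unname(co["kd", "Estimate"]),
       stderr = unname(co["kd", "Std. Error"]),
       rss = sum(stats::residuals(fit)^2), n = length(fu))
}

#' Conductance-voltage relation from tail currents
#'
#' Normalizes tail-current amplitudes to their maximum and, optionally,
#' fits the Boltzmann activation curve
#' \eqn{G/G_{max} = 1/(1 + \exp(-(V - V_{1/2})/k))}. The Boltzmann form is
#' a phenotype summary convenience, not a mechanistic claim.
#'
#' @param voltages Test voltages in mV, increasing.
#' @param tails Tail-current amplitudes (>= 0), same length.
#' @param fitBoltzmann Fit V1/2 and slope (default TRUE).
#' @return A \linkS4class{GVCurve}; a voltage-independent curve is flagged
#'   degenerate with NA fit parameters.
#' @export
gvFromTails <- function(voltages, tails, fitBoltzmann = TRUE) {
  if (length(voltages) != length(tails))
    stop("voltages and tails must have equal length", call. = FALSE)
  if (any(diff(voltages) <= 0))
    stop("voltages must be strictly increasing", call. = FALSE)
  if (all(tails == 0))
    stop("all tail currents are zero: conductance undefined", call. = FALSE)
  g <- tails / max(tails)
  degenerate <- stats::sd(g) < 1e-6
  vh <- sl <- NA_real_
  if (fitBoltzmann && !degenerate) {
    v0 <- voltages[which.min(abs(g - 0.5))]
    # free amplitude absorbs incomplete saturation of the tail maximum;
    # nls.lm is used directly so exact-fit (zero-residual) data pose no
    # problem
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(A = 1, vh = v0, k = 10),
        fn = function(p) g - p[1] / (1 + exp(-(voltages - p[2]) / p[3])),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      vh <- unname(fit$par["vh"]); sl <- unname(fit$par["k"])
    }
  }
  new("GVCurve", voltage = voltages, conductance = g, vHalf = vh,
      slope = sl, degenerate = degenerate)
}
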