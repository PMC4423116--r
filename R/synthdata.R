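#' @include AllClasses.R
NULL

# asymmetric-Gaussian line shape: distinct widths left/right of the peak so
# the argmax stays exactly at lambdaMax for any asymmetry in [0, 1)
.spectrumShape <- function(grid, lambdaMax, width, amplitude, asymmetry) {
  sigma <- ifelse(grid < lambdaMax,
                  width * (1 - asymmetry), width * (1 + asymmetry))
  amplitude * exp(-0.5 * ((grid - lambdaMax) / sigma)^2)
}

#' Simulate a tryptophan emission spectrum
#'
#' Generates a single emission spectrum on a wavelength grid with an
#' asymmetric-Gaussian line shape (independent left/right widths, so the
#' peak sits exactly at \code{lambdaMax}) and optional multiplicative
#' Gaussian noise, approximating fluorescence shot noise.
#'
#' @param lambdaMax Peak wavelength in nm, within [300, 450].
#' @param width Spectral width parameter in nm (> 0).
#' @param amplitude Peak intensity in arbitrary units (> 0).
#' @param asymmetry Skew in [0, 1): the red side is wider by
#'   \code{1 + asymmetry}, the blue side narrower by \code{1 - asymmetry}.
#' @param grid Strictly increasing wavelength grid in nm within [300, 450].
#' @param noiseSd Relative standard deviation of multiplicative noise.
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @param lipidTotal,quencher,label Condition metadata stored on the
#'   spectrum.
#' @return An \linkS4class{EmissionSpectrum}.
#' @examples
#' sp <- simEmissionSpectrum(lambdaMax = 350, noiseSd = 0)
#' wavelengths(sp)[which.max(intensities(sp))]
#' @export
simEmissionSpectrum <- function(lambdaMax = 350, width = 25,
                                amplitude = 1e4, asymmetry = 0.15,
                                grid = seq(300, 450, by = 1),
                                noiseSd = 0, seed = NULL,
                                lipidTotal = 0, quencher = 0, label = "") {
  if (length(grid) == 0L)
    stop("wavelength grid must be non-empty", call. = FALSE)
  .assertNumeric(grid, "grid", lower = 300)
  if (any(grid > 450) || any(diff(grid) <= 0))
    stop("grid must be strictly increasing within [300, 450]", call. = FALSE)
  .assertNumber(lambdaMax, "lambdaMax", 300, 450)
  .assertNumber(width, "width", 0, strict = TRUE, upper = Inf)
  .assertNumber(amplitude, "amplitude", 0, strict = TRUE, upper = Inf)
  .assertNumber(asymmetry, "asymmetry", 0, 1)
  base <- .spectrumShape(grid, lambdaMax, width, amplitude, asymmetry)
  noisy <- .withSeed(seed,
    base * pmax(0, 1 + stats::rnorm(length(grid), sd = noiseSd)))
  new("EmissionSpectrum", wavelength = grid, intensity = noisy,
      lipidTotal = lipidTotal, quencher = quencher, label = label)
}

#' Simulate a membrane-shifted emission spectrum
#'
#' Convenience wrapper modelling the blue shift upon membrane partitioning:
#' the bound fraction at the given lipid concentration (mole-fraction
#' partition equilibrium) linearly interpolates the peak between its aqueous
#' and fully-membrane-bound positions, and scales the amplitude towards
#' \code{fMax} times the aqueous amplitude.
#'
#' @param K Mole-fraction partition coefficient.
#' @param lipidTotal Total lipid concentration in mM.
#' @param lambdaAqueous,lambdaMembrane Peak positions (nm) of the free and
#'   fully bound states; \code{lambdaMembrane < lambdaAqueous} gives a blue
#'   shift.
#' @param fMax Maximal relative fluorescence F/F0max (> 1).
#' @param availableFraction Fraction of total lipid available (default 0.60).
#' @param waterMolarity Water molarity (default 55.3 M).
#' @param ... Further arguments passed to \code{\link{simEmissionSpectrum}}.
#' @return An \linkS4class{EmissionSpectrum}.
#' @export
simMembraneSpectrum <- function(K, lipidTotal, lambdaAqueous = 350,
                                lambdaMembrane = 335, fMax = 2.3,
                                availableFraction = 0.60,
                                waterMolarity = 55.3, ...) {
  b <- partitionBoundFraction(K, lipidTotal, availableFraction,
                              waterMolarity)
  simEmissionSpectrum(
    lambdaMax = lambdaAqueous + b * (lambdaMembrane - lambdaAqueous),
    amplitude = 1e4 * (1 + b * (fMax - 1)),
    lipidTotal = lipidTotal, ...)
}

#' Simulate a membrane partition titration
#'
#' Evaluates the mole-fraction partition model
#' \deqn{F/F_0(L) = 1 + (F/F_0^{max} - 1)\,K [L] / ([W] + K [L])}
#' on a grid of total lipid concentrations ([L] is the available lipid in
#' molar, [W] the molarity of water) and applies multiplicative Gaussian
#' noise. The noiseless series is exactly the model curve, so fitting it
#' back recovers the generating parameters.
#'
#' @param K Mole-fraction partition coefficient (> 0).
#' @param fMax Maximal relative fluorescence (> 1).
#' @param lipidGrid Total lipid concentrations in mM, non-negative,
#'   including 0. The default spans the half-saturation point of a
#'   K ~ 5e6 toxin and reaches the 1 mM plateau used experimentally.
#' @param availableFraction Fraction of total lipid available to the
#'   peptide (default 0.60).
#' @param waterMolarity Molar concentration of water (default 55.3 M).
#' @param noiseSd Relative noise SD.
#' @param seed Integer seed or NULL.
#' @param responseKind Stored response kind; use
#'   \code{"intensity_at_320nm"} for direct partitioning (K_x) and
#'   \code{"max_intensity"} for dequenching (K_dx) series.
#' @return A \linkS4class{TitrationSeries}.
#' @examples
#' s <- simPartitionTitration(K = 4.6e6, fMax = 2.3, noiseSd = 0)
#' s
#' @export
simPartitionTitration <- function(K, fMax,
                                  lipidGrid = c(0, 0.01, 0.02, 0.05,
                                                0.1, 0.2, 0.5, 1.0),
                                  availableFraction = 0.60,
                                  waterMolarity = 55.3,
                                  noiseSd = 0, seed = NULL,
                                  responseKind = "intensity_at_320nm") {
  .assertNumber(K, "K", 0, strict = TRUE, upper = Inf)
  .assertNumber(fMax, "fMax", 1, strict = TRUE, upper = Inf)
  .assertNumeric(lipidGrid, "lipidGrid", lower = 0)
  if (!any(lipidGrid == 0))
    stop("lipidGrid must include the zero-lipid normalization point",
         call. = FALSE)
  mean <- evaluatePartitionModel(K, fMax, lipidGrid, availableFraction,
                                 waterMolarity)
  resp <- .withSeed(seed,
    mean * pmax(1e-6, 1 + stats::rnorm(length(mean), sd = noiseSd)))
  new("TitrationSeries", lipidTotal = lipidGrid, response = resp,
      responseKind = responseKind, availableFraction = availableFraction,
      waterMolarity = waterMolarity)
}

#' Simulate a Stern-Volmer quenching titration
#'
#' Noiseless means follow \eqn{F_0/F = 1 + K_{sv}[Q]} exactly; noise is
#' multiplicative Gaussian.
#'
#' @param ksv Stern-Volmer constant in 1/M (>= 0).
#' @param quencherGrid Quencher concentrations in M, non-negative.
#' @param noiseSd Relative noise SD.
#' @param seed Integer seed or NULL.
#' @return A \linkS4class{QuenchSeries}.
#' @examples
#' simQuenchTitration(37.7, noiseSd = 0)
#' @export
simQuenchTitration <- function(ksv, quencherGrid = seq(0, 0.3, by = 0.05),
                               noiseSd = 0, seed = NULL) {
  .assertNumber(ksv, "ksv", 0)
  if (any(quencherGrid < 0))
    stop("quencher concentrations must be non-negative", call. = FALSE)
  mean <- 1 + ksv * quencherGrid
  ratio <- .withSeed(seed,
    mean * pmax(1e-6, 1 + stats::rnorm(length(mean), sd = noiseSd)))
  new("QuenchSeries", quencher = quencherGrid, ratio = ratio)
}

#' Simulate a steady-state inhibition experiment
#'
#' Generates paired before/after steady-state currents at weak
#' depolarizations for a panel of toxin concentrations under the
#' independent-sites occupancy model: the noiseless fraction unbound is
#' \eqn{F_u = (K_d/(K_d+[T]))^{n}} with \eqn{n} independent binding sites
#' (default 4), occupancy of any one site preventing opening. Currents get
#' multiplicative Gaussian noise per record.
#'
#' @param kdTrue True per-site K_d in nM (> 0).
#' @param toxinNM Toxin concentrations in nM (> 0).
#' @param nSites Number of independent binding sites (default 4).
#' @param voltages Weak-depolarization test voltages in mV.
#' @param i0NA Baseline steady-state current amplitude in nA.
#' @param noiseSd Relative noise SD applied to each current.
#' @param nCells Number of replicate cells.
#' @param seed Integer seed or NULL.
#' @return An \linkS4class{InhibitionSet}.
#' @examples
#' ex <- simInhibitionExperiment(224, toxinNM = 224, noiseSd = 0)
#' head(records(ex))
#' @export
simInhibitionExperiment <- function(kdTrue, toxinNM,
                                    nSites = 4L,
                                    voltages = seq(-20, 10, by = 10),
                                    i0NA = 2000, noiseSd = 0,
                                    nCells = 1L, seed = NULL) {
  .assertNumber(kdTrue, "kdTrue", 0, strict = TRUE, upper = Inf)
  .assertNumeric(toxinNM, "toxinNM", lower = 0)
  if (nSites < 1L) stop("nSites must be >= 1", call. = FALSE)
  .withSeed(seed, {
    rows <- expand.grid(cell = seq_len(nCells), toxin = toxinNM,
                        voltage = voltages, KEEP.OUT.ATTRS = FALSE)
    fu <- (kdTrue / (kdTrue + rows$toxin))^nSites
    i0 <- i0NA * pmax(1e-3, 1 + stats::rnorm(nrow(rows), sd = noiseSd))
    i <- i0 * fu * pmax(1e-3, 1 + stats::rnorm(nrow(rows), sd = noiseSd))
    new("InhibitionSet", records = data.frame(
      cell_id = sprintf("cell%02d", rows$cell),
      toxin_nM = rows$toxin,
      voltage_mV = rows$voltage,
      I0_nA = i0, I_nA = i))
  })
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# Ca positions of an ideal helix along +z, phase/z chosen so residue 1 sits
# at angle 0, z = 0
.idealHelixCa <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  ang <- (seq_len(n) - 1L) * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), (seq_len(n) - 1L) * rise)
}

#' Build a toy helix-plus-toxin complex
#'
#' Constructs an ideal alpha-helix (Calpha trace along +z; canonical
#' defaults of 100 degrees twist and 1.5 Angstrom rise per residue) as chain
#' \code{helixChain}, plus a rigid "toxin" placeholder of carbon atoms on a
#' deterministic Fibonacci sphere, centred at \code{placementOffset} from
#' the helix midpoint, as chain \code{toxinChain}. Used as a fixture for
#' superposition, SASA, interface and grafting analyses.
#'
#' @param helixLength Number of helix residues (>= 4).
#' @param rise Helical rise per residue in Angstrom (> 0).
#' @param twist Helical twist per residue in degrees, in (0, 180).
#' @param helixRadius Calpha radial distance from the helix axis (Angstrom).
#' @param toxinAtomCount Number of toxin placeholder atoms.
#' @param toxinRadius Radius of the toxin atom shell (Angstrom).
#' @param placementOffset Length-3 offset (Angstrom) of the toxin centroid
#'   from the helix midpoint.
#' @param helixChain,toxinChain Chain identifiers.
#' @return A \linkS4class{StructureModel} with the two chains.
#' @examples
#' toy <- simToyComplex(helixLength = 10)
#' toy
#' @export
simToyComplex <- function(helixLength = 18, rise = 1.5, twist = 100,
                          helixRadius = 2.3, toxinAtomCount = 24,
                          toxinRadius = 3.0,
                          placementOffset = c(12, 0, 0),
                          helixChain = "A", toxinChain = "B") {
  if (helixLength < 4L) stop("helixLength must be >= 4", call. = FALSE)
  .assertNumber(rise, "rise", 0, strict = TRUE, upper = Inf)
  .assertNumber(twist, "twist", 0, 180, strict = TRUE)
  if (length(placementOffset) != 3L)
    stop("placementOffset must have length 3", call. = FALSE)
  ca <- .idealHelixCa(helixLength, rise, twist, helixRadius)
  helix <- data.frame(
    chain = helixChain, resno = seq_len(helixLength), resid = "ALA",
    elety = "CA", element = "C",
    x = ca[, 1], y = ca[, 2], z = ca[, 3],
    radius = .radiusForElement("C"))
  mid <- colMeans(ca)
  shell <- .fibonacciSphere(toxinAtomCount) * toxinRadius
  centre <- mid + placementOffset
  names <- c("CA", "CB", "CG", "CD")
  toxin <- data.frame(
    chain = toxinChain,
    resno = (seq_len(toxinAtomCount) - 1L) %/% 4L + 1L,
    resid = "TOX",
    elety = names[(seq_len(toxinAtomCount) - 1L) %% 4L + 1L],
    element = "C",
    x = shell[, 1] + centre[1], y = shell[, 2] + centre[2],
    z = shell[, 3] + centre[3],
    radius = .radiusForElement("C"))
  new("StructureModel", atoms = rbind(helix, toxin))
}
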