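#' @import methods
NULL

#' EmissionSpectrum: a tryptophan fluorescence emission spectrum
#'
#' Holds a single background-corrected emission spectrum recorded on a
#' wavelength grid (conventionally 300--450 nm, 280 nm excitation), together
#' with the condition it was recorded under: total lipid concentration (mM)
#' and aqueous quencher concentration (M).
#'
#' @slot wavelength Numeric, strictly increasing wavelengths in nm.
#' @slot intensity Numeric, non-negative intensities (arbitrary units),
#'   same length as \code{wavelength}.
#' @slot lipidTotal Total lipid concentration in mM for this condition.
#' @slot quencher Aqueous quencher (acrylamide) concentration in M.
#' @slot label Free-text condition label.
#' @export
setClass("EmissionSpectrum",
  representation(wavelength = "numeric", intensity = "numeric",
                 lipidTotal = "numeric", quencher = "numeric",
                 label = "character"),
  prototype(lipidTotal = 0, quencher = 0, label = ""))

setValidity("EmissionSpectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@intensity))
    msg <- c(msg, "wavelength and intensity must have equal length")
  if (length(object@wavelength) > 1L &&
      any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@lipidTotal) != 1L || object@lipidTotal < 0)
    msg <- c(msg, "lipidTotal must be a single non-negative number")
  if (length(object@quencher) != 1L || object@quencher < 0)
    msg <- c(msg, "quencher must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' TitrationSeries: normalized fluorescence response versus lipid
#'
#' The substrate for mole-fraction partition fits. Responses are F/F0 values
#' normalized to the zero-lipid condition, recorded either as intensity at
#' 320 nm (direct partitioning, yields K_x) or as the spectral maximum in a
#' pre-quenched solution (acrylamide dequenching, yields K_dx).
#'
#' @slot lipidTotal Total lipid concentrations in mM.
#' @slot response F/F0 values, same length.
#' @slot responseKind Either \code{"intensity_at_320nm"} or
#'   \code{"max_intensity"}.
#' @slot availableFraction Fraction of total lipid accessible to the peptide
#'   (outer leaflet availability); default 0.60.
#' @slot waterMolarity Molar concentration of water, default 55.3 M.
#' @export
setClass("TitrationSeries",
  representation(lipidTotal = "numeric", response = "numeric",
                 responseKind = "character", availableFraction = "numeric",
                 waterMolarity = "numeric"),
  prototype(responseKind = "intensity_at_320nm",
            availableFraction = 0.60, waterMolarity = 55.3))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (length(object@lipidTotal) != length(object@response))
    msg <- c(msg, "lipidTotal and response must have equal length")
  if (any(object@lipidTotal < 0))
    msg <- c(msg, "lipid concentrations must be non-negative")
  if (any(object@response <= 0))
    msg <- c(msg, "responses must be positive")
  if (!object@responseKind %in% c("intensity_at_320nm", "max_intensity"))
    msg <- c(msg, "responseKind must be 'intensity_at_320nm' or 'max_intensity'")
  if (object@availableFraction <= 0 || object@availableFraction > 1)
    msg <- c(msg, "availableFraction must lie in (0, 1]")
  if (object@waterMolarity <= 0)
    msg <- c(msg, "waterMolarity must be positive")
  if (length(msg)) msg else TRUE
})

#' QuenchSeries: Stern-Volmer quenching data
#'
#' F0/F ratios versus aqueous quencher concentration, the substrate for a
#' Stern-Volmer fit.
#'
#' @slot quencher Quencher concentrations in M, non-negative.
#' @slot ratio F0/F ratios, same length.
#' @export
setClass("QuenchSeries",
  representation(quencher = "numeric", ratio = "numeric"))

setValidity("QuenchSeries", function(object) {
  msg <- character()
  if (length(object@quencher) != length(object@ratio))
    msg <- c(msg, "quencher and ratio must have equal length")
  if (any(object@quencher < 0))
    msg <- c(msg, "quencher concentrations must be non-negative")
  if (any(object@ratio <= 0))
    msg <- c(msg, "ratios must be positive")
  if (length(msg)) msg else TRUE
})

#' PartitionFit: result of a mole-fraction partition fit
#'
#' @slot K Mole-fraction partition coefficient (dimensionless); K_x for
#'   intensity-at-320nm data, K_dx for dequenching maxima. NA when the fit
#'   was flagged degenerate (no partitioning signal).
#' @slot fMax Fitted maximal relative fluorescence F/F0max.
#' @slot KStderr,fMaxStderr Asymptotic standard errors from the fit.
#' @slot rss Residual sum of squares.
#' @slot nPoints Number of titration points used.
#' @slot modelKind \code{"partition"} (K_x) or \code{"dequench"} (K_dx).
#' @slot degenerate TRUE when all responses were ~1 and only a lower bound
#'   on K can be stated (held in \code{KLowerBound}).
#' @slot KLowerBound Lower bound on K for degenerate fits, else NA.
#' @export
setClass("PartitionFit",
  representation(K = "numeric", fMax = "numeric", KStderr = "numeric",
                 fMaxStderr = "numeric", rss = "numeric",
                 nPoints = "integer", modelKind = "character",
                 degenerate = "logical", KLowerBound = "numeric"),
  prototype(degenerate = FALSE, KLowerBound = NA_real_))

setValidity("PartitionFit", function(object) {
  msg <- character()
  if (!object@modelKind %in% c("partition", "dequench"))
    msg <- c(msg, "modelKind must be 'partition' or 'dequench'")
  if (!object@degenerate) {
    if (!is.finite(object@K) || object@K <= 0)
      msg <- c(msg, "K must be positive for a non-degenerate fit")
    if (!is.finite(object@fMax) || object@fMax <= 1)
      msg <- c(msg, "fMax must exceed 1 for a non-degenerate fit")
  }
  if (length(msg)) msg else TRUE
})

#' SternVolmerFit: linear quenching fit
#'
#' @slot ksv Stern-Volmer constant in 1/M (slope of F0/F versus [Q]).
#' @slot intercept Fitted or fixed intercept (1 when fixed).
#' @slot ksvStderr Standard error of the slope.
#' @slot rss Residual sum of squares.
#' @slot interceptFixed TRUE when the intercept was constrained to 1.
#' @export
setClass("SternVolmerFit",
  representation(ksv = "numeric", intercept = "numeric",
                 ksvStderr = "numeric", rss = "numeric",
                 interceptFixed = "logical"))

#' BromoQuenchProfile: depth-dependent quenching by brominated lipids
#'
#' Per-label intensity ratios F(labeled)/F(unlabeled) evaluated at the
#' unlabeled-condition emission maximum, for acyl-chain bromine positions
#' 6,7-, 9,10- and 11,12-diBr. Lower ratios mean stronger quenching, i.e.
#' deeper/closer tryptophan burial near that bilayer depth.
#'
#' @slot ratios Named numeric vector, names are the diBr labels.
#' @slot lambdaMax Wavelength (nm) at which ratios were evaluated.
#' @export
setClass("BromoQuenchProfile",
  representation(ratios = "numeric", lambdaMax = "numeric"))

#' InhibitionSet: paired steady-state currents before/after toxin
#'
#' One row per (cell, toxin concentration, voltage), holding the steady-state
#' current before toxin (I0) and at toxin equilibrium (I), measured with
#' depolarizations too weak to open toxin-bound channels.
#'
#' @slot records data.frame with columns \code{cell_id}, \code{toxin_nM},
#'   \code{voltage_mV}, \code{I0_nA}, \code{I_nA}.
#' @export
setClass("InhibitionSet", representation(records = "data.frame"))

setValidity("InhibitionSet", function(object) {
  need <- c("cell_id", "toxin_nM", "voltage_mV", "I0_nA", "I_nA")
  miss <- setdiff(need, names(object@records))
  if (length(miss))
    return(paste("records is missing column(s):",
                 paste(miss, collapse = ", ")))
  if (any(object@records$I0_nA <= 0))
    return("I0_nA must be positive")
  if (any(object@records$toxin_nM < 0))
    return("toxin_nM must be non-negative")
  TRUE
})

#' KdEstimate: apparent dissociation constant aggregated across cells
#'
#' @slot label Toxin label.
#' @slot kdNM Mean apparent K_d in nM.
#' @slot kdSemNM Standard error of the mean (0 with \code{singleCell} flag
#'   when n = 1).
#' @slot nCells Number of cells averaged.
#' @slot singleCell TRUE when the SEM is undefined (n = 1).
#' @export
setClass("KdEstimate",
  representation(label = "character", kdNM = "numeric", kdSemNM = "numeric",
                 nCells = "integer", singleCell = "logical"))

setValidity("KdEstimate", function(object) {
  if (object@kdNM <= 0) return("kdNM must be positive")
  if (object@nCells < 1L) return("nCells must be >= 1")
  TRUE
})

#' DdgTable: alanine-scan perturbation energies
#'
#' K_d ratios and binding free-energy perturbations DDG = RT ln(Kd_mut/Kd_wt)
#' for a panel of point mutants relative to a wild-type reference.
#'
#' @slot table data.frame with columns \code{toxin}, \code{kd_nM},
#'   \code{kd_sem_nM}, \code{ratio}, \code{ddg_kcal_mol}.
#' @slot wtLabel Label of the wild-type row used as reference.
#' @slot temperatureK Temperature (K) used in the DDG conversion.
#' @export
setClass("DdgTable",
  representation(table = "data.frame", wtLabel = "character",
                 temperatureK = "numeric"))

#' GVCurve: normalized conductance-voltage relation
#'
#' @slot voltage Voltages in mV, increasing.
#' @slot conductance Tail-current-derived conductance normalized to its
#'   maximum.
#' @slot vHalf Boltzmann midpoint in mV (NA when not fit or degenerate).
#' @slot slope Boltzmann slope factor in mV.
#' @slot degenerate TRUE when the curve carried no voltage dependence.
#' @export
setClass("GVCurve",
  representation(voltage = "numeric", conductance = "numeric",
                 vHalf = "numeric", slope = "numeric",
                 degenerate = "logical"),
  prototype(vHalf = NA_real_, slope = NA_real_, degenerate = FALSE))

#' StructureModel: an atomic structure with assigned radii
#'
#' A lightweight container for protein coordinates: one row per atom with
#' chain, residue and atom identity, Cartesian coordinates in Angstrom and a
#' van der Waals radius assigned per element. Substrate for superposition,
#' SASA, interface mapping and grafting.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{radius}.
#' @slot modelIndex Which MODEL of a multi-model (NMR) file these
#'   coordinates came from; 1 for single-model files.
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", modelIndex = "integer"),
  prototype(modelIndex = 1L))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "element",
            "x", "y", "z", "radius")
  miss <- setdiff(need, names(a))
  if (length(miss))
    return(paste("atoms is missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(a)) {
    if (any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z)))
      return("coordinates must be finite")
    if (any(a$radius <= 0))
      return("radii must be positive")
    key <- paste(a$chain, a$resno)
    if (anyDuplicated(unique(data.frame(key, a$resid))$key))
      return("residue numbering must be unique within a chain")
  }
  TRUE
})

#' RigidTransform: a proper rigid-body transform
#'
#' Rotation (3x3, orthonormal, det +1) plus translation; applied to row
#' coordinate matrices as \code{x \%*\% t(R) + t}.
#'
#' @slot rotation 3x3 rotation matrix.
#' @slot translation Length-3 translation vector (Angstrom).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det +1)")
  TRUE
})

#' SasaReport: Shrake-Rupley solvent-accessible surface area
#'
#' @slot probe Probe radius in Angstrom (1.4 for water).
#' @slot nPoints Quadrature points per atom sphere.
#' @slot atoms data.frame with per-atom SASA (\code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{sasa}).
#' @slot residues data.frame with per-residue SASA sums.
#' @slot total Total SASA in Angstrom^2.
#' @export
setClass("SasaReport",
  representation(probe = "numeric", nPoints = "integer",
                 atoms = "data.frame", residues = "data.frame",
                 total = "numeric"))

setValidity("SasaReport", function(object) {
  if (any(object@atoms$sasa < 0)) return("per-atom SASA must be >= 0")
  if (abs(sum(object@atoms$sasa) - object@total) > 1e-6 * max(1, object@total))
    return("total must equal the sum of per-atom values")
  TRUE
})

#' DeltaSasaReport: per-residue interface burial
#'
#' Per-residue change in solvent-accessible surface area between a component
#' extracted alone and the same residues inside the complex; positive values
#' mark interface burial.
#'
#' @slot residues data.frame with \code{chain}, \code{resno}, \code{resid},
#'   \code{sasa_free}, \code{sasa_complex}, \code{dsasa}, ordered by
#'   decreasing \code{dsasa}.
#' @slot componentChains Chains treated as the free component.
#' @slot probe Probe radius used (identical for both states).
#' @slot nPoints Quadrature points used.
#' @export
setClass("DeltaSasaReport",
  representation(residues = "data.frame", componentChains = "character",
                 probe = "numeric", nPoints = "integer"))

#' GraftModel: a register-offset placement of a toxin on a target helix
#'
#' The result of superposing a toxin-bound template helix onto a target
#' helix and stepping the placement by whole-residue register offsets (a
#' fixed twist about and rise along the target helix axis per step), with a
#' steric clash report and interface residue lists.
#'
#' @slot offset Integer register offset (0 = direct superposition).
#' @slot transform The full \linkS4class{RigidTransform} applied to the
#'   toxin model.
#' @slot structure Combined \linkS4class{StructureModel} (target plus placed
#'   toxin).
#' @slot clashCount Number of inter-chain heavy-atom pairs closer than the
#'   clash cutoff.
#' @slot clashes data.frame of clashing atom pairs.
#' @slot interface list of two data.frames of interface residues (toxin
#'   side, target side).
#' @slot toxinChains,targetChains Chain identifiers of the two sides.
#' @export
setClass("GraftModel",
  representation(offset = "integer", transform = "RigidTransform",
                 structure = "StructureModel", clashCount = "integer",
                 clashes = "data.frame", interface = "list",
                 toxinChains = "character", targetChains = "character"))

#' ResultBundle: outputs of a configured pipeline run
#'
#' @slot results Named list of per-stage outputs.
#' @slot provenance List with the configuration, its hash, package version
#'   and timestamp.
#' @export
setClass("ResultBundle",
  representation(results = "list", provenance = "list"))
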