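#' @include AllClasses.R
NULL

#' Accessors for ToxinScan classes
#'
#' Small accessor generics returning slot contents of the package's S4
#' containers; use these rather than \code{@} access.
#'
#' @param object An object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("partitionCoef", function(object) standardGeneric("partitionCoef"))
#' @rdname accessors
#' @export
setGeneric("fMax", function(object) standardGeneric("fMax"))
#' @rdname accessors
#' @export
setGeneric("quenchConstant", function(object)
  standardGeneric("quenchConstant"))
#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("kdNM", function(object) standardGeneric("kdNM"))
#' @rdname accessors
#' @export
setGeneric("kdSemNM", function(object) standardGeneric("kdSemNM"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("ddgValues", function(object) standardGeneric("ddgValues"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("atomSasa", function(object) standardGeneric("atomSasa"))
#' @rdname accessors
#' @export
setGeneric("residueSasa", function(object) standardGeneric("residueSasa"))
#' @rdname accessors
#' @export
setGeneric("totalSasa", function(object) standardGeneric("totalSasa"))
#' @rdname accessors
#' @export
setGeneric("registerOffset", function(object)
  standardGeneric("registerOffset"))
#' @rdname accessors
#' @export
setGeneric("clashCount", function(object) standardGeneric("clashCount"))
#' @rdname accessors
#' @export
setGeneric("graftTransform", function(object)
  standardGeneric("graftTransform"))

setMethod("wavelengths", "EmissionSpectrum", function(object)
  object@wavelength)
setMethod("intensities", "EmissionSpectrum", function(object)
  object@intensity)
setMethod("partitionCoef", "PartitionFit", function(object) object@K)
setMethod("fMax", "PartitionFit", function(object) object@fMax)
setMethod("quenchConstant", "SternVolmerFit", function(object) object@ksv)
setMethod("records", "InhibitionSet", function(object) object@records)
setMethod("kdNM", "KdEstimate", function(object) object@kdNM)
setMethod("kdSemNM", "KdEstimate", function(object) object@kdSemNM)
setMethod("nCells", "KdEstimate", function(object) object@nCells)
setMethod("ddgValues", "DdgTable", function(object) object@table)
setMethod("atoms", "StructureModel", function(object) object@atoms)
setMethod("coords", "StructureModel", function(object) {
  m <- as.matrix(object@atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
})
setMethod("rotation", "RigidTransform", function(object) object@rotation)
setMethod("translation", "RigidTransform", function(object)
  object@translation)
setMethod("atomSasa", "SasaReport", function(object) object@atoms)
setMethod("residueSasa", "SasaReport", function(object) object@residues)
setMethod("totalSasa", "SasaReport", function(object) object@total)
setMethod("registerOffset", "GraftModel", function(object) object@offset)
setMethod("clashCount", "GraftModel", function(object) object@clashCount)
setMethod("graftTransform", "GraftModel", function(object) object@transform)

setMethod("show", "EmissionSpectrum", function(object) {
  cat(sprintf(
    "EmissionSpectrum '%s': %d points, %.0f-%.0f nm, lipid %.3g mM, [Q] %.3g M\n",
    object@label, length(object@wavelength),
    min(object@wavelength), max(object@wavelength),
    object@lipidTotal, object@quencher))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf(
    "TitrationSeries (%s): %d points, lipid %.3g-%.3g mM total\n",
    object@responseKind, length(object@lipidTotal),
    min(object@lipidTotal), max(object@lipidTotal)))
})

setMethod("show", "PartitionFit", function(object) {
  lab <- if (object@modelKind == "partition") "K_x" else "K_dx"
  if (object@degenerate) {
    cat(sprintf("PartitionFit (degenerate): no partitioning signal; %s > %.3g\n",
                lab, object@KLowerBound))
  } else {
    cat(sprintf("PartitionFit: %s = %.3g +/- %.2g, F/F0max = %.3g +/- %.2g (n = %d)\n",
                lab, object@K, object@KStderr, object@fMax,
                object@fMaxStderr, object@nPoints))
  }
})

setMethod("show", "SternVolmerFit", function(object) {
  cat(sprintf("SternVolmerFit: K_sv = %.3g +/- %.2g 1/M (intercept %s)\n",
              object@ksv, object@ksvStderr,
              if (object@interceptFixed) "fixed at 1"
              else sprintf("%.3g", object@intercept)))
})

setMethod("show", "KdEstimate", function(object) {
  cat(sprintf("KdEstimate '%s': %.4g +/- %.3g nM (n = %d cells%s)\n",
              object@label, object@kdNM, object@kdSemNM, object@nCells,
              if (object@singleCell) "; SEM undefined, reported 0" else ""))
})

setMethod("show", "DdgTable", function(object) {
  cat(sprintf("DdgTable: %d toxins, wild type '%s', T = %.2f K\n",
              nrow(object@table), object@wtLabel, object@temperatureK))
  print(utils::head(object@table, 8L))
  if (nrow(object@table) > 8L) cat("  ...\n")
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel: %d atoms, %d chains (%s), model %d\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              object@modelIndex))
})

setMethod("show", "SasaReport", function(object) {
  cat(sprintf("SasaReport: total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              object@total, nrow(object@atoms), object@probe,
              object@nPoints))
})

setMethod("show", "DeltaSasaReport", function(object) {
  cat(sprintf("DeltaSasaReport for chain(s) %s: %d residues, buried %.1f A^2\n",
              paste(object@componentChains, collapse = ","),
              nrow(object@residues), sum(object@residues$dsasa)))
})

setMethod("show", "GraftModel", function(object) {
  cat(sprintf("GraftModel: register %+d, %d clash pair(s)\n",
              object@offset, object@clashCount))
})

setMethod("show", "ResultBundle", function(object) {
  cat(sprintf("ResultBundle: stages [%s], config hash %s\n",
              paste(names(object@results), collapse = ", "),
              object@provenance$configHash))
})
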