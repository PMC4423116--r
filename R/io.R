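#' @include AllClasses.R
NULL

# read a CSV, insist on required columns, coerce numeric columns and report
# malformed rows by line number; with skipBad they are dropped with a warning
.readValidatedCsv <- function(path, required, numericCols,
                              skipBad = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("'", basename(path), "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- rep(FALSE, nrow(df))
  for (col in intersect(numericCols, names(df))) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    # empty cells and literal NA are permitted missing values, not errors
    bad <- bad | (is.na(v) & !is.na(raw) & !(raw %in% c("", "NA")))
    df[[col]] <- v
  }
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (!skipBad)
      stop("non-numeric value(s) in '", basename(path), "' at line(s): ",
           paste(lines, collapse = ", "), call. = FALSE)
    warning("dropping ", sum(bad), " malformed row(s) at line(s): ",
            paste(lines, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Read tables in the package's CSV schemas
#'
#' Comma-separated, UTF-8, mandatory header; units are declared by column
#' suffix (\code{_nM}, \code{_mM}, \code{_mV}, \code{_M}, \code{_nA}).
#' Malformed numeric cells are reported with their line numbers, or dropped
#' with a warning when \code{skipBad = TRUE}.
#'
#' \itemize{
#'   \item \code{readSpectrumCsv}: columns \code{wavelength_nm},
#'     \code{intensity} (optional constant \code{lipid_mM},
#'     \code{quencher_M}, \code{label}); returns an
#'     \linkS4class{EmissionSpectrum}.
#'   \item \code{readTitrationCsv}: columns \code{lipid_mM},
#'     \code{f_over_f0}; returns a \linkS4class{TitrationSeries}.
#'   \item \code{readQuenchCsv}: columns \code{quencher_M},
#'     \code{f0_over_f}; returns a \linkS4class{QuenchSeries}.
#'   \item \code{readCurrentsCsv}: columns \code{cell_id}, \code{toxin_nM},
#'     \code{voltage_mV}, \code{I0_nA}, \code{I_nA}; returns an
#'     \linkS4class{InhibitionSet}.
#'   \item \code{readKdTableCsv}: columns \code{toxin}, \code{kd_nM}
#'     (optional \code{kd_sem_nM}, \code{ratio}, \code{ddg_kcal_mol});
#'     returns a data.frame.
#' }
#'
#' @param path CSV file path.
#' @param skipBad Drop malformed rows instead of erroring (default FALSE).
#' @param responseKind,availableFraction,waterMolarity Metadata for
#'   \code{readTitrationCsv}.
#' @return See the list above.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
readSpectrumCsv <- function(path, skipBad = FALSE) {
  df <- .readValidatedCsv(path, c("wavelength_nm", "intensity"),
                          c("wavelength_nm", "intensity", "lipid_mM",
                            "quencher_M"), skipBad)
  df <- df[order(df$wavelength_nm), , drop = FALSE]
  new("EmissionSpectrum",
      wavelength = df$wavelength_nm, intensity = df$intensity,
      lipidTotal = if ("lipid_mM" %in% names(df)) df$lipid_mM[1] else 0,
      quencher = if ("quencher_M" %in% names(df)) df$quencher_M[1] else 0,
      label = if ("label" %in% names(df)) as.character(df$label[1]) else "")
}

#' @rdname tableIO
#' @export
readTitrationCsv <- function(path, responseKind = "intensity_at_320nm",
                             availableFraction = 0.60,
                             waterMolarity = 55.3, skipBad = FALSE) {
  df <- .readValidatedCsv(path, c("lipid_mM", "f_over_f0"),
                          c("lipid_mM", "f_over_f0"), skipBad)
  new("TitrationSeries", lipidTotal = df$lipid_mM,
      response = df$f_over_f0, responseKind = responseKind,
      availableFraction = availableFraction,
      waterMolarity = waterMolarity)
}

#' @rdname tableIO
#' @export
readQuenchCsv <- function(path, skipBad = FALSE) {
  df <- .readValidatedCsv(path, c("quencher_M", "f0_over_f"),
                          c("quencher_M", "f0_over_f"), skipBad)
  new("QuenchSeries", quencher = df$quencher_M, ratio = df$f0_over_f)
}

#' @rdname tableIO
#' @export
readCurrentsCsv <- function(path, skipBad = FALSE) {
  df <- .readValidatedCsv(path,
    c("cell_id", "toxin_nM", "voltage_mV", "I0_nA", "I_nA"),
    c("toxin_nM", "voltage_mV", "I0_nA", "I_nA"), skipBad)
  new("InhibitionSet", records = df)
}

#' @rdname tableIO
#' @export
readKdTableCsv <- function(path, skipBad = FALSE) {
  .readValidatedCsv(path, c("toxin", "kd_nM"),
                    c("kd_nM", "kd_sem_nM", "ratio", "ddg_kcal_mol"),
                    skipBad)
}

#' Write inhibition records or a DDG table as CSV
#'
#' Inverse of the corresponding readers; numeric formatting uses R's
#' default 15 significant digits so a write/read round trip preserves
#' values.
#'
#' @param x An \linkS4class{InhibitionSet} or \linkS4class{DdgTable}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @name tableOutput
NULL

#' @rdname tableOutput
#' @export
writeCurrentsCsv <- function(x, path) {
  stopifnot(is(x, "InhibitionSet"))
  utils::write.csv(x@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tableOutput
#' @export
writeDdgTableCsv <- function(x, path) {
  stopifnot(is(x, "DdgTable"))
  utils::write.csv(x@table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged GxTx-1E alanine-scan affinity table
#'
#' Published apparent affinities for the wild-type toxin and 27 point
#' mutants against the Kv2.1 channel: columns \code{toxin}, \code{kd_nM},
#' \code{kd_sem_nM}, plus the published \code{ratio} and
#' \code{ddg_kcal_mol} columns for regression against recomputed values.
#'
#' @return data.frame with 28 rows.
#' @examples
#' head(gxtxScanTable())
#' @export
gxtxScanTable <- function() {
  readKdTableCsv(system.file("extdata", "gxtx_alanine_scan_kd.csv",
                             package = "ToxinScan", mustWork = TRUE))
}

# ---- PDB structures (via bio3d) ----

#' Read a PDB file into a StructureModel
#'
#' Parses ATOM/HETATM records with \pkg{bio3d}; multi-model (NMR) files
#' yield the requested model only (default the first). Elements are taken
#' from the element column when present, else guessed from atom names, and
#' van der Waals radii assigned from \code{\link{vdwRadii}}.
#'
#' @param path PDB file path.
#' @param model Model number for multi-model files (default 1).
#' @return A \linkS4class{StructureModel}.
#' @export
readStructurePdb <- function(path, model = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nModels <- nrow(pdb$xyz)
  if (model < 1L || model > nModels)
    stop("model ", model, " not present (file has ", nModels, ")",
         call. = FALSE)
  a <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- .guessElement(a$elety)
  elem[is.na(elem) | elem == ""] <- .guessElement(a$elety[
    is.na(elem) | elem == ""])
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  new("StructureModel", atoms = data.frame(
    chain = chain, resno = a$resno, resid = a$resid, elety = a$elety,
    element = toupper(elem),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = .radiusForElement(elem)), modelIndex = as.integer(model))
}

#' Write a StructureModel as a PDB file
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeStructurePdb <- function(structure, path) {
  stopifnot(is(structure, "StructureModel"))
  a <- structure@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

# ---- configured pipeline runs ----

#' Run configured analysis stages
#'
#' Executes the analysis stages named in a configuration (a named list, or
#' a path to a YAML/JSON file) and returns their outputs with provenance.
#' Recognized stage blocks:
#' \itemize{
#'   \item \code{partition}: \code{titration_csv} (+ optional
#'     \code{response_kind}, \code{available_fraction},
#'     \code{water_molarity}) -> \linkS4class{PartitionFit}.
#'   \item \code{sternvolmer}: \code{quench_csv} (+ optional
#'     \code{fix_intercept}) -> \linkS4class{SternVolmerFit}.
#'   \item \code{occupancy}: \code{currents_csv} (+ optional
#'     \code{plateau_tolerance}, \code{n_sites}, \code{aggregate} =
#'     \code{"mean"} or \code{"joint"}) -> per-toxin
#'     \linkS4class{KdEstimate} list. \code{"mean"} inverts each
#'     (cell, concentration) F_u separately and averages; \code{"joint"}
#'     fits one K_d per cell across its concentrations first.
#'   \item \code{ddg}: \code{kd_csv}, \code{wt_label} (+ optional
#'     \code{temperature_K}) -> \linkS4class{DdgTable}.
#'   \item \code{sasa}: \code{pdb}, optional \code{probe}, \code{points},
#'     \code{model} -> \linkS4class{SasaReport}.
#'   \item \code{dsasa}: \code{pdb}, \code{component_chains}, optional
#'     \code{probe}, \code{points} -> \linkS4class{DeltaSasaReport}.
#' }
#' Identical configuration and inputs give identical numeric outputs; the
#' provenance block (timestamp) is the only run-dependent part.
#'
#' @param config Named list, or path to a YAML or JSON configuration file.
#' @return A \linkS4class{ResultBundle}.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  results <- list()
  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$partition)) {
    p <- config$partition
    results$partition <- runStage("partition", function() {
      s <- readTitrationCsv(
        p$titration_csv,
        responseKind = p$response_kind %||% "intensity_at_320nm",
        availableFraction = p$available_fraction %||% 0.60,
        waterMolarity = p$water_molarity %||% 55.3)
      fitPartition(s)
    })
  }
  if (!is.null(config$sternvolmer)) {
    p <- config$sternvolmer
    results$sternvolmer <- runStage("sternvolmer", function()
      fitSternVolmer(readQuenchCsv(p$quench_csv),
                     fixIntercept = p$fix_intercept %||% TRUE))
  }
  if (!is.null(config$occupancy)) {
    p <- config$occupancy
    results$occupancy <- runStage("occupancy", function() {
      set <- readCurrentsCsv(p$currents_csv)
      fu <- fractionUnbound(set,
                            plateauTolerance = p$plateau_tolerance %||% 0.10)
      n <- p$n_sites %||% 4L
      mode <- p$aggregate %||% "mean"
      if (mode == "joint") {
        kds <- vapply(split(fu, fu$cell_id), function(g)
          fitConcentrationResponse(g$F_u, g$toxin_nM, n)$kd, numeric(1))
      } else {
        kds <- kdFourSite(fu$F_u, fu$toxin_nM, n)
      }
      aggregateKd(unname(kds))
    })
  }
  if (!is.null(config$ddg)) {
    p <- config$ddg
    results$ddg <- runStage("ddg", function()
      buildDdgTable(readKdTableCsv(p$kd_csv), wtLabel = p$wt_label,
                    temperatureK = p$temperature_K %||% 298.15))
  }
  if (!is.null(config$sasa)) {
    p <- config$sasa
    results$sasa <- runStage("sasa", function()
      shrakeRupleySasa(readStructurePdb(p$pdb, model = p$model %||% 1L),
                       probe = p$probe %||% 1.4,
                       nPoints = p$points %||% 960L))
  }
  if (!is.null(config$dsasa)) {
    p <- config$dsasa
    results$dsasa <- runStage("dsasa", function()
      deltaSasa(readStructurePdb(p$pdb, model = p$model %||% 1L),
                componentChains = p$component_chains,
                probe = p$probe %||% 1.4, nPoints = p$points %||% 960L))
  }
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(cfgJson, tmp)
  new("ResultBundle", results = results,
      provenance = list(
        config = config,
        configHash = unname(tools::md5sum(tmp)),
        packageVersion = as.character(utils::packageVersion("ToxinScan")),
        timestamp = format(Sys.time(), tz = "UTC")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
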