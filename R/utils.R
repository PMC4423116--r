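# internal helpers shared across modules

.assertNumber <- function(x, name, lower = -Inf, upper = Inf,
                          strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("'%s' = %g is outside the allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

.assertNumeric <- function(x, name, lower = -Inf, allowEmpty = FALSE) {
  if (!is.numeric(x) || (!allowEmpty && length(x) == 0L))
    stop(sprintf("'%s' must be a non-empty numeric vector", name),
         call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  if (any(x < lower))
    stop(sprintf("'%s' contains values below %g", name, lower), call. = FALSE)
  invisible(x)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's stream
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Van der Waals radii by element
#'
#' Element-wise van der Waals radii (Bondi values, Angstrom) used to assign
#' atomic radii for solvent-accessible surface area calculations. Elements
#' missing from the table fall back to the carbon radius.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @examples
#' vdwRadii()[["C"]]
#' @export
vdwRadii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

# element symbol from a PDB atom name ("CA" -> "C", "1HG" -> "H", "SD" -> "S")
.guessElement <- function(elety) {
  nm <- toupper(gsub("[0-9' ]", "", elety))
  two <- substr(nm, 1L, 2L)
  one <- substr(nm, 1L, 1L)
  tab <- vdwRadii()
  ifelse(two %in% c("CL", "BR", "SE") & two %in% names(tab), two, one)
}

.radiusForElement <- function(element) {
  tab <- vdwRadii()
  r <- tab[toupper(element)]
  r[is.na(r)] <- tab[["C"]]
  unname(r)
}
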