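# Elemental-formula arithmetic: monoisotopic masses, adduct m/z, ppm errors.
# Masses are monoisotopic (most-abundant isotope, IUPAC 2021), in Da.

#' Monoisotopic masses of the supported elements
#'
#' Most-abundant-isotope masses (Da) for the element set used in suspect
#' screening of food-contact chemicals. Values carry >= 9 decimal places.
#'
#' @format Named numeric vector, one entry per element symbol.
#' @keywords internal
.element_masses <- c(
  C  = 12.000000000,
  H  = 1.007825032,
  N  = 14.003074005,
  O  = 15.994914620,
  S  = 31.972071174,
  Cl = 34.968852682,
  Br = 78.918337100,
  F  = 18.998403163,
  P  = 30.973761998,
  Na = 22.989769282,
  K  = 38.963706487
)

#' Mass difference between a protonated ion and its neutral molecule (Da).
#' Proton mass, i.e. hydrogen atom minus one electron.
#' @keywords internal
.proton_mass <- 1.007276

#' Parse a molecular formula in Hill notation
#'
#' Parses strings such as `"C12H10O2"` into a `chem_formula` object, a named
#' integer vector of element counts. Whitespace between element tokens is
#' ignored, so `"C12 H10 O2"` is accepted. An omitted count means 1.
#'
#' @param text Formula string (Hill notation, e.g. `"C8H10O5"`).
#' @return A `chem_formula`: named integer vector of per-element counts.
#' @examples
#' parse_formula("C12H10O2")
#' monoisotopic_mass(parse_formula("C7H9NO2"))
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) {
    stop("empty formula string")
  }
  toks <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  matched <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE))[[1]]
  if (sum(nchar(matched)) != nchar(s)) {
    stop("cannot parse formula: ", text)
  }
  elems <- sub("[0-9]*$", "", matched)
  counts <- sub("^[A-Za-z]+", "", matched)
  counts <- ifelse(counts == "", 1L, suppressWarnings(as.integer(counts)))
  unknown <- setdiff(elems, names(.element_masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("element counts must be positive integers in: ", text)
  }
  # collapse repeated symbols (e.g. "CH3COOH" style inputs)
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  out <- as.integer(out)
  names(out) <- unique(elems)
  structure(out[order_hill(names(out))], class = "chem_formula")
}

# Hill order: C, then H, then remaining symbols alphabetically; if no carbon,
# everything alphabetical.
order_hill <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    match(intersect(c("C", "H", rest), symbols), symbols)
  } else {
    order(symbols)
  }
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (",
      sprintf("%.6f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic (exact) mass of a formula
#'
#' Sum over elements of count times the most-abundant-isotope mass.
#'
#' @param f A `chem_formula` (from [parse_formula()]) or a formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C12H10O2")  # 186.068080
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  sum(.element_masses[names(f)] * as.numeric(f))
}

#' Ion m/z of an adduct of a neutral molecule
#'
#' Positive electrospray produces predominantly protonated molecules; the
#' supported adducts are `[M+H]+` (default) and `[M+Na]+`-free workflows are
#' out of scope. The proton mass used (1.007276 Da) accounts for the electron.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), > 0.
#' @param adduct Adduct label; only `"[M+H]+"` is supported.
#' @return Ion m/z in Da.
#' @examples
#' adduct_mz(186.068080)  # 187.075356
#' @export
adduct_mz <- function(neutral_mass, adduct = "[M+H]+") {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  if (!identical(adduct, "[M+H]+")) {
    stop("unsupported adduct: ", adduct)
  }
  neutral_mass + .proton_mass
}

#' Signed mass error in parts per million
#'
#' `(measured - theoretical) / theoretical * 1e6`, the usual sign convention
#' in non-target screening mass-error columns.
#'
#' @param measured Measured mass or m/z (Da).
#' @param theoretical Theoretical mass or m/z (Da), > 0.
#' @return Signed error in ppm.
#' @examples
#' ppm_error(186.0681, 186.068080)  # about +0.11 ppm
#' @export
ppm_error <- function(measured, theoretical) {
  stopifnot(is.numeric(measured), is.numeric(theoretical))
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  (measured - theoretical) / theoretical * 1e6
}

#' Round half away from zero
#'
#' Decimal rounding where .5 always rounds up in magnitude (unlike base
#' [round()]'s round-half-to-even), matching how percentages and decile sizes
#' are reported.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
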