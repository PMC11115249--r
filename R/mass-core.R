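# Elemental-formula arithmetic and exact monoisotopic mass / m/z computation.
# Everything downstream (residue model, fragment prediction, spectrum
# annotation) funnels through these few functions, so the conventions are
# fixed here once: monoisotopic atomic masses to >= 7 decimals, the electron
# mass subtracted for cations and added for anions, and ppm errors reported
# unsigned to match mass-accuracy tables.

ELECTRON_MASS <- 0.000548579909

.mass_env <- new.env(parent = emptyenv())

#' Monoisotopic atomic mass table
#'
#' Returns the package's authoritative table of monoisotopic atomic masses
#' (most-abundant isotope, IUPAC 2021), read from the plain-text resource
#' shipped in `inst/extdata/atomic_masses.csv`.
#'
#' @return A data frame with columns `element` and `monoisotopic_mass` (Da).
#' @export
atomic_masses <- function() {
  if (is.null(.mass_env$table)) {
    path <- system.file("extdata", "atomic_masses.csv", package = "depsinet",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .mass_env$table <- tab
    .mass_env$lookup <- stats::setNames(tab$monoisotopic_mass, tab$element)
  }
  .mass_env$table
}

.element_masses <- function() {
  atomic_masses()
  .mass_env$lookup
}

#' Parse a Hill-notation elemental formula
#'
#' Accepts strings such as `"C44H64N4O8"` or `"C7H11NO2Na"`; an implicit
#' count is 1 and a trailing charge sign (`+` or `-`) is ignored (charge is
#' carried by [ion_species()], not by the formula).
#'
#' @param text A single formula string.
#' @return A `chem_formula`: a named integer vector of element counts in
#'   canonical Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C44H64N4O8")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop2("formula string must be a single non-empty string")
  body <- sub("[+-]+$", "", text)
  if (!nzchar(body)) stop2("formula string has no element symbols: ", text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", body)[[1]]
  pieces <- regmatches(body, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(body))
    stop2("cannot parse formula: ", text)
  syms <- sub("[0-9]*$", "", pieces)
  cnts <- sub("^[A-Z][a-z]?", "", pieces)
  cnts <- ifelse(cnts == "", 1L, as.integer(cnts))
  known <- names(.element_masses())
  bad <- setdiff(syms, known)
  if (length(bad))
    stop2("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  counts <- tapply(cnts, syms, sum)
  chem_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Construct a `chem_formula` from named counts
#'
#' @param counts Named integer vector, element symbol -> count (>= 0).
#' @return A `chem_formula` in canonical Hill order with zero counts dropped.
#' @export
chem_formula <- function(counts = integer()) {
  if (length(counts) && is.null(names(counts)))
    stop2("counts must be named by element symbol")
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop2("element counts must be non-negative")
  storage.mode(counts) <- "integer"
  counts <- counts[hill_order(names(counts))]
  structure(counts, class = "chem_formula")
}

hill_order <- function(elements) {
  # Hill convention: C first, H second (when C present), rest alphabetical.
  if (!length(elements)) return(integer(0))
  pr <- if ("C" %in% elements) {
    ifelse(elements == "C", 1L, ifelse(elements == "H", 2L, 3L))
  } else rep(3L, length(elements))
  order(pr, elements)
}

#' @export
format.chem_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  chem_formula(out)
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  if (missing(e2)) stop2("unary minus is not defined for formulas")
  els <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] - unclass(e2)
  if (any(out < 0))
    stop2("formula subtraction would give negative count for: ",
          paste(names(out)[out < 0], collapse = ", "))
  chem_formula(out)
}

#' @export
`==.chem_formula` <- function(e1, e2) {
  identical(format(chem_formula(unclass(e1))), format(chem_formula(unclass(e2))))
}

formula_sum <- function(formulas) {
  Reduce(`+`, formulas, chem_formula())
}

formula_multiply <- function(f, k) {
  stopifnot(k >= 0)
  chem_formula(unclass(f) * as.integer(k))
}

#' Monoisotopic mass of a neutral formula
#'
#' @param f A `chem_formula` or a formula string.
#' @return Mass in Da; 0 for the empty formula.
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (!length(f)) return(0)
  masses <- .element_masses()
  sum(unclass(f) * masses[names(f)])
}

as_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else parse_formula(f)
}

# ---- ion species ----------------------------------------------------------

.ADDUCTS <- list(
  "M+H"   = list(delta = c(H = 1L),           sign = +1L, charge = +1L),
  "M+Na"  = list(delta = c(Na = 1L),          sign = +1L, charge = +1L),
  "M+NH4" = list(delta = c(N = 1L, H = 4L),   sign = +1L, charge = +1L),
  "M+K"   = list(delta = c(K = 1L),           sign = +1L, charge = +1L),
  "M-H"   = list(delta = c(H = 1L),           sign = -1L, charge = -1L)
)

#' Ion species (adduct + charge)
#'
#' @param adduct One of `"M+H"`, `"M+Na"`, `"M+NH4"`, `"M+K"`, `"M-H"`.
#' @param charge Signed integer charge; must be consistent with the adduct
#'   polarity (`"M-H"` only negative, the others only positive).
#' @export
ion_species <- function(adduct, charge = NULL) {
  adduct <- gsub("\u2212", "-", adduct)   # unicode minus
  adduct <- gsub("[][]|\\^.*$", "", adduct)    # tolerate "[M+Na]+" style
  adduct <- sub("(?<=[A-Za-z0-9])[+-]+$", "", adduct, perl = TRUE)
  if (!adduct %in% names(.ADDUCTS))
    stop2("unknown adduct: ", adduct, " (known: ",
          paste(names(.ADDUCTS), collapse = ", "), ")")
  spec <- .ADDUCTS[[adduct]]
  charge <- charge %||% spec$charge
  if (charge == 0L) stop2("charge 0 is not a valid ion species")
  if (sign(charge) != sign(spec$charge))
    stop2("adduct ", adduct, " cannot carry charge ", charge)
  structure(list(adduct = adduct, charge = as.integer(charge),
                 delta = chem_formula(spec$delta), sign = spec$sign,
                 polarity = if (charge > 0) "positive" else "negative"),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat("<ion_species> [", x$adduct, "]", if (x$charge > 0) "+" else "-", "\n",
      sep = "")
  invisible(x)
}

#' Charged-species formula for a neutral molecule under an ion species
#'
#' e.g. `C44H64N4O8` under `M+H` gives `C44H65N4O8` (the printed cation
#' composition); under `M-H` gives `C44H63N4O8`.
#'
#' @param f Neutral formula (`chem_formula` or string).
#' @param species An [ion_species()].
#' @export
charged_formula <- function(f, species) {
  f <- as_formula(f)
  if (species$sign > 0) f + species$delta else f - species$delta
}

#' Theoretical m/z of an ion
#'
#' `m/z = (mass(M) + sign * mass(delta) - charge * m_e) / |charge|`, i.e. the
#' electron mass is subtracted for cations and added for anions. Reproduces
#' published 4-decimal "calcd" values for singly charged adducts.
#'
#' @param f Neutral molecular formula (`chem_formula` or string).
#' @param species An [ion_species()], or an adduct string.
#' @return m/z in Thomson.
#' @examples
#' ion_mz("C44H64N4O8", "M+H")   # 777.4797
#' ion_mz("C44H64N4O8", "M+Na")  # 799.4616
#' @export
ion_mz <- function(f, species) {
  if (is.character(species)) species <- ion_species(species)
  m <- monoisotopic_mass(as_formula(f)) +
    species$sign * monoisotopic_mass(species$delta)
  (m - species$charge * ELECTRON_MASS) / abs(species$charge)
}

# m/z directly from a charged-species formula (cationizing atom included).
mz_from_charged <- function(fc, charge = 1L) {
  (monoisotopic_mass(fc) - charge * ELECTRON_MASS) / abs(charge)
}

#' Relative mass error in ppm
#'
#' Reported unsigned by default, matching the convention of instrument
#' mass-accuracy tables; `signed = TRUE` gives `1e6 * (obs - theo) / theo`.
#'
#' @param observed,theoretical m/z values (> 0).
#' @param signed Keep the sign? Default `FALSE`.
#' @export
ppm_error <- function(observed, theoretical, signed = FALSE) {
  if (any(theoretical <= 0)) stop2("theoretical m/z must be > 0")
  if (any(observed <= 0)) stop2("observed m/z must be > 0")
  ppm <- 1e6 * (observed - theoretical) / theoretical
  if (signed) ppm else abs(ppm)
}

#' Ring-plus-double-bond equivalents
#'
#' Standard CHN rule `C - H/2 + N/2 + 1`; O, S and monovalent Na are ignored.
#' Defined for neutral formulas only.
#'
#' @param f Formula or string.
#' @examples
#' rdbe("C44H64N4O8")  # 15
#' @export
rdbe <- function(f) {
  f <- as_formula(f)
  cnt <- function(el) if (el %in% names(f)) unclass(f)[[el]] else 0L
  cnt("C") - cnt("H") / 2 + cnt("N") / 2 + 1
}

CO_FORMULA_STRING <- "CO"
co_formula <- function() parse_formula(CO_FORMULA_STRING)
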