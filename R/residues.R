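# Residue alphabet and the directed cyclic depsipeptide sequence type.
#
# Residue formulas are stored DEHYDRATED (free acid minus H2O), so the neutral
# formula of a macrocycle is the plain element-wise sum over its residues:
# cyclization consumes exactly the waters the dehydrated convention already
# removed. Linear peptides would add back one H2O; they are documented but not
# needed here.

#' Construct a residue
#'
#' @param name Short residue code (e.g. `"Phe"`, `"Hba"`).
#' @param formula Dehydrated residue formula (string or `chem_formula`).
#' @param linkage_class `"amino"` (forms an amide at its alpha-amine) or
#'   `"hydroxy"` (forms an ester at its alpha-oxygen).
#' @export
residue <- function(name, formula, linkage_class = c("amino", "hydroxy")) {
  linkage_class <- match.arg(linkage_class)
  f <- as_formula(formula)
  if (monoisotopic_mass(f) <= 0) stop2("residue formula must have mass > 0")
  n_N <- if ("N" %in% names(f)) unclass(f)[["N"]] else 0L
  if (linkage_class == "amino" && n_N < 1L)
    stop2("amino residue ", name, " must contain nitrogen")
  if (linkage_class == "hydroxy" && n_N > 0L)
    stop2("hydroxy residue ", name, " must not contain nitrogen")
  structure(list(name = name, formula = f, linkage_class = linkage_class),
            class = "residue")
}

#' @export
print.residue <- function(x, ...) {
  cat(sprintf("<residue> %s  %s  (%s, %.4f Da)\n", x$name, format(x$formula),
              x$linkage_class, monoisotopic_mass(x$formula)))
  invisible(x)
}

# Residue codes that the Lxx wildcard stands for (all C6H11NO).
LXX_GROUP <- c("Leu", "Ile", "MeVal")

#' Load a residue alphabet
#'
#' The default alphabet ships with the package (Phe, Leu/Ile/MeVal/Lxx, Hba,
#' Lac, Hda, Hdda); a user file extends or overrides it. Format: CSV with
#' columns `name, formula, linkage_class`, `#` comments allowed.
#'
#' @param path Optional path to an extension file; `NULL` returns the default
#'   alphabet alone.
#' @param base Alphabet to extend; defaults to the shipped alphabet. Pass an
#'   empty list to load a file standalone.
#' @return Named list of [residue()] objects.
#' @export
load_alphabet <- function(path = NULL, base = NULL) {
  if (is.null(base)) {
    base_path <- system.file("extdata", "residue_alphabet.csv",
                             package = "depsinet", mustWork = TRUE)
    base <- read_alphabet_file(base_path)
  }
  if (is.null(path)) return(base)
  ext <- read_alphabet_file(path)
  base[names(ext)] <- ext
  base
}

read_alphabet_file <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         strip.white = TRUE)
  need <- c("name", "formula", "linkage_class")
  if (!all(need %in% names(tab)))
    stop2("alphabet file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop2("duplicate residue name(s) in alphabet file: ",
          paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    residue(tab$name[i], tab$formula[i], tab$linkage_class[i])
  })
  stats::setNames(out, tab$name)
}

#' Default residue alphabet
#' @export
default_alphabet <- function() load_alphabet()

resolve_residues <- function(names, alphabet) {
  missing <- setdiff(names, names(alphabet))
  if (length(missing))
    stop2("unknown residue code(s): ", paste(unique(missing), collapse = ", "))
  alphabet[names]
}

#' Construct a cyclic depsipeptide
#'
#' @param residues Character vector of residue codes, length >= 2, in the
#'   written ring order. Rings are directional; no canonical start exists
#'   (compare with [cyclic_equivalent()]).
#' @param alphabet Residue alphabet; default the shipped one.
#' @export
cyclic_peptide <- function(residues, alphabet = default_alphabet()) {
  if (length(residues) < 2L) stop2("a cyclic peptide needs >= 2 residues")
  res <- resolve_residues(residues, alphabet)
  structure(list(residues = as.character(residues), resolved = res,
                 alphabet = alphabet, cyclic = TRUE),
            class = "cyclic_peptide")
}

#' @export
print.cyclic_peptide <- function(x, ...) {
  cat("<cyclic_peptide> cyclo(", paste(x$residues, collapse = "-"), ")  ",
      format(peptide_formula(x)), "\n", sep = "")
  invisible(x)
}

#' Neutral molecular formula of a cyclic depsipeptide
#'
#' Element-wise sum of the dehydrated residue formulas.
#'
#' @param p A [cyclic_peptide()].
#' @examples
#' p <- cyclic_peptide(c("Phe", "Lxx", "Hba", "Phe", "Lxx", "Hda"))
#' format(peptide_formula(p))  # "C44H64N4O8"
#' @export
peptide_formula <- function(p) {
  formula_sum(lapply(p$resolved, `[[`, "formula"))
}

residue_names_match <- function(a, b, wildcard = FALSE) {
  if (a == b) return(TRUE)
  if (!wildcard) return(FALSE)
  (a == "Lxx" && b %in% LXX_GROUP) || (b == "Lxx" && a %in% LXX_GROUP)
}

#' Cyclic equivalence of two directed residue sequences
#'
#' TRUE iff some rotation of `a` equals `b` residue-by-residue; reflections
#' never match (peptide rings are directional). With `wildcard = TRUE` the
#' codes Leu, Ile and MeVal each match the ambiguity code Lxx.
#'
#' @param a,b Character vectors of residue codes, or [cyclic_peptide()]s.
#' @param wildcard Honor the Lxx wildcard? Default `FALSE`.
#' @export
cyclic_equivalent <- function(a, b, wildcard = FALSE) {
  if (inherits(a, "cyclic_peptide")) a <- a$residues
  if (inherits(b, "cyclic_peptide")) b <- b$residues
  n <- length(a)
  if (n != length(b)) return(FALSE)
  for (r in seq_len(n)) {
    rot <- a[c(r:n, seq_len(r - 1L))]
    ok <- all(vapply(seq_len(n), function(i) {
      residue_names_match(rot[i], b[i], wildcard)
    }, logical(1)))
    if (ok) return(TRUE)
  }
  FALSE
}

# Map Leu/Ile/MeVal to Lxx so mass-equivalent sequences share one canonical
# spelling; used when deduplicating de novo candidates.
wildcard_canonical <- function(residues) {
  ifelse(residues %in% LXX_GROUP, "Lxx", residues)
}
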