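# MS2 spectrum container used by the sequencer and the networking module.

#' Construct an MS2 spectrum
#'
#' @param mz,intensity Numeric peak vectors (intensities >= 0); peaks are
#'   stored sorted by m/z.
#' @param precursor_mz Precursor m/z (Thomson).
#' @param species Precursor [ion_species()] (or adduct string), or `NULL`
#'   when unknown.
#' @param id Feature id; any scalar, stored as character.
#' @param rt Retention time in minutes (optional).
#' @param neutral_formula Neutral molecular formula string when known
#'   (e.g. from an external formula-assignment tool), else `NULL`.
#' @param title Free-text title (carried through MGF round trips).
#' @export
new_spectrum <- function(mz, intensity, precursor_mz, species = NULL,
                         id = NULL, rt = NA_real_, neutral_formula = NULL,
                         title = NULL) {
  if (length(mz) != length(intensity))
    stop2("mz and intensity must have equal length")
  if (any(intensity < 0)) stop2("intensities must be >= 0")
  if (!is.null(species) && is.character(species)) species <- ion_species(species)
  o <- order(mz)
  structure(list(id = if (is.null(id)) NA_character_ else as.character(id),
                 precursor_mz = as.numeric(precursor_mz),
                 species = species,
                 peaks = data.frame(mz = as.numeric(mz[o]),
                                    intensity = as.numeric(intensity[o])),
                 rt = rt, neutral_formula = neutral_formula, title = title),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> id=%s precursor=%.4f (%s), %d peaks\n",
              x$id, x$precursor_mz,
              if (is.null(x$species)) "species unknown" else x$species$adduct,
              nrow(x$peaks)))
  invisible(x)
}
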