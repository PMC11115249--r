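# Theoretical MS2 fragment ladders for cyclic depsipeptides.
#
# Two ring-opening pathways are modeled, matching how sodiated macrocyclic
# depsipeptides actually fragment:
#
#   P1 ("lactone b"): the ring opens at an ester linkage; successive b-type
#   cleavages then peel residues off the acyl terminus one at a time, so the
#   b_k ladder is the sequence of prefix sums of the opened linear form.
#
#   P2 ("alpha a"): the ring opens at the alpha-C/C=O bond of a residue
#   (isobaric with the precursor, label a0); the first neutral loss is that
#   residue minus CO, subsequent b-type cleavages lose whole residues, and
#   the terminal retained ion x_1 is the adjacent residue still carrying the
#   CO (e.g. "Lxx-CO").
#
# Ring direction convention: in the written residue order r_1..r_n, linkage i
# joins r_i and r_{i+1 (mod n)} and is an ESTER iff r_i is hydroxy-class (the
# acyl chain runs opposite to the written order). This is the convention
# under which the published ladders of this compound family come out right;
# see the methods vignette for the full argument.

ring_linkages <- function(p) {
  n <- length(p$residues)
  cls <- vapply(p$resolved, `[[`, character(1), "linkage_class")
  data.frame(
    index = seq_len(n),
    from = p$residues,
    to = p$residues[c(2:n, 1L)],
    type = ifelse(cls == "hydroxy", "ester", "amide"),
    stringsAsFactors = FALSE
  )
}

#' Open a cyclic depsipeptide into a linear form
#'
#' @param p A [cyclic_peptide()].
#' @param pathway `"P1"` (ester/lactone b-type opening; `site` is a linkage
#'   index and must be an ester) or `"P2"` (alpha-C/C=O a-type opening;
#'   `site` is a residue index). Ring opening itself changes no mass.
#' @param site Linkage index (P1) or residue index (P2), 1-based in the
#'   written residue order.
#' @return A `linear_form`: ordered residue list plus terminal chemistry tag.
#' @export
open_ring <- function(p, pathway = c("P1", "P2"), site) {
  pathway <- match.arg(pathway)
  n <- length(p$residues)
  if (site < 1L || site > n) stop2("site out of range: ", site)
  idx_back <- function(i) ((i - 1L) %% n) + 1L
  if (pathway == "P1") {
    lk <- ring_linkages(p)
    if (lk$type[site] != "ester")
      stop2("P1 opening requires an ester linkage; linkage ", site, " (",
            lk$from[site], "-", lk$to[site], ") is an amide")
    # reverse traversal starting at the hydroxy residue: prefix sums of this
    # order are the b ions, and C-terminal losses proceed forward around the
    # ring from the residue after the opened ester.
    ord <- idx_back(site - seq_len(n) + 1L)
    terminal <- "lactone_b"
  } else {
    # loss order: opened residue first (lost as residue - CO), then forward
    # around the ring; the last listed residue is retained as x1 (+ CO).
    ord <- idx_back(site + seq_len(n) - 1L)
    terminal <- "alpha_a"
  }
  structure(list(residues = p$residues[ord], pathway = pathway, site = site,
                 site_label = paste0(pathway, "@", site, ":", p$residues[site]),
                 terminal = terminal, peptide = p),
            class = "linear_form")
}

#' Predicted fragment-ion ladder for an opened linear form
#'
#' @param lf A `linear_form` from [open_ring()].
#' @param species Singly charged [ion_species()] (or adduct string).
#' @return A data frame of fragment ions: `label`, `pathway`, `site`,
#'   `formula` (charged-species composition including the cationizing atom),
#'   `mz`, `neutral_loss` (formula that together with the fragment
#'   reconstitutes the precursor ion).
#' @export
fragment_ladder <- function(lf, species) {
  if (is.character(species)) species <- ion_species(species)
  if (abs(species$charge) != 1L)
    stop2("fragment ladders are only generated for |charge| = 1")
  res <- resolve_residues(lf$residues, lf$peptide$alphabet)
  fres <- lapply(res, `[[`, "formula")
  n <- length(fres)
  precursor <- charged_formula(formula_sum(fres), species)

  rows <- list()
  add_ion <- function(label, frag_formula) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label,
      pathway = if (lf$pathway == "P1") "P1_lactone_b" else "P2_alpha_a",
      site = lf$site_label,
      formula = format(frag_formula),
      mz = mz_from_charged(frag_formula, species$charge),
      neutral_loss = format(precursor - frag_formula),
      stringsAsFactors = FALSE
    )
  }

  if (lf$pathway == "P1") {
    ks <- if (n >= 3L) seq(n - 1L, 2L) else 1L
    for (k in ks) {
      frag <- charged_formula(formula_sum(fres[seq_len(k)]), species)
      add_ion(paste0("b", k), frag)
    }
  } else {
    add_ion("a0", precursor)  # ring-opened ion, isobaric with the precursor
    co <- co_formula()
    for (k in seq(n - 1L, 1L)) {
      keep <- fres[seq(n - k + 1L, n)]
      frag <- charged_formula(formula_sum(keep) + co, species)
      add_ion(paste0("x", k), frag)
    }
  }
  do.call(rbind, rows)
}

#' All predicted fragments of a cyclic depsipeptide
#'
#' Union of the P1 ladder over every ester linkage and the P2 ladder over
#' every residue; duplicates (same charged formula and label class) are
#' merged with provenance retained, and the table is sorted by m/z
#' descending.
#'
#' @inheritParams fragment_ladder
#' @param p A [cyclic_peptide()].
#' @export
all_fragments <- function(p, species) {
  if (is.character(species)) species <- ion_species(species)
  lk <- ring_linkages(p)
  tabs <- list()
  for (i in lk$index[lk$type == "ester"])
    tabs[[length(tabs) + 1L]] <- fragment_ladder(open_ring(p, "P1", i), species)
  for (i in seq_along(p$residues))
    tabs[[length(tabs) + 1L]] <- fragment_ladder(open_ring(p, "P2", i), species)
  tab <- do.call(rbind, tabs)
  cls <- sub("[0-9]+$", "", tab$label)
  key <- paste(tab$formula, cls)
  prov <- tapply(paste0(tab$site, "/", tab$label), key, function(x)
    paste(sort(unique(x)), collapse = ";"))
  first <- !duplicated(key)
  out <- tab[first, , drop = FALSE]
  out$provenance <- as.character(prov[key[first]])
  out <- out[order(-out$mz, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
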