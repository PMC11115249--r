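# De novo residue sequencing from MS2 neutral-loss ladders.
#
# The procedure mirrors manual depsipeptide elucidation: predicted fragment
# ladders are matched against the peak list, and candidate rings are read off
# a spectrum graph whose edges are residue-mass (or residue +/- CO) neutral
# losses, rooted at the precursor. A candidate is only returned when its
# residue-formula sum reproduces the precursor's neutral formula exactly.

#' Match predicted fragments against a peak list
#'
#' Greedy nearest-m/z matching, each peak used at most once (ties broken by
#' higher intensity, then peak order).
#'
#' @param pred Fragment table from [all_fragments()] / [fragment_ladder()].
#' @param s An [new_spectrum()] object.
#' @param tol_ppm Match tolerance in ppm (default 10; deliberately looser
#'   than instrument accuracy to absorb mixed observed/calculated values in
#'   published ladders).
#' @return A `match_report`: data frame of matches plus `coverage` (fraction
#'   of predicted ladder positions matched) and `score`
#'   (sum of log10(1 + intensity) over matches).
#' @export
match_fragments <- function(pred, s, tol_ppm = 10) {
  if (tol_ppm <= 0) stop2("tol_ppm must be > 0")
  peaks <- s$peaks
  used <- rep(FALSE, nrow(peaks))
  rows <- list()
  for (i in seq_len(nrow(pred))) {
    if (!nrow(peaks)) break
    tol <- tol_ppm * 1e-6 * pred$mz[i]
    cand <- which(!used & abs(peaks$mz - pred$mz[i]) <= tol)
    if (!length(cand)) next
    err <- abs(peaks$mz[cand] - pred$mz[i])
    cand <- cand[order(err, -peaks$intensity[cand], cand)]
    j <- cand[1L]
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      pred_row = i, label = pred$label[i], mz_pred = pred$mz[i],
      peak = j, mz_obs = peaks$mz[j], intensity = peaks$intensity[j],
      ppm = ppm_error(peaks$mz[j], pred$mz[i], signed = TRUE),
      stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pred_row = integer(), label = character(), mz_pred = numeric(),
               peak = integer(), mz_obs = numeric(), intensity = numeric(),
               ppm = numeric(), stringsAsFactors = FALSE)
  structure(list(
    matches = matches,
    coverage = if (nrow(pred)) nrow(matches) / nrow(pred) else 0,
    score = sum(log10(1 + matches$intensity)),
    n_pred = nrow(pred), tol_ppm = tol_ppm
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d/%d ladder positions (coverage %.2f), score %.2f\n",
              nrow(x$matches), x$n_pred, x$coverage, x$score))
  invisible(x)
}

# Collapse the alphabet to mass-unique residues for graph matching, preferring
# the wildcard code (Lxx) as the canonical spelling of its mass class.
matching_alphabet <- function(alphabet) {
  forms <- vapply(alphabet, function(r) format(r$formula), character(1))
  keep <- character(0)
  for (f in unique(forms)) {
    nms <- names(alphabet)[forms == f]
    keep <- c(keep, if ("Lxx" %in% nms) "Lxx" else sort(nms)[1L])
  }
  alphabet[keep]
}

#' Infer candidate cyclic residue sequences from an MS2 spectrum
#'
#' Builds a spectrum graph (nodes = peaks plus a virtual precursor node;
#' directed edges where a mass difference matches a residue mass, or a
#' residue minus CO for the a-type opening step), enumerates precursor-rooted
#' paths under both pathway interpretations, assembles cyclic candidates, and
#' ranks them by matched ladder steps, matched intensity, then mean absolute
#' ppm. Candidates are deduplicated up to rotation with the Lxx wildcard.
#'
#' @param s Spectrum with known precursor species.
#' @param neutral_formula Neutral molecular formula (string or
#'   `chem_formula`) constraining candidate composition, or `NULL` to fall
#'   back on a precursor-m/z consistency check.
#' @param alphabet Residue alphabet.
#' @param tol_ppm Ladder tolerance in ppm.
#' @param max_results Maximum number of candidate equivalence classes.
#' @param min_rel_intensity Drop peaks below this fraction of the base peak
#'   before graph construction (default 0 = keep all).
#' @return Data frame of candidates (best first): `sequence`, `formula`,
#'   `n_matched`, `coverage`, `score`, `mean_abs_ppm`, `two_pathway`.
#'   Zero rows (with a `diagnostics` attribute) when no candidate satisfies
#'   the composition constraint.
#' @export
infer_residues <- function(s, neutral_formula = NULL,
                           alphabet = default_alphabet(), tol_ppm = 10,
                           max_results = 5L, min_rel_intensity = 0) {
  if (is.null(s$species))
    stop2("precursor ion species unknown; cannot interpret the neutral-loss ladder")
  species <- s$species
  if (!is.null(neutral_formula)) neutral_formula <- as_formula(neutral_formula)
  alpha <- matching_alphabet(alphabet)
  rnames <- names(alpha)
  rform <- lapply(alpha, `[[`, "formula")
  rmass <- vapply(rform, monoisotopic_mass, numeric(1))
  rclass <- vapply(alpha, `[[`, character(1), "linkage_class")
  co_m <- monoisotopic_mass(co_formula())

  mz0 <- if (!is.null(neutral_formula)) ion_mz(neutral_formula, species)
         else s$precursor_mz
  peaks <- s$peaks
  if (nrow(peaks) && min_rel_intensity > 0)
    peaks <- peaks[peaks$intensity >= min_rel_intensity * max(peaks$intensity), ]
  peaks <- peaks[peaks$mz < mz0 - 0.5, , drop = FALSE]
  node_mz <- c(mz0, peaks$mz)          # node 1 = virtual precursor
  nn <- length(node_mz)

  # terminal acceptors -----------------------------------------------------
  x1_mz <- vapply(rform, function(f)
    mz_from_charged(charged_formula(f + co_formula(), species),
                    species$charge), numeric(1))
  hydroxy <- rnames[rclass == "hydroxy"]
  pair_tab <- do.call(rbind, lapply(hydroxy, function(a) {
    data.frame(a = a, b = rnames,
               mz = vapply(rnames, function(b)
                 mz_from_charged(charged_formula(rform[[a]] + rform[[b]],
                                                 species), species$charge),
                 numeric(1)),
               stringsAsFactors = FALSE)
  }))

  # edges -------------------------------------------------------------------
  edges <- vector("list", nn)   # per source node: data.frame(to, residue, kind)
  for (u in seq_len(nn)) {
    vs <- which(node_mz < node_mz[u] - 1)
    if (!length(vs)) { edges[u] <- list(NULL); next }
    tol <- tol_ppm * 1e-6 * node_mz[u]
    d <- node_mz[u] - node_mz[vs]
    hit <- outer(d, rmass, function(x, y) abs(x - y) <= tol)
    rows <- which(hit, arr.ind = TRUE)
    el <- if (nrow(rows)) data.frame(to = vs[rows[, 1L]],
                                     residue = rnames[rows[, 2L]],
                                     kind = "res", stringsAsFactors = FALSE)
          else NULL
    if (u == 1L) {  # a-type first step: loss of residue minus CO
      hit2 <- outer(d, rmass - co_m, function(x, y) abs(x - y) <= tol)
      rows2 <- which(hit2, arr.ind = TRUE)
      if (nrow(rows2))
        el <- rbind(el, data.frame(to = vs[rows2[, 1L]],
                                   residue = rnames[rows2[, 2L]],
                                   kind = "res_minus_co",
                                   stringsAsFactors = FALSE))
    }
    edges[u] <- list(el)
  }

  # composition constraint ---------------------------------------------------
  ring_ok <- function(ring) {
    f <- formula_sum(rform[ring])
    if (!is.null(neutral_formula)) return(f == neutral_formula)
    abs(ion_mz(f, species) - s$precursor_mz) <=
      tol_ppm * 1e-6 * s$precursor_mz
  }

  rings <- list()   # canonical string -> list(residues, from_p1, from_p2)
  register <- function(ring, origin) {
    if (!ring_ok(ring)) return(invisible())
    canon <- canonical_rotation(wildcard_canonical(ring))
    key <- paste(canon, collapse = "-")
    entry <- rings[[key]] %||% list(residues = canon, from_p1 = FALSE,
                                    from_p2 = FALSE)
    entry[[paste0("from_", tolower(origin))]] <- TRUE
    rings[[key]] <<- entry
  }

  # DFS over precursor-rooted paths ------------------------------------------
  max_depth <- 12L
  budget <- new.env(parent = emptyenv()); budget$n <- 0L
  walk <- function(node, losses, first_kind) {
    budget$n <- budget$n + 1L
    if (budget$n > 50000L) return(invisible())
    tol_here <- tol_ppm * 1e-6 * node_mz[node]
    if (node > 1L) {
      if (first_kind == "res_minus_co") {
        # P2: losses[1] is the opened residue; terminal peak must be x1
        term <- rnames[abs(node_mz[node] - x1_mz) <= tol_here]
        for (r in term)
          if (length(losses) >= 1L) register(c(losses, r), "P2")
      }
      if (first_kind == "res") {
        # P1: terminal peak is a residue pair b2 with a hydroxy lead residue
        hitp <- which(abs(node_mz[node] - pair_tab$mz) <= tol_here)
        for (h in hitp)
          register(c(pair_tab$a[h], losses, pair_tab$b[h]), "P1")
      }
    }
    if (length(losses) >= max_depth) return(invisible())
    el <- edges[[node]]
    if (is.null(el)) return(invisible())
    for (k in seq_len(nrow(el))) {
      kind <- if (node == 1L) el$kind[k] else first_kind
      if (node > 1L && el$kind[k] != "res") next
      walk(el$to[k], c(losses, el$residue[k]),
           if (node == 1L) el$kind[k] else first_kind)
    }
  }
  walk(1L, character(0), "none")

  # fast numeric scorer: same ladder model and greedy matching as
  # all_fragments + match_fragments, on masses only (used to rank the many
  # assembled rings; the returned top candidates are re-scored through the
  # full fragment tables)
  cat_add <- (species$sign * monoisotopic_mass(species$delta) -
              species$charge * ELECTRON_MASS) / abs(species$charge)
  fast_score <- function(ring) {
    rm_ <- rmass[ring]
    cls_ <- rclass[ring]
    n <- length(rm_)
    total <- sum(rm_)
    mzs <- total + cat_add
    labc <- "a"
    for (i in which(cls_ == "hydroxy")) {
      o <- ((i - seq_len(n)) %% n) + 1L
      cs <- cumsum(rm_[o])
      ks <- if (n >= 3L) 2L:(n - 1L) else 1L
      mzs <- c(mzs, cs[ks] + cat_add)
      labc <- c(labc, rep("b", length(ks)))
    }
    for (i in seq_len(n)) {
      q <- rm_[((i + seq_len(n - 1L) - 1L) %% n) + 1L]
      sufs <- rev(cumsum(rev(q)))
      mzs <- c(mzs, sufs + co_m + cat_add)
      labc <- c(labc, rep("x", n - 1L))
    }
    keep <- !duplicated(paste(round(mzs, 5), labc))
    mzs <- mzs[keep]; labc <- labc[keep]
    o <- order(-mzs)
    mzs <- mzs[o]; labc <- labc[o]
    pk_mz <- s$peaks$mz; pk_int <- s$peaks$intensity
    used <- rep(FALSE, length(pk_mz))
    nm <- 0L; tot_int <- 0; ppm_sum <- 0
    got_b <- FALSE; got_ax <- FALSE
    for (ii in seq_along(mzs)) {
      tl <- tol_ppm * 1e-6 * mzs[ii]
      cnd <- which(!used & abs(pk_mz - mzs[ii]) <= tl)
      if (!length(cnd)) next
      err <- abs(pk_mz[cnd] - mzs[ii])
      j <- cnd[order(err, -pk_int[cnd], cnd)][1L]
      used[j] <- TRUE
      nm <- nm + 1L
      tot_int <- tot_int + pk_int[j]
      ppm_sum <- ppm_sum + 1e6 * err[which(cnd == j)][1L] / mzs[ii]
      if (labc[ii] == "b") got_b <- TRUE else got_ax <- TRUE
    }
    c(n_matched = nm, coverage = nm / length(mzs),
      matched_intensity = tot_int,
      mean_abs_ppm = if (nm) ppm_sum / nm else NA_real_,
      two_pathway = as.numeric(got_b && got_ax))
  }

  # score and rank ------------------------------------------------------------
  if (!length(rings)) {
    out <- data.frame(sequence = character(), formula = character(),
                      n_matched = integer(), coverage = numeric(),
                      score = numeric(), mean_abs_ppm = numeric(),
                      two_pathway = logical(), stringsAsFactors = FALSE)
    attr(out, "diagnostics") <- sprintf(
      "no ring satisfied the composition constraint (%d graph paths explored)",
      budget$n)
    return(out)
  }
  pre <- t(vapply(rings, function(entry) fast_score(entry$residues),
                  c(n_matched = 0, coverage = 0, matched_intensity = 0,
                    mean_abs_ppm = 0, two_pathway = 0)))
  seqs <- vapply(rings, function(e) paste(e$residues, collapse = "-"),
                 character(1))
  # ranking: matched ladder steps, then coverage (penalizing predicted-but-
  # unobserved ions), then matched intensity, mean |ppm|, lexicographic
  o <- order(-pre[, "n_matched"], -pre[, "coverage"],
             -pre[, "matched_intensity"], pre[, "mean_abs_ppm"], seqs)
  top <- rings[o[seq_len(min(max_results, length(o)))]]

  scored <- lapply(top, function(entry) {
    p <- cyclic_peptide(entry$residues, alphabet)
    rep <- match_fragments(all_fragments(p, species), s, tol_ppm)
    lab <- sub("[0-9]+$", "", rep$matches$label)
    data.frame(
      sequence = paste(entry$residues, collapse = "-"),
      formula = format(peptide_formula(p)),
      n_matched = nrow(rep$matches),
      coverage = rep$coverage,
      score = rep$score,
      matched_intensity = sum(rep$matches$intensity),
      mean_abs_ppm = if (nrow(rep$matches)) mean(abs(rep$matches$ppm)) else NA_real_,
      two_pathway = any(lab == "b") && any(lab %in% c("a", "x")),
      from_p1 = entry$from_p1, from_p2 = entry$from_p2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, scored)
  rownames(out) <- NULL
  out
}

#' Assign congeners of a reference sequence by residue substitution
#'
#' For each spectrum, evaluates every combination of the given residue swaps
#' applied to the reference ring, keeps the combinations whose molecular
#' formula is consistent with that spectrum's precursor (its neutral formula
#' when known, otherwise its precursor m/z), and reports the best-scoring
#' variant. Spectra with no consistent variant are reported unassigned.
#'
#' @param reference A [cyclic_peptide()] or character residue vector.
#' @param spectra List of spectra (known precursor species each).
#' @param substitution_pairs List of length-2 character vectors of mutually
#'   substitutable residues; default Hba<->Lac and Hda<->Hdda.
#' @param alphabet Residue alphabet.
#' @param tol_ppm Tolerance for precursor consistency and ladder matching.
#' @export
annotate_congeners <- function(reference, spectra,
                               substitution_pairs = list(c("Hba", "Lac"),
                                                         c("Hda", "Hdda")),
                               alphabet = default_alphabet(), tol_ppm = 10) {
  ref <- if (inherits(reference, "cyclic_peptide")) reference$residues
         else as.character(reference)
  # applicable swap for each pair, as from -> to
  swaps <- list()
  for (pr in substitution_pairs) {
    if (pr[1] %in% ref) swaps[[length(swaps) + 1L]] <- pr
    else if (pr[2] %in% ref) swaps[[length(swaps) + 1L]] <- rev(pr)
  }
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(swaps)))
  if (!nrow(combos)) combos <- data.frame(row.names = 1)

  rows <- lapply(seq_along(spectra), function(si) {
    s <- spectra[[si]]
    if (is.null(s$species)) stop2("spectrum ", s$id, " has unknown ion species")
    best <- NULL
    for (ci in seq_len(nrow(combos))) {
      var <- ref
      applied <- character(0)
      for (k in seq_along(swaps)) {
        if (isTRUE(combos[ci, k])) {
          var[var == swaps[[k]][1]] <- swaps[[k]][2]
          applied <- c(applied, paste0(swaps[[k]][1], "->", swaps[[k]][2]))
        }
      }
      p <- cyclic_peptide(var, alphabet)
      pf <- peptide_formula(p)
      ok <- if (!is.null(s$neutral_formula)) pf == as_formula(s$neutral_formula)
            else abs(ion_mz(pf, s$species) - s$precursor_mz) <=
                 tol_ppm * 1e-6 * s$precursor_mz
      if (!ok) next
      rep <- match_fragments(all_fragments(p, s$species), s, tol_ppm)
      cand <- data.frame(
        spectrum = s$id, assigned = TRUE,
        sequence = paste(var, collapse = "-"), formula = format(pf),
        substitutions = if (length(applied)) paste(applied, collapse = ";")
                        else "identity",
        n_swaps = length(applied), n_matched = nrow(rep$matches),
        score = rep$score, stringsAsFactors = FALSE)
      if (is.null(best) ||
          cand$n_matched > best$n_matched ||
          (cand$n_matched == best$n_matched && cand$score > best$score) ||
          (cand$n_matched == best$n_matched && cand$score == best$score &&
           cand$n_swaps < best$n_swaps))
        best <- cand
    }
    best %||% data.frame(spectrum = s$id, assigned = FALSE,
                         sequence = NA_character_, formula = NA_character_,
                         substitutions = NA_character_, n_swaps = NA_integer_,
                         n_matched = NA_integer_, score = NA_real_,
                         stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
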