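# Feature-based molecular networking (modified-cosine edges) and ion-identity
# grouping of adducts by chromatographic peak-shape correlation.

#' Molecular networking parameters
#'
#' Defaults follow common feature-based molecular-networking practice:
#' minimum cosine 0.7, 0.01 Da precursor/fragment tolerances, at least 6
#' matched fragment ions per edge.
#'
#' @param min_cosine Minimum modified-cosine score for an edge, in (0, 1].
#' @param frag_tol_da,precursor_tol_da Fragment / precursor tolerances (Da).
#' @param min_matched_peaks Minimum matched fragment ions per edge.
#' @export
network_params <- function(min_cosine = 0.7, frag_tol_da = 0.01,
                           precursor_tol_da = 0.01, min_matched_peaks = 6L) {
  if (min_cosine <= 0 || min_cosine > 1) stop2("min_cosine must be in (0, 1]")
  if (frag_tol_da <= 0 || precursor_tol_da <= 0) stop2("tolerances must be > 0")
  structure(list(min_cosine = min_cosine, frag_tol_da = frag_tol_da,
                 precursor_tol_da = precursor_tol_da,
                 min_matched_peaks = as.integer(min_matched_peaks)),
            class = "network_params")
}

#' Modified cosine similarity between two MS2 spectra
#'
#' Intensities are square-root transformed (switchable), then peak pairs are
#' admissible when their m/z difference is within `frag_tol_da` of either 0
#' or the precursor m/z difference; a one-to-one pairing is chosen greedily
#' by descending intensity product.
#'
#' @param a,b Spectra.
#' @param frag_tol_da Fragment tolerance in Da.
#' @param sqrt_transform Square-root the intensities first? Default `TRUE`.
#' @return `list(score, n_matched)` with score in `[0, 1]`.
#' @export
modified_cosine <- function(a, b, frag_tol_da = 0.01, sqrt_transform = TRUE) {
  pa <- a$peaks; pb <- b$peaks
  if (!nrow(pa) || !nrow(pb)) return(list(score = 0, n_matched = 0L))
  ia <- if (sqrt_transform) sqrt(pa$intensity) else pa$intensity
  ib <- if (sqrt_transform) sqrt(pb$intensity) else pb$intensity
  na <- sqrt(sum(ia^2)); nb <- sqrt(sum(ib^2))
  if (na == 0 || nb == 0) return(list(score = 0, n_matched = 0L))
  shift <- a$precursor_mz - b$precursor_mz
  d <- outer(pa$mz, pb$mz, `-`)
  adm <- abs(d) <= frag_tol_da | abs(d - shift) <= frag_tol_da
  idx <- which(adm, arr.ind = TRUE)
  if (!nrow(idx)) return(list(score = 0, n_matched = 0L))
  prod <- ia[idx[, 1L]] * ib[idx[, 2L]]
  o <- order(-prod, idx[, 1L], idx[, 2L])
  used_a <- rep(FALSE, nrow(pa)); used_b <- rep(FALSE, nrow(pb))
  total <- 0; nmatch <- 0L
  for (k in o) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    total <- total + prod[k]
    nmatch <- nmatch + 1L
  }
  list(score = min(1, total / (na * nb)), n_matched = nmatch)
}

#' Build a molecular network from MS2 spectra
#'
#' An edge is kept iff modified cosine >= `min_cosine` AND the number of
#' matched fragment ions >= `min_matched_peaks`. No top-K neighbor pruning is
#' applied. Connected components are labeled as molecular families
#' (singletons included).
#'
#' @param spectra List of spectra, each with a feature id.
#' @param params [network_params()].
#' @return `list(edges, families)`: `edges` a data frame
#'   (`node_a, node_b, kind, score, n_matched`), `families` a named integer
#'   vector mapping feature id to component label.
#' @export
build_network <- function(spectra, params = network_params()) {
  ids <- vapply(spectra, function(s) s$id, character(1))
  if (anyNA(ids) || any(!nzchar(ids))) stop2("every spectrum needs a feature id")
  if (anyDuplicated(ids)) stop2("duplicate spectrum feature ids")
  o <- order(ids)
  spectra <- spectra[o]; ids <- ids[o]
  n <- length(spectra)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      mc <- modified_cosine(spectra[[i]], spectra[[j]], params$frag_tol_da)
      if (mc$score >= params$min_cosine &&
          mc$n_matched >= params$min_matched_peaks)
        rows[[length(rows) + 1L]] <- data.frame(
          node_a = ids[i], node_b = ids[j], kind = "cosine",
          score = mc$score, n_matched = mc$n_matched,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_a = character(), node_b = character(), kind = character(),
               score = numeric(), n_matched = integer(),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  list(edges = edges, families = stats::setNames(as.integer(comp), names(comp)))
}

# pairwise adduct m/z deltas among singly charged cation species
default_adduct_deltas <- function() {
  adds <- c("M+H", "M+Na", "M+NH4", "M+K")
  mzs <- vapply(adds, function(a) ion_mz(chem_formula(), a), numeric(1))
  out <- numeric(0)
  for (i in seq_along(adds)) for (j in seq_along(adds)) {
    if (i >= j) next
    d <- abs(mzs[i] - mzs[j])
    out[paste0(adds[i], "/", adds[j])] <- d
  }
  out
}

#' Ion-identity grouping parameters
#'
#' @param rt_tol_min Retention-time tolerance in minutes (default 0.05).
#' @param min_shape_corr Minimum Pearson correlation of chromatographic peak
#'   shapes (default 0.85, strict inequality).
#' @param adduct_deltas Named vector of absolute adduct m/z differences; the
#'   default covers H/Na/NH4/K pairs (e.g. Na-H = 21.98194 Da).
#' @export
ion_identity_params <- function(rt_tol_min = 0.05, min_shape_corr = 0.85,
                                adduct_deltas = default_adduct_deltas()) {
  if (min_shape_corr < 0 || min_shape_corr > 1)
    stop2("min_shape_corr must be in [0, 1]")
  structure(list(rt_tol_min = rt_tol_min, min_shape_corr = min_shape_corr,
                 adduct_deltas = adduct_deltas), class = "ion_identity_params")
}

#' Group MS1 features that are different ion species of one molecule
#'
#' Two features are linked when their retention times agree within
#' `rt_tol_min`, their extracted-ion chromatograms correlate with Pearson r
#' strictly greater than `min_shape_corr`, and their m/z difference matches a
#' known adduct delta within 0.01 Da. Transitive closure of links forms the
#' groups; each group is annotated with an inferred neutral mass (lowest-m/z
#' member assumed protonated).
#'
#' @param features Data frame with columns `id`, `mz`, `rt`.
#' @param eics Matrix of EIC traces on a shared time grid, one column per
#'   feature id (column names must match `features$id`). Features lacking a
#'   trace are left ungrouped (with a message).
#' @param params [ion_identity_params()].
#' @param mz_tol_da Adduct-delta tolerance in Da.
#' @return `list(groups, edges)`: `groups` a data frame
#'   (`id, group, neutral_mass`), `edges` the accepted pair links.
#' @export
ion_identity_groups <- function(features, eics, params = ion_identity_params(),
                                mz_tol_da = 0.01) {
  ids <- as.character(features$id)
  has_trace <- ids %in% colnames(eics)
  if (any(!has_trace))
    message("ion_identity_groups: no EIC trace for feature(s) ",
            paste(ids[!has_trace], collapse = ", "), "; left ungrouped")
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) { parent[find(i)] <<- find(j) }
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (!has_trace[i] || !has_trace[j]) next
      if (abs(features$rt[i] - features$rt[j]) > params$rt_tol_min) next
      dmz <- abs(features$mz[i] - features$mz[j])
      hit <- which(abs(params$adduct_deltas - dmz) <= mz_tol_da)
      if (!length(hit)) next
      r <- suppressWarnings(stats::cor(eics[, ids[i]], eics[, ids[j]]))
      if (is.na(r) || r <= params$min_shape_corr) next
      union2(i, j)
      rows[[length(rows) + 1L]] <- data.frame(
        node_a = ids[i], node_b = ids[j], kind = "ion_identity",
        score = r, n_matched = NA_integer_,
        delta = names(params$adduct_deltas)[hit[1L]],
        stringsAsFactors = FALSE)
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  grp <- match(grp, unique(grp))
  proton <- ion_mz(chem_formula(), "M+H")
  neutral <- vapply(split(seq_len(n), grp), function(members) {
    min(features$mz[members]) - proton
  }, numeric(1))
  groups <- data.frame(id = ids, group = grp,
                       neutral_mass = neutral[as.character(grp)],
                       stringsAsFactors = FALSE)
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_a = character(), node_b = character(), kind = character(),
               score = numeric(), n_matched = integer(), delta = character(),
               stringsAsFactors = FALSE)
  list(groups = groups, edges = edges)
}
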