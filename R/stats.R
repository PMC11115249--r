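# Ordination and correlation statistics implemented from their definitions:
# Bray-Curtis dissimilarity, principal coordinate analysis (Gower centering),
# distance-based PERMANOVA, and pairwise Spearman correlation with
# Benjamini-Hochberg FDR control.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`; symmetric, zero diagonal,
#' bounded in `[0, 1]`. A pair of all-zero samples has undefined
#' dissimilarity; it is reported as 0 with a warning.
#'
#' @param m Non-negative abundance matrix, samples as columns.
#' @return Symmetric matrix of dissimilarities with sample dimnames.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop2("abundances must be non-negative")
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  warned <- FALSE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    den <- sum(m[, i] + m[, j])
    if (den == 0) {
      if (!warned) { warning("all-zero sample pair; distance set to 0"); warned <- TRUE }
      val <- 0
    } else val <- sum(abs(m[, i] - m[, j])) / den
    d[i, j] <- d[j, i] <- val
  }
  d
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are reported but excluded from the
#' coordinates (no Cailliez/Lingoes correction). For a Euclidean-embeddable
#' input the pairwise coordinate distances reproduce `d` exactly.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param n_axes Number of axes to return (default: all positive).
#' @return An `ordination`: `coordinates` (samples x axes), `eigenvalues`
#'   (all, descending, negatives retained), `proportion_explained`
#'   (relative to the sum of positive eigenvalues).
#' @export
pcoa_ordination <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop2("distance matrix must be symmetric")
  n <- nrow(d)
  a <- -0.5 * d^2
  centered <- a - rowMeans(a)[row(a)] - colMeans(a)[col(a)] + mean(a)
  eig <- eigen(centered, symmetric = TRUE)
  vals <- eig$values
  pos <- which(vals > max(abs(vals)) * 1e-9)
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  coords <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(vals[pos[seq_len(k)]]), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(
    coordinates = coords,
    eigenvalues = vals,
    proportion_explained = ifelse(vals > 0, vals / sum(vals[vals > 0]), 0),
    permanova = NULL
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d axes (%.1f%% + %.1f%% on first two)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$proportion_explained[1],
              if (length(x$proportion_explained) > 1)
                100 * x$proportion_explained[2] else 0))
  if (!is.null(x$permanova))
    cat(sprintf("  PERMANOVA pseudo-F %.2f, p %.3g (%d permutations)\n",
                x$permanova$pseudo_F, x$permanova$p,
                x$permanova$n_permutations))
  invisible(x)
}

# Pseudo-F from squared distances for a label vector (Anderson's
# distance-based one-way formulation).
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  g <- unique(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in g) {
    idx <- which(groups == lev)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (length(g) - 1)) / (ss_within / (n - length(g)))
}

#' Distance-based PERMANOVA (one-way)
#'
#' Pseudo-F is computed from squared distances; the p-value uses label
#' permutations with the +1 convention, so `p = 0.001` is the smallest value
#' attainable at 999 permutations.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group labels, one per sample; >= 2 groups of >= 2 samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed for the permutations.
#' @return `list(pseudo_F, p, n_permutations, seed)`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop2("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop2("need >= 2 groups")
  if (any(sizes < 2L))
    stop2("group(s) with < 2 samples: ",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      permanova_f(d2, sample(groups)) >= f_obs
    }, logical(1)))
  })
  list(pseudo_F = f_obs, p = (1 + exceed) / (1 + n_perm),
       n_permutations = as.integer(n_perm), seed = seed)
}

#' Pairwise Spearman correlation with Benjamini-Hochberg FDR
#'
#' Every OTU x feature pair is tested. OTU counts are first converted to
#' proportions by sample sequencing depth (switchable). Spearman rho uses
#' average ranks for ties; p-values come from the t-distribution
#' approximation `t = rho * sqrt((n-2) / (1-rho^2))`; BH adjustment is
#' applied jointly over all pairs.
#'
#' @param features Numeric matrix, features x samples.
#' @param otus Numeric matrix of counts, OTUs x samples; sample columns are
#'   aligned with `features` by name.
#' @param alpha Significance threshold on the adjusted q-value (default 0.05).
#' @param proportion_transform Divide OTU counts by sample depth first?
#' @return Data frame of correlation records `(otu, feature, rho, p, q,
#'   significant)` sorted by q, then descending absolute rho; deterministic
#'   total order.
#' @export
spearman_bh <- function(features, otus, alpha = 0.05,
                        proportion_transform = TRUE) {
  features <- as.matrix(features); otus <- as.matrix(otus)
  shared <- intersect(colnames(features), colnames(otus))
  if (length(shared) < 4L)
    stop2("need >= 4 shared samples, got ", length(shared))
  f <- features[, shared, drop = FALSE]
  o <- otus[, shared, drop = FALSE]
  if (proportion_transform) {
    depth <- colSums(o)
    if (any(depth == 0)) stop2("zero sequencing depth in sample(s): ",
                               paste(shared[depth == 0], collapse = ", "))
    o <- sweep(o, 2L, depth, `/`)
  }
  n <- length(shared)
  rho <- suppressWarnings(stats::cor(t(o), t(f), method = "spearman"))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
  otu_ids <- rownames(o) %||% paste0("otu", seq_len(nrow(o)))
  feat_ids <- colnames(rho) %||% paste0("feature", seq_len(ncol(rho)))
  out <- data.frame(
    otu = rep(otu_ids, times = ncol(rho)),
    feature = rep(feat_ids, each = nrow(rho)),
    rho = as.vector(rho), p = as.vector(p), q = as.vector(q),
    stringsAsFactors = FALSE)
  out$significant <- out$q < alpha
  out <- out[order(out$q, -abs(out$rho), out$otu, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select top correlations for a heatmap
#'
#' Among significant records (already ranked), the top `k` positive and top
#' `k` negative correlations are kept; records whose OTU or feature id is in
#' `forced_ids` are included regardless of significance and flagged.
#'
#' @param records Output of [spearman_bh()].
#' @param k Top-k per sign (default 20).
#' @param forced_ids Ids to force-include.
#' @export
top_k_select <- function(records, k = 20L, forced_ids = NULL) {
  sig <- records[records$significant, , drop = FALSE]
  pos <- utils::head(sig[sig$rho > 0, , drop = FALSE], k)
  neg <- utils::head(sig[sig$rho < 0, , drop = FALSE], k)
  sel <- rbind(pos, neg)
  sel$forced <- logical(nrow(sel))
  if (length(forced_ids)) {
    forced <- records[(records$otu %in% forced_ids |
                       records$feature %in% forced_ids), , drop = FALSE]
    keep_keys <- paste(sel$otu, sel$feature)
    forced <- forced[!paste(forced$otu, forced$feature) %in% keep_keys, ,
                     drop = FALSE]
    if (nrow(forced)) { forced$forced <- TRUE; sel <- rbind(sel, forced) }
  }
  rownames(sel) <- NULL
  sel
}
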