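# MS feature-table preprocessing: washout removal, blank subtraction,
# total-ion-count normalization, prevalence filtering, centering/scaling.
# Pipeline order is fixed: washout -> blank -> TIC -> (for correlation only)
# prevalence -> center/scale.

#' Construct an MS feature table
#'
#' @param features Data frame with columns `id`, `mz`, `rt` (minutes).
#' @param areas Numeric matrix of peak areas, features x samples,
#'   non-negative, with column names matching `meta$sample`.
#' @param meta Sample metadata: data frame with columns `sample`, `station`,
#'   `exposure` (`"submerged"` / `"exposed"` / NA for blanks), `is_blank`.
#' @export
feature_table <- function(features, areas, meta) {
  if (anyDuplicated(features$id)) stop2("duplicate feature ids")
  areas <- as.matrix(areas)
  if (any(areas < 0)) stop2("peak areas must be non-negative")
  if (nrow(areas) != nrow(features))
    stop2("areas and features row counts differ")
  if (is.null(colnames(areas))) stop2("areas must have sample column names")
  missing <- setdiff(colnames(areas), meta$sample)
  if (length(missing))
    stop2("samples without metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(areas), meta$sample), , drop = FALSE]
  rownames(areas) <- as.character(features$id)
  structure(list(features = features, areas = areas, meta = meta,
                 log = character(0)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%d blank)\n",
              nrow(x$areas), ncol(x$areas), sum(x$meta$is_blank)))
  if (length(x$log)) cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

append_log <- function(t, msg) { t$log <- c(t$log, msg); t }

subset_features <- function(t, keep) {
  t$features <- t$features[keep, , drop = FALSE]
  t$areas <- t$areas[keep, , drop = FALSE]
  t
}

#' Remove washout-region features
#'
#' Features eluting in the final high-organic washout segment of the LC
#' gradient (retention time >= `rt_cut_min`) are instrument carry-over, not
#' sample chemistry, and are removed.
#'
#' @param t A [feature_table()].
#' @param rt_cut_min Start of the washout phase, minutes (default 10.0).
#' @export
remove_washout <- function(t, rt_cut_min = 10.0) {
  if (anyNA(t$features$rt))
    stop2("features without retention time: ",
          paste(t$features$id[is.na(t$features$rt)], collapse = ", "))
  keep <- t$features$rt < rt_cut_min
  append_log(subset_features(t, keep),
             sprintf("remove_washout: removed %d features at RT >= %.2f min",
                     sum(!keep), rt_cut_min))
}

#' Blank subtraction
#'
#' A feature is removed when the ratio of its mean area in blank channels to
#' its mean area in real samples is >= `cutoff` (background dominates).
#' Degenerate cases are removed conservatively: 0/0, and blank signal with no
#' sample signal. Blank columns are dropped from the returned table.
#'
#' @param t A [feature_table()] with at least one blank column.
#' @param cutoff Removal threshold on the blank/sample mean ratio
#'   (default 0.3; a ratio of exactly 0.3 removes).
#' @export
blank_subtract <- function(t, cutoff = 0.3) {
  blank <- t$meta$is_blank
  if (!any(blank)) stop2("no blank columns in the feature table")
  bm <- rowMeans(t$areas[, blank, drop = FALSE])
  sm <- rowMeans(t$areas[, !blank, drop = FALSE])
  keep <- sm > 0 & (bm / sm) < cutoff
  t <- subset_features(t, keep)
  t$areas <- t$areas[, !blank, drop = FALSE]
  t$meta <- t$meta[!blank, , drop = FALSE]
  append_log(t, sprintf(
    "blank_subtract: removed %d features at blank/sample ratio >= %.2f; dropped %d blank columns",
    sum(!keep), cutoff, sum(blank)))
}

#' Total-ion-count normalization
#'
#' Divides each cell by its sample's column sum, so every sample column sums
#' to 1.
#' @param t A [feature_table()].
#' @export
tic_normalize <- function(t) {
  cs <- colSums(t$areas)
  if (any(cs == 0))
    stop2("all-zero sample(s): ",
          paste(colnames(t$areas)[cs == 0], collapse = ", "))
  t$areas <- sweep(t$areas, 2L, cs, `/`)
  append_log(t, "tic_normalize: columns scaled to sum 1")
}

#' Prevalence filter
#'
#' Keeps features observed (area > 0) in at least
#' `ceiling(min_frac * n_samples)` samples. At the default 10%, a feature in
#' 2 of 20 samples is retained and one in 1 of 20 is removed.
#'
#' @param t A [feature_table()].
#' @param min_frac Minimum fraction of samples (default 0.10).
#' @export
prevalence_filter <- function(t, min_frac = 0.10) {
  need <- ceiling(min_frac * ncol(t$areas))
  keep <- rowSums(t$areas > 0) >= need
  append_log(subset_features(t, keep),
             sprintf("prevalence_filter: removed %d features below %d samples",
                     sum(!keep), need))
}

#' Center and scale feature rows
#'
#' Each row is brought to mean 0 and standard deviation 1 (denominator
#' n - 1). Zero-variance rows cannot be scaled and are dropped with a
#' message; this never divides by zero.
#'
#' @param m Numeric matrix, variables in rows.
#' @return The standardized matrix; dropped row names are recorded in the
#'   `"dropped"` attribute.
#' @export
center_scale <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 1L, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop))
    message("center_scale: dropping ", sum(drop), " zero-variance row(s)")
  out <- m[!drop, , drop = FALSE]
  out <- (out - rowMeans(out)) / apply(out, 1L, stats::sd)
  attr(out, "dropped") <- rownames(m)[drop]
  out
}

#' Standard cleaning pipeline
#'
#' Washout removal, blank subtraction and TIC normalization in the fixed
#' order; optionally the prevalence filter (used before correlation only).
#'
#' @inheritParams remove_washout
#' @inheritParams blank_subtract
#' @param prevalence Apply [prevalence_filter()]? Default `FALSE`.
#' @param min_frac Prevalence threshold if applied.
#' @export
clean_pipeline <- function(t, rt_cut_min = 10.0, cutoff = 0.3,
                           prevalence = FALSE, min_frac = 0.10) {
  t <- remove_washout(t, rt_cut_min)
  t <- blank_subtract(t, cutoff)
  t <- tic_normalize(t)
  if (prevalence) t <- prevalence_filter(t, min_frac)
  t
}
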