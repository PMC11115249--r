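# Readers and writers for the plain-text formats the pipeline consumes:
# MGF peak lists, MZmine-style quantification tables, OTU count tables, and
# the tabular/JSON outputs. Readers reject malformed input rather than
# silently coercing; every writer produces files its own reader accepts.

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, optional `CHARGE`,
#' `TITLE`, `RTINSECONDS`, and `FEATURE_ID`/`SCANS`. The feature id is taken
#' from `FEATURE_ID`, else `SCANS`, else assigned sequentially. An ion
#' annotation such as `[M+Na]+` in `TITLE` or an `ION` field sets the
#' precursor species.
#'
#' @param path MGF file path.
#' @return List of [new_spectrum()] objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block <- NULL
  start_line <- NA_integer_
  seq_id <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (line == "BEGIN IONS") {
      if (in_block) stop2("line ", ln, ": nested BEGIN IONS")
      in_block <- TRUE
      start_line <- ln
      block <- list(headers = character(0), mz = numeric(0),
                    intensity = numeric(0))
      next
    }
    if (line == "END IONS") {
      if (!in_block) stop2("line ", ln, ": END IONS without BEGIN IONS")
      seq_id <- seq_id + 1L
      spectra[[length(spectra) + 1L]] <-
        mgf_block_to_spectrum(block, start_line, seq_id)
      in_block <- FALSE
      next
    }
    if (!in_block) stop2("line ", ln, ": content outside BEGIN/END IONS block")
    if (grepl("=", line, fixed = TRUE)) {
      block$headers <- c(block$headers, line)
    } else {
      parts <- strsplit(line, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) < 2L || anyNA(vals[1:2]))
        stop2("line ", ln, ": malformed peak line: ", line)
      block$mz <- c(block$mz, vals[1L])
      block$intensity <- c(block$intensity, vals[2L])
    }
  }
  if (in_block) stop2("unterminated BEGIN IONS block starting at line ", start_line)
  spectra
}

mgf_header <- function(block, key) {
  hit <- grep(paste0("^", key, "="), block$headers, value = TRUE)
  if (!length(hit)) NULL else sub(paste0("^", key, "="), "", hit[1L])
}

mgf_block_to_spectrum <- function(block, start_line, seq_id) {
  pep <- mgf_header(block, "PEPMASS")
  if (is.null(pep))
    stop2("block at line ", start_line, ": missing PEPMASS")
  precursor <- as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1L])
  if (is.na(precursor))
    stop2("block at line ", start_line, ": unparseable PEPMASS: ", pep)
  id <- mgf_header(block, "FEATURE_ID") %||% mgf_header(block, "SCANS") %||%
    as.character(seq_id)
  title <- mgf_header(block, "TITLE")
  rt <- mgf_header(block, "RTINSECONDS")
  ion <- mgf_header(block, "ION")
  species <- NULL
  ann <- ion %||% title
  if (!is.null(ann)) {
    m <- regmatches(ann, regexpr("\\[M[+-][A-Za-z0-9]+\\][+-]", ann))
    if (length(m) && nzchar(m)) species <- tryCatch(ion_species(m),
                                                    error = function(e) NULL)
  }
  charge <- mgf_header(block, "CHARGE")
  if (!is.null(charge) && !is.null(species)) {
    z <- suppressWarnings(as.integer(sub("([0-9]+)[+-]?", "\\1", charge)))
    if (!is.na(z) && grepl("-", charge, fixed = TRUE)) z <- -z
    if (!is.na(z) && z != 0L) species <- ion_species(species$adduct, z)
  }
  nf <- mgf_header(block, "FORMULA")
  new_spectrum(block$mz, block$intensity, precursor_mz = precursor,
               species = species, id = id,
               rt = if (is.null(rt)) NA_real_ else as.numeric(rt) / 60,
               neutral_formula = nf, title = title)
}

#' Write spectra to an MGF file
#' @param spectra List of spectra.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("FEATURE_ID=", s$id), con)
    if (!is.null(s$title)) writeLines(paste0("TITLE=", s$title), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.null(s$species)) {
      writeLines(sprintf("CHARGE=%d%s", abs(s$species$charge),
                         if (s$species$charge > 0) "+" else "-"), con)
      writeLines(sprintf("ION=[%s]%s", s$species$adduct,
                         if (s$species$charge > 0) "+" else "-"), con)
    }
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.3f", s$rt * 60), con)
    if (!is.null(s$neutral_formula))
      writeLines(paste0("FORMULA=", s$neutral_formula), con)
    writeLines(sprintf("%.6f %.4f", s$peaks$mz, s$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

norm_header <- function(x) tolower(gsub("[ .]+", "", trimws(x)))

#' Read an MZmine-style quantification table with sample metadata
#'
#' The quant table is CSV with header columns `row ID`, `row m/z`,
#' `row retention time` (matched case-insensitively with whitespace
#' stripped) and one peak-area column per sample (a trailing " Peak area"
#' suffix is removed from sample names). The metadata file is CSV with
#' columns `sample`, `station`, `exposure`, `is_blank` and must cover every
#' sample column.
#'
#' @param path Quant table path.
#' @param metadata_path Sample metadata path.
#' @return A [feature_table()].
#' @export
read_quant_table <- function(path, metadata_path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- norm_header(names(raw))
  id_col <- match("rowid", hdr)
  mz_col <- match("rowm/z", hdr)
  rt_col <- match("rowretentiontime", hdr)
  if (anyNA(c(id_col, mz_col, rt_col)))
    stop2("quant table must have 'row ID', 'row m/z', 'row retention time' columns")
  sample_cols <- setdiff(seq_along(raw), c(id_col, mz_col, rt_col))
  sample_names <- sub("\\s*Peak area\\s*$", "", names(raw)[sample_cols])
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids))
    stop2("duplicate feature id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample", "station", "exposure", "is_blank")
  if (!all(need %in% names(meta)))
    stop2("metadata must have columns: ", paste(need, collapse = ", "))
  meta$is_blank <- as.logical(meta$is_blank)
  unmatched <- setdiff(sample_names, meta$sample)
  if (length(unmatched))
    stop2("sample(s) missing from metadata: ", paste(unmatched, collapse = ", "))
  areas <- as.matrix(raw[, sample_cols, drop = FALSE])
  storage.mode(areas) <- "double"
  colnames(areas) <- sample_names
  feature_table(
    features = data.frame(id = ids, mz = as.numeric(raw[[mz_col]]),
                          rt = as.numeric(raw[[rt_col]]),
                          stringsAsFactors = FALSE),
    areas = areas, meta = meta)
}

#' Write a feature table as an MZmine-style quant CSV (+ metadata CSV)
#' @param t A [feature_table()].
#' @param path Output CSV path.
#' @param metadata_path Optional metadata CSV path.
#' @export
write_quant_table <- function(t, path, metadata_path = NULL) {
  df <- data.frame(`row ID` = t$features$id, `row m/z` = t$features$mz,
                   `row retention time` = t$features$rt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  areas <- as.data.frame(t$areas)
  names(areas) <- paste(colnames(t$areas), "Peak area")
  utils::write.csv(cbind(df, areas), path, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.csv(t$meta, metadata_path, row.names = FALSE)
  invisible(path)
}

#' Read / write an OTU count table (CSV: otu, taxonomy, one column per sample)
#' @param path CSV path.
#' @param counts Integer count matrix, OTUs x samples (writer).
#' @param taxonomy Data frame with columns `otu`, `taxonomy` (writer).
#' @export
read_otu_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("otu", "taxonomy") %in% names(raw)))
    stop2("OTU table must have 'otu' and 'taxonomy' columns")
  counts <- as.matrix(raw[, setdiff(names(raw), c("otu", "taxonomy")),
                          drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- raw$otu
  list(table = counts,
       taxonomy = data.frame(otu = raw$otu, taxonomy = raw$taxonomy,
                             stringsAsFactors = FALSE))
}

#' @rdname read_otu_table
#' @export
write_otu_table <- function(counts, taxonomy, path) {
  df <- cbind(data.frame(otu = rownames(counts),
                         taxonomy = taxonomy$taxonomy[
                           match(rownames(counts), taxonomy$otu)],
                         stringsAsFactors = FALSE),
              as.data.frame(counts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write network edges as a three-column edge list and as GraphML
#' @param net Output of [build_network()].
#' @param edge_path Edge-list CSV path.
#' @param graphml_path Optional GraphML path.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  utils::write.csv(net$edges, edge_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("node_a", "node_b", "kind", "score")],
      directed = FALSE,
      vertices = data.frame(name = names(net$families),
                            family = as.integer(net$families)))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
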