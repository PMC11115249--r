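# Deterministic synthetic-data generator with queryable ground truth.
#
# The generator stands in for the field collection: MS2 spectra of planted
# cyclic depsipeptides with ppm-scale mass jitter and noise peaks, an MS
# feature table with blank channels, washout-region features and a planted
# submerged-vs-exposed group effect, and an OTU count table with planted
# monotone microbe-metabolite associations. Same seed, same tables.

#' Simulation manifest
#'
#' The manifest fully determines every synthetic output. Defaults encode the
#' emulated field design at desk scale: nine flagged stations (numbered 1-8
#' and 10, stations 2 and 4-7 submerged, the rest surface exposed), twelve
#' samples per station, 500 MS features and 300 OTUs.
#'
#' @param seed Integer seed; every derived table is a pure function of it.
#' @param n_stations,samples_per_station Station design.
#' @param n_features,n_otus,n_blanks Table dimensions.
#' @param effect_size Multiplicative submerged enrichment applied to the
#'   planted features (1 = null).
#' @param n_effect_features Number of features carrying the planted effect.
#' @param frac_washout,frac_blank_contaminated Fractions of features planted
#'   in the washout region (RT >= 10 min) and with dominating blank signal
#'   (blank/sample mean ratio >= 0.3), so every cleaning rule fires.
#' @param dropout Per-cell probability of a missing (zero) peak area.
#' @param depth Sequencing depth per sample for the OTU base community.
#' @param n_planted_pairs,pair_strength Number of planted monotone
#'   OTU-feature couplings and their strength in `[0, 1]` (1 = noise-free;
#'   signs alternate positive/negative).
#' @param peptides List of residue-code vectors planted as MS2 spectra.
#' @param ppm_sd,n_noise Spectrum jitter (ppm standard deviation) and number
#'   of uniform-m/z noise peaks.
#' @export
simulation_manifest <- function(seed = 1L, n_stations = 9L,
                                samples_per_station = 12L, n_features = 500L,
                                n_otus = 300L, n_blanks = 3L, effect_size = 4,
                                n_effect_features = 30L, frac_washout = 0.05,
                                frac_blank_contaminated = 0.05, dropout = 0.1,
                                depth = 10000L, n_planted_pairs = 10L,
                                pair_strength = 0.9,
                                peptides = NULL, ppm_sd = 5, n_noise = 20L) {
  if (is.null(peptides)) {
    peptides <- list(
      A = c("Phe", "Lxx", "Hba", "Phe", "Lxx", "Hda"),
      B = c("Phe", "Lxx", "Lac", "Phe", "Lxx", "Hda"),
      C = c("Phe", "Lxx", "Lac", "Phe", "Lxx", "Hdda"),
      D = c("Phe", "Lxx", "Hba", "Phe", "Lxx", "Hdda"))
  }
  structure(as.list(environment()), class = "simulation_manifest")
}

#' Load a preset manifest
#'
#' Presets ship as a JSON configuration file (`inst/extdata/presets.json`):
#' `"demo"` (the desk-scale defaults), `"null"` (no planted group effect, no
#' planted pairs) and `"strong-signal"` (effect size 8 on 30 features over 40
#' samples).
#'
#' @param name Preset name.
#' @param seed Optional seed override.
#' @export
manifest_preset <- function(name, seed = NULL) {
  path <- system.file("extdata", "presets.json", package = "depsinet",
                      mustWork = TRUE)
  presets <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!name %in% names(presets))
    stop2("unknown preset: ", name, " (available: ",
          paste(names(presets), collapse = ", "), ")")
  args <- presets[[name]]
  if (!is.null(seed)) args$seed <- seed
  do.call(simulation_manifest, args)
}

station_design <- function(manifest) {
  labels <- c(1:8, 10)
  stations <- if (manifest$n_stations <= 9) labels[seq_len(manifest$n_stations)]
              else seq_len(manifest$n_stations)
  submerged <- stations %in% c(2, 4, 5, 6, 7)
  data.frame(
    sample = sprintf("S%02d_%02d", rep(stations, each = manifest$samples_per_station),
                     seq_len(manifest$samples_per_station)),
    station = rep(stations, each = manifest$samples_per_station),
    exposure = rep(ifelse(submerged, "submerged", "exposed"),
                   each = manifest$samples_per_station),
    is_blank = FALSE, stringsAsFactors = FALSE)
}

#' Simulate an MS2 spectrum of a cyclic depsipeptide
#'
#' All predicted fragments of the peptide are jittered by
#' `Normal(0, ppm_sd)` ppm with log-uniform intensities in `[1e3, 1e6]`;
#' `n_noise` uniform-m/z noise peaks (same intensity law) are added below the
#' precursor.
#'
#' @param p A [cyclic_peptide()] (or residue-code vector).
#' @param species Ion species (default sodiated).
#' @param ppm_sd Mass jitter standard deviation in ppm (>= 0).
#' @param n_noise Number of noise peaks.
#' @param seed Optional seed (restores the caller's RNG).
#' @param id Feature id stored on the spectrum.
#' @export
simulate_spectrum <- function(p, species = "M+Na", ppm_sd = 5, n_noise = 20L,
                              seed = NULL, id = NULL) {
  if (!inherits(p, "cyclic_peptide")) p <- cyclic_peptide(p)
  if (ppm_sd < 0) stop2("ppm_sd must be >= 0")
  if (is.character(species)) species <- ion_species(species)
  frag <- all_fragments(p, species)
  prec <- ion_mz(peptide_formula(p), species)
  with_seed(seed, {
    mz <- frag$mz * (1 + stats::rnorm(nrow(frag), 0, ppm_sd) * 1e-6)
    intensity <- 10^stats::runif(nrow(frag), 3, 6)
    if (n_noise > 0) {
      mz <- c(mz, stats::runif(n_noise, 100, prec - 1))
      intensity <- c(intensity, 10^stats::runif(n_noise, 3, 6))
    }
    new_spectrum(mz, intensity, precursor_mz = prec, species = species,
                 id = id, neutral_formula = format(peptide_formula(p)))
  })
}

#' Simulate the MS feature table
#'
#' Log-normal baseline abundances with dropout; planted washout features
#' (RT in 10-13 min), blank-contaminated features (blank/sample mean ratio
#' guaranteed >= 0.3 by construction) and submerged-enriched features
#' (multiplied by `effect_size` in submerged samples). The returned truth
#' records exactly which features each cleaning rule should remove and which
#' carry the group effect.
#'
#' @param manifest A [simulation_manifest()].
#' @return `list(table, truth)` with `table` a [feature_table()].
#' @export
simulate_feature_table <- function(manifest) {
  meta <- station_design(manifest)
  if (manifest$n_blanks > 0) {
    meta <- rbind(meta, data.frame(
      sample = sprintf("BLANK_%02d", seq_len(manifest$n_blanks)),
      station = NA, exposure = NA_character_, is_blank = TRUE,
      stringsAsFactors = FALSE))
  }
  nf <- manifest$n_features
  n_wash <- round(manifest$frac_washout * nf)
  n_contam <- round(manifest$frac_blank_contaminated * nf)
  ids <- sprintf("F%04d", seq_len(nf))
  washout_ids <- ids[seq_len(n_wash)]
  contam_ids <- ids[n_wash + seq_len(n_contam)]
  clean_ids <- setdiff(ids, c(washout_ids, contam_ids))

  with_seed(manifest$seed + 101L, {
    rt <- c(stats::runif(n_wash, 10, 13),
            stats::runif(nf - n_wash, 0.5, 9.9))
    mz <- stats::runif(nf, 150, 1500)
    smp <- meta$sample[!meta$is_blank]
    ns <- length(smp)
    meanlog <- stats::runif(nf, 8, 12)
    areas <- matrix(stats::rlnorm(nf * ns, meanlog, 1), nf, ns,
                    dimnames = list(ids, smp))
    if (manifest$dropout > 0)
      areas[matrix(stats::runif(nf * ns) < manifest$dropout, nf, ns)] <- 0
    effect_ids <- utils::head(clean_ids, manifest$n_effect_features)
    submerged <- meta$exposure[!meta$is_blank] == "submerged"
    if (manifest$effect_size != 1 && length(effect_ids))
      areas[effect_ids, submerged] <- areas[effect_ids, submerged] *
        manifest$effect_size
    sm <- rowMeans(areas)
    blanks <- NULL
    if (manifest$n_blanks > 0) {
      ratio <- ifelse(ids %in% contam_ids,
                      stats::runif(nf, 0.4, 1.5),
                      stats::runif(nf, 0, 0.15))
      blanks <- matrix(0, nf, manifest$n_blanks,
                       dimnames = list(ids, meta$sample[meta$is_blank]))
      for (b in seq_len(manifest$n_blanks))
        blanks[, b] <- sm * ratio * stats::runif(nf, 0.9, 1.1)
      # per-blank jitter preserves the mean-ratio classes only approximately;
      # re-anchor the means so the truth is exact by construction
      bm_target <- sm * ratio
      bm_now <- rowMeans(blanks)
      scale <- ifelse(bm_now > 0, bm_target / bm_now, 1)
      blanks <- blanks * scale
    }
    tab <- feature_table(
      features = data.frame(id = ids, mz = mz, rt = rt,
                            stringsAsFactors = FALSE),
      areas = cbind(areas, blanks)[, meta$sample, drop = FALSE],
      meta = meta)
    truth <- list(washout_ids = washout_ids, blank_ids = contam_ids,
                  effect_ids = effect_ids,
                  exposure = stats::setNames(meta$exposure, meta$sample))
    list(table = tab, truth = truth)
  })
}

#' Simulate the OTU count table
#'
#' Dirichlet-multinomial base community at fixed depth per sample; planted
#' OTU-feature pairs are coupled monotonically to the (noisy, rank-scaled)
#' feature signal, positive and negative signs alternating. With a single
#' planted pair at `pair_strength = 1` the proportion-transformed OTU is an
#' exact monotone transform of the feature, so Spearman rho is exactly +/-1.
#'
#' @param manifest A [simulation_manifest()].
#' @param feature_result Output of [simulate_feature_table()] (shared design).
#' @return `list(table, taxonomy, truth)`; `table` is an integer count
#'   matrix OTUs x samples, `truth$pairs` lists `(otu, feature, sign)`.
#' @export
simulate_otu_table <- function(manifest, feature_result) {
  ft <- feature_result$table
  smp <- colnames(ft$areas)[!ft$meta$is_blank]
  ns <- length(smp)
  no <- manifest$n_otus
  otu_ids <- sprintf("OTU%d", seq_len(no))
  npair <- min(manifest$n_planted_pairs, no,
               length(setdiff(rownames(ft$areas),
                              c(feature_result$truth$washout_ids,
                                feature_result$truth$blank_ids))))
  with_seed(manifest$seed + 202L, {
    clean <- setdiff(rownames(ft$areas),
                     c(feature_result$truth$washout_ids,
                       feature_result$truth$blank_ids))
    pair_features <- utils::tail(clean, npair)  # disjoint from effect ids
    pair_otus <- otu_ids[seq_len(npair)]
    signs <- rep_len(c(1, -1), npair)

    base_alpha <- stats::rgamma(no, shape = 0.5, rate = 1) + 1e-3
    counts <- matrix(0L, no, ns, dimnames = list(otu_ids, smp))
    free <- setdiff(seq_len(no), seq_len(npair))
    for (s in seq_len(ns)) {
      g <- stats::rgamma(length(free), shape = base_alpha[free], rate = 1)
      pr <- g / sum(g)
      counts[free, s] <- stats::rmultinom(1, manifest$depth, pr)[, 1L]
    }
    for (k in seq_len(npair)) {
      sig <- as.numeric(ft$areas[pair_features[k], smp])
      z <- manifest$pair_strength * scale(rank(sig, ties.method = "average"))[, 1] +
        (1 - manifest$pair_strength) * stats::rnorm(ns)
      if (signs[k] < 0) z <- -z
      counts[pair_otus[k], ] <- rank(z, ties.method = "first")
    }
    taxonomy <- data.frame(
      otu = otu_ids,
      taxonomy = sprintf("Bacteria;Phylum%02d;Genus%03d",
                         (seq_len(no) %% 12) + 1, seq_len(no)),
      stringsAsFactors = FALSE)
    truth <- if (npair) data.frame(otu = pair_otus, feature = pair_features,
                                   sign = signs, stringsAsFactors = FALSE)
             else data.frame(otu = character(), feature = character(),
                             sign = numeric())
    list(table = counts, taxonomy = taxonomy, truth = list(pairs = truth))
  })
}

#' Simulate MS2 spectra for the manifest's planted peptides
#'
#' @param manifest A [simulation_manifest()].
#' @param species Ion species for all spectra (default sodiated).
#' @return Named list of spectra (ids `planted_<name>`).
#' @export
simulate_spectra <- function(manifest, species = "M+Na") {
  out <- lapply(seq_along(manifest$peptides), function(i) {
    simulate_spectrum(manifest$peptides[[i]], species = species,
                      ppm_sd = manifest$ppm_sd, n_noise = manifest$n_noise,
                      seed = manifest$seed + 300L + i,
                      id = paste0("planted_", names(manifest$peptides)[i] %||% i))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}
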