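mk_spec <- function(mz, int, prec, id = "s") {
  new_spectrum(mz, int, precursor_mz = prec, id = id)
}

test_that("modified cosine: self-similarity is 1, disjoint spectra score 0", {
  s <- mk_spec(c(100, 200, 300, 400, 500, 600), c(1, 2, 3, 4, 5, 6), 700)
  mc <- modified_cosine(s, s)
  expect_equal(mc$score, 1, tolerance = 1e-12)
  expect_equal(mc$n_matched, 6L)
  a <- mk_spec(c(100, 200), c(1, 1), 500)
  b <- mk_spec(c(150, 250), c(1, 1), 500)   # shift 0, nothing within tol
  expect_equal(modified_cosine(a, b)$score, 0)
  z <- mk_spec(c(100, 200), c(0, 0), 500)
  expect_equal(modified_cosine(z, s)$score, 0)
})

test_that("precursor-shifted peaks pair up", {
  a <- mk_spec(c(100, 228.05), c(1, 1), 400)
  b <- mk_spec(c(100, 250.03), c(1, 1), 421.98)  # second peak shifted by dM
  mc <- modified_cosine(a, b)
  expect_equal(mc$n_matched, 2L)
  expect_equal(mc$score, 1, tolerance = 1e-9)
})

test_that("greedy pairing equals the exhaustive oracle on small spectra", {
  set.seed(52)
  for (i in 1:60) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    prec_a <- runif(1, 400, 600); prec_b <- prec_a + sample(c(0, 21.98), 1)
    a <- mk_spec(sort(runif(na, 100, 390)), 10^runif(na, 2, 5), prec_a)
    # half the peaks related to a's, half random
    mzb <- c(a$peaks$mz[seq_len(ceiling(na / 2))] +
               sample(c(0, prec_b - prec_a), ceiling(na / 2), replace = TRUE),
             runif(nb - ceiling(na / 2) + 1, 100, 390))
    b <- mk_spec(sort(mzb[seq_len(nb)]), 10^runif(nb, 2, 5), prec_b)
    expect_equal(modified_cosine(a, b)$score, modified_cosine_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("modified cosine is symmetric and bounded", {
  set.seed(53)
  for (i in 1:20) {
    a <- mk_spec(sort(runif(5, 100, 500)), 10^runif(5, 2, 5), runif(1, 500, 700))
    b <- mk_spec(sort(runif(5, 100, 500)), 10^runif(5, 2, 5), runif(1, 500, 700))
    ab <- modified_cosine(a, b); ba <- modified_cosine(b, a)
    expect_equal(ab$score, ba$score, tolerance = 1e-12)
    expect_gte(ab$score, 0); expect_lte(ab$score, 1)
  }
})

test_that("network edges honor min_cosine AND min_matched_peaks", {
  peaks6 <- c(100, 150, 200, 250, 300, 350)
  s1 <- mk_spec(peaks6, rep(1, 6), 400, id = "f1")
  s2 <- mk_spec(peaks6, rep(1, 6), 400, id = "f2")
  net <- build_network(list(s1, s2))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$score, 1, tolerance = 1e-12)
  # 5 shared peaks: cosine 1 but below the matched-ion floor
  s3 <- mk_spec(peaks6[1:5], rep(1, 5), 400, id = "f1")
  s4 <- mk_spec(peaks6[1:5], rep(1, 5), 400, id = "f2")
  expect_equal(nrow(build_network(list(s3, s4))$edges), 0L)
  expect_error(build_network(list(s1, s1)), "duplicate")
})

test_that("a constructed congener family forms one connected component", {
  # congener spectra built from the fragmenter with a shared intensity law:
  # substituted-residue ions pair through the precursor-shift clause
  rings <- list(ring_A, ring_B, ring_C, ring_D)
  spectra <- lapply(seq_along(rings), function(i) {
    p <- cyclic_peptide(rings[[i]])
    frag <- all_fragments(p, "M+Na")
    new_spectrum(frag$mz, rep(1e5, nrow(frag)),
                 precursor_mz = ion_mz(peptide_formula(p), "M+Na"),
                 species = "M+Na", id = paste0("fam", i))
  })
  lone <- mk_spec(c(111, 222, 333, 444, 555, 666), rep(1, 6), 900, id = "lone")
  net <- build_network(c(spectra, list(lone)))
  fam <- net$families
  expect_equal(length(unique(fam[paste0("fam", 1:4)])), 1L)
  expect_false(fam[["lone"]] %in% fam[paste0("fam", 1:4)])
})

test_that("edge set is invariant under spectrum input order", {
  rings <- list(ring_A, ring_B, ring_C, ring_D)
  spectra <- lapply(seq_along(rings), function(i) {
    p <- cyclic_peptide(rings[[i]])
    frag <- all_fragments(p, "M+Na")
    new_spectrum(frag$mz, rep(1e5, nrow(frag)),
                 precursor_mz = ion_mz(peptide_formula(p), "M+Na"),
                 species = "M+Na", id = paste0("s", i))
  })
  n1 <- build_network(spectra)
  expect_gt(nrow(n1$edges), 0)
  n2 <- build_network(rev(spectra))
  key <- function(e) paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
  expect_setequal(key(n1$edges), key(n2$edges))
})

test_that("ion-identity grouping needs RT, shape correlation and an adduct delta", {
  tgrid <- seq(0, 1, length.out = 50)
  shape <- exp(-((tgrid - 0.5) / 0.08)^2)
  feats <- data.frame(id = c("h", "na", "decoy", "shapeless"),
                      mz = c(777.4806, 799.4625, 777.4806 + 21.9819, 300),
                      rt = c(7.80, 7.81, 7.80, 7.80))
  eics <- cbind(h = shape, na = shape * 0.4,
                decoy = 1 - shape,    # anticorrelated peak shape
                shapeless = shape)
  out <- ion_identity_groups(feats, eics)
  grp <- out$groups
  expect_equal(grp$group[grp$id == "h"], grp$group[grp$id == "na"])
  expect_false(grp$group[grp$id == "decoy"] == grp$group[grp$id == "h"])
  expect_equal(out$edges$delta, "M+H/M+Na")
  # inferred neutral mass: protonated member minus a proton
  expect_equal(grp$neutral_mass[grp$id == "h"], 777.4806 - 1.00727646,
               tolerance = 1e-4)
})

test_that("features lacking traces stay ungrouped with a message", {
  feats <- data.frame(id = c("a", "b"), mz = c(100, 121.9819), rt = c(1, 1))
  eics <- matrix(runif(20), 20, 1, dimnames = list(NULL, "a"))
  expect_message(out <- ion_identity_groups(feats, eics), "no EIC trace")
  expect_equal(length(unique(out$groups$group)), 2L)
  single <- ion_identity_groups(data.frame(id = "x", mz = 100, rt = 1),
                                matrix(runif(10), 10, 1,
                                       dimnames = list(NULL, "x")))
  expect_equal(nrow(single$groups), 1L)
})
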