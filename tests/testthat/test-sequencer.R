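pep_A <- cyclic_peptide(ring_A)

test_that("match_fragments finds the published ladder anchors at 10 ppm", {
  pred <- all_fragments(pep_A, "M+Na")
  s <- new_spectrum(c(799.4562, 652.3932, 306.2035, 164.0677),
                    intensity = c(1e5, 8e4, 6e4, 4e4),
                    precursor_mz = 799.4562, species = "M+Na", id = "anchors")
  rep <- match_fragments(pred, s, tol_ppm = 10)
  expect_equal(nrow(rep$matches), 4L)
  expect_true(all(abs(rep$matches$ppm) <= 10))
})

test_that("match_fragments handles empty spectra and the tolerance boundary", {
  pred <- all_fragments(pep_A, "M+Na")
  empty <- new_spectrum(numeric(0), numeric(0), 799.4616, "M+Na")
  rep <- match_fragments(pred, empty)
  expect_equal(rep$coverage, 0)
  expect_equal(rep$score, 0)
  one <- pred$mz[1] * (1 + 20e-6)   # 20 ppm off
  s <- new_spectrum(one, 100, 799.4616, "M+Na")
  expect_equal(nrow(match_fragments(pred[1, ], s, tol_ppm = 10)$matches), 0L)
})

test_that("each peak is consumed at most once by greedy matching", {
  pred <- all_fragments(pep_A, "M+Na")
  s <- new_spectrum(rep(306.2040, 1), 100, 799.4616, "M+Na")
  rep <- match_fragments(rbind(pred, pred), s)
  expect_equal(nrow(rep$matches), 1L)
})

test_that("noiseless round trip recovers the planted ring on top", {
  s <- simulate_spectrum(pep_A, "M+Na", ppm_sd = 0, n_noise = 0, seed = 1)
  cand <- infer_residues(s, neutral_formula = "C44H64N4O8")
  expect_gt(nrow(cand), 0)
  expect_true(cyclic_equivalent(strsplit(cand$sequence[1], "-")[[1]], ring_A,
                                wildcard = TRUE))
  expect_true(cand$two_pathway[1])
  expect_true(cand$from_p1[1] && cand$from_p2[1])
})

test_that("every returned candidate satisfies the composition constraint exactly", {
  set.seed(41)
  for (i in 1:3) {
    res <- random_hexadepsipeptide()
    p <- cyclic_peptide(res)
    s <- simulate_spectrum(p, "M+Na", 5, 20, seed = 600 + i)
    nf <- peptide_formula(p)
    cand <- infer_residues(s, neutral_formula = nf)
    expect_gt(nrow(cand), 0)
    expect_true(all(cand$formula == format(nf)))
  }
})

test_that("pure-noise spectra yield an empty candidate list with diagnostics", {
  set.seed(42)
  s <- new_spectrum(runif(40, 100, 790), 10^runif(40, 3, 6),
                    precursor_mz = 799.4616, species = "M+Na")
  cand <- infer_residues(s, neutral_formula = "C44H64N4O8")
  expect_equal(nrow(cand), 0L)
  expect_match(attr(cand, "diagnostics"), "composition")
})

test_that("unknown precursor species is an error", {
  s <- new_spectrum(306.2040, 100, 799.4616, species = NULL)
  expect_error(infer_residues(s, "C44H64N4O8"), "species unknown")
})

test_that("adding a matched peak never lowers the score", {
  pred <- all_fragments(pep_A, "M+Na")
  base <- new_spectrum(pred$mz[3:8], rep(1e4, 6), 799.4616, "M+Na")
  more <- new_spectrum(pred$mz[2:8], rep(1e4, 7), 799.4616, "M+Na")
  expect_gte(match_fragments(pred, more)$score,
             match_fragments(pred, base)$score)
})

test_that("congener assignment reads the substitutions off the precursor delta", {
  spectra <- list(
    simulate_spectrum(cyclic_peptide(ring_B), "M+Na", 3, 10, seed = 11,
                      id = "B"),
    simulate_spectrum(cyclic_peptide(ring_C), "M+Na", 3, 10, seed = 12,
                      id = "C"),
    simulate_spectrum(pep_A, "M+Na", 3, 10, seed = 13, id = "A"))
  out <- annotate_congeners(ring_A, spectra)
  expect_true(all(out$assigned))
  expect_identical(out$substitutions[out$spectrum == "B"], "Hba->Lac")
  expect_identical(out$substitutions[out$spectrum == "C"],
                   "Hba->Lac;Hda->Hdda")
  expect_identical(out$substitutions[out$spectrum == "A"], "identity")
  expect_identical(out$formula[out$spectrum == "B"], "C43H62N4O8")
})

test_that("spectra inconsistent with every substitution are reported unassigned", {
  odd <- new_spectrum(c(300, 400), c(10, 10), precursor_mz = 500.1234,
                      species = "M+Na", id = "odd")
  odd$neutral_formula <- NULL
  out <- annotate_congeners(ring_A, list(odd))
  expect_false(out$assigned)
})
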