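# Shared fixtures: the four congener rings, published analytical anchors, and
# small spectrum builders. Everything is generated in code; no binary data.

ring_A <- c("Phe", "Lxx", "Hba", "Phe", "Lxx", "Hda")
ring_B <- c("Phe", "Lxx", "Lac", "Phe", "Lxx", "Hda")
ring_C <- c("Phe", "Lxx", "Lac", "Phe", "Lxx", "Hdda")
ring_D <- c("Phe", "Lxx", "Hba", "Phe", "Lxx", "Hdda")

# published precursor anchors: formula, adduct, calcd m/z, observed m/z
analytical_anchors <- data.frame(
  congener = c("A", "A", "A", "B", "B", "C", "C", "D", "D"),
  formula = c("C44H64N4O8", "C44H64N4O8", "C44H64N4O8",
              "C43H62N4O8", "C43H62N4O8", "C45H66N4O8", "C45H66N4O8",
              "C46H68N4O8", "C46H68N4O8"),
  adduct = c("M+H", "M+Na", "M-H", "M+H", "M+Na", "M+H", "M+Na",
             "M+H", "M+Na"),
  calcd = c(777.4797, 799.4616, 775.4651, 763.4640, 785.4460,
            791.4953, 813.4773, 805.5110, 827.4929),
  observed = c(777.4806, 799.4562, 775.4674, 763.4666, 785.4488,
               791.5013, 813.4831, 805.5135, 827.4955),
  dppm = c(1.2, 6.8, 3.0, 3.4, 3.6, 7.6, 7.1, 3.1, 3.1),
  stringsAsFactors = FALSE)

# Peak list reconstructing the annotated sodiated MS2 ladder of congener A:
# the four fragment values printed in the text (a-type opened ion 799.4562,
# b2 306.2035, x1 164.0677, and the x-ion implied by the reported 142.1345
# neutral loss) plus the calculated values for the remaining ladder steps.
fig6a_peaklist <- function() {
  p <- cyclic_peptide(ring_A)
  frag <- all_fragments(p, "M+Na")
  mz <- round(frag$mz, 4)
  swap <- function(from, to) mz[abs(mz - from) < 0.01] <<- to
  swap(799.4616, 799.4562)   # a0, observed
  swap(306.2040, 306.2035)   # b2, printed
  swap(164.0682, 164.0677)   # x1 (Lxx-CO), printed
  swap(657.3259, 799.4562 - 142.1345)  # x5 via the printed neutral loss
  new_spectrum(mz, intensity = rep(1e4, length(mz)) + seq_along(mz),
               precursor_mz = 799.4562, species = "M+Na", id = "fig6a")
}

# uniform random hexadepsipeptide over the mass-unique alphabet with at least
# one hydroxy residue (a depsipeptide needs an ester)
random_hexadepsipeptide <- function() {
  pool <- c("Phe", "Lxx", "Hba", "Lac", "Hda", "Hdda")
  hydroxy <- c("Hba", "Lac", "Hda", "Hdda")
  repeat {
    res <- sample(pool, 6, replace = TRUE)
    if (any(res %in% hydroxy)) return(res)
  }
}

# small random formula over common elements (no zero-count clutter)
random_formula <- function() {
  els <- c("C", "H", "N", "O", "S", "Na")
  n <- sample(2:5, 1)
  pick <- sample(els, n)
  chem_formula(stats::setNames(sample(1:30, n, replace = TRUE), pick))
}

# exhaustive modified-cosine oracle for tiny spectra: maximum over all
# one-to-one admissible pairings (used against the greedy implementation)
modified_cosine_oracle <- function(a, b, frag_tol_da = 0.01) {
  ia <- sqrt(a$peaks$intensity); ib <- sqrt(b$peaks$intensity)
  na <- sqrt(sum(ia^2)); nb <- sqrt(sum(ib^2))
  if (na == 0 || nb == 0) return(0)
  shift <- a$precursor_mz - b$precursor_mz
  d <- outer(a$peaks$mz, b$peaks$mz, `-`)
  adm <- abs(d) <= frag_tol_da | abs(d - shift) <= frag_tol_da
  pairs <- which(adm, arr.ind = TRUE)
  if (!nrow(pairs)) return(0)
  best <- 0
  recurse <- function(k, used_a, used_b, acc) {
    if (k > nrow(pairs)) { best <<- max(best, acc); return(invisible()) }
    recurse(k + 1L, used_a, used_b, acc)   # skip this pair
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      recurse(k + 1L, used_a, used_b, acc + ia[i] * ib[j])
    }
  }
  recurse(1L, rep(FALSE, length(ia)), rep(FALSE, length(ib)), 0)
  min(1, best / (na * nb))
}
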