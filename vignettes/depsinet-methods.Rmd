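---
title: "Methods: cyclic depsipeptide annotation and the environmental statistics behind it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cyclic depsipeptide annotation and the environmental statistics behind it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depsinet)
```

# Scope

depsinet implements the computational core of an environmental-metabolomics
workflow around cyclic hexadepsipeptides: exact-mass arithmetic, theoretical
MS² fragment prediction, de novo residue sequencing, feature-based molecular
networking with ion-identity grouping, MS feature-table cleaning, and the
ordination/correlation statistics that localize metabolites across a set of
field stations. This vignette records the models, the conventions, and the
design decisions that were genuinely open — the things a maintainer would
otherwise have to reverse-engineer from the code.

# Mass arithmetic

All masses are monoisotopic, computed from a single constants table
(`atomic_masses()`, shipped as plain text, IUPAC values to at least 7
decimals). Ion m/z follows

$$ m/z = \frac{M + \delta_{\mathrm{adduct}} - z\,m_e}{|z|} $$

with the electron mass $m_e$ = 0.000548580 Da subtracted for cations and
added for anions. The correction matters: published 4-decimal "calcd" values
for these compounds only reproduce with it. Supported singly charged species
are [M+H]⁺, [M+Na]⁺, [M+NH₄]⁺, [M+K]⁺ and [M−H]⁻.

Relative mass errors (`ppm_error()`) are reported unsigned and rounded
half-up to one decimal, matching the convention of instrument
mass-accuracy tables (R's `round()` is banker's rounding, which does not).
Ring-plus-double-bond equivalents use the standard CHN rule
$C - H/2 + N/2 + 1$, ignoring O, S and monovalent Na.

# Residue model

Residues are stored **dehydrated** (free acid minus H₂O), so the neutral
formula of a macrocycle is the plain element-wise sum over its residues:
cyclization consumes exactly the waters the convention already removed. A
linear peptide would add one H₂O back; that case is documented but untested
because the package targets macrocycles.

The default alphabet covers the residues seen in this compound family: Phe;
the C₆H₁₁NO trio Leu/Ile/MeVal, which MS² cannot distinguish and which are
therefore mass-aliased to the wildcard code **Lxx**; and the α-hydroxy acids
Hba (C₄H₆O₂), Lac (C₃H₄O₂), Hda (C₁₀H₁₈O₂) and Hdda (C₁₂H₂₂O₂). De novo
results always report Lxx and never assert a Leu/Ile placement; the wildcard
only participates in sequence comparison when explicitly enabled
(`cyclic_equivalent(..., wildcard = TRUE)`). Rings are directional: rotations
are equivalent, reflections are not.

## Ring direction and linkage typing

A genuinely open decision was how the written residue order maps onto ring
chemistry. In `cyclo(r_1 … r_n)` we define linkage *i* to join `r_i` and
`r_{i+1}`, and type it an **ester iff `r_i` is hydroxy-class** — i.e. the
acyl chain runs opposite to the written order, with the hydroxy residue
contributing its α-oxygen to the bond named after it. This is the only
convention under which the annotated ladders of this compound family come
out right simultaneously: opening the Hda–Phe ester produces sequential
losses Phe, Lxx, Hba, Phe down to a b₂ ion of composition Lxx+Hda
(C₁₆H₂₉NO₃Na⁺), exactly the published pathway-1 ladder.

# Fragment prediction

Two ring-opening pathways are modeled for singly charged precursors:

* **P1 (lactone b-type)**: the ring opens at an ester; b-type cleavages then
  peel residues off one at a time, so the ladder is the set of prefix sums
  of the opened linear form (b₂ … b₍ₙ₋₁₎), each plus the cationizing atom.
* **P2 (α-C/C=O a-type)**: the ring opens at a residue's α-carbon/carbonyl
  bond. The opened ion (a₀) is isobaric with the precursor; the first
  neutral loss is that residue **minus CO** (for Hda, C₉H₁₈O), subsequent
  losses are whole residues, and the terminal retained ion x₁ is the
  adjacent residue still carrying the CO (e.g. Lxx–CO, C₇H₁₁NO₂Na⁺).

`all_fragments()` takes the union over every ester (P1) and every residue
(P2), merging duplicates by (charged formula, label class) with provenance
retained. Mass conservation — fragment plus neutral loss equals the
precursor ion — holds to 10⁻⁶ Da for every generated ion and is
property-tested, as is invariance of the fragment m/z multiset under ring
rotation.

Published fragment values in the source literature mix observed and
calculated numbers and deviate from strict theory by up to ~3 ppm; tests
therefore use a 5 ppm window for fragment anchors, and exact 4-decimal
equality only for precursor "calcd" values.

# De novo sequencing

`infer_residues()` reproduces the manual elucidation procedure as a spectrum
graph: nodes are peaks plus a virtual precursor node (placed at the
theoretical m/z when the neutral formula is known); a directed edge u→v
exists when the m/z difference matches a residue mass within tolerance, or a
residue-minus-CO for the first a-type step out of the precursor. Maximal
precursor-rooted paths are assembled into rings two ways: a P2 path fixes
the full cycle (opened residue, losses in ring order, x₁ terminus); a P1
path fixes the loss order plus a terminal residue pair whose lead residue
must be hydroxy-class. Candidates must reproduce the supplied neutral
formula **exactly** (or, without one, the observed precursor m/z within
tolerance).

## Ranking

Candidates are ranked by (1) matched ladder steps across both pathway
interpretations, (2) **coverage** — matched over predicted ions, (3) total
matched intensity, (4) mean |ppm|, (5) lexicographic order. Coverage was
added after observing that without it, ties systematically go to wrong rings
that *over-predict*: a ring with more ester sites predicts more ions, can
match the same peaks, and leaves its surplus predictions unexplained.
Penalizing predicted-but-unobserved ions is the standard remedy in de novo
scoring and it is decisive here.

The default match tolerance is 10 ppm — deliberately looser than
instrument-level ~2 ppm, to absorb the mixed observed/calculated values in
published ladders; it is a parameter everywhere.

## What recovery does and does not establish

On 100 random hexadepsipeptides (uniform over the mass-unique alphabet,
at least one hydroxy residue, 5 ppm jitter, 20 noise peaks, fixed seed) the
planted ring is the top candidate ≥ 95 times. Every observed failure is a
ring whose theoretical fragment multiset is **identical** to another ring's
(verified directly): such isospectral pairs are unresolvable from MS² in
principle, by any scorer, and cap top-1 recovery below 100%. A green
recovery test therefore establishes that the implementation extracts all
the sequence information the spectrum contains — not that MS² determines
hexadepsipeptide rings uniquely, which it does not.

`annotate_congeners()` handles the homologous-series case: given a reference
ring and residue swap pairs (default Hba↔Lac, Hda↔Hdda), it keeps the swap
combinations consistent with each spectrum's precursor composition and
scores them against the peak list; a spectrum whose precursor fits no
combination is reported unassigned rather than forced.

# Molecular networking

`modified_cosine()` square-root transforms intensities (the common FBMN
convention; switchable), admits peak pairs within 0.01 Da of either zero or
the precursor mass difference, and selects a one-to-one pairing greedily by
descending intensity product. On spectra of ≤ 5 peaks the greedy score
equals the exhaustive-pairing maximum on every tested case (tolerance 0);
that bound is property-tested, not assumed. Edges require cosine ≥ 0.7 AND
≥ 6 matched ions; no top-K pruning is applied, favoring faithfulness over
scalability at desk scale.

Ion-identity grouping links co-eluting features (default RT tolerance 0.05
min — chosen MZmine-style because the emulated workflow states only "retention
time matches") whose chromatographic peak shapes correlate with Pearson
r > 0.85 and whose m/z difference matches an adduct delta (e.g. Na−H =
21.98194 Da) within 0.01 Da; transitive closure forms the groups.

# Feature-table cleaning

Order is fixed: washout removal → blank subtraction → TIC normalization →
(before correlation only) prevalence filter → centering/scaling.

* **Washout**: features at RT ≥ 10.0 min are removed; the cut is where the
  emulated LC gradient enters its 99%-organic washout phase (10–13 min).
* **Blank subtraction**: a feature is removed when mean(blank)/mean(sample)
  ≥ 0.3. The source description's parenthetical reads "less than 30% …
  removed", which inverts standard semantics and would delete real signal
  while keeping contaminants; the standard reading is implemented and the
  discrepancy documented here. Boundary exactly 0.3 removes (conservative);
  0/0 and blank-only signal remove.
* **Prevalence**: keep features observed (area > 0) in at least
  ⌈0.10 · n⌉ samples, so exactly 10% retains.
* **Centering/scaling**: per-feature mean 0, sd 1 (n−1); zero-variance rows
  are dropped with a message, never divided by zero. For the Spearman step
  this transform is a mathematical no-op (rank correlations are invariant);
  it is retained for workflow fidelity and tested as such.

TIC normalization runs after blank columns are dropped (the emulated
workflow leaves the order unstated; normalizing real samples against real
samples is the defensible choice).

# Statistics

All four statistics are implemented from their definitions; `vegan` and
`ape` appear only as independent oracles in the test suite.

* **Bray–Curtis**: Σ|x−y| / Σ(x+y) per sample pair; an all-zero pair is
  reported as 0 with a warning rather than NaN.
* **PCoA**: Gower double-centering of −d²/2, eigendecomposition,
  coordinates scaled by √λ for positive eigenvalues. Negative eigenvalues
  are reported, excluded from coordinates, and not corrected
  (no Cailliez/Lingoes), matching the emulated QIIME behavior. For
  Euclidean-embeddable input the coordinate distances reproduce d to 1e−8.
* **PERMANOVA**: Anderson's distance-based one-way pseudo-F from squared
  distances; p by label permutation with the +1 convention, so 0.001 is the
  floor at 999 permutations. Type-I error is calibrated by simulation in the
  acceptance suite (500 null data sets; rejection rate must sit in
  0.05 ± 0.02).
* **Spearman/BH**: OTU counts become proportions per sample; ρ uses average
  ranks; p-values come from the t approximation
  t = ρ√((n−2)/(1−ρ²)) (|ρ| = 1 maps to p = 0); BH is applied **jointly**
  over all OTU × feature pairs — the stricter reading of "FDR-controlled
  over the pair matrix" — and significance means q < 0.05.

# Synthetic data: the stated world

The generator emulates the field design at desk scale: nine flagged
stations (numbered 1–8 and 10; stations 2 and 4–7 submerged, the others
surface-exposed), 12 samples per station, 500 MS features, 300 OTUs, 3
blank channels — scaled down from field scale (~15k features, ~12k OTUs)
for sub-minute runtimes. Defaults that the emulated study does not pin down
were chosen once: log-normal feature baselines; a 10% per-cell dropout; a
4× submerged enrichment on 30 planted features for the demo preset (8× on
40 samples for `strong-signal`, 1× for `null`); fragment and noise
intensities log-uniform on [10³, 10⁶] (only rank/threshold behavior matters
to the tested statistics, so a fitted intensity law would add realism the
tests cannot see).

Planted OTU–feature couplings use rank coupling: the planted OTU's counts
are a monotone (or anti-monotone) rank transform of the feature's abundance
plus Gaussian noise scaled by 1 − strength. The base community is
Dirichlet-multinomial at fixed depth, so with a single noise-free pair the
proportion-transformed OTU is an exact monotone transform of the feature
(x/(c+x) is increasing) and Spearman ρ is exactly ±1 — a sharp oracle the
tests exploit.

What the generator does **not** emulate: chromatographic peak shapes beyond
Gaussian EICs, isotope envelopes, intensity structure shared across
congeners, compositionality artifacts of real counts. A green pipeline test
establishes correct plumbing and statistical calibration under the stated
world, not field realism.

Everything is a pure function of the manifest seed; the same seed gives
byte-identical tables, which the acceptance suite verifies end to end
through the command-line `all` pipeline.

# Known limitations

* Only singly charged, single-cation fragments; no y/c/z series, no
  internal double cleavages beyond the two pathways, no intensity modeling.
* Isospectral rings (above) bound de novo top-1 accuracy.
* The networking module keeps all pairwise edges; it is not built for
  field-scale (15k-node) inputs.
* Leu/Ile/MeVal remain Lxx forever at the MS² level; resolving them needs
  orthogonal data.
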