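# depsinet

Annotation, de novo sequencing and environmental statistics for cyclic
depsipeptide metabolomics.

## The problem

Microbialite (stromatolite) pools host layered microbial communities whose
specialized metabolites can be surveyed directly from small environmental
core samples by LC–MS². A recurring task in such surveys is to take a family
of unknown cyclic hexadepsipeptides — six-residue macrocycles mixing amide
and ester (lactone) backbone bonds — and (i) pin down their molecular
formulas from exact masses, (ii) read their residue sequence off the MS²
neutral-loss ladders, (iii) group the many ion species and congeners in a
molecular network, and (iv) ask which bacteria co-vary with them across the
pool. depsinet implements that entire desk-side workflow as a tested R
package, for natural-product and microbiome researchers who want each step
reproducible and separately testable.

## What is inside

| Area | Functions |
|---|---|
| Exact mass | `parse_formula`, `monoisotopic_mass`, `ion_mz`, `ppm_error`, `rdbe` |
| Residue model | `load_alphabet`, `cyclic_peptide`, `peptide_formula`, `cyclic_equivalent` |
| MS² prediction | `open_ring`, `fragment_ladder`, `all_fragments` |
| De novo sequencing | `match_fragments`, `infer_residues`, `annotate_congeners` |
| Networking | `modified_cosine`, `build_network`, `ion_identity_groups` |
| Feature cleaning | `remove_washout`, `blank_subtract`, `tic_normalize`, `prevalence_filter`, `center_scale` |
| Statistics | `bray_curtis`, `pcoa_ordination`, `permanova`, `spearman_bh`, `top_k_select` |
| Synthetic data | `simulation_manifest`, `simulate_spectrum`, `simulate_feature_table`, `simulate_otu_table` |
| IO / CLI | `read_mgf`, `read_quant_table`, `depsinet_cli` |

The core model: ion m/z is `(M + δ_adduct − z·mₑ)/|z|` with the electron
mass correction; a cyclic depsipeptide's neutral formula is the sum of its
dehydrated residue formulas; MS² ladders follow two ring openings (b-type at
an ester; a-type at an α-C/C=O bond, losing residue−CO first and retaining a
terminal residue+CO "x₁" ion); network edges need modified cosine ≥ 0.7 with
≥ 6 matched ions; group separation is tested by Bray–Curtis PERMANOVA and
microbe–metabolite association by Spearman ρ with Benjamini–Hochberg FDR.
See `vignettes/depsinet-methods.Rmd` for the full account.

## Worked example

```r
library(depsinet)

pep <- cyclic_peptide(c("Phe", "Lxx", "Hba", "Phe", "Lxx", "Hda"))
pep
#> <cyclic_peptide> cyclo(Phe-Lxx-Hba-Phe-Lxx-Hda)  C44H64N4O8

ion_mz(peptide_formula(pep), "M+H")    # 777.4797
ion_mz(peptide_formula(pep), "M+Na")   # 799.4616
rdbe(peptide_formula(pep))             # 15

head(all_fragments(pep, "M+Na")[, c("label", "formula", "mz")], 3)
#>   label      formula       mz
#> 1    a0 C44H64N4NaO8 799.4616
#> 2    x5 C41H58N4NaO7 741.4198
#> 3    x5 C39H53N3NaO8 714.3725

# round trip: simulate a sodiated spectrum (5 ppm jitter, 20 noise peaks)
# and sequence it de novo under the formula constraint
s <- simulate_spectrum(pep, "M+Na", ppm_sd = 5, n_noise = 20, seed = 7)
cand <- infer_residues(s, neutral_formula = "C44H64N4O8")
cand[1, c("sequence", "formula", "n_matched", "coverage", "two_pathway")]
#>                  sequence    formula n_matched  coverage two_pathway
#> 1 Hba-Phe-Lxx-Hda-Phe-Lxx C44H64N4O8        23 0.8518519        TRUE

cyclic_equivalent(strsplit(cand$sequence[1], "-")[[1]], pep, wildcard = TRUE)
#> TRUE
```

Reading the output: the top candidate is the planted ring up to rotation
(rings have no canonical start); it explains 23 ladder ions at 85% coverage
with support from both fragmentation pathways; `Lxx` marks the
Leu/Ile/MeVal mass ambiguity that MS² cannot resolve. A mass-accuracy check
against a printed table value:

```r
round_half_up(ppm_error(777.4806, 777.4797), 1)
#> 1.2
```

## Command-line pipeline

```sh
Rscript inst/cli/depsinet.R all --preset demo --seed 7 --out-dir out/
```

chains simulate → clean → network → annotate → correlate → ordinate, writing
MGF/CSV/GraphML/JSON artifacts and a run manifest per stage; identical seeds
give byte-identical outputs. Individual stages are available as subcommands
(`simulate`, `clean`, `network`, `annotate`, `correlate`, `ordinate`).

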