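# mitocons

Conservation and disease-variant analysis of primate mitochondrial
protein-coding genes.

Human mtDNA disease variants come in two evidence tiers — MITOMAP's
*confirmed* pathogenic mutations and merely *reported* ones. Comparative
genomics can separate them: amino-acid replacements that recur and persist
across the primate radiation are unlikely to be severely deleterious, while
positions held invariant by purifying selection are strong pathogenicity
candidates. `mitocons` implements the full comparative pipeline for the 13
mitochondrial protein genes, for molecular evolutionists and clinical
mtDNA curators alike.

## What it computes

Per aligned codon column *j* of a bound alignment/tree pair:

* **Ind1**, the number of distinct amino acids;
* **Ind2**, the parsimony-counted non-synonymous substitutions, with
  multi-nucleotide codon changes averaged over minimal stop-free mutational
  pathways;
* **Ind3**, a standardized empirical-Bayes evolutionary rate (discrete-gamma
  prior, k = 16, mtREV24 replacement model, shape by marginal maximum
  likelihood; standardized to mean 0 / SD 1);
* a SLAC-style selection test: observed N and S substitution counts over
  branches vs expected site fractions of the ancestral codons, with
  `dN = N/EN`, `dS = S/ES` and a two-tailed extended-binomial p-value for
  the split `N/(N+S)` against the neutral `EN/(EN+ES)`; columns with
  `dN < dS` and `p <= 0.1` (strict mode: 0.05) are flagged negatively
  selected;
* TreeSAAP-style radical physicochemical change summaries over a packaged
  31-property table (8 equal-width magnitude categories; radical =
  categories 6–8, optionally with dataset-level z > 3.09);
* rCRS coordinate mapping of m.-notation variants (overlapping reading
  frames, light-strand mt-ND6), clade-tier presence, exact
  minimum-over-MPRs independent-origin counts, species counts and
  reversion detection.

A fully ground-truthed GY94-style codon simulator (birth–death trees,
per-site rates and omega mixture, event logs that replay exactly, planted
variants of known conservation class) makes every stage testable offline.

## Worked example

The `analysis/` scripts run the whole workflow on the default
study-condition simulation (148 sequences, 139 species, 1000 codon sites,
seed 1234):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_conserve.R
Rscript analysis/03_map_variants.R
Rscript analysis/04_compare_statistics.R
```

Step 2 prints, for this seed:

```
1000 columns analysed; 361 (36.1%) residue-invariant; 77.0% flagged under
negative selection (p <= 0.1).
Ind1 mean 2.68 (sd 1.93), Ind2 mean 3.55, Ind3 standardized to mean 0 / sd 1.
```

i.e. about a third of codon columns never changed their amino acid across
the tree, and three quarters show a significant excess of synonymous over
non-synonymous substitutions — purifying selection dominates. Step 4 then
contrasts the planted variant tiers:

```
 index       comparison          D            p  n1   n2
  ind3 confirmed_vs_all 0.44114286 4.977422e-05  28 1000
  ind3  reported_vs_all 0.02404167 9.999856e-01 192 1000

Pathogenicity scores, confirmed vs reported: t = 6.803, df = 216, p = 9.9e-11
Mean GTR+G+I distance (40-taxon subsample): 0.239
Printed human variant coordinates matching the rCRS map: 92/94
```

Confirmed-like variants concentrate among the most conserved columns
(Kolmogorov–Smirnov D = 0.44, p ≈ 5×10⁻⁵) while reported-like variants are
indistinguishable from the background — the planted contrast is recovered.
The last line checks the packaged table of published human variants
against the rCRS gene model; the two mismatches are documented printed
errata in the source tables (m.4160T>C and m.11232T>C).

Interactively:

```r
library(mitocons)
map_mtdna_position(8528)
#      gene codon offset_in_codon strand
#   mt-ATP8    55               0      +
#   mt-ATP6     1               1      +
translate_codon("TGA")   # "W" under the vertebrate mitochondrial code
```

## Layout

* `R/` — the package: reference data and coordinate mapping, I/O,
  parsimony machinery, conservation indices, selection test, property
  scoring, variant reports, statistics, simulator, pipeline stages.
* `inst/extdata/` — rCRS gene model inputs, the 31-property table, the
  curated printed variant table (TSV).
* `analysis/` — the numbered workflow scripts shown above.
* `vignettes/mitogenome-conservation.Rmd` — model and methods notes:
  assumptions, parameter choices, numerical conventions, limitations.
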