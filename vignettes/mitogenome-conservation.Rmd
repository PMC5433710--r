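---
title: "Conservation scoring and disease-variant recurrence in primate mitochondrial protein genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation scoring and disease-variant recurrence in primate mitochondrial protein genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Human mitochondrial DNA carries hundreds of variants in the 13 protein-coding
genes that have been linked to disease, but with very uneven evidence:
MITOMAP distinguishes *confirmed* pathogenic mutations (accepted by multiple
independent laboratories) from merely *reported* ones (suggested by at least
one publication). A comparative argument can separate these tiers: a
replacement that has arisen repeatedly and persisted across the primate
radiation is unlikely to be severely deleterious, whereas a position held
invariant by purifying selection for tens of millions of years is a strong
candidate for genuine pathogenicity when mutated.

`mitocons` implements that comparison end to end: per-aligned-codon
conservation indices, a counting-based selection test, radical
physicochemical change detection, coordinate mapping of m.-notation variants
onto the rCRS gene model (including overlapping reading frames and the
light-strand gene), parsimony-based recurrence and reversion analysis, and
the comparative statistics — plus a fully ground-truthed codon simulator so
every stage is testable without downloads.

## Conservation indices

For every aligned codon column (after the inclusion rule below):

* **Ind1** — the number of distinct amino acids among defined residues.
  Gaps, stops and undetermined codons are excluded; a column with no defined
  residue is undefined.
* **Ind2** — the total number of non-synonymous substitutions over the tree,
  counted on a parsimony reconstruction of ancestral codons. A branch whose
  endpoint codons differ at several positions is decomposed over all minimal
  single-nucleotide pathways that avoid stop codons (all pathways, if every
  minimal route passes through a stop), and the per-step synonymous /
  non-synonymous counts are averaged over pathways. The reported integer is
  the rounded pathway average; the raw fractional count is retained.
* **Ind3** — a standardized evolutionary rate per residue column under an
  empirical-Bayes model: a discrete-gamma prior over rate multipliers
  (k = 16 equal-probability categories), a fixed empirical amino-acid
  replacement matrix appropriate to vertebrate mitochondria (mtREV24
  exchangeabilities with mitochondrial equilibrium frequencies, taken at run
  time from phangorn's model library), and the gamma shape chosen by
  maximising the sum of per-site marginal log-likelihoods. Each column's
  posterior-mean rate is standardized to mean 0 / SD 1 over included
  columns, so conserved columns score negative. Because the exact settings
  of the original server implementations of this method are not published,
  Ind3 is a rank-level index: its ordering is meaningful, its absolute
  values are implementation-specific.

## The selection test

The per-site test follows the single-likelihood-ancestor-counting (SLAC)
logic. For a column, ancestral codons are reconstructed by parsimony;
observed synonymous (S) and non-synonymous (N) substitution counts are
accumulated over branches with pathway averaging. Expected site fractions
come from the mutational opportunity of each branch's ancestral codon: at
each codon position, the fraction of single-nucleotide changes to non-stop
codons that are synonymous, summed over positions and normalised so
`es + en = 3`, then averaged over branches weighted by branch length.
Normalised rates are `dN = N/en` and `dS = S/es`, and the observed split is
tested against the neutral proportion `en/(en+es)` with a two-tailed
*extended binomial* — binomial tails generalised to fractional counts
through the regularised incomplete beta function.

A column is flagged **negatively selected** when `dN < dS` with p ≤ 0.1 (the
counting method's customary default); a strict p ≤ 0.05 flag is emitted
alongside, because the two readings of the published procedure ("α = 0.05"
vs "considered negatively selected when dN < dS") differ and both should be
reproducible. Both flags appear in every site table.

## Ancestral reconstruction policy

All counting rests on parsimony over a rooted input tree (never re-rooted):

* Minimum change counts use a unit-cost dynamic program (Sankoff), which is
  exact on binary *and* non-binary trees; gap/unknown leaves are classic
  missing data (any state, zero cost).
* The deterministic reconstruction resolves ties top-down: the root takes
  the first optimal state in alphabet order, and every child keeps its
  parent's state whenever that is optimal for its subtree (a DELTRAN-like
  delay of transformations). The number of branch substitutions under this
  policy always equals the parsimony minimum, and the output is
  deterministic given the alphabet and child order.
* **Independent origins** of a residue are computed exactly by a
  bi-criterion dynamic program that minimises total changes first and
  residue gains second, i.e. the true minimum over all most-parsimonious
  reconstructions — a conservative lower bound on recurrence. A root
  reconstructed in the residue state counts as one (ancestral) origin, so a
  residue carried by any leaf always has at least one origin and the origin
  count is zero exactly when no species carries the residue.
* Reconstruction-dependent counts (Ind2, origin counts) can shift by ±1–2
  under other tie-breaking policies; this is inherent to parsimony counting,
  not to the implementation.

Two plausible-looking invariants are *not* theorems and are tested in their
corrected forms: (i) `Ind1 = 1` does not force `Ind2 = 0`, because the two
serine codon classes (TCN and AGY) interconvert only through non-serine
intermediates; (ii) origin counts on a tree pruned to carriers plus the
reference can be smaller than on the full tree (pruning can merge carrier
clusters), so the pruned count is a lower bound, equal whenever the full
count is 1.

## Coordinate mapping

The packaged gene model fixes the canonical rCRS (NC_012920) boundaries of
the 13 protein genes. Codon numbering is 1-based from each gene's own start
in its own frame; overlapping genes (ATP8/ATP6, ND4L/ND4) are numbered
independently. mt-ND6 is read on the light strand: codon 1 begins at the
gene's *highest* rCRS coordinate, the within-codon offset counts in
translation order (offset 0 = first position of the codon), and callers
complement ref/alt bases. Incomplete terminal codons (stops completed by
polyadenylation) are excluded from codon counts. m.8528T>C therefore maps
to both ATP6 codon 1 (offset 1) and ATP8 codon 55 (offset 0), and
m.14484T>C to the first position of ND6 codon 64 — consistent with the
printed protein changes M1T/W55R and M64V. Published variant tables
occasionally disagree with this arithmetic; the packaged table retains the
printed codon numbers and marks the two rows whose printed values
contradict both the arithmetic and MITOMAP's canonical annotations
(m.4160T>C, m.11232T>C) as errata in the tests.

The column inclusion rule anchors everything to a designated human
reference row: a column enters the analysis when the reference cell is a
sense codon. This drops reference-gapped columns and terminal stops — the
natural explanation of a concatenated alignment analysing slightly fewer
columns than its raw width — and makes "codon position in humans"
well-defined. Without a reference row, any column with at least one sense
codon is included.

## Radical physicochemical changes

Each amino-acid replacement on each branch is scored against a packaged
table of 31 physicochemical properties — 20 standard published empirical
scales (hydropathy, polarity, volume, secondary-structure propensities,
transfer energies, and others) plus 11 exact compositional descriptors
(atom counts, charge, hydrogen-bond donors/acceptors, aromatic ring size,
rotatable bonds, side-chain pKa distance). The table is versioned inside
the package and is the single source of truth; different editions of the
classic property sets disagree in places, so cross-implementation
byte-agreement is not claimed.

For a property, the absolute change of a replacement is binned into 8
equal-width magnitude categories spanning that property's maximum
attainable pairwise change; identity replacements are category 0. A change
is **radical** when its category is 6–8; in z-score mode a dataset-level
enrichment `z > 3.09` (p < 0.001) for that (property, category) is
additionally required, where z compares observed branch substitutions with
the neutral mutational opportunity (all single-nucleotide missense changes
permitted by the mitochondrial code, weighted by the dataset's codon
usage). Category-only mode is the default because z-scores are unstable on
small datasets; z-mode is a switch. Per column, the site summary reports
the number of branch substitutions with at least one radical change and
the maximum number of properties radically affected by any single
substitution.

## Recurrence, clade tiers and reversions

For each variant, the disease residue comes from the `protein_change`
field when present, otherwise it is derived from ref/alt through the
reading frame (a strict-coordinates mode makes the derived residue win;
conflicts are flagged either way). Presence flags are computed for nested
clade tiers — non-human primates ⊃ catarrhines ⊃ hominids ⊃ extinct *Homo*
— and species counts deduplicate multiple sequences per species (a species
carries a residue if any of its sequences does; the human reference is
excluded from "other species" counts). A variant is a **reversion** when
an ancestor on the root-to-human path is reconstructed with the disease
residue while the modern human does not carry it.

Position-level summaries deduplicate by aligned column; mutation-level
tallies are emitted alongside, because both denominators are legitimate
and published summaries mix them.

## Comparative statistics

Kolmogorov–Smirnov two-sample tests compare each index's distribution
between all columns and the confirmed/reported variant columns (asymptotic
p by default; a permutation p is available because the discrete indices are
heavily tied). The pathogenicity-score comparison uses Student's
pooled-variance t (df = n1 + n2 − 2), with Welch as an option. Exponential
goodness of fit uses the maximum-likelihood rate (1/mean), equal-width bins
over [0, max] with an open tail bin, and df = bins − 2; the standardized
Ind3 is shifted to positive support (x − min) before fitting. No
multiple-testing correction is applied across the battery, mirroring the
procedure the package reproduces; users comparing many indices should
correct externally.

## The simulator and what passing tests mean

`simulate_alignment()` evolves codon sequences along a birth–death tree
(rescaled to a target mean root-to-tip divergence) by a continuous-time
chain over the 60 sense codons: single-nucleotide moves, transition bias
κ, per-site rate multipliers (invariant fraction plus gamma), and a
two-class per-site ω mixture; moves into stop codons are rejected and the
chain is normalised so a neutral site substitutes at ~1 per unit branch
length. Every event is logged, and replaying the log from the root must
reproduce the leaves exactly — the internal consistency check of the
generator. Gap blocks of 1–3 codons are planted on clades (never the
reference tip). All randomness flows from one master seed through named
per-component sub-seeds.

Defaults emulate a primate mitogenome protein-coding dataset: 148
sequences of 139 species (9 species sampled twice), 1000 codon sites (desk
scale), mean root-to-tip 1.2 *neutral* substitutions/site (≈0.5 observed
after purifying suppression), κ = 8, 60% of sites at ω = 0.03 and 40% at
ω = 0.3 (mitochondrial "variable" sites are still purifying), gamma shape
1.5 for mutation-rate spread, 5% rate-zero sites. Under these settings
roughly 40% of columns are residue-invariant, matching the real dataset's
published proportion; the negative-selection fraction (~0.7) and mean Ind2
(~3) remain below the real data's values because a two-class ω model at
desk scale cannot jointly match every marginal — the qualitative structure
(purifying dominance, exponential-like index distributions) is what the
generator guarantees. The simulator does not model heterotachy, indel
realism beyond simple blocks, codon-usage evolution, or sequencing error;
passing tests demonstrate algorithmic correctness and statistical
behaviour under the model, not performance on real alignments.

`plant_variants()` places confirmed-like variants at sites in the lowest
decile of true rate and reported-like variants uniformly, fabricates
m.-notation coordinates on a single synthetic gene map, and draws
synthetic pathogenicity scores higher on average for confirmed-like
variants. The planted contrast gives the comparative statistics a known
answer: on the default study conditions the confirmed-like Ind3
distribution is rejected against the background at α = 0.01 while the
uniform reported-like sample is not.

The site-rate recovery check runs under a matched design — sites evolving
neutrally with known gamma rates — because that is the quantity the
estimator targets; under the purifying study conditions most sites carry
zero amino-acid events and even the realized event counts correlate only
~0.7 with the true rates, an information ceiling no estimator can beat.

## Numerical choices

* Pairwise GTR+Γ+I distances: model parameters (exchangeabilities, base
  frequencies, gamma shape with 4 categories, invariant proportion) are
  estimated once per gene on a neighbour-joining guide tree, then each
  pair's distance is optimised under the fixed model from the 4×4 joint
  pattern counts; distances are capped at 10 substitutions/site with a
  warning.
* Indel polarity: gap-block characters resolve root ties toward
  ancestrally *present* sequence, so equivocal blocks are polarised as
  deletions.
* Likelihood pruning rescales per node and works in log space; rate-matrix
  exponentials use the symmetrised spectral decomposition.
* All tie-breaks (root state, child state, bin edges, block ordering) are
  deterministic; identical inputs give byte-identical output tables, each
  carrying the package version and a configuration hash in its header.
* Problem sizes used by the test-suite and acceptance runs — 148–150 taxa
  and 500–1000 codon sites for the simulation-based checks, ≤7-leaf trees
  for the exhaustive oracles, 40-taxon subsamples for pairwise distances —
  were chosen as the package's desk-scale standard.

## Known limitations

Reproduction of the original full-scale numbers requires the deposited
alignment, tree and complete variant table as inputs; the package ships
only the printed variant tables. Parsimony counts are
reconstruction-policy-dependent (±1–2). Ind3 is rank-level. The 31-property
table is a curated equivalent, not a byte-copy, of the classic property
set. The KS p-values on heavily tied discrete indices are approximate —
use the permutation option where that matters.
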