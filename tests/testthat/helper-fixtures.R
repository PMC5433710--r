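# small constructed fixtures shared across tests

quartet_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# alignment fixture mirroring the ATP6/ATP8 overlap: column 1 = mt-ATP6
# codon 1 (ATG), column 2 = mt-ATP8 codon 54 (AAA), column 3 = mt-ATP8
# codon 55 (TGA), column 4 = mt-ND6 codon 64 (ATG, gene reading frame)
overlap_alignment <- function(taxa = c("Homo_sapiens", "Pan", "Pongo")) {
  m <- matrix(rep(c("ATG", "AAA", "TGA", "ATG"), each = length(taxa)),
              nrow = length(taxa), dimnames = list(taxa, NULL))
  codon_alignment(m)
}

overlap_lookup <- function(gene, codon) {
  if (gene == "mt-ATP6" && codon == 1) return(1L)
  if (gene == "mt-ATP8" && codon == 54) return(2L)
  if (gene == "mt-ATP8" && codon == 55) return(3L)
  if (gene == "mt-ND6" && codon == 64) return(4L)
  NA_integer_
}

small_sim <- function(seed = 7L, n_taxa = 20L, n_sites = 60L,
                      gap_blocks = 2L, ...) {
  simulate_alignment(sim_config(n_taxa = n_taxa, n_sites = n_sites,
                                seed = seed, gap_blocks = gap_blocks,
                                n_duplicate_species = 2L, ...))
}
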