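#' rCRS coordinate map of the 13 human mitochondrial protein-coding genes
#'
#' Canonical gene boundaries on the revised Cambridge Reference Sequence
#' (rCRS, NC_012920), 1-based inclusive. All genes are encoded on the heavy
#' strand reference orientation (`+`) except mt-ND6 (`-`), whose reading frame
#' runs from its highest rCRS coordinate downwards on the complementary
#' strand. `ATP8`/`ATP6` and `ND4L`/`ND4` overlap in different frames.
#'
#' `n_codons` is the number of translated codons: terminal stop codons are
#' excluded, whether complete or completed by polyadenylation (incomplete
#' terminal codons).
#'
#' @return data.frame with columns `gene`, `start`, `end`, `strand`,
#'   `length_bp`, `n_codons`.
#' @export
rcrs_gene_map <- function() {
  gm <- data.frame(
    gene = c("mt-ND1", "mt-ND2", "mt-CO1", "mt-CO2", "mt-ATP8", "mt-ATP6",
             "mt-CO3", "mt-ND3", "mt-ND4L", "mt-ND4", "mt-ND5", "mt-ND6",
             "mt-CYB"),
    start = c(3307L, 4470L, 5904L, 7586L, 8366L, 8527L,
              9207L, 10059L, 10470L, 10760L, 12337L, 14149L, 14747L),
    end = c(4262L, 5511L, 7445L, 8269L, 8572L, 9207L,
            9990L, 10404L, 10766L, 12137L, 14148L, 14673L, 15887L),
    strand = c("+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "-",
               "+"),
    stringsAsFactors = FALSE
  )
  gm$length_bp <- gm$end - gm$start + 1L
  # translated codons: full codons minus a terminal stop when the gene length
  # is an exact codon multiple (complete stop); incomplete terminal codons
  # (stop completed by polyadenylation) are dropped by integer division
  gm$n_codons <- gm$length_bp %/% 3L - as.integer(gm$length_bp %% 3L == 0L)
  gm
}

#' Map an rCRS position onto protein-gene codons
#'
#' Returns one row per protein-coding gene overlapping the position. Codon
#' numbering is 1-based from each gene's own start in its own frame;
#' overlapping genes are numbered independently. For the light-strand gene
#' mt-ND6 codon 1 begins at the gene's highest rCRS coordinate and
#' `offset_in_codon` counts in translation order, so callers must complement
#' reference/alternate bases for that gene. `offset_in_codon` is 0 for the
#' first position of a codon in reading direction.
#'
#' Positions in no protein gene (tRNA/rRNA/D-loop) return a zero-row frame.
#'
#' @param pos Integer rCRS coordinate, 1..16569.
#' @param gmap Gene map from [rcrs_gene_map()] (or a synthetic map with the
#'   same columns).
#' @return data.frame with columns `gene`, `codon`, `offset_in_codon`,
#'   `strand`; zero rows if the position lies in no protein gene.
#' @export
#' @examples
#' map_mtdna_position(10158)  # mt-ND3 codon 34
#' map_mtdna_position(8528)   # mt-ATP6 codon 1 and mt-ATP8 codon 55
map_mtdna_position <- function(pos, gmap = rcrs_gene_map()) {
  pos <- as.integer(pos)
  if (length(pos) != 1L || is.na(pos) || pos < 1L) {
    stop("`pos` must be a single positive integer", call. = FALSE)
  }
  hit <- gmap[gmap$start <= pos & pos <= gmap$end, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(gene = character(), codon = integer(),
                      offset_in_codon = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  off <- ifelse(hit$strand == "+", pos - hit$start, hit$end - pos)
  codon <- off %/% 3L + 1L
  res <- data.frame(
    gene = hit$gene,
    codon = as.integer(codon),
    offset_in_codon = as.integer(off %% 3L),
    strand = hit$strand,
    stringsAsFactors = FALSE
  )
  # drop positions falling in an incomplete terminal codon (not translated)
  keep <- res$codon <= hit$n_codons + as.integer(hit$length_bp %% 3L == 0L)
  res[keep, , drop = FALSE]
}

#' rCRS positions of a gene codon
#'
#' Inverse of [map_mtdna_position()]: the three rCRS coordinates of codon
#' `codon` of `gene`, in translation order (descending for mt-ND6).
#'
#' @param gene Gene name as in the map (e.g. `"mt-ND3"`).
#' @param codon 1-based codon index.
#' @param gmap Gene map.
#' @return Integer vector of length 3 in reading order.
#' @export
codon_positions <- function(gene, codon, gmap = rcrs_gene_map()) {
  row <- gmap[gmap$gene == gene, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown gene: ", gene, call. = FALSE)
  codon <- as.integer(codon)
  max_codon <- row$n_codons + as.integer(row$length_bp %% 3L == 0L)
  if (codon < 1L || codon > max_codon) {
    stop("codon ", codon, " out of range for ", gene, call. = FALSE)
  }
  if (row$strand == "+") {
    row$start + (codon - 1L) * 3L + 0:2
  } else {
    row$end - (codon - 1L) * 3L - 0:2
  }
}

#' Complement of DNA bases
#'
#' @param x Character vector of bases over `{A,C,G,T,N,-}`.
#' @return Complemented bases; `N` and `-` are preserved.
#' @export
complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}
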