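#' Construct a codon alignment
#'
#' A codon alignment is a character matrix (taxa x codon columns) whose cells
#' are 3-letter strings over `{A,C,G,T,N,-}`. Cells containing any gap
#' character but not fully gapped are normalised to `"---"`.
#'
#' @param codons Character matrix of 3-letter cells with taxon rownames.
#' @param gene Optional gene name.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons, gene = NA_character_) {
  stopifnot(is.matrix(codons), is.character(codons))
  if (is.null(rownames(codons))) {
    stop("codon matrix must have taxon rownames", call. = FALSE)
  }
  if (any(nchar(codons) != 3L)) {
    stop("all cells must be 3-letter codon strings", call. = FALSE)
  }
  codons[] <- toupper(codons)
  partial <- grepl("-", codons, fixed = TRUE) & codons != "---"
  if (any(partial)) {
    warning(sum(partial), " partially gapped codon cell(s) normalised to '---'",
            call. = FALSE)
    codons[partial] <- "---"
  }
  odd <- grepl("[^ACGTN-]", codons)
  if (any(odd)) {
    codons[odd] <- gsub("[^ACGTN-]", "N", codons[odd])
  }
  structure(list(codons = codons, gene = gene), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment: ", nrow(x$codons), " taxa x ", ncol(x$codons),
      " codon columns", if (!is.na(x$gene)) paste0(" (", x$gene, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Number of taxa / columns of a codon alignment
#' @param x A `codon_alignment`.
#' @return Integer.
#' @export
n_taxa <- function(x) nrow(x$codons)

#' @rdname n_taxa
#' @export
n_columns <- function(x) ncol(x$codons)

#' Read an aligned FASTA file as a codon alignment
#'
#' Sequences must be aligned (equal length). The first `frame_offset` bases
#' of every sequence are discarded before splitting into codons; a trailing
#' remainder shorter than a codon is dropped with a warning.
#'
#' @param path FASTA file.
#' @param frame_offset Number of leading bases to skip (default 0).
#' @param gene Optional gene name attached to the alignment.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, frame_offset = 0L, gene = NA_character_) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (unequal lengths): ", path, call. = FALSE)
  }
  m <- toupper(as.character(as.matrix(dna)))
  if (frame_offset > 0L) m <- m[, -(seq_len(frame_offset)), drop = FALSE]
  rem <- ncol(m) %% 3L
  if (rem != 0L) {
    warning("alignment length not a codon multiple; dropping trailing ", rem,
            " base(s)", call. = FALSE)
    m <- m[, seq_len(ncol(m) - rem), drop = FALSE]
  }
  ncod <- ncol(m) %/% 3L
  cod <- vapply(seq_len(ncod), function(j) {
    apply(m[, (3L * j - 2L):(3L * j), drop = FALSE], 1L, paste0, collapse = "")
  }, character(nrow(m)))
  if (nrow(m) == 1L) cod <- matrix(cod, nrow = 1L)
  rownames(cod) <- names(dna)
  codon_alignment(cod, gene = gene)
}

#' Write a codon alignment to FASTA
#'
#' @param x A `codon_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_codon_alignment <- function(x, path) {
  seqs <- apply(x$codons, 1L, paste0, collapse = "")
  lines <- as.vector(rbind(paste0(">", names(seqs)), seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Amino-acid view of a codon alignment
#'
#' @param x A `codon_alignment`.
#' @param code Genetic code.
#' @return Character matrix of residues (`"*"` stop, `"X"` unknown/gap).
#' @export
translate_alignment <- function(x, code = mito_genetic_code()) {
  m <- x$codons
  aa <- translate_codons(as.vector(m), code)
  matrix(aa, nrow = nrow(m), dimnames = dimnames(m))
}

#' Nucleotide view of a codon alignment
#'
#' @param x A `codon_alignment`.
#' @return Character matrix of single bases (taxa x 3*columns).
#' @export
nucleotide_matrix <- function(x) {
  n <- nrow(x$codons)
  out <- matrix("", n, 3L * ncol(x$codons), dimnames = list(rownames(x$codons), NULL))
  for (k in 0:2) {
    out[, seq(1L + k, ncol(out), by = 3L)] <- substr(x$codons, k + 1L, k + 1L)
  }
  out
}

#' Parse a MITOMAP-style variant notation
#'
#' @param notation String of the form `"m.<position><ref>><alt>"`, e.g.
#'   `"m.10191T>C"`.
#' @return List with `position` (integer), `ref`, `alt` (upper-case bases).
#' @export
#' @examples
#' parse_variant("m.10191T>C")
parse_variant <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1L)
  m <- regmatches(notation,
                  regexec("^m\\.([0-9]+)([ACGTacgt])>([ACGTacgt])$", notation))[[1]]
  if (length(m) != 4L) {
    stop("malformed variant notation: '", notation,
         "' (expected m.<digits><base>><base>)", call. = FALSE)
  }
  list(position = as.integer(m[2]), ref = toupper(m[3]), alt = toupper(m[4]))
}

#' Read a disease-variant table
#'
#' Tab-separated file with header; required columns `notation` and `status`
#' (`confirmed` or `reported`); optional `protein_change`, `phenotype`,
#' `score`, `gene`. Notations are parsed and positions/ref/alt appended.
#'
#' @param path TSV file.
#' @return data.frame with one row per variant.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("notation", "status") %in% names(df))) {
    stop("variant table needs columns 'notation' and 'status'", call. = FALSE)
  }
  bad <- setdiff(unique(df$status), c("confirmed", "reported"))
  if (length(bad)) {
    stop("unknown variant status: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  parsed <- lapply(df$notation, parse_variant)
  df$position <- vapply(parsed, `[[`, integer(1), "position")
  df$ref <- vapply(parsed, `[[`, character(1), "ref")
  df$alt <- vapply(parsed, `[[`, character(1), "alt")
  if (is.null(df$protein_change)) df$protein_change <- NA_character_
  df$protein_change[!nzchar(trimws(as.character(df$protein_change)))] <- NA
  df
}

#' Packaged human mtDNA disease-variant table
#'
#' Curated MITOMAP-derived list of disease-associated missense variants in the
#' 13 mitochondrial protein genes with confirmed/reported status, printed
#' codon numbers and phenotypes.
#'
#' @return data.frame as from [read_variant_table()].
#' @export
mito_disease_variants <- function() {
  path <- system.file("extdata", "mito_disease_variants.tsv",
                      package = "mitocons")
  if (path == "") path <- file.path("inst", "extdata", "mito_disease_variants.tsv")
  read_variant_table(path)
}

#' Read a rooted newick tree
#'
#' Internal node labels / support values are retained as metadata but never
#' used in computation. Branch lengths must be present and non-negative.
#'
#' @param path Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path, call. = FALSE)
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths: ", path, call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  tr
}

#' Bind a tree to a codon alignment
#'
#' Checks that every tree leaf has an alignment row (exact string match,
#' optionally bridged by a rename map) and reorders the alignment rows to the
#' tree's tip order. Alignment rows without a leaf are dropped.
#'
#' @param tree An `ape::phylo` tree.
#' @param alignment A `codon_alignment`.
#' @param rename Optional named character vector mapping tree labels to
#'   alignment labels.
#' @return List of class `bound_data` with elements `tree` and `alignment`.
#' @export
bind_tree_alignment <- function(tree, alignment, rename = NULL) {
  labels <- tree$tip.label
  if (!is.null(rename)) {
    hit <- labels %in% names(rename)
    labels[hit] <- unname(rename[labels[hit]])
  }
  missing <- setdiff(labels, rownames(alignment$codons))
  if (length(missing)) {
    stop("tree leaves absent from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  aln <- alignment
  aln$codons <- alignment$codons[labels, , drop = FALSE]
  rownames(aln$codons) <- tree$tip.label
  structure(list(tree = tree, alignment = aln), class = "bound_data")
}
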