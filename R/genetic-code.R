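#' Vertebrate mitochondrial genetic code
#'
#' Returns the vertebrate mitochondrial code (NCBI translation table 2) as a
#' named character vector mapping each of the 64 codons (DNA alphabet, upper
#' case) to a one-letter amino-acid symbol, with `"*"` for stop codons. The
#' table differs from the standard code at ATA (Met, not Ile), TGA (Trp, not
#' stop) and AGA/AGG (stop, not Arg), leaving 60 sense codons.
#'
#' @return Named character vector of length 64; names are codons, values are
#'   one-letter amino acids or `"*"`.
#' @export
#' @examples
#' code <- mito_genetic_code()
#' code[["TGA"]]  # "W"
#' code[["ATA"]]  # "M"
mito_genetic_code <- function() {
  if (is.null(.mito_code_env$code)) {
    assign("code", .build_mito_code(), envir = .mito_code_env)
  }
  .mito_code_env$code
}

.mito_code_env <- new.env(parent = emptyenv())

.build_mito_code <- function() {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  # standard code, then apply the four vertebrate-mitochondrial differences
  std <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  mito <- std
  mito[["ATA"]] <- "M"
  mito[["TGA"]] <- "W"
  mito[["AGA"]] <- "*"
  mito[["AGG"]] <- "*"
  mito[codons]
}

#' Sense codons of the vertebrate mitochondrial code
#'
#' @return Character vector of the 60 codons that encode an amino acid.
#' @export
mito_sense_codons <- function() {
  code <- mito_genetic_code()
  names(code)[code != "*"]
}

#' Translate a single codon under the vertebrate mitochondrial code
#'
#' Codons containing `N` or gap characters translate to the unknown sentinel
#' `"X"`; stop codons translate to `"*"`.
#'
#' @param codon Length-3 string over `{A,C,G,T,N,-}` (case-insensitive).
#' @param code Genetic code as returned by [mito_genetic_code()].
#' @return One-letter amino-acid symbol, `"*"` (stop) or `"X"` (unknown).
#' @export
#' @examples
#' translate_codon("TGA")  # "W"
#' translate_codon("NNN")  # "X"
translate_codon <- function(codon, code = mito_genetic_code()) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("`codon` must be a single 3-letter string", call. = FALSE)
  }
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon)) {
    if (grepl("[^ACGTN-]", codon)) {
      stop("codon contains characters outside {A,C,G,T,N,-}: ", codon,
           call. = FALSE)
    }
    return("X")
  }
  unname(code[[codon]])
}

#' Translate a vector of codons
#'
#' Vectorised companion to [translate_codon()]: any codon containing a
#' character outside `{A,C,G,T}` yields `"X"`.
#'
#' @param codons Character vector of 3-letter codon strings.
#' @param code Genetic code lookup vector.
#' @return Character vector of amino-acid symbols (`"*"` stop, `"X"` unknown).
#' @export
translate_codons <- function(codons, code = mito_genetic_code()) {
  codons <- toupper(codons)
  out <- rep("X", length(codons))
  ok <- !is.na(codons) & codons %in% names(code)
  out[ok] <- unname(code[codons[ok]])
  out
}
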