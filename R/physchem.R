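#' Property-category z-scores of an amino-acid substitution inventory
#'
#' Tests, for every (property, magnitude category) cell, whether the observed
#' genome-wide branch substitutions are enriched relative to the neutral
#' mutational opportunity: all single-nucleotide codon changes permitted by
#' the mitochondrial code, weighted by the dataset's codon usage. Under the
#' binomial neutral model `z = (observed - n q) / sqrt(n q (1 - q))`, where
#' `q` is the neutral probability that a missense change falls in the cell.
#' Categories with zero neutral expectation are undefined (`NA`) and excluded
#' from the radical set.
#'
#' @param inventory data.frame of observed substitutions with columns `from`
#'   and `to` (one-letter residues, identities ignored).
#' @param usage Named codon-usage frequencies over sense codons (uniform if
#'   omitted).
#' @param table Property matrix.
#' @param code Genetic code.
#' @param z_cut Radical-change threshold on z (default 3.09, p < 0.001).
#' @return List with `z` (31 x 8 matrix), `observed`, `expected_prob`, `n`,
#'   and `radical_set` (logical 31 x 8: category >= 6 and z > z_cut).
#' @export
property_zscores <- function(inventory, usage = NULL,
                             table = aa_property_table(),
                             code = mito_genetic_code(), z_cut = 3.09) {
  inventory <- inventory[inventory$from != inventory$to, , drop = FALSE]
  if (nrow(inventory) == 0L) stop("empty substitution inventory", call. = FALSE)
  sense <- names(code)[code != "*"]
  if (is.null(usage)) usage <- stats::setNames(rep(1 / length(sense), length(sense)), sense)
  arr <- magnitude_category_array(table)
  nprop <- dim(arr)[1L]
  # neutral missense opportunity: codon -> single-nt non-stop neighbours
  qcell <- matrix(0, nprop, 8L, dimnames = list(rownames(table), NULL))
  total_w <- 0
  for (cdn in sense) {
    aa_from <- code[[cdn]]
    nbs <- .codon_neighbours(cdn)
    nbs <- nbs[code[nbs] != "*"]
    for (d in nbs) {
      aa_to <- code[[d]]
      if (aa_to == aa_from) next
      w <- usage[[cdn]] / 9
      total_w <- total_w + w
      cats <- arr[, aa_from, aa_to]
      pos <- cats > 0L
      qcell[cbind(which(pos), cats[pos])] <-
        qcell[cbind(which(pos), cats[pos])] + w
    }
  }
  qcell <- qcell / total_w
  n <- nrow(inventory)
  obs <- matrix(0, nprop, 8L, dimnames = dimnames(qcell))
  for (i in seq_len(n)) {
    cats <- arr[, inventory$from[i], inventory$to[i]]
    pos <- cats > 0L
    obs[cbind(which(pos), cats[pos])] <- obs[cbind(which(pos), cats[pos])] + 1
  }
  z <- (obs - n * qcell) / sqrt(n * qcell * (1 - qcell))
  z[qcell == 0] <- NA
  radical <- matrix(FALSE, nprop, 8L, dimnames = dimnames(qcell))
  radical[, 6:8] <- !is.na(z[, 6:8]) & z[, 6:8] > z_cut
  list(z = z, observed = obs, expected_prob = qcell, n = n,
       radical_set = radical)
}

# radical summary given a precomputed branch-substitution list; radical_set
# NULL means category-only mode (categories 6-8 alone are radical)
site_radical_summary_from_subs <- function(subs, radical_set = NULL,
                                           arr = NULL) {
  if (is.null(arr)) arr <- .radical_arr_cache()
  if (is.null(subs) || nrow(subs) == 0L) {
    return(list(n_radical = 0L, max_props = 0L))
  }
  n_rad <- 0L
  max_props <- 0L
  for (i in seq_len(nrow(subs))) {
    cats <- arr[, subs$from[i], subs$to[i]]
    hit <- cats >= 6L
    if (!is.null(radical_set)) {
      pos <- which(hit)
      hit[pos] <- radical_set[cbind(pos, cats[pos])]
    }
    nprops <- sum(hit)
    if (nprops > 0L) n_rad <- n_rad + 1L
    max_props <- max(max_props, nprops)
  }
  list(n_radical = n_rad, max_props = as.integer(max_props))
}

.radical_env <- new.env(parent = emptyenv())
.radical_arr_cache <- function() {
  if (is.null(.radical_env$arr)) {
    assign("arr", magnitude_category_array(), envir = .radical_env)
  }
  .radical_env$arr
}

#' Radical physicochemical change summary of one residue column
#'
#' Counts, among the column's parsimony branch substitutions, those whose
#' amino-acid replacement changes at least one property radically, and the
#' maximum number of properties radically affected by any single
#' substitution. A radical change is a property change in magnitude category
#' 6-8; in z-score mode the dataset-level z > 3.09 is additionally required
#' for that (property, category).
#'
#' @param aa_states Residue column in `tree$tip.label` order.
#' @param tree Rooted tree.
#' @param radical_set Optional logical 31 x 8 matrix from
#'   [property_zscores()]; `NULL` for category-only mode.
#' @return List with `n_radical` and `max_props`.
#' @export
site_radical_summary <- function(aa_states, tree, radical_set = NULL) {
  subs <- enumerate_branch_substitutions(aa_states, tree,
                                         alphabet = aa_alphabet())
  site_radical_summary_from_subs(subs, radical_set)
}
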