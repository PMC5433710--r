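#' Column inclusion rule
#'
#' Which aligned codon columns enter the per-site analyses. With a designated
#' human reference row (the default anchoring), a column is included when the
#' human cell is a sense codon — this drops columns that are gapped or
#' undefined in the reference and terminal stop codons. Without a reference,
#' columns with at least one sense codon are included.
#'
#' @param x A `codon_alignment`.
#' @param human Human reference row label, or `NULL`.
#' @param code Genetic code.
#' @return Logical vector over columns.
#' @export
included_columns <- function(x, human = NULL, code = mito_genetic_code()) {
  sense <- names(code)[code != "*"]
  if (!is.null(human)) {
    if (!human %in% rownames(x$codons)) {
      stop("human reference row '", human, "' not in alignment", call. = FALSE)
    }
    x$codons[human, ] %in% sense
  } else {
    apply(matrix(x$codons %in% sense, nrow = nrow(x$codons)), 2L, any)
  }
}

# codon-level per-column statistics sharing one ancestral reconstruction:
# Ind2 (pathway-averaged non-synonymous count) and the SLAC quantities
.site_codon_stats <- function(states, tree, code, alpha = 0.1) {
  sense <- names(code)[code != "*"]
  n_informative <- sum(states %in% sense)
  if (n_informative == 0L) {
    return(list(ind2_raw = NA_real_, ind2 = NA_integer_, dN = NA_real_,
                dS = NA_real_, p_value = NA_real_,
                negatively_selected = NA, negatively_selected_strict = NA,
                obs_syn = NA_real_, obs_nonsyn = NA_real_,
                n_informative = 0L))
  }
  rec <- fitch_reconstruct(states, tree, alphabet = sense)
  edge <- rec$tree$edge
  el <- rec$tree$edge.length
  if (is.null(el)) el <- rep(1, nrow(edge))
  from <- rec$node_state[edge[, 1L]]
  to <- rec$node_state[edge[, 2L]]
  sf <- expected_site_fractions(code)
  w <- el / sum(el)
  es_site <- sum(w * sf[from, "es"])
  en_site <- sum(w * sf[from, "en"])
  syn <- nonsyn <- 0
  for (i in which(from != to)) {
    pc <- codon_path_counts(from[i], to[i], code)
    syn <- syn + pc[["syn"]]
    nonsyn <- nonsyn + pc[["nonsyn"]]
  }
  dN <- if (en_site > 0) nonsyn / en_site else 0
  dS <- if (es_site > 0) syn / es_site else 0
  p <- extended_binomial_p(nonsyn, nonsyn + syn, en_site / (en_site + es_site))
  list(ind2_raw = nonsyn, ind2 = as.integer(round(nonsyn)), dN = dN, dS = dS,
       p_value = p,
       negatively_selected = (dN < dS) && p <= alpha,
       negatively_selected_strict = (dN < dS) && p <= 0.05,
       obs_syn = syn, obs_nonsyn = nonsyn, n_informative = n_informative)
}

#' Per-column conservation table
#'
#' Computes, for every included aligned codon column of a bound
#' tree/alignment pair: Ind1 (distinct residues), Ind2 (parsimony-counted
#' non-synonymous substitutions, pathway-averaged; integer and raw), the
#' SLAC quantities (dN, dS, extended-binomial p, negative-selection flags at
#' p <= 0.1 and the strict p <= 0.05), Ind3 (standardized empirical-Bayes
#' rate over the included columns), the radical-change summary from the
#' physicochemical module, and the number of informative leaves.
#'
#' @param bound A `bound_data` pair from [bind_tree_alignment()].
#' @param human Human reference row label used by the inclusion rule
#'   (`NULL` to include all columns with data).
#' @param alpha Significance level of the default negative-selection flag.
#' @param k Gamma categories for Ind3.
#' @param radical_mode `"category"` (category 6-8 alone marks a radical
#'   change; robust for small datasets) or `"zscore"` (additionally requires
#'   the dataset-level z > 3.09 for that property/category).
#' @param code Genetic code.
#' @return data.frame with one row per included column (column ids kept in
#'   `column`).
#' @export
site_conservation <- function(bound, human = NULL, alpha = 0.1, k = 16L,
                              radical_mode = c("category", "zscore"),
                              code = mito_genetic_code()) {
  radical_mode <- match.arg(radical_mode)
  tree <- bound$tree
  aln <- bound$alignment
  inc <- which(included_columns(aln, human, code))
  aa <- translate_alignment(aln, code)
  cod <- aln$codons
  ind1_v <- apply(aa[, inc, drop = FALSE], 2L, ind1)
  stats_l <- lapply(inc, function(j) .site_codon_stats(cod[, j], tree, code, alpha))
  r3 <- ind3(aa[, inc, drop = FALSE], tree, k = k)
  # genome-wide amino-acid substitution inventory for the z-score model
  subs <- lapply(inc, function(j) {
    enumerate_branch_substitutions(aa[, j], tree, alphabet = aa_alphabet())
  })
  inv <- do.call(rbind, subs[!vapply(subs, is.null, logical(1))])
  radical_set <- NULL
  if (radical_mode == "zscore" && !is.null(inv) && nrow(inv) > 0L) {
    usage <- codon_usage(aln, code)
    z <- property_zscores(inv, usage = usage, code = code)
    radical_set <- z$radical_set
  }
  rad <- lapply(subs, function(s) site_radical_summary_from_subs(s, radical_set))
  out <- data.frame(
    column = inc,
    ind1 = as.integer(ind1_v),
    ind2 = vapply(stats_l, function(s) s$ind2, integer(1)),
    ind2_raw = vapply(stats_l, function(s) s$ind2_raw, numeric(1)),
    ind3 = r3$standardized,
    dN = vapply(stats_l, function(s) s$dN, numeric(1)),
    dS = vapply(stats_l, function(s) s$dS, numeric(1)),
    p_value = vapply(stats_l, function(s) s$p_value, numeric(1)),
    negatively_selected = vapply(stats_l, function(s) isTRUE(s$negatively_selected), logical(1)),
    negatively_selected_strict = vapply(stats_l, function(s) isTRUE(s$negatively_selected_strict), logical(1)),
    n_radical_substitutions = vapply(rad, `[[`, integer(1), "n_radical"),
    max_properties_affected = vapply(rad, `[[`, integer(1), "max_props"),
    n_informative = vapply(stats_l, function(s) s$n_informative, integer(1))
  )
  attr(out, "ind3_alpha") <- r3$alpha
  attr(out, "radical_mode") <- radical_mode
  out
}

#' Observed codon usage of an alignment
#'
#' @param x A `codon_alignment`.
#' @param code Genetic code.
#' @return Named numeric vector of relative frequencies over sense codons.
#' @export
codon_usage <- function(x, code = mito_genetic_code()) {
  sense <- names(code)[code != "*"]
  tab <- table(factor(x$codons[x$codons %in% sense], levels = sense))
  u <- as.numeric(tab)
  names(u) <- sense
  if (sum(u) == 0) u[] <- 1
  u / sum(u)
}

#' Independent indel events of a gene alignment
#'
#' Contiguous runs of fully gapped codon columns per taxon are merged into
#' gap blocks; each distinct block (same start and end column) is a binary
#' presence/absence character whose independent evolutionary events are its
#' parsimony changes on the tree. Events are labelled insertions or
#' deletions by the reconstructed ancestral state: an ancestrally present
#' block (sequence present, i.e. gap absent) that is lost on a branch is a
#' deletion of sequence.
#'
#' @param bound A `bound_data` pair.
#' @return data.frame with one row per distinct gap block: `start`, `end`,
#'   `n_taxa_gapped`, `n_events`, `n_deletions`, `n_insertions`; zero rows
#'   for a gapless alignment.
#' @export
enumerate_indel_events <- function(bound) {
  cod <- bound$alignment$codons
  tree <- bound$tree
  gap <- cod == "---"
  empty <- data.frame(start = integer(), end = integer(),
                      n_taxa_gapped = integer(), n_events = integer(),
                      n_deletions = integer(), n_insertions = integer())
  if (!any(gap)) return(empty)
  blocks <- list()
  for (i in seq_len(nrow(gap))) {
    r <- rle(gap[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      key <- paste(starts[b], ends[b])
      blocks[[key]] <- c(blocks[[key]], rownames(cod)[i])
    }
  }
  rows <- lapply(names(blocks), function(key) {
    se <- as.integer(strsplit(key, " ")[[1]])
    gapped <- blocks[[key]]
    # character: "gap" vs "seq" presence of the block
    states <- ifelse(rownames(cod) %in% gapped, "gap", "seq")
    names(states) <- rownames(cod)
    # alphabet order makes ties at the root resolve to ancestrally present
    # sequence, so equivocal blocks are polarised as deletions
    rec <- fitch_reconstruct(states[tree$tip.label], tree,
                             alphabet = c("seq", "gap"))
    edge <- rec$tree$edge
    from <- rec$node_state[edge[, 1L]]
    to <- rec$node_state[edge[, 2L]]
    chg <- which(from != to)
    ndel <- sum(from[chg] == "seq")   # sequence lost on the branch
    nins <- sum(from[chg] == "gap")
    data.frame(start = se[1], end = se[2], n_taxa_gapped = length(gapped),
               n_events = length(chg), n_deletions = ndel,
               n_insertions = nins)
  })
  do.call(rbind, rows)
}

#' Distribution summary of a conservation index
#'
#' @param x Numeric vector.
#' @param digits Rounding used to define the mode for continuous indices.
#' @return List with `mode`, `median`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
index_summary <- function(x, digits = 3L) {
  x <- x[!is.na(x)]
  tab <- table(round(x, digits))
  list(mode = as.numeric(names(tab)[which.max(tab)]),
       median = stats::median(x), mean = mean(x), sd = stats::sd(x),
       min = min(x), max = max(x), n = length(x))
}
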