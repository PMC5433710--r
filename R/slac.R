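.slac_env <- new.env(parent = emptyenv())

# single-nucleotide neighbours of a codon (9 per codon)
.codon_neighbours <- function(codon) {
  b <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in 1:3) {
    cur <- substr(codon, p, p)
    for (nb in setdiff(b, cur)) {
      x <- codon
      substr(x, p, p) <- nb
      out <- c(out, x)
    }
  }
  out
}

#' Expected synonymous/non-synonymous site fractions per codon
#'
#' For each sense codon of the vertebrate mitochondrial code, the expected
#' number of synonymous and non-synonymous "sites" out of 3: at each codon
#' position the fraction of single-nucleotide changes (to non-stop codons)
#' that are synonymous. Changes into stop codons are excluded from the
#' opportunity set; the two fractions sum to 3 for every codon with at least
#' one viable neighbour per position.
#'
#' @param code Genetic code.
#' @return data.frame with rownames = sense codons and columns `es`, `en`.
#' @export
expected_site_fractions <- function(code = mito_genetic_code()) {
  key <- "site_fractions"
  if (!is.null(.slac_env[[key]])) return(.slac_env[[key]])
  sense <- names(code)[code != "*"]
  es <- en <- numeric(length(sense))
  names(es) <- names(en) <- sense
  for (cdn in sense) {
    aa <- code[[cdn]]
    for (p in 1:3) {
      cur <- substr(cdn, p, p)
      nbs <- vapply(setdiff(c("A", "C", "G", "T"), cur), function(nb) {
        x <- cdn; substr(x, p, p) <- nb; x
      }, character(1))
      viable <- nbs[code[nbs] != "*"]
      if (length(viable) == 0L) next
      syn_frac <- mean(code[viable] == aa)
      es[cdn] <- es[cdn] + syn_frac
      en[cdn] <- en[cdn] + (1 - syn_frac)
    }
  }
  out <- data.frame(es = es, en = en)
  assign(key, out, envir = .slac_env)
  out
}

#' Pathway-averaged substitution counts between two codons
#'
#' Decomposes a (possibly multi-nucleotide) codon change into single-step
#' mutational pathways, averaging synonymous and non-synonymous step counts
#' over all minimal orderings that avoid stop-codon intermediates. If every
#' minimal pathway passes through a stop, all pathways are used (steps through
#' a stop count as non-synonymous when the translation changes).
#'
#' @param from,to Sense codons.
#' @param code Genetic code.
#' @return Numeric vector `c(syn = , nonsyn = )`; both 0 when `from == to`.
#' @export
#' @examples
#' codon_path_counts("TCC", "CCC")  # one non-synonymous step (S -> P)
codon_path_counts <- function(from, to, code = mito_genetic_code()) {
  if (from == to) return(c(syn = 0, nonsyn = 0))
  key <- paste0(from, ">", to)
  memo <- .slac_env$paths
  if (is.null(memo)) {
    memo <- new.env(parent = emptyenv())
    assign("paths", memo, envir = .slac_env)
  }
  if (!is.null(memo[[key]])) return(memo[[key]])
  pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  perms <- .permutations(pos)
  paths <- lapply(perms, function(ord) {
    cur <- from
    steps <- matrix(character(0), ncol = 2)
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      steps <- rbind(steps, c(cur, nxt))
      cur <- nxt
    }
    steps
  })
  stop_free <- vapply(paths, function(st) {
    inter <- setdiff(unique(as.vector(st)), c(from, to))
    all(code[inter] != "*")
  }, logical(1))
  use <- if (any(stop_free)) paths[stop_free] else paths
  counts <- vapply(use, function(st) {
    aa_from <- unname(code[st[, 1L]])
    aa_to <- unname(code[st[, 2L]])
    syn <- sum(aa_from == aa_to)
    c(syn, nrow(st) - syn)
  }, numeric(2))
  out <- c(syn = mean(counts[1L, ]), nonsyn = mean(counts[2L, ]))
  assign(key, out, envir = memo)
  out
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

#' Two-tailed extended binomial test probability
#'
#' Binomial tail probabilities extended to non-integer counts and trials via
#' the regularised incomplete beta function; used to test whether the
#' observed split of substitutions into non-synonymous vs synonymous deviates
#' from the neutral expectation.
#'
#' @param k Observed (possibly fractional) successes.
#' @param n Total (possibly fractional) trials.
#' @param p Null success probability.
#' @return Two-tailed p-value in `[0, 1]`.
#' @export
extended_binomial_p <- function(k, n, p) {
  if (n <= 0) return(1)
  k <- min(max(k, 0), n)
  lower <- if (k >= n) 1 else stats::pbeta(1 - p, n - k, k + 1)
  upper <- if (k <= 0) 1 else stats::pbeta(p, k, n - k + 1)
  min(1, 2 * min(lower, upper))
}

#' SLAC-style per-site selection test
#'
#' Reconstructs ancestral codons for one aligned codon column by parsimony,
#' counts observed synonymous and non-synonymous substitutions over branches
#' (pathway-averaged for multi-nucleotide changes), computes expected site
#' fractions from the ancestral codon of each branch (branch-length
#' weighted), and tests the observed split against the neutral proportion
#' with the two-tailed extended binomial.
#'
#' A site is flagged negatively selected when `dN < dS` and the p-value is at
#' or below `alpha` (default 0.1, SLAC's customary default; use
#' `alpha = 0.05` for the strict mode). Both `dN` and `dS` are normalised
#' per-site rates: observed counts divided by expected site counts.
#'
#' @param states Codon column in `tree$tip.label` order; cells that are not
#'   sense codons (gaps, Ns, stops) are missing data.
#' @param tree Rooted tree with branch lengths.
#' @param code Genetic code.
#' @param alpha Significance level for the negative-selection flag.
#' @return List with `dN`, `dS`, `p_value`, `negatively_selected`,
#'   `obs_syn`, `obs_nonsyn`, `exp_syn_sites`, `exp_nonsyn_sites`,
#'   `n_informative`. All-missing columns return `NULL`.
#' @export
slac_site <- function(states, tree, code = mito_genetic_code(), alpha = 0.1) {
  sense <- names(code)[code != "*"]
  n_informative <- sum(states %in% sense)
  if (n_informative == 0L) return(NULL)
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
  obs <- c(syn = 0, nonsyn = 0)
  for (i in which(from != to)) {
    obs <- obs + codon_path_counts(from[i], to[i], code)
  }
  dN <- if (en_site > 0) obs[["nonsyn"]] / en_site else 0
  dS <- if (es_site > 0) obs[["syn"]] / es_site else 0
  p <- extended_binomial_p(obs[["nonsyn"]], obs[["nonsyn"]] + obs[["syn"]],
                           en_site / (en_site + es_site))
  list(dN = dN, dS = dS, p_value = p,
       negatively_selected = (dN < dS) && p <= alpha,
       obs_syn = obs[["syn"]], obs_nonsyn = obs[["nonsyn"]],
       exp_syn_sites = es_site, exp_nonsyn_sites = en_site,
       n_informative = n_informative)
}

#' Non-synonymous substitution count of a codon column (Ind2)
#'
#' Total number of non-synonymous substitution events over the tree for one
#' aligned codon column: parsimony branch substitutions with multi-nucleotide
#' changes decomposed by pathway averaging. The integer index is the rounded
#' pathway-averaged count; the raw fractional count is also returned.
#'
#' @inheritParams slac_site
#' @return List with `raw` (fractional) and `count` (rounded integer);
#'   `NULL` for an all-missing column.
#' @export
ind2 <- function(states, tree, code = mito_genetic_code()) {
  sense <- names(code)[code != "*"]
  if (!any(states %in% sense)) return(NULL)
  rec <- fitch_reconstruct(states, tree, alphabet = sense)
  edge <- rec$tree$edge
  from <- rec$node_state[edge[, 1L]]
  to <- rec$node_state[edge[, 2L]]
  nonsyn <- 0
  for (i in which(from != to)) {
    nonsyn <- nonsyn + codon_path_counts(from[i], to[i], code)[["nonsyn"]]
  }
  list(raw = nonsyn, count = as.integer(round(nonsyn)))
}

#' Distinct amino-acid count of a residue column (Ind1)
#'
#' @param aa_states Character vector of residues; gaps/unknowns (`"-"`,
#'   `"X"`, `"*"`, `NA`) are excluded.
#' @return Integer count, or `NA` when no cell carries a defined residue.
#' @export
ind1 <- function(aa_states) {
  ok <- aa_states %in% aa_alphabet()
  if (!any(ok)) return(NA_integer_)
  length(unique(aa_states[ok]))
}
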