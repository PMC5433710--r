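#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a primate mitogenome
#' protein-coding dataset: ~148 sequences with a few species sampled twice,
#' strong purifying selection on most sites (two-class omega mixture), an
#' exponential-like spread of site rates (gamma shape < 1 plus an invariant
#' fraction), a transition-biased mutation process, and occasional codon
#' gap blocks.
#'
#' @param n_taxa Number of sequences.
#' @param n_sites Number of codon sites.
#' @param seed Master seed; every component (tree, sites, events, gaps,
#'   planting) draws its own derived sub-seed so outputs are reproducible
#'   bit-for-bit.
#' @param birth,death Birth-death rates of the tree shape.
#' @param tree_scale Mean root-to-tip path length (expected neutral
#'   substitutions/site).
#' @param gamma_shape Gamma shape of site rate multipliers.
#' @param p_invariant Fraction of sites with rate 0.
#' @param frac_conserved Fraction of sites in the conserved omega class.
#' @param omega_conserved,omega_variable Nonsynonymous/synonymous rate
#'   ratios of the two site classes.
#' @param kappa Transition/transversion rate ratio.
#' @param codon_freqs Equilibrium codon frequencies over the 60 sense codons
#'   (uniform when `NULL`).
#' @param gap_blocks Expected number of gap blocks planted on the alignment.
#' @param n_duplicate_species Number of species represented by two sequences.
#' @param human_label Label given to the reference tip.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 148L, n_sites = 1000L, seed = 1L,
                       birth = 1, death = 0.5, tree_scale = 1.2,
                       gamma_shape = 1.5, p_invariant = 0.05,
                       frac_conserved = 0.6, omega_conserved = 0.03,
                       omega_variable = 0.3, kappa = 8,
                       codon_freqs = NULL, gap_blocks = 10L,
                       n_duplicate_species = 9L,
                       human_label = "Homo_sapiens") {
  stopifnot(p_invariant >= 0, p_invariant <= 1,
            frac_conserved >= 0, frac_conserved <= 1,
            omega_conserved >= 0, omega_variable >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# codon kinetics under the two omega classes: neighbour index matrix,
# per-neighbour rates, total leaving rates; rates normalised so a neutral
# (omega = 1, rate-1) site substitutes at ~1 per unit branch length
.codon_kinetics <- function(config, code = mito_genetic_code()) {
  sense <- names(code)[code != "*"]
  ns <- length(sense)
  nbr_idx <- matrix(NA_integer_, ns, 9L)
  nbr_rate <- array(0, c(ns, 9L, 2L))  # class 1 conserved, 2 variable
  omega <- c(config$omega_conserved, config$omega_variable)
  is_transition <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  for (ci in seq_len(ns)) {
    cdn <- sense[ci]
    nbs <- .codon_neighbours(cdn)
    for (k in seq_along(nbs)) {
      d <- nbs[k]
      if (code[[d]] == "*") next  # substitutions into stops are rejected
      pos <- which(strsplit(cdn, "")[[1]] != strsplit(d, "")[[1]])
      base_rate <- if (is_transition(substr(cdn, pos, pos),
                                     substr(d, pos, pos))) config$kappa else 1
      syn <- code[[d]] == code[[cdn]]
      nbr_idx[ci, k] <- match(d, sense)
      for (cl in 1:2) {
        nbr_rate[ci, k, cl] <- base_rate * if (syn) 1 else omega[cl]
      }
    }
  }
  # neutral normalisation: mean total rate over codons at omega = 1
  neutral_tot <- vapply(seq_len(ns), function(ci) {
    cdn <- sense[ci]
    nbs <- .codon_neighbours(cdn)
    sum(vapply(nbs, function(d) {
      if (code[[d]] == "*") return(0)
      pos <- which(strsplit(cdn, "")[[1]] != strsplit(d, "")[[1]])
      if (is_transition(substr(cdn, pos, pos), substr(d, pos, pos)))
        config$kappa else 1
    }, numeric(1)))
  }, numeric(1))
  mu <- mean(neutral_tot)
  nbr_rate <- nbr_rate / mu
  tot_rate <- apply(nbr_rate, c(1L, 3L), sum)
  syn_mat <- matrix(FALSE, ns, 9L)
  for (ci in seq_len(ns)) {
    ok <- !is.na(nbr_idx[ci, ])
    syn_mat[ci, ok] <- code[sense[nbr_idx[ci, ok]]] == code[sense[ci]]
  }
  list(sense = sense, nbr_idx = nbr_idx, nbr_rate = nbr_rate,
       tot_rate = tot_rate, syn = syn_mat)
}

#' Simulate a birth-death tree rescaled to a target divergence
#'
#' @param n_taxa Number of tips.
#' @param birth,death Birth-death rates.
#' @param scale Target mean root-to-tip path length.
#' @return Rooted ultrametric `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, birth = 1, death = 0.5, scale = 0.35) {
  tr <- ape::rphylo(n_taxa, birth, death)
  depth <- mean(ape::node.depth.edgelength(tr)[seq_len(n_taxa)])
  tr$edge.length <- tr$edge.length / depth * scale
  tr
}

#' Simulate a codon alignment with full ground truth
#'
#' Continuous-time codon substitution along each branch of a simulated
#' birth-death tree: per-site rate multipliers (discrete invariant fraction
#' plus gamma), a two-class per-site omega mixture, transition bias, and
#' stop-codon-avoiding single-nucleotide moves. Every substitution event is
#' logged so leaf sequences can be replayed exactly; codon gap blocks are
#' planted on clades (never on the reference tip) after sequence evolution.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_data` with `alignment` (codon_alignment),
#'   `tree` (tips renamed, reference tip = `config$human_label`), `truth`
#'   (site rates/omega classes, event log, root sequence, gap blocks,
#'   species map) and `config`.
#' @export
simulate_alignment <- function(config = sim_config()) {
  code <- mito_genetic_code()
  seeds <- .derive_seeds(config$seed)
  set.seed(seeds["tree"])
  tree <- simulate_tree(config$n_taxa, config$birth, config$death,
                        config$tree_scale)
  tree$tip.label <- sprintf("t%03d", seq_len(config$n_taxa))
  tree$tip.label[1L] <- config$human_label
  ti <- .tree_index(tree)
  kin <- .codon_kinetics(config, code)
  ns <- length(kin$sense)
  nsite <- config$n_sites
  set.seed(seeds["sites"])
  rate <- ifelse(stats::runif(nsite) < config$p_invariant, 0,
                 stats::rgamma(nsite, shape = config$gamma_shape,
                               rate = config$gamma_shape))
  class_ <- ifelse(stats::runif(nsite) < config$frac_conserved, 1L, 2L)
  freqs <- config$codon_freqs
  if (is.null(freqs)) freqs <- stats::setNames(rep(1 / ns, ns), kin$sense)
  root_seq <- sample.int(ns, nsite, replace = TRUE, prob = freqs[kin$sense])
  set.seed(seeds["events"])
  seqs <- vector("list", ti$nnode)
  seqs[[ti$root]] <- root_seq
  edge <- ti$edge
  el <- ti$edge_length
  events <- list()
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    cur <- seqs[[parent]]
    remaining <- rep(el[i], nsite)
    elapsed <- rep(0, nsite)
    active <- which(rate > 0)
    while (length(active) > 0L) {
      lam <- rate[active] * kin$tot_rate[cbind(cur[active], class_[active])]
      wait <- stats::rexp(length(active), lam)
      hit <- wait < remaining[active]
      sites <- active[hit]
      if (length(sites) == 0L) break
      elapsed[sites] <- elapsed[sites] + wait[hit]
      remaining[sites] <- remaining[sites] - wait[hit]
      for (s in sites) {
        pr <- kin$nbr_rate[cur[s], , class_[s]]
        k <- sample.int(9L, 1L, prob = pr)
        events[[length(events) + 1L]] <-
          c(edge = i, site = s, from = cur[s], to = kin$nbr_idx[cur[s], k],
            syn = as.integer(kin$syn[cur[s], k]), time = elapsed[s])
        cur[s] <- kin$nbr_idx[cur[s], k]
      }
      active <- sites
    }
    seqs[[child]] <- cur
  }
  ev <- if (length(events)) as.data.frame(do.call(rbind, events)) else
    data.frame(edge = integer(), site = integer(), from = integer(),
               to = integer(), syn = integer(), time = numeric())
  cod <- t(vapply(seq_len(ti$ntip), function(i) kin$sense[seqs[[i]]],
                  character(nsite)))
  rownames(cod) <- ti$tree$tip.label
  # gap blocks on clades excluding the reference tip
  set.seed(seeds["gaps"])
  nblocks <- stats::rpois(1L, config$gap_blocks)
  human_tip <- match(config$human_label, ti$tree$tip.label)
  blocks <- list()
  if (nblocks > 0L) {
    for (b in seq_len(nblocks)) {
      for (try in 1:50) {
        ei <- sample.int(nrow(edge), 1L)
        tips <- .descendant_tips(ti, edge[ei, 2L])
        if (!(human_tip %in% tips)) break
      }
      if (human_tip %in% tips) next
      width <- sample.int(3L, 1L)
      start <- sample.int(nsite - width + 1L, 1L)
      cod[tips, start:(start + width - 1L)] <- "---"
      blocks[[length(blocks) + 1L]] <-
        data.frame(start = start, end = start + width - 1L,
                   n_taxa = length(tips))
    }
  }
  aln <- codon_alignment(cod, gene = "sgene1")
  species <- .species_map(ti$tree, config$n_duplicate_species,
                          config$human_label, seeds["species"])
  truth <- list(site_rate = rate, site_class = class_,
                site_omega = c(config$omega_conserved,
                               config$omega_variable)[class_],
                root_seq = kin$sense[root_seq], events = ev,
                gap_blocks = if (length(blocks)) do.call(rbind, blocks) else NULL,
                species_map = species, sense = kin$sense)
  structure(list(alignment = aln, tree = ti$tree, truth = truth,
                 config = config), class = "sim_data")
}

.derive_seeds <- function(seed) {
  base <- (as.integer(seed) %% 100000L) * 7919L
  stats::setNames((base + c(11L, 23L, 37L, 53L, 71L)) %% .Machine$integer.max,
                  c("tree", "sites", "events", "gaps", "species"))
}

.descendant_tips <- function(ti, node) {
  if (node <= ti$ntip) return(node)
  out <- integer(0)
  stack <- node
  edge <- ti$edge
  while (length(stack)) {
    nd <- stack[1L]; stack <- stack[-1L]
    ch <- edge[edge[, 1L] == nd, 2L]
    out <- c(out, ch[ch <= ti$ntip])
    stack <- c(stack, ch[ch > ti$ntip])
  }
  out
}

.species_map <- function(tree, n_dup, human_label, seed) {
  tips <- tree$tip.label
  species <- stats::setNames(tips, tips)
  if (n_dup > 0L) {
    set.seed(seed)
    # sister-pair tips (cherries) collapse to one species
    edge <- tree$edge
    ntip <- length(tips)
    internal <- unique(edge[edge[, 2L] <= ntip, 1L])
    cherries <- Filter(function(nd) {
      ch <- edge[edge[, 1L] == nd, 2L]
      length(ch) == 2L && all(ch <= ntip) &&
        !(human_label %in% tips[ch])
    }, internal)
    if (length(cherries) > 0L) {
      take <- utils::head(sample(cherries), n_dup)
      for (nd in take) {
        ch <- edge[edge[, 1L] == nd, 2L]
        species[tips[ch[2L]]] <- tips[ch[1L]]
      }
    }
  }
  species
}

#' Replay a simulation's event log
#'
#' Applies the logged substitution events branch by branch from the root
#' sequence and returns the implied leaf codon matrix (before gap planting);
#' used to verify that the emitted alignment is consistent with its truth.
#'
#' @param sim A `sim_data` object.
#' @return Character codon matrix, taxa x sites.
#' @export
replay_events <- function(sim) {
  ti <- .tree_index(sim$tree)
  sense <- sim$truth$sense
  nsite <- length(sim$truth$site_rate)
  seqs <- vector("list", ti$nnode)
  seqs[[ti$root]] <- match(sim$truth$root_seq, sense)
  ev <- sim$truth$events
  edge <- ti$edge
  for (i in rev(seq_len(nrow(edge)))) {
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    cur <- seqs[[parent]]
    e <- ev[ev$edge == i, , drop = FALSE]
    if (nrow(e) > 0L) {
      e <- e[order(e$time), , drop = FALSE]
      for (j in seq_len(nrow(e))) {
        stopifnot(cur[e$site[j]] == e$from[j])
        cur[e$site[j]] <- e$to[j]
      }
    }
    seqs[[child]] <- cur
  }
  cod <- t(vapply(seq_len(ti$ntip), function(i) sense[seqs[[i]]],
                  character(nsite)))
  rownames(cod) <- ti$tree$tip.label
  cod
}

#' Synthetic single-gene map for planted variants
#'
#' @param n_sites Number of codon columns.
#' @return Gene map data.frame compatible with [map_mtdna_position()].
#' @export
synthetic_gene_map <- function(n_sites) {
  data.frame(gene = "sgene1", start = 1L, end = 3L * n_sites, strand = "+",
             length_bp = 3L * n_sites, n_codons = n_sites - 1L,
             stringsAsFactors = FALSE)
}

#' Plant disease-like variants with known conservation class
#'
#' "Confirmed-like" variants are placed at sites in the lowest decile of
#' true evolutionary rate; "reported-like" variants at sites drawn
#' uniformly. Each variant is a single-nucleotide missense change of the
#' reference (human) codon, written in m.-notation on the synthetic gene
#' map, with a synthetic pathogenicity score drawn higher on average for
#' confirmed-like variants.
#'
#' @param sim A `sim_data` object.
#' @param n_conserved Number of confirmed-like variants.
#' @param n_variable Number of reported-like variants.
#' @param seed Seed for placement and scores.
#' @return data.frame in the variant-table dialect (`notation`, `status`,
#'   `protein_change`, `phenotype`, `score`) plus truth columns
#'   `true_class` and `column`.
#' @export
plant_variants <- function(sim, n_conserved = 28L, n_variable = 192L,
                           seed = sim$config$seed + 101L) {
  code <- mito_genetic_code()
  sense <- mito_sense_codons()
  human <- sim$config$human_label
  hrow <- sim$alignment$codons[human, ]
  eligible <- which(hrow %in% sense)
  rate <- sim$truth$site_rate
  cutoff <- stats::quantile(rate[eligible], 0.1)
  low <- eligible[rate[eligible] <= cutoff]
  if (n_conserved > length(low)) {
    stop("requested more conserved-like variants than eligible sites",
         call. = FALSE)
  }
  if (n_variable > length(eligible)) {
    stop("requested more reported-like variants than eligible sites",
         call. = FALSE)
  }
  set.seed(seed)
  cols_c <- sample(low, n_conserved)
  cols_v <- sample(eligible, n_variable)
  make_row <- function(col, status, true_class) {
    hc <- hrow[[col]]
    ref_aa <- translate_codon(hc, code)
    for (off in sample(0:2)) {
      ref <- substr(hc, off + 1L, off + 1L)
      for (alt in sample(setdiff(c("A", "C", "G", "T"), ref))) {
        mc <- hc
        substr(mc, off + 1L, off + 1L) <- alt
        alt_aa <- translate_codon(mc, code)
        if (alt_aa != "*" && alt_aa != ref_aa) {
          pos <- (col - 1L) * 3L + off + 1L
          return(data.frame(
            notation = sprintf("m.%d%s>%s", pos, ref, alt),
            status = status,
            protein_change = paste0(ref_aa, col, alt_aa),
            phenotype = "synthetic", position = pos, ref = ref, alt = alt,
            score = NA_real_, true_class = true_class, column = col,
            stringsAsFactors = FALSE))
        }
      }
    }
    NULL
  }
  rows <- c(lapply(cols_c, make_row, status = "confirmed",
                   true_class = "conserved"),
            lapply(cols_v, make_row, status = "reported",
                   true_class = "uniform"))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  conf <- out$status == "confirmed"
  out$score[conf] <- pmin(1, pmax(0, stats::rnorm(sum(conf), 0.8, 0.08)))
  out$score[!conf] <- pmin(1, pmax(0, stats::rnorm(sum(!conf), 0.65, 0.12)))
  out
}
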