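#' Clade registry for presence-tier flags
#'
#' Named taxon sets used to flag where a disease-associated residue occurs:
#' non-human primates, catarrhines (Old World monkeys + apes), hominids
#' (great apes + humans) and extinct Homo, which must be nested
#' (`extinct_homo` within `hominids` within `catarrhines` within
#' `nonhuman_primates` plus the human).
#'
#' @param nonhuman_primates,catarrhines,hominids,extinct_homo Character
#'   vectors of taxon labels (each excluding the human reference).
#' @param human Human reference taxon label.
#' @return List of class `clade_registry`.
#' @export
clade_registry <- function(nonhuman_primates, catarrhines = character(),
                           hominids = character(), extinct_homo = character(),
                           human) {
  chk <- function(inner, outer, ni, no) {
    if (!all(inner %in% outer)) {
      stop("clade nesting violated: ", ni, " not contained in ", no,
           call. = FALSE)
    }
  }
  chk(extinct_homo, hominids, "extinct_homo", "hominids")
  chk(hominids, catarrhines, "hominids", "catarrhines")
  chk(catarrhines, nonhuman_primates, "catarrhines", "nonhuman_primates")
  structure(list(nonhuman_primates = nonhuman_primates,
                 catarrhines = catarrhines, hominids = hominids,
                 extinct_homo = extinct_homo, human = human),
            class = "clade_registry")
}

#' Map a parsed variant onto gene codons and aligned columns
#'
#' For every protein gene overlapping the variant's position: the gene-local
#' codon, the human reference codon (from the designated alignment row), the
#' mutant codon (strand-aware: bases are complemented for light-strand
#' genes), both residues, and the missense/samesense/nonsense
#' classification.
#'
#' @param variant List or one-row data.frame with `position`, `ref`, `alt`
#'   (see [parse_variant()]), optionally `protein_change`.
#' @param gmap Gene map (see [rcrs_gene_map()]).
#' @param alignment Optional `codon_alignment` holding the human row.
#' @param human Human reference row label (required with `alignment`).
#' @param column_lookup Function `(gene, codon) -> column index or NA`
#'   translating gene codons to alignment columns; identity by default
#'   (single-gene alignments whose columns are the gene's codons).
#' @param code Genetic code.
#' @return data.frame with one row per overlapped gene (zero rows when the
#'   position lies outside all protein genes).
#' @export
map_variant <- function(variant, gmap = rcrs_gene_map(), alignment = NULL,
                        human = NULL, column_lookup = NULL,
                        code = mito_genetic_code()) {
  tg <- map_mtdna_position(variant$position, gmap)
  if (nrow(tg) == 0L) {
    return(data.frame(gene = character(), codon = integer(),
                      offset_in_codon = integer(), strand = character(),
                      column = integer(), human_codon = character(),
                      mutant_codon = character(), ref_residue = character(),
                      alt_residue = character(), classification = character(),
                      ref_match = logical(), stringsAsFactors = FALSE))
  }
  if (is.null(column_lookup)) column_lookup <- function(gene, codon) codon
  n <- nrow(tg)
  tg$column <- vapply(seq_len(n), function(i) {
    as.integer(column_lookup(tg$gene[i], tg$codon[i]))
  }, integer(1))
  tg$human_codon <- NA_character_
  tg$mutant_codon <- NA_character_
  tg$ref_residue <- NA_character_
  tg$alt_residue <- NA_character_
  tg$classification <- NA_character_
  tg$ref_match <- NA
  if (!is.null(alignment)) {
    if (is.null(human) || !human %in% rownames(alignment$codons)) {
      stop("designate a `human` row present in the alignment", call. = FALSE)
    }
    for (i in seq_len(n)) {
      col <- tg$column[i]
      if (is.na(col) || col > ncol(alignment$codons)) next
      hc <- alignment$codons[human, col]
      if (!hc %in% mito_sense_codons()) next
      minus <- tg$strand[i] == "-"
      ref_g <- if (minus) complement_base(variant$ref) else variant$ref
      alt_g <- if (minus) complement_base(variant$alt) else variant$alt
      off <- tg$offset_in_codon[i]
      mc <- hc
      substr(mc, off + 1L, off + 1L) <- alt_g
      tg$human_codon[i] <- hc
      tg$mutant_codon[i] <- mc
      tg$ref_match[i] <- substr(hc, off + 1L, off + 1L) == ref_g
      ra <- translate_codon(hc, code)
      ma <- translate_codon(mc, code)
      tg$ref_residue[i] <- ra
      tg$alt_residue[i] <- ma
      tg$classification[i] <- if (ma == "*") "nonsense"
        else if (ra == ma) "samesense" else "missense"
    }
  }
  tg
}

#' Detect an evolutionary reversion toward a disease residue
#'
#' `TRUE` when some ancestor on the path from the root to the human leaf is
#' reconstructed with the disease residue while the human leaf itself does
#' not carry it — i.e. a later branch on the human lineage substituted away
#' from the residue, so the modern variant restores an ancestral state.
#'
#' @param aa_states Residue column in `tree$tip.label` order.
#' @param tree Rooted tree.
#' @param human Human leaf label.
#' @param residue Disease residue.
#' @return Logical flag.
#' @export
detect_reversion <- function(aa_states, tree, human, residue) {
  rec <- fitch_reconstruct(aa_states, tree, alphabet = aa_alphabet())
  if (is.null(rec)) return(FALSE)
  tr <- rec$tree
  tip <- match(human, tr$tip.label)
  if (is.na(tip)) stop("human leaf '", human, "' not in tree", call. = FALSE)
  # walk up parent links
  path <- tip
  node <- tip
  repeat {
    parent <- tr$edge[tr$edge[, 2L] == node, 1L]
    if (length(parent) == 0L) break
    path <- c(path, parent)
    node <- parent
  }
  human_state <- rec$node_state[tip]
  anc_states <- rec$node_state[path[-1L]]
  human_state != residue && any(anc_states == residue)
}

#' Recurrence report for one disease variant
#'
#' Maps the variant, determines the disease residue (from the
#' `protein_change` field when present, otherwise derived from ref/alt
#' through the reading frame), and reports for each mapped gene target:
#' presence flags of the disease residue in the nested clade tiers, the
#' exact minimum number of independent evolutionary origins, the number of
#' species carrying the residue (deduplicated by species, human excluded),
#' and whether the variant restores an ancestral state on the human lineage
#' (reversion). A conservation snapshot is attached when a site table is
#' supplied.
#'
#' @param variant One-row data.frame (or list) with `notation`, `position`,
#'   `ref`, `alt`, `status`, optional `protein_change`.
#' @param bound `bound_data` pair.
#' @param clades [clade_registry()].
#' @param gmap Gene map.
#' @param human Human reference row label (defaults to the registry's).
#' @param species_map Named vector mapping taxon label to species; identity
#'   when `NULL`. A species carries a residue if any of its sequences does.
#' @param site_table Optional [site_conservation()] table.
#' @param column_lookup As in [map_variant()].
#' @param residue_source `"protein_change"` (field wins, default) or
#'   `"derived"` (strict-coordinates mode: the frame-derived residue wins).
#' @param code Genetic code.
#' @return data.frame with one row per mapped target; zero rows if unmapped.
#' @export
recurrence_report <- function(variant, bound, clades, gmap = rcrs_gene_map(),
                              human = clades$human, species_map = NULL,
                              site_table = NULL, column_lookup = NULL,
                              residue_source = c("protein_change", "derived"),
                              code = mito_genetic_code()) {
  residue_source <- match.arg(residue_source)
  aln <- bound$alignment
  tree <- bound$tree
  vm <- map_variant(variant, gmap, aln, human, column_lookup, code)
  if (nrow(vm) == 0L) return(vm)
  aa <- translate_alignment(aln, code)
  taxa <- rownames(aln$codons)
  if (is.null(species_map)) species_map <- stats::setNames(taxa, taxa)
  pc <- variant$protein_change
  pc_residue <- if (!is.null(pc) && !is.na(pc) && nzchar(pc)) {
    sub("^.*?([A-Z])$", "\\1", pc)
  } else NA_character_
  out <- vm
  out$status <- variant$status %||% NA_character_
  out$notation <- variant$notation %||% NA_character_
  out$disease_residue <- NA_character_
  out$residue_conflict <- FALSE
  out$present_nonhuman_primates <- NA
  out$present_catarrhines <- NA
  out$present_hominids <- NA
  out$present_extinct_homo <- NA
  out$n_independent_origins <- NA_integer_
  out$n_species_with_residue <- NA_integer_
  out$is_reversion <- NA
  out$reason <- NA_character_
  for (i in seq_len(nrow(out))) {
    derived <- out$alt_residue[i]
    residue <- if (!is.na(pc_residue)) pc_residue else derived
    if (residue_source == "derived" && !is.na(derived)) residue <- derived
    if (!is.na(pc_residue) && !is.na(derived) && pc_residue != derived) {
      out$residue_conflict[i] <- TRUE
    }
    if (is.na(residue) || !(residue %in% aa_alphabet())) {
      out$reason[i] <- "disease residue undeterminable"
      next
    }
    out$disease_residue[i] <- residue
    col <- out$column[i]
    if (is.na(col) || col > ncol(aa)) {
      out$reason[i] <- "no aligned column"
      next
    }
    states <- aa[, col]
    names(states) <- taxa
    carriers <- taxa[states == residue & !is.na(states)]
    carrier_species <- unique(species_map[carriers])
    human_species <- unname(species_map[human])
    carrier_species <- setdiff(carrier_species, human_species)
    in_tier <- function(tier) {
      any(species_map[intersect(carriers, tier)] %in% carrier_species)
    }
    out$present_nonhuman_primates[i] <- in_tier(clades$nonhuman_primates)
    out$present_catarrhines[i] <- in_tier(clades$catarrhines)
    out$present_hominids[i] <- in_tier(clades$hominids)
    out$present_extinct_homo[i] <- in_tier(clades$extinct_homo)
    out$n_species_with_residue[i] <- length(carrier_species)
    org <- count_independent_origins(states[tree$tip.label], tree, residue,
                                     alphabet = aa_alphabet())
    # origins are counted among non-human carriers: a residue carried only
    # by the human is not a recurrence
    if (length(carrier_species) == 0L) org <- 0L
    out$n_independent_origins[i] <- org
    out$is_reversion[i] <- detect_reversion(states[tree$tip.label], tree,
                                            human, residue)
  }
  if (!is.null(site_table)) {
    m <- match(out$column, site_table$column)
    out$ind1 <- site_table$ind1[m]
    out$ind2 <- site_table$ind2[m]
    out$ind3 <- site_table$ind3[m]
    out$negatively_selected <- site_table$negatively_selected[m]
    out$n_radical_substitutions <- site_table$n_radical_substitutions[m]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summaries of recurrence reports (positions and mutations)
#'
#' Builds the gene-by-status position tallies (total / invariant / variable /
#' presence in each nested clade tier), the list of reported variants at
#' completely conserved columns, the list of reported variants at variable
#' columns whose substitutions never changed any property radically, and
#' distribution summaries of origin and species counts. Position counts
#' deduplicate by aligned column; mutation counts keep one row per variant
#' target.
#'
#' @param reports data.frame of rbound [recurrence_report()] rows carrying a
#'   site snapshot (built with `site_table`).
#' @return List with `positions_by_gene`, `totals`, `invariant_reported`
#'   (conserved-position analogue), `nonradical_variable_reported`,
#'   `origin_summary`, `species_summary`.
#' @export
summarize_reports <- function(reports) {
  stopifnot(all(c("ind1", "ind2") %in% names(reports)))
  rep_ok <- reports[!is.na(reports$disease_residue), , drop = FALSE]
  key <- interaction(rep_ok$gene, rep_ok$column, rep_ok$status, drop = TRUE)
  pos <- do.call(rbind, lapply(split(rep_ok, key), function(d) {
    data.frame(gene = d$gene[1L], column = d$column[1L], status = d$status[1L],
               invariant = d$ind1[1L] == 1L,
               present_nonhuman_primates = any(d$present_nonhuman_primates),
               present_catarrhines = any(d$present_catarrhines),
               present_hominids = any(d$present_hominids),
               present_extinct_homo = any(d$present_extinct_homo),
               stringsAsFactors = FALSE)
  }))
  tally <- function(d) {
    data.frame(n_positions = nrow(d), n_invariant = sum(d$invariant),
               n_variable = sum(!d$invariant),
               n_nonhuman = sum(d$present_nonhuman_primates),
               n_catarrhines = sum(d$present_catarrhines),
               n_hominids = sum(d$present_hominids),
               n_extinct_homo = sum(d$present_extinct_homo))
  }
  by_gene <- do.call(rbind, lapply(
    split(pos, interaction(pos$gene, pos$status, drop = TRUE)),
    function(d) cbind(gene = d$gene[1L], status = d$status[1L], tally(d))))
  totals <- do.call(rbind, lapply(split(pos, pos$status), function(d) {
    cbind(status = d$status[1L], tally(d))
  }))
  reported <- rep_ok[rep_ok$status == "reported", , drop = FALSE]
  invariant_reported <- reported[reported$ind1 == 1L & reported$ind2 == 0L, ,
                                 drop = FALSE]
  nonrad <- reported[reported$ind1 > 1L &
                       reported$n_radical_substitutions == 0L, , drop = FALSE]
  rep_pos <- pos[pos$status == "reported", , drop = FALSE]
  per_pos <- lapply(seq_len(nrow(rep_pos)), function(i) {
    d <- reported[reported$gene == rep_pos$gene[i] &
                    reported$column == rep_pos$column[i], , drop = FALSE]
    c(origins = max(d$n_independent_origins, 0, na.rm = TRUE),
      species = max(d$n_species_with_residue, 0, na.rm = TRUE))
  })
  om <- vapply(per_pos, `[[`, numeric(1), "origins")
  sm <- vapply(per_pos, `[[`, numeric(1), "species")
  list(positions_by_gene = by_gene, totals = totals,
       invariant_reported = invariant_reported,
       nonradical_variable_reported = nonrad,
       origin_summary = if (length(om)) index_summary(om) else NULL,
       species_summary = if (length(sm)) index_summary(sm) else NULL)
}
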