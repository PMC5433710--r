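#' Hash of an R object (for run manifests and determinism checks)
#'
#' MD5 of the canonical serialization, via a temporary file and
#' [tools::md5sum()].
#'
#' @param x Any serialisable object.
#' @return Hex string.
#' @export
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

.write_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("mitocons"))
  writeLines(paste0("# mitocons ", ver,
                    if (!is.null(config_hash)) paste0(" config=", config_hash)),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Conservation stage of the pipeline
#'
#' Runs the per-column conservation analysis on a bound alignment/tree pair:
#' the site table ([site_conservation()]), indel events, per-index
#' distribution summaries, exponential goodness-of-fit tests (Ind3 shifted
#' to positive support first) and, optionally, the per-gene mean GTR+G+I
#' distance. All computation is deterministic; re-running with the same
#' inputs gives byte-identical tables.
#'
#' @param bound A `bound_data` pair.
#' @param human Human reference row label (`NULL` disables reference
#'   anchoring).
#' @param alpha Negative-selection significance level.
#' @param k Gamma categories for Ind3.
#' @param radical_mode See [site_conservation()].
#' @param compute_distance Also fit the GTR+G+I model and mean pairwise
#'   distance (quadratic in taxa; off by default).
#' @param gof_bins Bins of the exponential fits for Ind1, Ind2, Ind3
#'   (defaults give 14, 7 and 8 degrees of freedom).
#' @param out_dir Optional directory for TSV outputs.
#' @return List of class `conserve_result` with `site_table`, `indels`,
#'   `summaries`, `gof`, `gene_summary`, `config_hash`.
#' @export
run_conserve <- function(bound, human = NULL, alpha = 0.1, k = 16L,
                         radical_mode = "category", compute_distance = FALSE,
                         gof_bins = c(ind1 = 16L, ind2 = 9L, ind3 = 10L),
                         out_dir = NULL) {
  cfg <- list(human = human, alpha = alpha, k = k,
              radical_mode = radical_mode, gof_bins = gof_bins)
  chash <- object_hash(list(cfg, bound$alignment$codons, bound$tree$edge,
                            bound$tree$edge.length))
  st <- site_conservation(bound, human = human, alpha = alpha, k = k,
                          radical_mode = radical_mode)
  indels <- enumerate_indel_events(bound)
  summaries <- list(ind1 = index_summary(st$ind1),
                    ind2 = index_summary(st$ind2),
                    ind3 = index_summary(st$ind3))
  gof <- list(
    ind1 = exponential_gof(st$ind1[!is.na(st$ind1)], gof_bins[["ind1"]]),
    ind2 = exponential_gof(st$ind2[!is.na(st$ind2)], gof_bins[["ind2"]]),
    ind3 = exponential_gof(shift_positive(st$ind3), gof_bins[["ind3"]])
  )
  gene <- bound$alignment$gene
  gs <- data.frame(gene = if (is.na(gene)) "all" else gene,
                   length_bp = 3L * ncol(bound$alignment$codons),
                   n_columns_included = nrow(st),
                   frac_invariant = mean(st$ind1 == 1L, na.rm = TRUE),
                   frac_negative = mean(st$negatively_selected, na.rm = TRUE),
                   n_indel_events = if (nrow(indels)) sum(indels$n_events) else 0L,
                   mean_distance = NA_real_)
  if (compute_distance) {
    gs$mean_distance <- gene_mean_distance(bound$alignment)$mean_distance
  }
  res <- structure(list(site_table = st, indels = indels,
                        summaries = summaries, gof = gof, gene_summary = gs,
                        config_hash = chash),
                   class = "conserve_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(st, file.path(out_dir, "site_conservation.tsv"), chash)
    .write_tsv(indels, file.path(out_dir, "indel_events.tsv"), chash)
    .write_tsv(gs, file.path(out_dir, "gene_summary.tsv"), chash)
    .write_tsv(.summaries_df(summaries, gof),
               file.path(out_dir, "index_summaries.tsv"), chash)
  }
  res
}

.summaries_df <- function(summaries, gof) {
  do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    g <- gof[[nm]]
    data.frame(index = nm, mode = s$mode, median = s$median, mean = s$mean,
               sd = s$sd, min = s$min, max = s$max, n = s$n,
               gof_chisq = g$statistic, gof_df = g$df, gof_p = g$p_value)
  }))
}

#' Variant-mapping stage of the pipeline
#'
#' Maps each disease variant onto aligned columns, builds recurrence reports
#' (clade presence, independent origins, species counts, reversions),
#' assembles the position/mutation summary tables, and runs the comparative
#' statistics: KS tests of Ind1/Ind2/Ind3 between all columns and columns
#' carrying confirmed or reported variants, and the pooled t test of
#' pathogenicity scores (confirmed vs reported) when scores are present.
#'
#' @param conserve A `conserve_result` (site table is reused, not
#'   recomputed).
#' @param variants Variant data.frame from [read_variant_table()] or
#'   [plant_variants()].
#' @param bound The same `bound_data` pair used for `conserve`.
#' @param clades A [clade_registry()].
#' @param gmap Gene map the variant coordinates refer to.
#' @param species_map Optional taxon-to-species map.
#' @param column_lookup As in [map_variant()].
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return List of class `mapvariants_result` with `reports`, `summary`,
#'   `ks_tests`, `t_test`, `config_hash`.
#' @export
run_mapvariants <- function(conserve, variants, bound, clades,
                            gmap = rcrs_gene_map(), species_map = NULL,
                            column_lookup = NULL, out_dir = NULL) {
  st <- conserve$site_table
  reports <- list()
  for (i in seq_len(nrow(variants))) {
    r <- recurrence_report(variants[i, ], bound, clades, gmap = gmap,
                           species_map = species_map, site_table = st,
                           column_lookup = column_lookup)
    if (nrow(r) > 0L) {
      if (!is.null(variants$score)) r$score <- variants$score[i]
      reports[[length(reports) + 1L]] <- r
    }
  }
  if (length(reports) == 0L) {
    warning("no variant mapped to an aligned column", call. = FALSE)
    return(structure(list(reports = NULL, summary = NULL, ks_tests = NULL,
                          t_test = NULL, config_hash = conserve$config_hash),
                     class = "mapvariants_result"))
  }
  reports <- do.call(rbind, reports)
  summary <- summarize_reports(reports)
  cols_conf <- unique(reports$column[reports$status == "confirmed" &
                                       !is.na(reports$disease_residue)])
  cols_rep <- unique(reports$column[reports$status == "reported" &
                                      !is.na(reports$disease_residue)])
  ks_for <- function(idx) {
    all_v <- st[[idx]]
    list(confirmed_vs_all =
           if (length(cols_conf) > 1L)
             ks_two_sample(st[[idx]][match(cols_conf, st$column)], all_v)
           else NULL,
         reported_vs_all =
           if (length(cols_rep) > 1L)
             ks_two_sample(st[[idx]][match(cols_rep, st$column)], all_v)
           else NULL)
  }
  ks_tests <- list(ind1 = ks_for("ind1"), ind2 = ks_for("ind2"),
                   ind3 = ks_for("ind3"))
  t_test <- NULL
  if (!is.null(reports$score)) {
    sc <- reports[!duplicated(reports$notation) & !is.na(reports$score), ]
    x <- sc$score[sc$status == "confirmed"]
    y <- sc$score[sc$status == "reported"]
    if (length(x) > 1L && length(y) > 1L) t_test <- two_sample_t(x, y)
  }
  res <- structure(list(reports = reports, summary = summary,
                        ks_tests = ks_tests, t_test = t_test,
                        config_hash = conserve$config_hash),
                   class = "mapvariants_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(reports, file.path(out_dir, "variant_reports.tsv"),
               conserve$config_hash)
    .write_tsv(summary$totals, file.path(out_dir, "position_totals.tsv"),
               conserve$config_hash)
    .write_tsv(summary$positions_by_gene,
               file.path(out_dir, "positions_by_gene.tsv"),
               conserve$config_hash)
    jsonlite::write_json(
      list(reports = reports,
           ks = lapply(ks_tests, function(k) lapply(k, unclass)),
           t_test = unclass(t_test)),
      file.path(out_dir, "variant_reports.json"), auto_unbox = TRUE,
      digits = NA, na = "null")
  }
  res
}

#' Simulation stage of the pipeline
#'
#' Simulates a dataset bundle ([simulate_alignment()] plus
#' [plant_variants()]) and optionally writes it in the same dialects the
#' readers consume (FASTA alignment, newick tree, variant TSV, truth and
#' manifest JSON).
#'
#' @param config A [sim_config()].
#' @param n_conserved,n_variable Planted variant counts.
#' @param out_dir Optional output directory.
#' @return List of class `sim_bundle` with `sim`, `variants`, `manifest`.
#' @export
run_simulate <- function(config = sim_config(), n_conserved = 28L,
                         n_variable = 192L, out_dir = NULL) {
  sim <- simulate_alignment(config)
  variants <- plant_variants(sim, n_conserved, n_variable)
  manifest <- list(seed = config$seed, n_taxa = config$n_taxa,
                   n_sites = config$n_sites,
                   alignment_hash = object_hash(sim$alignment$codons),
                   package = as.character(utils::packageVersion("mitocons")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_codon_alignment(sim$alignment, file.path(out_dir, "alignment.fasta"))
    ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
    .write_tsv(variants, file.path(out_dir, "variants.tsv"))
    jsonlite::write_json(list(site_rate = sim$truth$site_rate,
                              site_omega = sim$truth$site_omega,
                              species_map = as.list(sim$truth$species_map)),
                         file.path(out_dir, "truth.json"), digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  structure(list(sim = sim, variants = variants, manifest = manifest),
            class = "sim_bundle")
}

#' Default clade registry for a simulated tree
#'
#' Derives nested clade tiers from the simulated tree: the smallest clades
#' containing the reference tip define the hominid/catarrhine analogues, and
#' a couple of reference-adjacent tips play the extinct-relatives role. This
#' gives the presence tiers the same nesting structure the real taxon sets
#' have.
#'
#' @param sim A `sim_data` object.
#' @return A [clade_registry()].
#' @export
sim_clade_registry <- function(sim) {
  tree <- sim$tree
  human <- sim$config$human_label
  tips <- tree$tip.label
  ti <- .tree_index(tree)
  htip <- match(human, tips)
  # walk rootward from the reference tip, collecting ever larger clades
  node <- htip
  clades <- list()
  repeat {
    parent <- ti$edge[ti$edge[, 2L] == node, 1L]
    if (length(parent) == 0L) break
    clades[[length(clades) + 1L]] <- tips[.descendant_tips(ti, parent)]
    node <- parent
  }
  nonhuman <- setdiff(tips, human)
  pick <- function(i) setdiff(clades[[min(i, length(clades))]], human)
  extinct <- utils::head(pick(1L), 2L)
  hominids <- unique(c(extinct, pick(2L)))
  catarrhines <- unique(c(hominids, pick(min(4L, length(clades)))))
  clade_registry(nonhuman_primates = nonhuman, catarrhines = catarrhines,
                 hominids = hominids, extinct_homo = extinct, human = human)
}
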