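test_that("property table is complete and categories well-formed", {
  tab <- aa_property_table()
  expect_identical(dim(tab), c(31L, 20L))
  expect_false(anyNA(tab))
  expect_identical(colnames(tab), aa_alphabet())
  expect_true(all(property_max_change(tab) > 0))
})

test_that("magnitude categories are symmetric, zero on identity, in 1..8", {
  tab <- aa_property_table()
  props <- rownames(tab)
  set.seed(41)
  for (i in 1:60) {
    a <- sample(aa_alphabet(), 1)
    b <- sample(aa_alphabet(), 1)
    p <- sample(props, 1)
    ca <- magnitude_category(a, b, p)
    expect_identical(ca, magnitude_category(b, a, p))
    if (a == b) {
      expect_identical(ca, 0L)
    } else {
      expect_true(ca %in% 0:8)
      # independent bin arithmetic
      delta <- abs(tab[p, a] - tab[p, b])
      maxc <- max(tab[p, ]) - min(tab[p, ])
      expected <- if (delta == 0) 0L else min(8L, floor(delta / maxc * 8) + 1L)
      expect_identical(ca, as.integer(expected))
    }
  }
  expect_error(magnitude_category("A", "Z", props[1]), "unknown residue")
  expect_error(magnitude_category("A", "T", "nope"), "unknown property")
  # the extreme pair of any property reaches category 8
  p <- "kd_hydropathy"
  hi <- names(which.max(tab[p, ]))
  lo <- names(which.min(tab[p, ]))
  expect_identical(magnitude_category(hi, lo, p), 8L)
})

test_that("category array matches the scalar function", {
  arr <- magnitude_category_array()
  set.seed(43)
  for (i in 1:30) {
    a <- sample(aa_alphabet(), 1); b <- sample(aa_alphabet(), 1)
    p <- sample(rownames(aa_property_table()), 1)
    expect_identical(arr[p, a, b], magnitude_category(a, b, p))
  }
})

test_that("z-scores vanish at expectation and flag enrichment", {
  code <- mito_genetic_code()
  sense <- mito_sense_codons()
  # inventory drawn exactly proportional to the neutral opportunity
  inv <- list()
  for (cdn in sense) {
    for (d in mitocons:::.codon_neighbours(cdn)) {
      if (code[[d]] == "*" || code[[d]] == code[[cdn]]) next
      inv[[length(inv) + 1L]] <- data.frame(from = code[[cdn]], to = code[[d]])
    }
  }
  inv <- do.call(rbind, inv)
  z <- property_zscores(inv)
  expect_lt(max(abs(z$z), na.rm = TRUE), 1e-6)
  expect_true(any(is.na(z$z)))         # empty cells are undefined sentinels
  expect_false(any(z$radical_set))
  expect_error(property_zscores(inv[0, ]), "empty")

  # an inventory of only extreme hydropathy swaps is enriched in high bins
  inv2 <- data.frame(from = rep("I", 60), to = rep("R", 60))
  z2 <- property_zscores(inv2)
  expect_gt(z2$z["kd_hydropathy", magnitude_category("I", "R", "kd_hydropathy")],
            3.09)
})

test_that("purifying simulation depletes radical categories", {
  sim <- simulate_alignment(sim_config(n_taxa = 60L, n_sites = 250L,
                                       seed = 47L, frac_conserved = 1,
                                       omega_conserved = 0.2,
                                       tree_scale = 0.8, gap_blocks = 0L))
  bound <- bind_tree_alignment(sim$tree, sim$alignment)
  aa <- translate_alignment(bound$alignment)
  subs <- lapply(seq_len(ncol(aa)), function(j)
    enumerate_branch_substitutions(aa[, j], bound$tree, aa_alphabet()))
  inv <- do.call(rbind, subs[!vapply(subs, is.null, logical(1))])
  inv <- inv[inv$from != inv$to, ]
  expect_gt(nrow(inv), 30)
  z <- property_zscores(inv, usage = codon_usage(bound$alignment))
  hi <- z$z[, 6:8]
  lo <- z$z[, 1:3]
  # under purifying selection the radical bins trend depleted relative to
  # the conservative bins (sign-level assertion)
  expect_lt(mean(hi, na.rm = TRUE), mean(lo, na.rm = TRUE))
})

test_that("per-site radical summaries bound Ind2 and respect subsets", {
  sim <- small_sim(seed = 53, n_taxa = 16L, n_sites = 50L)
  bound <- bind_tree_alignment(sim$tree, sim$alignment)
  aa <- translate_alignment(bound$alignment)
  for (j in seq_len(50L)) {
    rs <- site_radical_summary(aa[, j], bound$tree)
    i2 <- ind2(bound$alignment$codons[, j], bound$tree)
    expect_gte(rs$n_radical, 0L)
    if (!is.null(i2)) expect_lte(rs$n_radical, max(i2$count, ceiling(i2$raw)))
    if (rs$n_radical == 0L) expect_identical(rs$max_props, 0L)
  }
  # invariant column
  col <- rep("M", ape::Ntip(bound$tree))
  expect_identical(site_radical_summary(col, bound$tree),
                   list(n_radical = 0L, max_props = 0L))
  # removing taxa never increases the radical count
  keep <- bound$tree$tip.label[1:10]
  sub_tree <- ape::keep.tip(bound$tree, keep)
  for (j in c(2L, 11L, 27L)) {
    full <- site_radical_summary(aa[, j], bound$tree)
    sub <- site_radical_summary(aa[keep, j][sub_tree$tip.label], sub_tree)
    expect_lte(sub$n_radical, full$n_radical)
  }
})
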