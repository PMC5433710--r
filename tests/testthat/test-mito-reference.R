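test_that("vertebrate mitochondrial code has the four canonical differences", {
  code <- mito_genetic_code()
  expect_length(code, 64L)
  expect_identical(code[["ATA"]], "M")
  expect_identical(code[["TGA"]], "W")
  expect_identical(code[["AGA"]], "*")
  expect_identical(code[["AGG"]], "*")
  expect_identical(sum(code != "*"), 60L)
  expect_setequal(unique(code), c(aa_alphabet(), "*"))
})

test_that("translate_codon handles sense, ambiguous and malformed input", {
  expect_identical(translate_codon("TGA"), "W")
  expect_identical(translate_codon("ATA"), "M")
  expect_identical(translate_codon("NNN"), "X")
  expect_identical(translate_codon("A-G"), "X")
  expect_error(translate_codon("AT"), "3-letter")
  expect_error(translate_codon("AXG"), "outside")
  expect_identical(translate_codons(c("atg", "TAA", "N--")), c("M", "*", "X"))
})

test_that("gene map matches rCRS anatomy", {
  gm <- rcrs_gene_map()
  expect_identical(nrow(gm), 13L)
  expect_identical(gm$strand[gm$gene == "mt-ND6"], "-")
  expect_true(all(gm$strand[gm$gene != "mt-ND6"] == "+"))
  atp8 <- gm[gm$gene == "mt-ATP8", ]
  atp6 <- gm[gm$gene == "mt-ATP6", ]
  expect_true(atp6$start <= atp8$end)  # ATP8/ATP6 overlap
  nd4l <- gm[gm$gene == "mt-ND4L", ]
  nd4 <- gm[gm$gene == "mt-ND4", ]
  expect_true(nd4$start <= nd4l$end)   # ND4L/ND4 overlap
  # protein lengths of the 13 human mt proteins
  expected <- c(`mt-ND1` = 318L, `mt-ND2` = 347L, `mt-CO1` = 513L,
                `mt-CO2` = 227L, `mt-ATP8` = 68L, `mt-ATP6` = 226L,
                `mt-CO3` = 261L, `mt-ND3` = 115L, `mt-ND4L` = 98L,
                `mt-ND4` = 459L, `mt-ND5` = 603L, `mt-ND6` = 174L,
                `mt-CYB` = 380L)
  expect_identical(stats::setNames(gm$n_codons, gm$gene), expected)
})

test_that("positions map to the documented gene codons", {
  m <- map_mtdna_position(10158)
  expect_identical(m$gene, "mt-ND3")
  expect_identical(m$codon, 34L)
  expect_identical(m$offset_in_codon, 0L)

  m <- map_mtdna_position(8528)
  expect_setequal(m$gene, c("mt-ATP8", "mt-ATP6"))
  expect_identical(m$codon[m$gene == "mt-ATP6"], 1L)
  expect_identical(m$offset_in_codon[m$gene == "mt-ATP6"], 1L)
  expect_identical(m$codon[m$gene == "mt-ATP8"], 55L)
  expect_identical(m$offset_in_codon[m$gene == "mt-ATP8"], 0L)

  m <- map_mtdna_position(8527)
  expect_identical(m$codon[m$gene == "mt-ATP8"], 54L)
  expect_identical(m$codon[m$gene == "mt-ATP6"], 1L)

  # light strand: codon 64 of mt-ND6 is read 14484 -> 14482
  m <- map_mtdna_position(14484)
  expect_identical(m$gene, "mt-ND6")
  expect_identical(m$codon, 64L)
  expect_identical(m$offset_in_codon, 0L)
  m <- map_mtdna_position(14482)
  expect_identical(m$offset_in_codon, 2L)

  expect_identical(nrow(map_mtdna_position(16000)), 0L)  # D-loop
  expect_error(map_mtdna_position(-1))
})

test_that("codon_positions round-trips through map_mtdna_position", {
  gm <- rcrs_gene_map()
  set.seed(11)
  for (g in gm$gene) {
    n <- gm$n_codons[gm$gene == g]
    for (k in unique(c(1L, n, sample.int(n, 5L)))) {
      pos <- codon_positions(g, k, gm)
      expect_length(pos, 3L)
      for (oi in 1:3) {
        mm <- map_mtdna_position(pos[oi], gm)
        row <- mm[mm$gene == g, ]
        expect_identical(row$codon, k)
        expect_identical(row$offset_in_codon, oi - 1L)
      }
    }
  }
})

test_that("packaged variant table agrees with the coordinate map", {
  v <- mito_disease_variants()
  # two rows are known printed errata in the source tables (the canonical
  # MITOMAP annotations are L285P at m.4160 and codon 158 at m.11232)
  errata <- c("m.4160T>C", "m.11232T>C")
  for (i in seq_len(nrow(v))) {
    m <- map_mtdna_position(v$position[i])
    row <- m[m$gene == v$gene[i], ]
    expect_identical(nrow(row), 1L)
    if (!(v$notation[i] %in% errata)) {
      expect_identical(row$codon, v$codon_printed[i])
    } else {
      expect_false(row$codon == v$codon_printed[i])
    }
  }
})
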