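test_that("parsimony counts match hand-worked quartets", {
  tr <- quartet_tree()
  expect_identical(fitch_min_changes(c("S", "S", "S", "S"), tr), 0L)
  expect_identical(fitch_min_changes(c("S", "S", "P", "P"), tr), 1L)
  expect_identical(fitch_min_changes(c("S", "P", "S", "P"), tr), 2L)
  expect_true(is.na(fitch_min_changes(c("-", "-", "-", "-"), tr,
                                      alphabet = c("S", "P"))))
  # missing data joins for free
  expect_identical(fitch_min_changes(c("S", NA, "P", "P"), tr,
                                     alphabet = c("S", "P")), 1L)
})

test_that("branch substitution lists are consistent with the minimum", {
  tr <- quartet_tree()
  expect_identical(nrow(enumerate_branch_substitutions(c("A", "A", "A", "A"), tr)), 0L)
  bs <- enumerate_branch_substitutions(c("S", "S", "P", "P"), tr)
  expect_identical(nrow(bs), 1L)
  # the single change lies on the internal edge (both endpoints internal)
  expect_true(bs$parent_node > 4 && bs$child_node > 4)
})

test_that("parsimony DP equals the exhaustive oracle on random columns", {
  set.seed(101)
  for (rep in 1:120) {
    n <- sample(4:7, 1)
    ab_size <- if (n == 7) sample(2:4, 1) else sample(2:5, 1)
    alphabet <- LETTERS[seq_len(ab_size)]
    tr <- random_tree(n)
    states <- sample(c(alphabet, NA), n, replace = TRUE,
                     prob = c(rep(1, ab_size), 0.3))
    if (all(is.na(states))) next
    oracle <- brute_parsimony(states, tr, alphabet)
    expect_identical(fitch_min_changes(states, tr, alphabet),
                     as.integer(oracle$min_changes))
    bs <- enumerate_branch_substitutions(states, tr, alphabet)
    expect_identical(nrow(bs), as.integer(oracle$min_changes))
  }
})

test_that("independent origins equal the exhaustive MPR minimum", {
  set.seed(202)
  for (rep in 1:80) {
    n <- sample(4:6, 1)
    alphabet <- LETTERS[1:3]
    tr <- random_tree(n)
    states <- sample(alphabet, n, replace = TRUE)
    res <- alphabet[1]
    oracle <- brute_parsimony(states, tr, alphabet, residue = res)
    expect_identical(count_independent_origins(states, tr, res, alphabet),
                     as.integer(oracle$min_origins))
  }
})

test_that("origins respect carrier bounds and clade structure", {
  set.seed(303)
  for (rep in 1:40) {
    n <- sample(5:9, 1)
    tr <- random_tree(n)
    states <- sample(c("A", "B"), n, replace = TRUE)
    org <- count_independent_origins(states, tr, "A", c("A", "B"))
    expect_lte(org, sum(states == "A"))
    if (!any(states == "A")) expect_identical(org, 0L)
  }
  # carriers forming a clade whose complement lacks the residue: one origin
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  states <- c(A = "H", B = "H", C = "Y", D = "Y", E = "Y")[tr$tip.label]
  expect_identical(count_independent_origins(states, tr, "H"), 1L)
  expect_error(count_independent_origins(states, tr, "Z", c("H", "Y")),
               "not in alphabet")
})

test_that("multiple origins are detected on a comb of scattered carriers", {
  tr <- ape::read.tree(
    text = "((((A:1,B:1):1,C:1):1,(D:1,E:1):1):1,(F:1,G:1):1);")
  # two isolated carriers: an all-carrier backbone would cost five losses,
  # so every MPR gains the residue twice
  states <- c(A = "H", B = "Y", C = "Y", D = "Y", E = "Y",
              F = "H", G = "Y")[tr$tip.label]
  oracle <- brute_parsimony(states, tr, c("H", "Y"), residue = "H")
  expect_identical(count_independent_origins(states, tr, "H"),
                   as.integer(oracle$min_origins))
  expect_identical(count_independent_origins(states, tr, "H"), 2L)
})
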