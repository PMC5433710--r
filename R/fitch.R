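#' Amino-acid alphabet used for parsimony over residue columns
#' @return Character vector of the 20 one-letter symbols.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# postorder edge matrix and node bookkeeping for a rooted tree
#' @importFrom ape reorder.phylo
.tree_index <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  list(tree = tr, ntip = ntip, nnode = ntip + tr$Nnode,
       root = ntip + 1L, edge = tr$edge, edge_length = tr$edge.length)
}

# per-node state cost matrix under unit substitution cost (exact parsimony
# minimum on any rooted tree, binary or not). `possible` is a logical
# alphabet x ntip matrix; a tip with no possible state (all FALSE) is treated
# as missing data (every state possible at zero cost).
.sankoff_cost <- function(possible, ti) {
  ns <- nrow(possible)
  C <- matrix(0, ns, ti$nnode)
  tipC <- matrix(Inf, ns, ti$ntip)
  tipC[possible] <- 0
  missing_tip <- colSums(possible) == 0L
  tipC[, missing_tip] <- 0
  C[, seq_len(ti$ntip)] <- tipC
  edge <- ti$edge
  for (i in seq_len(nrow(edge))) {
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    cc <- C[, child]
    C[, parent] <- C[, parent] + pmin(cc, min(cc) + 1)
  }
  C
}

# logical alphabet x ntip matrix of observed states; unknowns all-FALSE
.possible_states <- function(states, alphabet) {
  m <- matrix(FALSE, length(alphabet), length(states),
              dimnames = list(alphabet, NULL))
  idx <- match(states, alphabet)
  ok <- !is.na(idx)
  m[cbind(idx[ok], which(ok))] <- TRUE
  m
}

#' Minimum number of substitutions for a character column on a tree
#'
#' Exact parsimony minimum (Fitch count) over all internal labelings,
#' computed by unit-cost dynamic programming; valid on non-binary trees.
#' Leaf states outside the alphabet (gaps, unknowns) are missing data and can
#' take any state free of cost.
#'
#' @param states Character vector of leaf states in `tree$tip.label` order.
#' @param tree Rooted `ape::phylo` tree.
#' @param alphabet State alphabet; defaults to the distinct observed states.
#' @return Integer minimum change count, or `NA` if every leaf is missing.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' fitch_min_changes(c("S", "S", "P", "P"), tr)  # 1
fitch_min_changes <- function(states, tree, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- sort(unique(states[!is.na(states)]))
  ti <- .tree_index(tree)
  states <- states[match(ti$tree$tip.label, tree$tip.label)]
  possible <- .possible_states(states, alphabet)
  if (all(colSums(possible) == 0L)) return(NA_integer_)
  C <- .sankoff_cost(possible, ti)
  as.integer(min(C[, ti$root]))
}

#' Deterministic most-parsimonious ancestral reconstruction
#'
#' Sankoff traceback with a fixed policy: the root takes the first
#' minimum-cost state in alphabet order; every other node keeps its parent's
#' state whenever that choice is optimal for its subtree (DELTRAN-like delay
#' of transformations), otherwise the first optimal state in alphabet order.
#' The number of branches whose endpoints differ always equals the parsimony
#' minimum.
#'
#' @inheritParams fitch_min_changes
#' @return List with `node_state` (character, one per node of the reordered
#'   tree), `changes` (integer minimum), `tree` (postorder-reordered tree) and
#'   `alphabet`. `NULL` if all leaves are missing.
#' @export
fitch_reconstruct <- function(states, tree, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- sort(unique(states[!is.na(states)]))
  ti <- .tree_index(tree)
  states <- states[match(ti$tree$tip.label, tree$tip.label)]
  possible <- .possible_states(states, alphabet)
  if (all(colSums(possible) == 0L)) return(NULL)
  C <- .sankoff_cost(possible, ti)
  missing_tip <- colSums(possible) == 0L
  nnode <- ti$nnode
  state <- integer(nnode)
  rootC <- C[, ti$root]
  state[ti$root] <- which(rootC == min(rootC))[1L]
  edge <- ti$edge
  # preorder = reverse postorder for edges
  for (i in rev(seq_len(nrow(edge)))) {
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    ps <- state[parent]
    cc <- C[, child]
    best <- min(cc)
    # optimal child states given parent state ps: cost cc[s] + (s != ps)
    tot <- cc + (seq_along(cc) != ps)
    opt <- min(tot)
    state[child] <- if (tot[ps] == opt) ps else which(tot == opt)[1L]
  }
  node_state <- alphabet[state]
  # leaves that are missing data keep the reconstructed (parent-consistent)
  # state; observed leaves keep their own state by construction
  list(node_state = node_state, changes = as.integer(min(rootC)),
       tree = ti$tree, alphabet = alphabet,
       missing_leaf = which(missing_tip))
}

#' Per-branch substitutions of a most-parsimonious reconstruction
#'
#' Lists every branch whose endpoints differ under the deterministic
#' reconstruction of [fitch_reconstruct()]. The list length equals the
#' parsimony minimum change count.
#'
#' @inheritParams fitch_min_changes
#' @return data.frame with columns `edge` (row of the reordered tree's edge
#'   matrix), `parent_node`, `child_node`, `from`, `to`; zero rows for an
#'   invariant column. `NULL` when every leaf is missing.
#' @export
enumerate_branch_substitutions <- function(states, tree, alphabet = NULL) {
  rec <- fitch_reconstruct(states, tree, alphabet)
  if (is.null(rec)) return(NULL)
  edge <- rec$tree$edge
  from <- rec$node_state[edge[, 1L]]
  to <- rec$node_state[edge[, 2L]]
  diff <- which(from != to)
  data.frame(edge = diff, parent_node = edge[diff, 1L],
             child_node = edge[diff, 2L], from = from[diff], to = to[diff],
             stringsAsFactors = FALSE)
}

#' Minimum number of independent origins of a residue
#'
#' The minimum, over all most-parsimonious reconstructions, of the number of
#' branches on which the state changes from non-`residue` to `residue`, with
#' a root reconstructed as `residue` counting as one (ancestral) origin so
#' that a residue present at any leaf always has at least one origin.
#' Computed exactly by a bi-criterion dynamic program that minimises total
#' changes first and residue gains second (lexicographically), so the value
#' is a conservative lower bound on recurrence.
#'
#' @inheritParams fitch_min_changes
#' @param residue State whose origins are counted (must be in the alphabet).
#' @return Integer gain count; 0 when no leaf carries `residue`; `NA` if all
#'   leaves are missing.
#' @export
count_independent_origins <- function(states, tree, residue, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- sort(unique(c(states[!is.na(states)], residue)))
  }
  if (!(residue %in% alphabet)) {
    stop("residue '", residue, "' not in alphabet", call. = FALSE)
  }
  ti <- .tree_index(tree)
  states <- states[match(ti$tree$tip.label, tree$tip.label)]
  possible <- .possible_states(states, alphabet)
  if (all(colSums(possible) == 0L)) return(NA_integer_)
  if (!any(states %in% residue, na.rm = TRUE)) return(0L)
  ns <- nrow(possible)
  ridx <- match(residue, alphabet)
  M <- 2^20  # lexicographic weight: changes dominate gains
  C <- matrix(0, ns, ti$nnode)
  tipC <- matrix(Inf, ns, ti$ntip)
  tipC[possible] <- 0
  tipC[, colSums(possible) == 0L] <- 0
  C[, seq_len(ti$ntip)] <- tipC
  edge <- ti$edge
  gain <- as.numeric(seq_len(ns) == ridx)
  for (i in seq_len(nrow(edge))) {
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    cc <- C[, child]
    # cost to move from parent state s to child state s':
    #   0 if s' == s, else M (one change) + 1 if s' is the residue (a gain)
    D <- cc + M + gain
    o <- order(D)[1:2]
    min1 <- D[o[1L]]; min2 <- D[o[2L]]
    excl <- rep(min1, ns); excl[o[1L]] <- min2
    C[, parent] <- C[, parent] + pmin(cc, excl)
  }
  best <- min(C[, ti$root] + gain)
  as.integer(round(best %% M))
}
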