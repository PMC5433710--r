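# Exhaustive-enumeration oracles, independent of the package's DP code.

# all rooted labelings of internal nodes (and missing leaves) are enumerated;
# returns the minimum change count and, among minimum-change labelings, the
# minimum number of residue gains (root counted as a gain when = residue)
brute_parsimony <- function(states, tree, alphabet, residue = NULL) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  states <- states[match(tr$tip.label, tree$tip.label)]
  nnode <- ntip + tr$Nnode
  fixed <- match(states, alphabet)          # NA = missing / free
  free <- c(which(is.na(fixed)), (ntip + 1L):nnode)
  ns <- length(alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), length(free))))
  lab <- matrix(rep(fixed[seq_len(nnode)], each = nrow(grid)),
                nrow = nrow(grid))
  lab[, free] <- grid
  changes <- rowSums(lab[, tr$edge[, 1L], drop = FALSE] !=
                     lab[, tr$edge[, 2L], drop = FALSE])
  mn <- min(changes)
  out <- list(min_changes = mn)
  if (!is.null(residue)) {
    ridx <- match(residue, alphabet)
    best <- lab[changes == mn, , drop = FALSE]
    gains <- rowSums(best[, tr$edge[, 1L], drop = FALSE] != ridx &
                     best[, tr$edge[, 2L], drop = FALSE] == ridx) +
      (best[, ntip + 1L] == ridx)
    out$min_origins <- min(gains)
  }
  out
}

# supremum ECDF distance by direct sweep
brute_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- abs(tr$edge.length) + 0.05
  tr
}
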