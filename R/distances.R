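#' Estimate GTR+G+I parameters for a gene alignment
#'
#' Fits the general time-reversible model with gamma rate variation (4
#' categories) and a free invariant-site proportion by maximum likelihood on
#' a neighbour-joining guide tree, once per gene; the fitted parameters are
#' shared by all pairwise distance computations for that gene.
#'
#' @param x A `codon_alignment` (nucleotide view is used).
#' @param k Number of gamma categories (default 4).
#' @return List with `Q` (lower-triangle exchangeabilities), `bf`, `shape`,
#'   `inv`, `k` and the eigen pieces of the normalised rate matrix.
#' @export
fit_gtr_gamma_inv <- function(x, k = 4L) {
  nuc <- nucleotide_matrix(x)
  pd <- phangorn::phyDat(nuc, type = "DNA")
  dm <- ape::dist.dna(ape::as.DNAbin(nuc), model = "JC69", pairwise.deletion = TRUE)
  dm[!is.finite(dm)] <- max(dm[is.finite(dm)], 0.5)
  guide <- ape::nj(dm)
  guide$edge.length[guide$edge.length < 0] <- 1e-8
  fit <- phangorn::pml(guide, pd, k = k, inv = 0.1)
  fit <- phangorn::optim.pml(fit, model = "GTR", optGamma = TRUE, optInv = TRUE,
                             optEdge = TRUE,
                             control = phangorn::pml.control(epsilon = 1e-6,
                                                            maxit = 5,
                                                            trace = 0))
  s <- matrix(0, 4, 4)
  s[lower.tri(s)] <- fit$Q
  s <- s + t(s)
  pi <- fit$bf
  Q <- s * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(Q = fit$Q, bf = pi, shape = fit$shape, inv = fit$inv, k = k,
       U = diag(1 / d) %*% e$vectors, Uinv = t(e$vectors) %*% diag(d),
       lambda = e$values)
}

# pairwise log-likelihood of distance t for a 4x4 joint pattern count matrix
.pair_loglik <- function(t, N, mod) {
  rates <- phangorn::discrete.gamma(mod$shape, mod$k) / (1 - mod$inv)
  mix <- 0
  for (r in rates) {
    P <- mod$U %*% (exp(mod$lambda * t * r) * mod$Uinv)
    P[P < 1e-12] <- 1e-12
    mix <- mix + P / mod$k
  }
  M <- (1 - mod$inv) * mix
  diag(M) <- diag(M) + mod$inv
  sum(N * log(pmax(mod$bf * M, 1e-300)))
}

#' Mean pairwise GTR+G+I distance of a gene alignment
#'
#' Model parameters are estimated once for the gene ([fit_gtr_gamma_inv()]);
#' each unordered pair's maximum-likelihood distance is then optimised under
#' those fixed parameters and the arithmetic mean over pairs is returned.
#' Distances are capped at 10 substitutions/site with a warning.
#'
#' @param x A `codon_alignment` with at least 2 sequences.
#' @param model Optional precomputed model from [fit_gtr_gamma_inv()].
#' @param cap Distance cap (substitutions/site).
#' @return List with `mean_distance`, `distances` (a `dist`), `model`.
#' @export
gene_mean_distance <- function(x, model = NULL, cap = 10) {
  n <- n_taxa(x)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(model)) model <- fit_gtr_gamma_inv(x)
  nuc <- nucleotide_matrix(x)
  bases <- c("A", "C", "G", "T")
  idx <- matrix(match(nuc, bases), nrow = n)
  D <- matrix(0, n, n)
  capped <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      if (!any(ok)) { D[i, j] <- D[j, i] <- NA; next }
      N <- matrix(0, 4, 4)
      tab <- table(factor(idx[i, ok], levels = 1:4),
                   factor(idx[j, ok], levels = 1:4))
      N[] <- tab
      if (sum(N) - sum(diag(N)) == 0) { d <- 0 } else {
        opt <- stats::optimize(function(t) -.pair_loglik(t, N, model),
                               interval = c(1e-8, cap), tol = 1e-6)
        d <- opt$minimum
        if (d > cap * 0.999) { d <- cap; capped <- TRUE }
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (capped) warning("some pairwise distances hit the cap of ", cap,
                      " substitutions/site", call. = FALSE)
  dd <- stats::as.dist(D)
  list(mean_distance = mean(dd, na.rm = TRUE), distances = dd, model = model)
}

#' Gene-size correlations with distance and negative selection
#'
#' Pearson correlations (as r-squared with two-sided p-values) of gene length
#' against mean model-corrected distance and against the fraction of codons
#' flagged negatively selected.
#'
#' @param summaries data.frame with columns `length_bp`, `mean_distance`,
#'   `frac_negative` (one row per gene).
#' @return List of two [htest-like] lists: `size_vs_distance` and
#'   `size_vs_frac_negative`, each with `r_squared`, `p_value`, `estimate`.
#' @export
size_distance_correlation <- function(summaries) {
  one <- function(y) {
    x <- summaries$length_bp
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(list(r_squared = 0, p_value = 1, estimate = 0))
    }
    ct <- stats::cor.test(x, y)
    list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
         estimate = unname(ct$estimate))
  }
  list(size_vs_distance = one(summaries$mean_distance),
       size_vs_frac_negative = one(summaries$frac_negative))
}
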