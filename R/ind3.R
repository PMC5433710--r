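.ind3_env <- new.env(parent = emptyenv())

#' Fixed amino-acid replacement model for site-rate estimation
#'
#' Builds the instantaneous rate matrix of the mtREV24 empirical model
#' (exchangeabilities and mitochondrial equilibrium frequencies taken from
#' phangorn's model library), normalised to one expected replacement per
#' unit branch length, together with its spectral decomposition.
#'
#' @return List with `Q` (20 x 20), `pi`, and eigen pieces `U`, `Uinv`,
#'   `lambda` such that `P(t) = U diag(exp(lambda t)) Uinv`; state order is
#'   [aa_alphabet()].
#' @export
aa_replacement_model <- function() {
  if (!is.null(.ind3_env$model)) return(.ind3_env$model)
  aas <- aa_alphabet()
  tr <- ape::read.tree(text = "(sp1:0.1,sp2:0.1);")
  dummy <- matrix(rep(aas[1:2], each = 2L), 2L,
                  dimnames = list(c("sp1", "sp2"), NULL))
  pd <- phangorn::phyDat(dummy, type = "AA")
  fit <- phangorn::pml(tr, pd, model = "mtREV24")
  lev <- attr(pd, "levels")
  s <- matrix(0, 20, 20, dimnames = list(lev, lev))
  s[lower.tri(s)] <- fit$Q
  s <- s + t(s)
  pi <- fit$bf
  names(pi) <- lev
  Q <- s * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)      # mean rate 1
  Q <- Q[aas, aas]
  pi <- pi[aas]
  # symmetrise for a stable eigendecomposition
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / d) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(d)
  model <- list(Q = Q, pi = pi, U = U, Uinv = Uinv, lambda = e$values)
  assign("model", model, envir = .ind3_env)
  model
}

.aa_transition_matrix <- function(model, t) {
  P <- model$U %*% (exp(model$lambda * t) * model$Uinv)
  P[P < 0] <- 0
  P
}

# per-site log-likelihood under rate multiplier r (Felsenstein pruning with
# per-node rescaling); tipL is a list of 20 x nsites likelihood matrices
.prune_loglik <- function(tipL, ti, model, r) {
  nsites <- ncol(tipL[[1L]])
  L <- vector("list", ti$nnode)
  L[seq_len(ti$ntip)] <- tipL
  scale_log <- numeric(nsites)
  edge <- ti$edge
  el <- ti$edge_length
  for (i in seq_len(nrow(edge))) {
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    P <- .aa_transition_matrix(model, el[i] * r)
    contrib <- P %*% L[[child]]
    if (is.null(L[[parent]])) L[[parent]] <- contrib
    else L[[parent]] <- L[[parent]] * contrib
    # rescale whenever a parent is touched; max.col on the transpose gets
    # per-site maxima at C speed
    m <- L[[parent]]
    mx <- m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
    mx[mx == 0] <- 1
    L[[parent]] <- m / rep(mx, each = 20L)
    scale_log <- scale_log + log(mx)
  }
  lik <- as.vector(model$pi %*% L[[ti$root]])
  log(pmax(lik, 1e-300)) + scale_log
}

#' Empirical-Bayes standardized evolutionary rates per residue column (Ind3)
#'
#' Estimates a relative substitution rate for every aligned amino-acid column
#' under a discrete-gamma prior (`k` equal-probability categories) and the
#' fixed mitochondrial replacement model, with the gamma shape chosen by
#' maximising the sum of per-site marginal log-likelihoods over the tree.
#' The posterior-mean rate of each site is then standardized to mean 0 and
#' standard deviation 1 over the included columns, so conserved sites score
#' negative and variable sites positive.
#'
#' @param aa Character matrix of residues, rows in `tree$tip.label` order
#'   (see [translate_alignment()] and [bind_tree_alignment()]); non-residue
#'   cells are missing data.
#' @param tree Rooted tree with branch lengths (total length must be > 0).
#' @param k Number of gamma rate categories (default 16).
#' @param alpha Optional fixed gamma shape; estimated when `NULL`.
#' @return List with `standardized` (per-column Ind3), `posterior_mean`
#'   (raw rates), `alpha`, and `loglik`.
#' @export
ind3 <- function(aa, tree, k = 16L, alpha = NULL) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0) {
    stop("tree has zero total length; rates are unidentifiable", call. = FALSE)
  }
  ti <- .tree_index(tree)
  aa <- aa[match(ti$tree$tip.label, rownames(aa)), , drop = FALSE]
  model <- aa_replacement_model()
  aas <- aa_alphabet()
  nsites <- ncol(aa)
  tipL <- lapply(seq_len(ti$ntip), function(i) {
    m <- matrix(0, 20L, nsites)
    idx <- match(aa[i, ], aas)
    miss <- is.na(idx)
    m[cbind(idx[!miss], which(!miss))] <- 1
    m[, miss] <- 1
    m
  })
  cat_loglik <- function(a) {
    r <- phangorn::discrete.gamma(a, k)
    vapply(r, function(ri) .prune_loglik(tipL, ti, model, ri),
           numeric(nsites))
  }
  site_marginal <- function(ll) {
    mx <- apply(ll, 1L, max)
    mx + log(rowMeans(exp(ll - mx)))
  }
  if (is.null(alpha)) {
    opt <- stats::optimize(function(a) -sum(site_marginal(cat_loglik(a))),
                           interval = c(0.05, 20), tol = 0.01)
    alpha <- opt$minimum
  }
  ll <- cat_loglik(alpha)            # nsites x k
  r <- phangorn::discrete.gamma(alpha, k)
  mx <- apply(ll, 1L, max)
  w <- exp(ll - mx)
  post <- as.vector((w %*% r) / rowSums(w))
  std <- (post - mean(post)) / stats::sd(post)
  list(standardized = std, posterior_mean = post, alpha = alpha,
       loglik = sum(site_marginal(ll)))
}
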