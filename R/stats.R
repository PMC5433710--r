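#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical distribution
#' functions; the p-value uses the asymptotic Kolmogorov distribution with
#' the standard small-sample correction. Because the conservation indices
#' are discrete, ties are frequent and the asymptotic p is approximate; the
#' permutation option resamples group labels to get an exact-style p.
#'
#' @param x,y Non-empty numeric samples.
#' @param permutation Number of label permutations (0 = asymptotic p only).
#' @param seed Seed used for the permutation p (ignored otherwise).
#' @return List (class `mito_test`) with `statistic`, `p_value`, optional
#'   `p_permutation`, `n1`, `n2`, `method`.
#' @export
ks_two_sample <- function(x, y, permutation = 0L, seed = 1L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  out <- list(statistic = unname(kt$statistic), p_value = kt$p.value,
              n1 = length(x), n2 = length(y),
              method = "two-sample Kolmogorov-Smirnov")
  if (permutation > 0L) {
    pooled <- c(x, y)
    n1 <- length(x)
    obs <- out$statistic
    old <- .save_seed()
    set.seed(seed)
    cnt <- 0L
    for (i in seq_len(permutation)) {
      idx <- sample.int(length(pooled), n1)
      d <- suppressWarnings(stats::ks.test(pooled[idx], pooled[-idx],
                                           exact = FALSE)$statistic)
      if (d >= obs - 1e-12) cnt <- cnt + 1L
    }
    .restore_seed(old)
    out$p_permutation <- (cnt + 1) / (permutation + 1)
  }
  class(out) <- "mito_test"
  out
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Two-sample t test
#'
#' Student's pooled-variance t by default (`df = n1 + n2 - 2`); Welch's
#' unequal-variance form as an option.
#'
#' @param x,y Numeric samples with `length(x) + length(y) >= 3`.
#' @param pooled Use the pooled-variance (Student) form (default `TRUE`).
#' @return List (class `mito_test`) with `statistic`, `df`, `p_value`,
#'   `n1`, `n2`, `method`.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  if (length(x) + length(y) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (pooled && stats::var(c(x - mean(x), y - mean(y))) == 0) {
    stop("zero pooled variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n1 = length(x), n2 = length(y),
                 method = if (pooled) "Student t (pooled)" else "Welch t"),
            class = "mito_test")
}

#' Chi-squared goodness of fit to an exponential distribution
#'
#' The rate is fitted by maximum likelihood (1/mean); observations are
#' binned into `n_bins` equal-width bins over `[0, max]` with an open tail
#' bin, and the chi-squared statistic compares observed with fitted expected
#' counts on `df = n_bins - 2` (one parameter estimated).
#'
#' @param values Non-negative sample (shift transformed indices to positive
#'   support before calling).
#' @param n_bins Number of bins (>= 3).
#' @return List (class `mito_test`) with `statistic`, `df`, `p_value`,
#'   `rate`, `n`, `method`.
#' @export
exponential_gof <- function(values, n_bins) {
  if (n_bins < 3L) stop("n_bins must be >= 3", call. = FALSE)
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  n <- length(values)
  rate <- 1 / mean(values)
  edges <- seq(0, max(values), length.out = n_bins)
  # n_bins - 1 closed bins plus an open tail above the last finite edge
  breaks <- c(edges, Inf)
  obs <- as.vector(table(cut(values, breaks, include.lowest = TRUE,
                             right = FALSE)))
  pr <- diff(stats::pexp(breaks, rate))
  exp_cnt <- n * pr
  stat <- sum((obs - exp_cnt)^2 / exp_cnt)
  df <- n_bins - 2L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 rate = rate, n = n,
                 method = "chi-squared exponential goodness of fit"),
            class = "mito_test")
}

#' @export
print.mito_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4),
      if (!is.null(x$df)) paste0(", df = ", x$df),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Shift a standardized index to positive support
#'
#' @param x Numeric vector.
#' @return `x - min(x)`, so the smallest value maps to 0.
#' @export
shift_positive <- function(x) x - min(x, na.rm = TRUE)
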