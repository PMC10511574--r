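#' Exact and rank-based hypothesis tests
#'
#' Self-contained implementations of the tests used throughout the pipeline:
#' Fisher's exact test on a 2x2 table, a Monte Carlo Freeman-Halton style
#' exact test for r x c tables, and the Mann-Whitney U, Wilcoxon signed-rank
#' and Kruskal-Wallis rank tests. All return a \code{reflux_test} object with
#' fields \code{statistic}, \code{p_value}, \code{method} and \code{n}.
#'
#' The two-sided Fisher p-value follows the point-probability convention:
#' the sum, over all tables with the observed margins, of hypergeometric
#' point probabilities no larger than the observed one (relative tolerance
#' 1e-7 for ties). A table with an empty row or column margin carries no
#' information and yields p = 1.
#'
#' @param table a 2x2 matrix or a length-4 vector \code{c(a, b, c, d)} read
#'   row-wise: a = (symptom+, reflux+), b = (symptom+, reflux-),
#'   c = (symptom-, reflux+), d = (symptom-, reflux-).
#' @param alternative \code{"two_sided"} (default), \code{"greater"} (positive
#'   association, large \code{a}) or \code{"less"}.
#' @return a \code{reflux_test} list.
#' @examples
#' fisher_exact_2x2(c(6, 0, 4, 10))   # p = 420/38760
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as_2x2(table)
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  N <- a + b + cc + d
  r1 <- a + b; c1 <- a + cc
  or <- (a * d) / (b * cc)
  res <- function(p) new_reflux_test(
    statistic = or, p_value = min(1, p),
    method = paste0("Fisher exact (", alternative, ")"), n = N)
  if (N == 0 || r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(res(1))
  lo <- max(0, r1 - (N - c1)); hi <- min(r1, c1)
  k <- lo:hi
  dk <- dhyper(k, c1, N - c1, r1)
  dobs <- dhyper(a, c1, N - c1, r1)
  p <- switch(alternative,
    two_sided = sum(dk[dk <= dobs * (1 + 1e-7)]),
    greater   = sum(dk[k >= a]),
    less      = sum(dk[k <= a]))
  res(p)
}

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == 2L))
    table <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  }
  stopifnot(length(table) == 4L, all(!is.na(table)), all(table >= 0))
  as.numeric(table)
}

new_reflux_test <- function(statistic, p_value, method, n, ...) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method, n = n, ...),
            class = "reflux_test")
}

#' @export
print.reflux_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value, digits = 4),
      " n =", paste(x$n, collapse = "/"), "\n")
  invisible(x)
}

#' Monte Carlo exact test for an r x c contingency table
#'
#' Freeman-Halton style generalisation of Fisher's exact test: the p-value is
#' the probability, under fixed margins, of a table whose multivariate
#' hypergeometric point probability is no larger than the observed one,
#' estimated by margin-preserving resampling (\code{r2dtable}). The +1/+1
#' adjusted estimator guarantees p > 0. Degenerate margins (fewer than two
#' non-empty rows or columns) give p = 1.
#'
#' @param table integer matrix, at least 2x2.
#' @param n_resamples number of resampled tables.
#' @param seed optional integer; fixes the resampling stream without touching
#'   the caller's RNG.
#' @return a \code{reflux_test} with an extra \code{mc_se} field (Monte Carlo
#'   standard error of the p estimate).
#' @export
exact_rxc_test <- function(table, n_resamples = 4000, seed = NULL) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be at least 2x2")
  if (any(is.na(table)) || any(table < 0)) stop("counts must be non-negative")
  r <- rowSums(table); cl <- colSums(table); N <- sum(table)
  if (sum(r > 0) < 2L || sum(cl > 0) < 2L || N == 0) {
    return(new_reflux_test(NA_real_, 1, "Monte Carlo exact r x c", N, mc_se = 0))
  }
  lp <- function(tab) -sum(lgamma(tab + 1))  # margins fixed: constant dropped
  obs <- lp(table)
  sims <- with_seed(seed, r2dtable(n_resamples, r, cl))
  lps <- vapply(sims, lp, numeric(1))
  hits <- sum(lps <= obs + 1e-7)
  p <- (1 + hits) / (n_resamples + 1)
  new_reflux_test(statistic = obs, p_value = p,
                  method = "Monte Carlo exact r x c", n = N,
                  mc_se = sqrt(p * (1 - p) / n_resamples))
}

#' Rank tests
#'
#' Mann-Whitney U (two independent samples), Wilcoxon signed-rank (paired,
#' zero differences dropped) and Kruskal-Wallis (k groups). Ties take average
#' ranks; no continuity correction. When the combined sample size is at most
#' \code{exact_limit} (default 10) the two-sample and paired tests switch to
#' exact permutation enumeration (two-sided via distance of the statistic from
#' its null mean); otherwise a tie-corrected normal (or chi-square)
#' approximation is used. Data with all values tied give p = 1 with a warning.
#'
#' @param x,y numeric samples (NAs dropped).
#' @param exact_limit combined-size threshold for the exact enumeration path.
#' @return a \code{reflux_test}.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 10) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("each sample needs at least one observation")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  method <- "Mann-Whitney U"
  if (length(unique(c(x, y))) == 1L) {
    warning("all observations tied; p = 1")
    return(new_reflux_test(U, 1, method, c(n1, n2)))
  }
  if (N <= exact_limit) {
    idx <- utils::combn(N, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(new_reflux_test(U, p, paste(method, "(exact)"), c(n1, n2)))
  }
  ties <- table(r)
  sg2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - mu) / sqrt(sg2)
  new_reflux_test(U, min(1, 2 * pnorm(-abs(z))), method, c(n1, n2))
}

#' @rdname mann_whitney_u
#' @param pre,post paired numeric vectors of equal length.
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_limit = 10) {
  stopifnot(length(pre) == length(post))
  d <- pre - post
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  method <- "Wilcoxon signed-rank"
  if (n == 0L) {
    warning("all paired differences zero; p = 1")
    return(new_reflux_test(0, 1, method, 0))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.vector(signs %*% r)
    p <- mean(abs(Vs - mu) >= abs(V - mu) - 1e-9)
    return(new_reflux_test(V, p, paste(method, "(exact)"), n))
  }
  z <- (V - mu) / sqrt(sum(r^2) / 4)
  new_reflux_test(V, min(1, 2 * pnorm(-abs(z))), method, n)
}

#' @rdname mann_whitney_u
#' @param groups list of numeric vectors, one per group.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  ng <- lengths(groups)
  if (any(ng < 1L)) stop("each group needs at least one observation")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (length(unique(pooled)) == 1L) {
    warning("all observations tied; p = 1")
    return(new_reflux_test(0, 1, "Kruskal-Wallis", ng))
  }
  r <- rank(pooled)
  gid <- rep(seq_len(k), ng)
  rbar <- tapply(r, gid, mean)
  H <- 12 / (N * (N + 1)) * sum(ng * (rbar - (N + 1) / 2)^2)
  ties <- table(r)
  Ct <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / Ct
  new_reflux_test(H, pchisq(H, df = k - 1, lower.tail = FALSE),
                  "Kruskal-Wallis", ng)
}
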