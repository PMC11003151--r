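#' Hypergeometric enrichment test (upper tail)
#'
#' Probability of drawing at least `m` marked elements when `t` elements are
#' drawn without replacement from a universe of `T_` elements of which `M`
#' are marked: P(X >= m) with X ~ Hypergeometric(T_, M, t). Used for
#' super-enhancer enrichment of tissue-specific eRNAs and for
#' tissue-specific genes near tissue-specific eRNAs.
#'
#' @param T_ universe size.
#' @param M marked elements in the universe.
#' @param t draws.
#' @param m marked elements among the draws.
#' @return upper-tail p-value.
#' @export
hypergeom_enrichment <- function(T_, M, t, m) {
  if (!(M <= T_ && t <= T_ && m >= 0 && m <= min(M, t)))
    stop("inconsistent hypergeometric counts")
  stats::phyper(m - 1, M, T_ - M, t, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of the probabilities of all tables with
#' the observed margins whose point probability does not exceed that of the
#' observed table (the usual convention, pinned here so results are
#' reproducible; a small relative tolerance guards against floating-point
#' ties). Vectorized over the four cells.
#'
#' @param a,b,c,d cell counts of the table [[a, b], [c, d]].
#' @return two-sided p-value(s).
#' @export
fisher_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; c1 <- a[i] + c[i]
    if (r1 + r2 == 0) return(1)
    k <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(k, r1, r2, c1)
    pobs <- stats::dhyper(a[i], r1, r2, c1)
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }, 0)
}

#' One-sided (enrichment) Fisher p-value for a 2x2 table
#'
#' Upper-tail probability of observing at least `a` foreground successes
#' given the table margins; equivalent to the hypergeometric upper tail.
#'
#' @param a,b foreground hits / foreground misses.
#' @param c,d background hits / background misses.
#' @return one-sided p-value(s).
#' @export
fisher_one_sided <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control: q_i = min over j >= i of
#' m * p_(j) / j, mapped back to the input order. Thin wrapper over
#' \code{stats::p.adjust} so the convention is fixed in one place.
#'
#' @param p numeric p-values in [0, 1] (`NA` allowed, passed through).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman correlation with t-approximation p-values over feature pairs
#'
#' Ranks (average ranks for ties) are correlated with Pearson's formula; the
#' p-value uses the t approximation with n - 2 degrees of freedom. Pairs
#' involving a constant vector have no defined correlation and are dropped
#' with a warning. q-values are Benjamini-Hochberg within the supplied batch,
#' i.e. the caller decides the multiple-testing family.
#'
#' @param mat_a,mat_b features x samples matrices sharing column order.
#' @param pairs data.frame with columns `a` (row id in `mat_a`) and `b`
#'   (row id in `mat_b`).
#' @return data.frame (a, b, rho, p, q) for the retained pairs.
#' @export
spearman_fdr <- function(mat_a, mat_b, pairs) {
  if (ncol(mat_a) != ncol(mat_b)) stop("sample columns differ")
  n <- ncol(mat_a)
  ra <- t(apply(mat_a, 1, rank))
  rb <- t(apply(mat_b, 1, rank))
  sda <- apply(ra, 1, stats::sd)
  sdb <- apply(rb, 1, stats::sd)
  const <- sda[pairs$a] == 0 | sdb[pairs$b] == 0
  if (any(const)) {
    warning(sum(const), " pair(s) dropped: constant expression vector")
    pairs <- pairs[!const, , drop = FALSE]
  }
  if (nrow(pairs) == 0)
    return(data.frame(a = character(0), b = character(0), rho = numeric(0),
                      p = numeric(0), q = numeric(0)))
  za <- (ra - rowMeans(ra)) / apply(ra, 1, stats::sd)
  zb <- (rb - rowMeans(rb)) / apply(rb, 1, stats::sd)
  rho <- rowSums(za[pairs$a, , drop = FALSE] *
                 zb[pairs$b, , drop = FALSE]) / (n - 1)
  rho <- pmin(1, pmax(-1, rho))
  tt <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) == 1] <- 0
  data.frame(a = pairs$a, b = pairs$b, rho = rho, p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE)
}
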