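# Dosage-expression trend statistics and contiguous deregulated-gene
# cluster analysis.

#' Bin units by altered-SNP count and tabulate deregulation
#'
#' Units (genes or regions) are assigned to ordered bins by their altered
#' SNP count; each bin records how many units it holds and how many are
#' deregulated.  Default region bins are 1-100 / 101-500 / >500 SNPs;
#' a gene-level binning usually adds a 0-SNP bin (most CN+ genes sit
#' between two altered SNPs and have none of their own).
#'
#' @param snp_counts integer per unit.
#' @param deregulated logical per unit.
#' @param breaks increasing bin edges as for [cut] (right-closed), default
#'   `c(0, 100, 500, Inf)`.
#' @return data.frame of class `trend_table` (bin, score, n, k, percent)
#'   with the unit-level score/outcome vectors kept as attributes for the
#'   trend test.  Empty bins are retained with n = 0.
#' @export
bin_trend_table <- function(snp_counts, deregulated,
                            breaks = c(0, 100, 500, Inf)) {
  stopifnot(length(snp_counts) == length(deregulated),
            all(diff(breaks) > 0))
  f <- cut(snp_counts, breaks, include.lowest = TRUE)
  score <- as.integer(f)
  tab <- data.frame(bin = levels(f), score = seq_along(levels(f)),
                    n = as.integer(table(f)),
                    k = as.integer(tapply(as.logical(deregulated), f, sum,
                                          default = 0L)),
                    stringsAsFactors = FALSE)
  tab$percent <- ifelse(tab$n > 0, 100 * tab$k / tab$n, NA_real_)
  attr(tab, "unit_score") <- score
  attr(tab, "unit_outcome") <- as.integer(deregulated)
  class(tab) <- c("trend_table", "data.frame")
  tab
}

#' Linear-by-linear (Mantel-Haenszel) association test for a trend table
#'
#' M2 = (N - 1) r^2 with r the Pearson correlation between the integer bin
#' score and the binary outcome over all N units; p from the df = 1
#' chi-square upper tail.  Invariant under affine rescaling of the scores.
#'
#' @param tab a `trend_table` from [bin_trend_table].
#' @return list: m2, p, r, n.  NA when scores or outcomes have zero
#'   variance (e.g. all units in one bin).
#' @export
linear_by_linear_test <- function(tab) {
  s <- attr(tab, "unit_score"); y <- attr(tab, "unit_outcome")
  N <- length(s)
  if (N < 2 || stats::sd(s) == 0 || stats::sd(y) == 0)
    return(list(m2 = NA_real_, p = NA_real_, r = NA_real_, n = N))
  r <- stats::cor(s, y)
  m2 <- (N - 1) * r^2
  list(m2 = m2, p = stats::pchisq(m2, 1, lower.tail = FALSE), r = r, n = N)
}

#' Spearman trend of downregulation against altered-SNP count
#'
#' Unit-level Spearman rank correlation between the altered SNP count and
#' the downregulation indicator (two-sided); a bin-level correlation of bin
#' rank vs downregulated fraction is also reported when >= 3 bins have data.
#'
#' @param snp_counts integer per unit.
#' @param down logical per unit (downregulated).
#' @param breaks bin edges for the bin-level summary.
#' @return list: rho, p (unit level), bin_rho (bin-level, NA when < 3
#'   informative bins), table (the per-bin fractions).
#' @export
downregulation_trend <- function(snp_counts, down,
                                 breaks = c(0, 100, 500, Inf)) {
  down <- as.logical(down)
  if (stats::sd(snp_counts) == 0 || stats::sd(down) == 0)
    return(list(rho = NA_real_, p = NA_real_, bin_rho = NA_real_,
                table = NULL))
  ct <- suppressWarnings(
    stats::cor.test(snp_counts, as.numeric(down), method = "spearman",
                    exact = FALSE))
  tab <- bin_trend_table(snp_counts, down, breaks)
  nz <- tab$n > 0
  bin_rho <- if (sum(nz) < 3) NA_real_
  else if (stats::sd(tab$percent[nz]) == 0) 0
  else stats::cor(tab$score[nz], tab$percent[nz], method = "spearman")
  list(rho = unname(ct$estimate), p = ct$p.value, bin_rho = bin_rho,
       table = tab)
}

#' Find clusters of contiguous deregulated genes
#'
#' Genes must be ordered by genomic position.  A cluster is a maximal run of
#' >= 2 consecutive genes that are up- or down-regulated (runs may mix
#' directions).  The clustered fraction is the share of deregulated genes
#' that lie inside such runs.
#'
#' @param status character per gene in {"up", "down", "unchanged"}.
#' @return list of class `cluster_report`: runs (data.frame start, end,
#'   length by gene index), n_deregulated, clustered, clustered_fraction
#'   (NA when there are no deregulated genes or < 2 genes).
#' @export
find_gene_clusters <- function(status) {
  stopifnot(all(status %in% c("up", "down", "unchanged")))
  n <- length(status)
  dereg <- status != "unchanged"
  if (n < 2)
    return(structure(list(runs = data.frame(start = integer(),
                                            end = integer(),
                                            length = integer()),
                          n_deregulated = sum(dereg), clustered = 0L,
                          clustered_fraction = NA_real_),
                     class = "cluster_report"))
  r <- rle(dereg)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2
  runs <- data.frame(start = starts[keep], end = ends[keep],
                     length = r$lengths[keep])
  clustered <- sum(runs$length)
  nd <- sum(dereg)
  structure(list(runs = runs, n_deregulated = nd, clustered = clustered,
                 clustered_fraction = if (nd > 0) clustered / nd else
                   NA_real_),
            class = "cluster_report")
}

#' Test clustering of deregulated genes against a random arrangement
#'
#' The expected number of clustered deregulated genes under random
#' placement is estimated by Monte-Carlo permutation of the statuses over
#' the gene positions (preserving the status counts); a goodness-of-fit
#' chi-square compares the observed clustered/unclustered split with the
#' permutation expectation.  When an expected cell is below 1 the
#' Monte-Carlo tail probability is reported as p instead.
#'
#' @param status ordered statuses (as in [find_gene_clusters]).
#' @param n_monte_carlo permutations (default 5000).
#' @param seed RNG seed.
#' @return list: observed, expected, chi2, p, mc_p, n_monte_carlo, seed.
#' @export
cluster_randomness_test <- function(status, n_monte_carlo = 5000,
                                    seed = 1L) {
  rep0 <- find_gene_clusters(status)
  nd <- rep0$n_deregulated
  if (nd < 10)
    warning("fewer than 10 deregulated genes; the test has little power")
  set.seed(seed)
  perm <- vapply(seq_len(n_monte_carlo), function(i)
    find_gene_clusters(sample(status))$clustered, numeric(1))
  expd <- mean(perm)
  obs <- rep0$clustered
  mc_p <- (1 + sum(perm >= obs)) / (n_monte_carlo + 1)
  e <- c(expd, nd - expd)
  o <- c(obs, nd - obs)
  if (any(e < 1)) {
    return(list(observed = obs, expected = expd, chi2 = NA_real_,
                p = mc_p, mc_p = mc_p, n_monte_carlo = n_monte_carlo,
                seed = seed))
  }
  chi2 <- sum((o - e)^2 / e)
  list(observed = obs, expected = expd, chi2 = chi2,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE), mc_p = mc_p,
       n_monte_carlo = n_monte_carlo, seed = seed)
}
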