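# Regional enrichment statistics: continuity-corrected 2x2 chi-square with
# Fisher fallback, and the parametric gene-set (PAGE) Z score.

#' 2x2 chi-square with Yates continuity correction and Fisher fallback
#'
#' chi2 = N (|ad - bc| - correction * N/2)^2 / ((a+b)(c+d)(a+c)(b+d)),
#' p from the upper tail of the df = 1 chi-square.  When any expected count
#' is below 5 or a margin is zero, Fisher's exact test is used instead (the
#' result is flagged in `method`).
#'
#' @param a,b,c,d non-negative integer cell counts: region hit/miss,
#'   background hit/miss.
#' @param correction apply the Yates continuity correction (default TRUE).
#' @param force "auto" (default), "chisq" or "fisher".
#' @return list: chi2 (NA under Fisher), p, method, min_expected.
#' @export
two_by_two_chisq <- function(a, b, c, d, correction = TRUE,
                             force = c("auto", "chisq", "fisher")) {
  force <- match.arg(force)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  N <- a + b + c + d
  rows <- c(a + b, c + d); cols <- c(a + c, b + d)
  expected <- outer(rows, cols) / N
  min_exp <- min(expected)
  zero_margin <- any(rows == 0) || any(cols == 0)
  use_fisher <- force == "fisher" ||
    (force == "auto" && (zero_margin || min_exp < 5))
  if (use_fisher) {
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    return(list(chi2 = NA_real_, p = p, method = "fisher",
                min_expected = min_exp))
  }
  num <- abs(a * d - b * c) - if (correction) N / 2 else 0
  num <- max(num, 0)
  chi2 <- N * num^2 / (as.numeric(rows[1]) * rows[2] * cols[1] * cols[2])
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       method = if (correction) "chisq-yates" else "chisq",
       min_expected = min_exp)
}

#' Scan regions (arms or cytobands) for enrichment of hits
#'
#' For every region, the hit frequency inside is compared with the rest of
#' the genome by the Yates-corrected 2x2 chi-square ([two_by_two_chisq]);
#' a region is flagged enriched when its rate exceeds the background and
#' p < alpha.  The same code path serves SNP-level (altered SNPs) and
#' gene-level (deregulated genes) scans.
#'
#' @param region region label per unit (arm or cytoband).
#' @param hit logical per unit (altered / deregulated).
#' @param alpha flag threshold (default 0.05).
#' @param correction Yates correction (default TRUE).
#' @return data.frame: region, n, hits, percent, background_percent, chi2,
#'   p, method, enriched.  Regions with zero units are skipped; a
#'   single-region input yields NA statistics.
#' @export
regional_enrichment_scan <- function(region, hit, alpha = 0.05,
                                     correction = TRUE) {
  stopifnot(length(region) == length(hit))
  keep <- !is.na(region) & !is.na(hit)
  region <- region[keep]; hit <- as.logical(hit[keep])
  regs <- sort(unique(region))
  total_hits <- sum(hit); total <- length(hit)
  rows <- lapply(regs, function(rg) {
    inr <- region == rg
    a <- sum(hit[inr]); b <- sum(inr) - a
    c <- total_hits - a; d <- total - sum(inr) - c
    if (length(regs) < 2 || (c + d) == 0) {
      return(data.frame(region = rg, n = sum(inr), hits = a,
                        percent = 100 * a / sum(inr),
                        background_percent = NA_real_, chi2 = NA_real_,
                        p = NA_real_, method = NA_character_,
                        enriched = NA, stringsAsFactors = FALSE))
    }
    tt <- two_by_two_chisq(a, b, c, d, correction = correction)
    pct <- 100 * a / sum(inr); bg <- 100 * c / (c + d)
    data.frame(region = rg, n = sum(inr), hits = a, percent = pct,
               background_percent = bg, chi2 = tt$chi2, p = tt$p,
               method = tt$method,
               enriched = !is.na(tt$p) && pct > bg && tt$p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parametric gene-set enrichment (PAGE) Z scores per region
#'
#' mu and delta are the mean and standard deviation of the fold change over
#' *all* deregulated genes; for each region holding m >= min_m deregulated
#' genes with mean fold change Sm, Z = (Sm - mu) * sqrt(m) / delta with a
#' two-tailed normal p.  Fold changes are used on the signed log2 scale by
#' default so up- and down-regulation are symmetric (ratios 1.5 and 1/1.5
#' map to +-0.585); set `scale = "ratio"` for raw ratios.
#'
#' @param fc fold change per gene (ratio scale).
#' @param deregulated logical per gene.
#' @param region region label per gene.
#' @param min_m minimum deregulated-set size (default 10; smaller sets are
#'   reported with NA Z and a reason).
#' @param scale "log2" (default) or "ratio".
#' @return data.frame: region, m, Sm, z, p, skipped.
#' @export
page_scan <- function(fc, deregulated, region, min_m = 10,
                      scale = c("log2", "ratio")) {
  scale <- match.arg(scale)
  v <- if (scale == "log2") log2(fc) else fc
  dv <- v[deregulated]
  mu <- mean(dv); delta <- stats::sd(dv)
  if (!is.finite(delta) || delta == 0)
    stop("degenerate global fold-change distribution (delta = 0)")
  regs <- sort(unique(region[deregulated]))
  rows <- lapply(regs, function(rg) {
    set <- v[deregulated & region == rg]
    m <- length(set)
    if (m < min_m)
      return(data.frame(region = rg, m = m, Sm = mean(set), z = NA_real_,
                        p = NA_real_, skipped = sprintf("m < %d", min_m),
                        stringsAsFactors = FALSE))
    z <- (mean(set) - mu) * sqrt(m) / delta
    data.frame(region = rg, m = m, Sm = mean(set), z = z,
               p = 2 * stats::pnorm(-abs(z)), skipped = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-region deregulation test against the whole region set
#'
#' Each region's deregulated/explored split is compared with the totals over
#' the whole set of regions by Yates chi-square; by default the background
#' *includes* the tested region.
#'
#' @param region_id region membership per explored gene.
#' @param deregulated logical per explored gene.
#' @param include_self keep the tested region in the background totals
#'   (default TRUE).
#' @return data.frame: region, n (explored), k (deregulated), percent,
#'   chi2, p, method.  Regions with n = 0 are reported as NA rows.
#' @export
mrr_deregulation_test <- function(region_id, deregulated,
                                  include_self = TRUE) {
  keep <- !is.na(region_id)
  region_id <- region_id[keep]; deregulated <- as.logical(deregulated[keep])
  K <- sum(deregulated); N <- length(deregulated)
  regs <- sort(unique(region_id))
  rows <- lapply(regs, function(rg) {
    inr <- region_id == rg
    n <- sum(inr); k <- sum(deregulated[inr])
    if (n == 0)
      return(data.frame(region = rg, n = 0L, k = 0L, percent = NA_real_,
                        chi2 = NA_real_, p = NA_real_,
                        method = NA_character_, stringsAsFactors = FALSE))
    if (include_self) { c0 <- K; d0 <- N - K } else {
      c0 <- K - k; d0 <- (N - n) - c0
    }
    tt <- two_by_two_chisq(k, n - k, c0, d0)
    data.frame(region = rg, n = n, k = k, percent = 100 * k / n,
               chi2 = tt$chi2, p = tt$p, method = tt$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
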