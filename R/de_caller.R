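# Deregulated-gene calling: fold-change cutoffs plus a SAM-style moderated
# statistic with permutation-estimated false discovery rate.
#
# The two-class unpaired d-statistic is d_i = (mean_T - mean_C)/(s_i + s0),
# with s_i the pooled standard error of the group difference and s0 a
# quantile (default median) of the s_i distribution.  Genes are ranked, the
# expected order statistics are estimated from label permutations, and the
# calling threshold delta is the smallest value whose estimated FDR meets
# the target.  Intensities are analysed on the log2 scale; fold changes are
# reported as plain tumour/control ratios of the raw intensities.

#' Configuration for deregulation calling
#'
#' @param fc_up up-regulation fold-change cutoff (ratio, default 1.5).
#' @param fc_down down cutoff (default 1/1.5; compared at full precision).
#' @param target_fdr target global FDR in percent (default 0).
#' @param local_fdr_max maximum local FDR in percent for a call (default 10).
#' @param n_permutations label permutations for the FDR estimate.
#' @param s0_quantile quantile of {s_i} used as the exchangeability
#'   constant s0 (default 0.5, the median).
#' @param local_fdr_window half-width of the d-space window of the local
#'   FDR estimate, as a multiple of sd(d) (default 0.25).
#' @param seed RNG seed for the permutations.
#' @return list of class `de_config`.
#' @export
de_config <- function(fc_up = 1.5, fc_down = 1 / 1.5, target_fdr = 0,
                      local_fdr_max = 10, n_permutations = 200,
                      s0_quantile = 0.5, local_fdr_window = 0.25,
                      seed = 1L) {
  stopifnot(fc_up >= 1, fc_down <= 1, fc_down > 0,
            n_permutations >= 100, s0_quantile >= 0, s0_quantile <= 1)
  structure(list(fc_up = fc_up, fc_down = fc_down, target_fdr = target_fdr,
                 local_fdr_max = local_fdr_max,
                 n_permutations = as.integer(n_permutations),
                 s0_quantile = s0_quantile,
                 local_fdr_window = local_fdr_window,
                 seed = as.integer(seed)),
            class = "de_config")
}

#' Per-gene fold change (tumour mean / control mean)
#'
#' @param expr an `expr_matrix`.
#' @return named numeric vector of ratios.
#' @export
fold_changes <- function(expr) {
  tum <- expr$roles == "tumor"
  if (!any(tum) || !any(!tum)) stop("need >= 1 tumour and >= 1 control")
  cm <- rowMeans(expr$mat[, !tum, drop = FALSE])
  if (any(cm <= 0)) stop("control mean must be positive")
  rowMeans(expr$mat[, tum, drop = FALSE]) / cm
}

sam_d <- function(x, y, s0) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  ss <- rowSums((x - m1)^2) + rowSums((y - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(d = (m1 - m2) / (s + s0), s = s, r = m1 - m2)
}

#' SAM-style moderated statistics
#'
#' @param expr an `expr_matrix` with >= 2 samples in each group.
#' @param config a [de_config].
#' @return list: `d` (named statistic per gene), `s` (pooled SE), `s0`,
#'   `r` (mean log2 difference).  Computed on log2 intensities.
#' @export
sam_statistics <- function(expr, config = de_config()) {
  tum <- expr$roles == "tumor"
  if (sum(tum) < 2 || sum(!tum) < 2)
    stop("each group needs >= 2 samples")
  lx <- log2(expr$mat)
  base <- sam_d(lx[, tum, drop = FALSE], lx[, !tum, drop = FALSE], 0)
  s0 <- as.numeric(stats::quantile(base$s, config$s0_quantile))
  res <- sam_d(lx[, tum, drop = FALSE], lx[, !tum, drop = FALSE], s0)
  list(d = res$d, s = res$s, s0 = s0, r = res$r)
}

#' Permutation FDR for the SAM statistic
#'
#' Label permutations give the expected order statistics of d and, for each
#' candidate delta, the median number of false calls; FDR = median false /
#' called.  The chosen delta is the smallest achieving the target; when no
#' delta does, the closest is returned with a warning.
#'
#' @param expr an `expr_matrix`.
#' @param stats result of [sam_statistics] on `expr`.
#' @param config a [de_config].
#' @param delta_grid optional increasing candidate deltas; default is the
#'   grid of observed |d - dbar| deviations.
#' @return list: `delta` (chosen), `fdr_table` (delta, called, median false,
#'   fdr_pct), `sign` (named vector -1/0/+1 call per gene), `q` (percent FDR
#'   at which each gene first enters the called set), `lfdr` (windowed local
#'   FDR, percent), `dbar` (expected order statistics).
#' @export
permutation_fdr <- function(expr, stats, config = de_config(),
                            delta_grid = NULL) {
  tum <- expr$roles == "tumor"
  lx <- log2(expr$mat)
  n <- ncol(lx); n1 <- sum(tum)
  m <- nrow(lx)
  set.seed(config$seed)
  B <- config$n_permutations
  perm_d <- matrix(0, m, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n1)
    g1 <- lx[, idx, drop = FALSE]
    g2 <- lx[, -idx, drop = FALSE]
    perm_d[, b] <- sam_d(g1, g2, stats$s0)$d
  }
  ord <- order(stats$d)
  ds <- stats$d[ord]
  dbar <- rowMeans(apply(perm_d, 2, sort))
  dev <- ds - dbar
  if (is.null(delta_grid))
    delta_grid <- sort(unique(c(0, abs(dev))))

  eval_delta <- function(delta) {
    up <- which(dev > delta & seq_along(dev) > which.min(abs(dbar)))
    lo <- which(-dev > delta & seq_along(dev) < which.min(abs(dbar)))
    # thresholds on the d scale implied by the called set
    cut_up <- if (length(up)) min(ds[up]) else Inf
    cut_lo <- if (length(lo)) max(ds[lo]) else -Inf
    called <- sum(ds >= cut_up) + sum(ds <= cut_lo)
    false <- apply(perm_d, 2, function(v)
      sum(v >= cut_up) + sum(v <= cut_lo))
    medf <- stats::median(false)
    c(called = called, false = medf,
      fdr = if (called == 0) 0 else 100 * medf / called,
      cut_up = cut_up, cut_lo = cut_lo)
  }
  tab <- t(vapply(delta_grid, eval_delta, numeric(5)))
  fdr_table <- data.frame(delta = delta_grid, called = tab[, "called"],
                          median_false = tab[, "false"],
                          fdr_pct = tab[, "fdr"],
                          cut_up = tab[, "cut_up"], cut_lo = tab[, "cut_lo"])
  ok <- which(fdr_table$fdr_pct <= config$target_fdr)
  if (length(ok) == 0) {
    warning("no delta achieves the target FDR; using the closest")
    chosen <- which.min(fdr_table$fdr_pct - config$target_fdr)
  } else chosen <- ok[1]
  delta <- fdr_table$delta[chosen]
  cu <- fdr_table$cut_up[chosen]; cl <- fdr_table$cut_lo[chosen]
  sgn <- ifelse(stats$d >= cu, 1L, ifelse(stats$d <= cl, -1L, 0L))
  names(sgn) <- names(stats$d)

  # q per gene: best achievable FDR among deltas at which the gene is called
  q <- rep(NA_real_, m)
  names(q) <- names(stats$d)
  absdev <- abs(dev)                     # in sorted order
  for (i in seq_len(m)) {
    at <- which(delta_grid < absdev[i])
    q[ord[i]] <- if (length(at)) min(fdr_table$fdr_pct[at]) else
      fdr_table$fdr_pct[1]
  }

  # windowed local FDR: expected null count / observed count around d_i
  w <- config$local_fdr_window * stats::sd(stats$d)
  lfdr <- vapply(stats$d, function(di) {
    obs <- sum(abs(stats$d - di) <= w)
    nul <- sum(abs(perm_d - di) <= w) / B
    100 * min(1, nul / max(obs, 1))
  }, numeric(1))

  list(delta = delta, fdr_table = fdr_table, sign = sgn, q = q,
       lfdr = lfdr, dbar = dbar)
}

#' Combine fold change and SAM calls into gene statuses
#'
#' A gene is "up" only if its fold change reaches the up cutoff *and* the
#' SAM procedure called it positive at the chosen delta with acceptable
#' local FDR; "down" symmetrically; otherwise "unchanged".  Genes passing
#' the fold-change filter but not the delta threshold stay unchanged.
#'
#' @param fc fold changes ([fold_changes]).
#' @param fdr result of [permutation_fdr].
#' @param config a [de_config].
#' @return data.frame of class `de_calls`: gene_id, fc, d, q, lfdr, status.
#' @export
call_deregulated <- function(fc, fdr, config = de_config()) {
  ok_lfdr <- fdr$lfdr < config$local_fdr_max
  status <- rep("unchanged", length(fc))
  status[fc >= config$fc_up & fdr$sign > 0 & ok_lfdr] <- "up"
  status[fc <= config$fc_down & fdr$sign < 0 & ok_lfdr] <- "down"
  res <- data.frame(gene_id = names(fc), fc = unname(fc),
                    q = unname(fdr$q), lfdr = unname(fdr$lfdr),
                    status = status, stringsAsFactors = FALSE)
  class(res) <- c("de_calls", "data.frame")
  res
}

#' One-call deregulation analysis of an expression matrix
#'
#' Runs [fold_changes], [sam_statistics], [permutation_fdr] and
#' [call_deregulated] in sequence.
#'
#' @param expr an `expr_matrix`.
#' @param config a [de_config].
#' @return `de_calls` data.frame (gene_id, fc, d, q, lfdr, status) with the
#'   chosen delta and s0 as attributes.
#' @export
de_call <- function(expr, config = de_config()) {
  fc <- fold_changes(expr)
  st <- sam_statistics(expr, config)
  fdr <- permutation_fdr(expr, st, config)
  res <- call_deregulated(fc, fdr, config)
  res$d <- unname(st$d)
  res <- res[, c("gene_id", "fc", "d", "q", "lfdr", "status")]
  attr(res, "delta") <- fdr$delta
  attr(res, "s0") <- st$s0
  class(res) <- c("de_calls", "data.frame")
  res
}
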