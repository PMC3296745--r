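# Minimal recurrent regions: n-way intersection of per-sample CNAs.

cnas_to_granges <- function(cnas) {
  GenomicRanges::GRanges(cnas$chrom,
                         IRanges::IRanges(cnas$start, cnas$end))
}

#' SNPs copy-number altered in every sample
#'
#' @param snp a [snp_data] object with >= 2 samples.
#' @return data.frame (snp_id, chrom, pos, label) for SNPs with state != 2
#'   in all samples; label is "recurrent-gained" / "recurrent-deleted" when
#'   the direction agrees across samples, else "recurrent-mixed".
#' @export
recurrent_altered_snps <- function(snp) {
  if (length(snp$samples) < 2) stop("need >= 2 samples")
  alt <- snp$states != 2L
  rec <- rowSums(alt) == ncol(alt)
  idx <- which(rec)
  lab <- vapply(idx, function(i) {
    d <- classify_snp_state(snp$states[i, ])
    if (all(d == "gain")) "recurrent-gained"
    else if (all(d == "loss")) "recurrent-deleted"
    else "recurrent-mixed"
  }, character(1))
  data.frame(snp$probes[idx, c("snp_id", "chrom", "pos")],
             label = lab, row.names = NULL, stringsAsFactors = FALSE)
}

#' Find minimal recurrent regions (MRRs)
#'
#' An MRR is a maximal interval contained in at least one CNA of every
#' sample (n-way interval intersection; the sample-count threshold is
#' configurable).  Direction need not agree: a region gained in some samples
#' and deleted in others is labelled "combined".  Intervals containing no
#' SNP probe are discarded; by default at least one recurrent altered SNP is
#' also required.
#'
#' @param cnas a `cna_set` covering >= 2 samples.
#' @param snp the [snp_data] the CNAs came from.
#' @param min_samples number of samples that must share the interval
#'   (default: all samples in `cnas`).
#' @param require_recurrent_snp discard intervals without a recurrent
#'   altered SNP (default TRUE).
#' @return data.frame of class `mrr_set`: mrr_id (e.g. "5-1" in genomic
#'   order per chromosome), chrom, start, end, direction
#'   (gained/deleted/combined), n_snps, recurrent_snp_count, size_kb,
#'   mean_log2 (NA without log2 ratios) and a list column `support`
#'   of per-sample supporting CNA ids.
#' @export
find_mrrs <- function(cnas, snp, min_samples = NULL,
                      require_recurrent_snp = TRUE) {
  samples <- unique(cnas$sample_id)
  if (length(samples) < 2) stop("MRR search needs CNAs from >= 2 samples")
  if (is.null(min_samples)) min_samples <- length(samples)
  chroms <- unique(c(snp$probes$chrom, cnas$chrom))
  ext <- rbind(data.frame(chrom = snp$probes$chrom, end = snp$probes$pos),
               data.frame(chrom = cnas$chrom, end = cnas$end))
  sinfo <- GenomeInfoDb::Seqinfo(
    seqnames = chroms,
    seqlengths = as.integer(tapply(ext$end, ext$chrom, max)[chroms]))
  per <- lapply(split(cnas, cnas$sample_id), function(x) {
    g <- cnas_to_granges(x)
    GenomeInfoDb::seqlevels(g) <- chroms
    GenomeInfoDb::seqinfo(g) <- sinfo
    g
  })
  cov <- Reduce(`+`, lapply(per, GenomicRanges::coverage))
  sl <- IRanges::slice(cov, lower = min_samples, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(sl)
  if (length(gr) == 0) return(empty_mrrs())

  rec <- if (length(snp$samples) >= 2) recurrent_altered_snps(snp) else
    snp$probes[0, c("snp_id", "chrom", "pos")]
  probe_gr <- GenomicRanges::GRanges(snp$probes$chrom,
                                     IRanges::IRanges(snp$probes$pos, width = 1))
  rec_gr <- GenomicRanges::GRanges(rec$chrom,
                                   IRanges::IRanges(rec$pos, width = 1))
  all_cna_gr <- cnas_to_granges(cnas)

  out <- list()
  for (i in seq_along(gr)) {
    g <- gr[i]
    n_snps <- IRanges::countOverlaps(g, probe_gr)
    if (n_snps == 0) next
    nrec <- IRanges::countOverlaps(g, rec_gr)
    if (require_recurrent_snp && nrec == 0) next
    hit <- IRanges::overlapsAny(all_cna_gr, g)
    sup <- cnas[hit, c("sample_id", "cna_id", "direction")]
    dirs <- unique(sup$direction)
    direction <- if (identical(dirs, "gain")) "gained"
      else if (identical(dirs, "loss")) "deleted" else "combined"
    st <- GenomicRanges::start(g); en <- GenomicRanges::end(g)
    ml <- NA_real_
    if (!is.null(snp$log2_ratio)) {
      inside <- snp$probes$chrom == as.character(GenomicRanges::seqnames(g)) &
        snp$probes$pos >= st & snp$probes$pos <= en
      ml <- mean(snp$log2_ratio[inside, , drop = FALSE])
    }
    row <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                      start = st, end = en, direction = direction,
                      n_snps = n_snps, recurrent_snp_count = nrec,
                      size_kb = (en - st + 1) / 1000, mean_log2 = ml,
                      stringsAsFactors = FALSE)
    row$support <- list(sup)
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0) return(empty_mrrs())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  k <- stats::ave(seq_len(nrow(res)), res$chrom, FUN = seq_along)
  res <- cbind(mrr_id = sprintf("%s-%d", chrom_core(res$chrom), k), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("mrr_set", "data.frame")
  res
}

empty_mrrs <- function() {
  res <- data.frame(mrr_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    direction = character(), n_snps = integer(),
                    recurrent_snp_count = integer(), size_kb = numeric(),
                    mean_log2 = numeric(), support = I(list()),
                    stringsAsFactors = FALSE)
  class(res) <- c("mrr_set", "data.frame")
  res
}

#' Per-MRR summary table with a location test of member log2 ratios
#'
#' For each MRR: size (kb), SNP count, mean log2 ratio pooled over member
#' SNPs x samples, and a one-sample t-test of those log2 ratios against 0
#' reported as -log10(p).  Zero-variance (degenerate) inputs are flagged and
#' reported with p = 1.
#'
#' @param mrrs an `mrr_set`.
#' @param snp the [snp_data] (log2 ratios optional).
#' @return data.frame: mrr_id, size_kb, n_snps, recurrent_snp_count,
#'   mean_log2, neg_log10_p, degenerate.
#' @export
summarize_mrr <- function(mrrs, snp) {
  have_lr <- !is.null(snp$log2_ratio)
  rows <- lapply(seq_len(nrow(mrrs)), function(i) {
    ml <- NA_real_; nlp <- NA_real_; degen <- FALSE
    if (have_lr) {
      inside <- snp$probes$chrom == mrrs$chrom[i] &
        snp$probes$pos >= mrrs$start[i] & snp$probes$pos <= mrrs$end[i]
      v <- as.vector(snp$log2_ratio[inside, , drop = FALSE])
      ml <- mean(v)
      if (length(v) >= 2 && stats::sd(v) > 0) {
        nlp <- -log10(stats::t.test(v, mu = 0)$p.value)
      } else {
        degen <- TRUE
        nlp <- 0                         # p = 1
      }
    }
    data.frame(mrr_id = mrrs$mrr_id[i], size_kb = mrrs$size_kb[i],
               n_snps = mrrs$n_snps[i],
               recurrent_snp_count = mrrs$recurrent_snp_count[i],
               mean_log2 = ml, neg_log10_p = nlp, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
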