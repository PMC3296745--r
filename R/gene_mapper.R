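# Gene-to-dosage mapping and the dosage/expression accounting table.

#' Map genes to CNAs and MRRs
#'
#' A gene is CN-altered in a sample when its span intersects any CNA of that
#' sample (any overlap, not containment: partially covered genes count).
#' `altered_snps` counts, per sample, the altered SNPs whose position lies
#' inside the gene span — genes lying between two altered SNPs inside a CNA
#' have a count of 0 yet are still CN+.  If a gene overlaps CNAs of both
#' directions in one sample, the direction of the largest overlap wins.
#'
#' @param genes gene annotation data.frame ([read_gene_annotation]).
#' @param cnas a `cna_set`.
#' @param snp the [snp_data].
#' @param mrrs optional `mrr_set` for region membership.
#' @return list of class `gene_dosage`: `calls` (long data.frame gene_id,
#'   sample_id, cn_class, altered_snps, cna_ids), `genes` (gene_id,
#'   recurrent flag = CN-altered in all samples, mrr_ids list column,
#'   recurrent_snps count).  Genes on chromosomes absent from the probe map
#'   are dropped with a warning.
#' @export
map_genes <- function(genes, cnas, snp, mrrs = NULL) {
  known <- unique(snp$probes$chrom)
  bad <- !(genes$chrom %in% known)
  if (any(bad)) {
    warning(sprintf("%d gene(s) on chromosomes without probes excluded",
                    sum(bad)))
    genes <- genes[!bad, , drop = FALSE]
  }
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  samples <- snp$samples
  calls <- list()
  for (s in samples) {
    cs <- cnas[cnas$sample_id == s, , drop = FALSE]
    cn_class <- rep("normal", nrow(genes))
    cna_ids <- vector("list", nrow(genes))
    if (nrow(cs) > 0) {
      cgr <- cnas_to_granges(cs)
      ov <- GenomicRanges::findOverlaps(gene_gr, cgr)
      if (length(ov) > 0) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        w <- IRanges::width(IRanges::pintersect(
          IRanges::ranges(gene_gr)[qh], IRanges::ranges(cgr)[sh]))
        for (g in unique(qh)) {
          j <- which(qh == g)
          cna_ids[[g]] <- cs$cna_id[sh[j]]
          best <- j[which.max(w[j])]
          cn_class[g] <- cs$direction[sh[best]]
        }
      }
    }
    alt_pos <- snp$probes[snp$states[, s] != 2L, c("chrom", "pos")]
    nalt <- if (nrow(alt_pos) > 0) {
      agr <- GenomicRanges::GRanges(alt_pos$chrom,
                                    IRanges::IRanges(alt_pos$pos, width = 1))
      GenomicRanges::countOverlaps(gene_gr, agr)
    } else rep(0L, nrow(genes))
    df <- data.frame(gene_id = genes$gene_id, sample_id = s,
                     cn_class = cn_class, altered_snps = nalt,
                     stringsAsFactors = FALSE)
    df$cna_ids <- cna_ids
    calls[[s]] <- df
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  rec_tab <- tapply(calls$cn_class != "normal", calls$gene_id, all)
  rec_snps <- rep(0L, nrow(genes))
  if (length(samples) >= 2) {
    rec <- recurrent_altered_snps(snp)
    if (nrow(rec) > 0) {
      rgr <- GenomicRanges::GRanges(rec$chrom,
                                    IRanges::IRanges(rec$pos, width = 1))
      rec_snps <- GenomicRanges::countOverlaps(gene_gr, rgr)
    }
  }
  mrr_ids <- vector("list", nrow(genes))
  if (!is.null(mrrs) && nrow(mrrs) > 0) {
    mgr <- cnas_to_granges(mrrs)
    ov <- GenomicRanges::findOverlaps(gene_gr, mgr)
    for (g in unique(S4Vectors::queryHits(ov)))
      mrr_ids[[g]] <- mrrs$mrr_id[
        S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == g]]
  }
  gene_tab <- data.frame(gene_id = genes$gene_id,
                         chrom = genes$chrom, start = genes$start,
                         end = genes$end, explored = genes$explored,
                         recurrent = as.logical(rec_tab[genes$gene_id]),
                         recurrent_snps = rec_snps,
                         stringsAsFactors = FALSE)
  gene_tab$mrr_ids <- mrr_ids
  structure(list(calls = calls, genes = gene_tab), class = "gene_dosage")
}

#' Average/percent arithmetic for the dosage-expression accounting table
#'
#' Given per-sample counts of CN-altered (CN+) and non-altered (CN-) genes
#' explored for expression and the deregulated (EX+) counts among them,
#' appends an average row whose percentages are ratios of the *unrounded*
#' mean counts (so e.g. mean EX+ / mean n, not the mean of per-sample
#' percentages), plus per-row percentages.
#'
#' @param per_sample data.frame with columns sample_id, genes_cn (potential
#'   CN+ genes), cnpos_n, cnpos_ex, cnneg_n, cnneg_ex, all_ex.
#' @param recurrent optional named list (n, ex, rest_n, rest_ex, all_n,
#'   all_ex) describing the recurrent-gene row.
#' @return data.frame with percentage columns and an "average" row (and a
#'   "recurrent" row when supplied).
#' @export
dosage_table_from_counts <- function(per_sample, recurrent = NULL) {
  df <- per_sample
  avg <- data.frame(sample_id = "average",
                    t(colMeans(df[, -1, drop = FALSE])))
  names(avg) <- names(df)
  df <- rbind(df, avg)
  df$cnpos_pct <- 100 * df$cnpos_ex / df$cnpos_n
  df$cnneg_pct <- 100 * df$cnneg_ex / df$cnneg_n
  df$all_n <- df$cnpos_n + df$cnneg_n
  df$all_pct <- 100 * df$all_ex / df$all_n
  df$cnpos_pct[df$cnpos_n == 0] <- NA_real_
  df$cnneg_pct[df$cnneg_n == 0] <- NA_real_
  if (!is.null(recurrent)) {
    rec <- data.frame(sample_id = "recurrent", genes_cn = NA_real_,
                      cnpos_n = recurrent$n, cnpos_ex = recurrent$ex,
                      cnneg_n = recurrent$rest_n, cnneg_ex = recurrent$rest_ex,
                      all_ex = recurrent$all_ex,
                      cnpos_pct = 100 * recurrent$ex / recurrent$n,
                      cnneg_pct = 100 * recurrent$rest_ex / recurrent$rest_n,
                      all_n = recurrent$all_n,
                      all_pct = 100 * recurrent$all_ex / recurrent$all_n)
    df <- rbind(df, rec)
  }
  rownames(df) <- NULL
  df
}

#' Build the dosage-expression accounting table from mapped calls
#'
#' Counts, per sample, the explored genes with/without copy-number
#' alteration and how many of each are deregulated; adds the average row
#' (Table-style arithmetic, see [dosage_table_from_counts]) and a
#' recurrent-gene row contrasting genes CN-altered in every sample with the
#' remaining explored genes, using the pooled deregulation call.
#'
#' @param dosage a `gene_dosage` object from [map_genes].
#' @param de_status logical matrix genes x samples (TRUE = deregulated in
#'   that line's contrast); rownames are gene ids.
#' @param pooled_status named logical vector: deregulated when all lines are
#'   contrasted together against the controls.
#' @return the accounting data.frame (see [dosage_table_from_counts]).
#' @export
build_dosage_expression_table <- function(dosage, de_status, pooled_status) {
  calls <- dosage$calls
  genes <- dosage$genes
  explored <- genes$gene_id[genes$explored == 1]
  samples <- unique(calls$sample_id)
  per <- do.call(rbind, lapply(samples, function(s) {
    cs <- calls[calls$sample_id == s, ]
    cnpos_all <- cs$gene_id[cs$cn_class != "normal"]
    cnpos <- intersect(cnpos_all, explored)
    cnneg <- setdiff(explored, cnpos_all)
    de <- de_status[, s]
    data.frame(sample_id = s, genes_cn = length(cnpos_all),
               cnpos_n = length(cnpos),
               cnpos_ex = sum(de[cnpos], na.rm = TRUE),
               cnneg_n = length(cnneg),
               cnneg_ex = sum(de[cnneg], na.rm = TRUE),
               all_ex = sum(de[explored], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rec_genes <- intersect(genes$gene_id[genes$recurrent], explored)
  rest <- setdiff(explored, rec_genes)
  recurrent <- list(n = length(rec_genes),
                    ex = sum(pooled_status[rec_genes], na.rm = TRUE),
                    rest_n = length(rest),
                    rest_ex = sum(pooled_status[rest], na.rm = TRUE),
                    all_n = length(explored),
                    all_ex = sum(pooled_status[explored], na.rm = TRUE))
  dosage_table_from_counts(per, recurrent)
}
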