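# End-to-end orchestration: CNA -> MRR -> gene mapping -> DE -> enrichment
# -> trend/cluster, with YAML-configurable inputs and a JSON summary.

#' Run the full copy-number / expression integration pipeline
#'
#' Reads the inputs named in `config`, executes every analysis stage and
#' writes the result bundle (CNA and MRR BED + TSV, the dosage-expression
#' accounting table, arm/cytoband enrichment tables, trend tables, cluster
#' reports and a JSON summary with the config and seed recorded) into
#' `config$out_dir`.
#'
#' @param config named list or path to a YAML file with elements:
#'   `snp_states`, `snp_log2` (optional), `cytobands`, `genes`,
#'   `expression` (paths); `seed`; `out_dir`; optional `de` (arguments to
#'   [de_config]), `trend_breaks`, `cluster_n_monte_carlo`.
#' @return invisible list with every stage's in-memory result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  snp <- read_snp_states(config$snp_states, config$snp_log2)
  bands <- read_cytobands(config$cytobands)
  snp <- annotate_probes(snp, bands)
  genes <- read_gene_annotation(config$genes, bands)
  expr <- read_expression(config$expression)

  cnas <- build_cnas(snp)
  export_bed(cnas, file.path(out, "cnas.bed"))
  mrrs <- find_mrrs(cnas, snp)
  export_bed(mrrs, file.path(out, "mrrs.bed"))
  write.table(summarize_mrr(mrrs, snp), file.path(out, "mrr_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  dosage <- map_genes(genes, cnas, snp, mrrs)

  de_args <- if (is.null(config$de)) list() else config$de
  lines <- unique(stats::na.omit(expr$line))
  de_status <- matrix(FALSE, nrow(expr$mat), length(lines),
                      dimnames = list(rownames(expr$mat), lines))
  per_line_calls <- list()
  for (i in seq_along(lines)) {
    cfg <- do.call(de_config, c(de_args, list(seed = seed + i)))
    calls <- de_call(subset_expression(expr, lines[i]), cfg)
    per_line_calls[[lines[i]]] <- calls
    de_status[calls$gene_id, i] <- calls$status != "unchanged"
  }
  cfg0 <- do.call(de_config, c(de_args, list(seed = seed)))
  pooled <- de_call(expr, cfg0)
  pooled_status <- stats::setNames(pooled$status != "unchanged",
                                   pooled$gene_id)
  write.table(pooled, file.path(out, "de_calls_pooled.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  table1 <- build_dosage_expression_table(dosage, de_status, pooled_status)
  write.table(table1, file.path(out, "dosage_expression_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # arm-level scans: altered SNPs (pooled recurrent) and deregulated genes
  rec <- recurrent_altered_snps(snp)
  snp_hit <- snp$probes$snp_id %in% rec$snp_id
  arm_snp <- regional_enrichment_scan(snp$probes$arm, snp_hit)
  explored <- genes$gene_id[genes$explored == 1]
  g_idx <- match(pooled$gene_id, genes$gene_id)
  arm_gene <- regional_enrichment_scan(genes$arm[g_idx],
                                       pooled$status != "unchanged")
  page <- if (sum(pooled$status != "unchanged") >= 2)
    tryCatch(page_scan(pooled$fc, pooled$status != "unchanged",
                       genes$arm[g_idx]),
             error = function(e) NULL)
  else NULL
  if (is.null(page))
    page <- data.frame(region = character(), m = integer(),
                       Sm = numeric(), z = numeric(), p = numeric(),
                       skipped = character())
  cyto_gene <- regional_enrichment_scan(genes$cytoband[g_idx],
                                        pooled$status != "unchanged")
  write.table(arm_snp, file.path(out, "arm_snp_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(merge(arm_gene, page, by.x = "region", by.y = "region",
                    all.x = TRUE),
              file.path(out, "arm_gene_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cyto_gene, file.path(out, "cytoband_gene_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # per-MRR deregulation and SNP-count trend
  gene_mrr <- dosage$genes
  first_mrr <- vapply(gene_mrr$mrr_ids, function(x)
    if (length(x)) x[1] else NA_character_, character(1))
  in_expl <- gene_mrr$gene_id %in% explored &
    gene_mrr$gene_id %in% pooled$gene_id
  mrr_test <- mrr_deregulation_test(
    first_mrr[in_expl],
    pooled_status[gene_mrr$gene_id[in_expl]])
  write.table(mrr_test, file.path(out, "mrr_deregulation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  trend_breaks <- if (is.null(config$trend_breaks))
    c(-1, 0, 1, 5, 20, Inf) else config$trend_breaks
  gi <- match(pooled$gene_id, gene_mrr$gene_id)
  tt <- bin_trend_table(gene_mrr$recurrent_snps[gi],
                        pooled$status != "unchanged", trend_breaks)
  lblt <- linear_by_linear_test(tt)
  down_tr <- downregulation_trend(gene_mrr$recurrent_snps[gi],
                                  pooled$status == "down", trend_breaks)
  write.table(as.data.frame(tt), file.path(out, "gene_snp_trend.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # per-arm cluster reports on position-ordered explored genes
  nmc <- if (is.null(config$cluster_n_monte_carlo)) 2000 else
    config$cluster_n_monte_carlo
  cluster_reports <- list()
  st_by_gene <- stats::setNames(pooled$status, pooled$gene_id)
  for (arm in unique(genes$arm)) {
    ids <- genes$gene_id[genes$arm == arm & genes$explored == 1]
    ids <- ids[ids %in% names(st_by_gene)]
    if (length(ids) < 10) next
    st <- unname(st_by_gene[ids])
    rep0 <- find_gene_clusters(st)
    if (rep0$n_deregulated < 10) next
    rt <- suppressWarnings(
      cluster_randomness_test(st, n_monte_carlo = nmc, seed = seed))
    cluster_reports[[arm]] <- c(list(arm = arm, n_genes = length(ids),
                                     n_deregulated = rep0$n_deregulated,
                                     clustered_fraction =
                                       rep0$clustered_fraction), rt)
  }
  jsonlite::write_json(cluster_reports,
                       file.path(out, "cluster_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary <- list(
    provenance = list(config = config, seed = seed,
                      package_version =
                        as.character(utils::packageVersion("cndosage"))),
    n_probes = nrow(snp$probes), n_cnas = nrow(cnas), n_mrrs = nrow(mrrs),
    altered_genome_pct = genome_altered_fraction(cnas,
                                                 bands$chrom_lengths),
    n_deregulated_pooled = sum(pooled$status != "unchanged"),
    trend_m2 = lblt$m2, trend_p = lblt$p,
    downregulation_rho = down_tr$rho, downregulation_p = down_tr$p)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(snp = snp, bands = bands, genes = genes, cnas = cnas,
                 mrrs = mrrs, dosage = dosage, de = pooled,
                 per_line = per_line_calls, table1 = table1,
                 arm_snp = arm_snp, arm_gene = arm_gene, page = page,
                 mrr_test = mrr_test, trend = lblt,
                 down_trend = down_tr, clusters = cluster_reports,
                 summary = summary))
}
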