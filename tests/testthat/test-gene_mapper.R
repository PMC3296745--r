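test_that("gene-to-CNA overlap is 'any intersection' with span SNP counting", {
  # CNA [100,500] with altered SNPs at 120 and 480; gene [150,250] overlaps
  # the CNA but contains no altered SNP
  probes <- data.frame(snp_id = c("a", "b"), chrom = "chr1",
                       pos = c(120L, 480L))
  snp <- snp_data(probes, cbind(S1 = c(3L, 3L)))
  cnas <- build_cnas(snp)
  genes <- data.frame(gene_id = c("g1", "g2"), symbol = c("G1", "G2"),
                      chrom = "chr1", start = c(150L, 600L),
                      end = c(250L, 700L), strand = "+", explored = 1L)
  dm <- map_genes(genes, cnas, snp)
  g1 <- dm$calls[dm$calls$gene_id == "g1", ]
  expect_equal(g1$cn_class, "gain")
  expect_equal(g1$altered_snps, 0L)
  # gene fully outside every CNA -> normal
  expect_equal(dm$calls$cn_class[dm$calls$gene_id == "g2"], "normal")
  # genes on unknown chromosomes are excluded with a warning
  genes2 <- rbind(genes, data.frame(gene_id = "g3", symbol = "G3",
                                    chrom = "chr9", start = 1L, end = 10L,
                                    strand = "+", explored = 1L))
  expect_warning(map_genes(genes2, cnas, snp), "excluded")
})

test_that("gene membership matches a quadratic-scan oracle", {
  set.seed(55)
  n_probes <- 300
  probes <- make_probes(n_probes, spacing = 300L)
  st <- matrix(sample(c(2L, 2L, 3L, 1L), n_probes * 2, replace = TRUE),
               n_probes, 2, dimnames = list(NULL, c("S1", "S2")))
  snp <- snp_data(probes, st)
  cnas <- build_cnas(snp)
  ng <- 300
  gs <- sample(90000L, ng)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:ng),
                      symbol = sprintf("G%03d", 1:ng), chrom = "chr1",
                      start = gs, end = gs + sample(200:5000, ng, TRUE),
                      strand = "+", explored = 1L)
  dm <- map_genes(genes, cnas, snp)
  for (s in c("S1", "S2")) {
    cs <- cnas[cnas$sample_id == s, ]
    calls <- dm$calls[dm$calls$sample_id == s, ]
    calls <- calls[match(genes$gene_id, calls$gene_id), ]
    for (i in sample(ng, 100)) {
      hit <- any(cs$start <= genes$end[i] & cs$end >= genes$start[i])
      expect_equal(calls$cn_class[i] != "normal", hit)
      altered <- probes$pos[st[, s] != 2L]
      expect_equal(calls$altered_snps[i],
                   sum(altered >= genes$start[i] & altered <= genes$end[i]))
    }
  }
  # membership symmetry: gene lists every overlapping CNA id
  calls <- dm$calls
  for (i in sample(nrow(calls), 50)) {
    ids <- calls$cna_ids[[i]]
    if (is.null(ids)) ids <- character(0)
    g <- genes[genes$gene_id == calls$gene_id[i], ]
    cs <- cnas[cnas$sample_id == calls$sample_id[i], ]
    hit <- cs$cna_id[cs$start <= g$end & cs$end >= g$start]
    expect_setequal(ids, hit)
  }
})

test_that("accounting-table averages use ratio-of-mean-counts arithmetic", {
  per <- data.frame(sample_id = c("CaLo", "CaSki", "HeLa", "SiHa"),
                    genes_cn = c(6864, 7706, 14276, 17829),
                    cnpos_n = c(4487, 4912, 8875, 11120),
                    cnpos_ex = c(532, 728, 2207, 1125),
                    cnneg_n = c(16254, 15829, 11866, 9621),
                    cnneg_ex = c(1686, 2197, 3088, 944),
                    all_ex = c(2218, 2925, 5295, 2069))
  rec <- list(n = 783, ex = 147, rest_n = 19958, rest_ex = 2975,
              all_n = 20741, all_ex = 3122)
  tab <- dosage_table_from_counts(per, rec)
  avg <- tab[tab$sample_id == "average", ]
  expect_equal(round(avg$genes_cn), 11669)
  expect_equal(round(avg$all_ex), 3127)
  expect_equal(round(avg$cnpos_pct, 1), 15.6)
  expect_equal(round(avg$cnneg_pct, 1), 14.8)
  recr <- tab[tab$sample_id == "recurrent", ]
  expect_equal(round(recr$cnpos_pct, 1), 18.8)
  expect_equal(round(recr$all_pct, 1), 15.1)

  # degenerate denominator -> NA percent
  per0 <- data.frame(sample_id = "S1", genes_cn = 10, cnpos_n = 0,
                     cnpos_ex = 0, cnneg_n = 5, cnneg_ex = 1, all_ex = 1)
  tab0 <- dosage_table_from_counts(per0)
  expect_true(is.na(tab0$cnpos_pct[1]))
})

test_that("the full accounting table is consistent with the mapped calls", {
  cfg <- sim_config(seed = 9, n_chromosomes = 2, n_genes = 300,
                    chrom_length_bp = 2e7)
  g <- generate_genome(cfg)
  pl <- plant_cnas(cfg, g)
  cnas <- build_cnas(pl$snp)
  mrrs <- find_mrrs(cnas, pl$snp)
  dm <- map_genes(g$genes, cnas, pl$snp, mrrs)
  gt <- g$genes
  set.seed(1)
  samples <- unique(dm$calls$sample_id)
  de <- matrix(runif(nrow(gt) * length(samples)) < 0.15,
               nrow(gt), length(samples),
               dimnames = list(gt$gene_id, samples))
  pooled <- setNames(runif(nrow(gt)) < 0.15, gt$gene_id)
  tab <- build_dosage_expression_table(dm, de, pooled)
  explored <- gt$gene_id[gt$explored == 1]
  for (s in samples) {
    row <- tab[tab$sample_id == s, ]
    expect_equal(row$cnpos_n + row$cnneg_n, length(explored))
    expect_equal(row$all_ex, row$cnpos_ex + row$cnneg_ex)
  }
  recr <- tab[tab$sample_id == "recurrent", ]
  expect_equal(recr$cnpos_n + recr$cnneg_n, length(explored))
})
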