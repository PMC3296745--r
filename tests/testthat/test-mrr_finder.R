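test_that("recurrent SNPs require alteration in every sample", {
  snp <- make_snp(cbind(S1 = c(3, 3, 2), S2 = c(3, 3, 3),
                        S3 = c(3, 1, 3), S4 = c(3, 3, 3)))
  rec <- recurrent_altered_snps(snp)
  expect_equal(rec$snp_id, snp$probes$snp_id[1:2])
  expect_equal(rec$label, c("recurrent-gained", "recurrent-mixed"))

  # brute force on a random 4 x 1000 state matrix
  set.seed(21)
  st <- matrix(sample(0:4, 4000, replace = TRUE), 1000, 4,
               dimnames = list(NULL, paste0("S", 1:4)))
  snp <- make_snp(st)
  rec <- recurrent_altered_snps(snp)
  brute <- which(apply(st, 1, function(r) all(r != 2)))
  expect_equal(rec$snp_id, snp$probes$snp_id[brute])
  expect_error(recurrent_altered_snps(make_snp(cbind(S1 = c(3, 3)))),
               ">= 2 samples")
})

test_that("MRRs are the n-way intersection of per-sample CNAs", {
  probes <- make_probes(10, spacing = 50L)   # positions 50..500
  st <- matrix(3L, 10, 4, dimnames = list(NULL, paste0("S", 1:4)))
  snp <- snp_data(probes, st)

  # identical CNA in all samples -> one identical MRR
  cnas <- do.call(rbind, lapply(paste0("S", 1:4), function(s)
    manual_cnas(s, "chr1", 100L, 500L)))
  class(cnas) <- c("cna_set", "data.frame")
  mrr <- find_mrrs(cnas, snp)
  expect_equal(nrow(mrr), 1L)
  expect_equal(c(mrr$start, mrr$end), c(100L, 500L))
  expect_equal(mrr$direction, "gained")
  expect_equal(mrr$mrr_id, "1-1")

  # CNA in only 3 of 4 samples -> no MRR
  mrr3 <- find_mrrs(cnas[cnas$sample_id != "S4", ], snp,
                    min_samples = 4)
  expect_equal(nrow(mrr3), 0L)

  # staggered gains intersect to [300, 500]
  stag <- do.call(rbind, Map(function(s, a, b) manual_cnas(s, "chr1", a, b),
                             paste0("S", 1:4),
                             c(100L, 200L, 300L, 250L),
                             c(500L, 600L, 700L, 650L)))
  class(stag) <- c("cna_set", "data.frame")
  mrr <- find_mrrs(stag, snp)
  expect_equal(c(mrr$start, mrr$end), c(300L, 500L))

  # mixed directions -> combined
  stag$direction[1] <- "loss"
  mrr <- find_mrrs(stag, snp)
  expect_equal(mrr$direction, "combined")
  expect_error(find_mrrs(stag[stag$sample_id == "S1", ], snp), ">= 2")
})

test_that("intersection matches a per-base-pair membership oracle", {
  set.seed(31)
  probes <- make_probes(500, spacing = 2L)   # dense probes, positions 2..1000
  st <- matrix(2L, 500, 3, dimnames = list(NULL, paste0("S", 1:3)))
  snp <- snp_data(probes, st)
  for (rep in 1:25) {
    sets <- lapply(paste0("S", 1:3), function(s) {
      k <- sample(1:4, 1)
      starts <- sort(sample(seq(1, 900, by = 40), k))
      ends <- pmin(starts + sample(20:120, k, replace = TRUE), 1000L)
      # enforce separated intervals within the sample (real CNA runs are
      # always split by at least one normal probe)
      for (i in seq_len(k - 1))
        if (i < k && ends[i] >= starts[i + 1] - 1) ends[i] <- starts[i + 1] - 2L
      manual_cnas(s, "chr1", starts, ends)
    })
    cnas <- do.call(rbind, sets)
    class(cnas) <- c("cna_set", "data.frame")
    got <- find_mrrs(cnas, snp, require_recurrent_snp = FALSE)
    want <- oracle_mrr_bp(sets, 1000L)
    # oracle intervals that contain at least one probe (even positions)
    want <- want[floor(want$end / 2) - ceiling(want$start / 2) + 1 > 0, ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # intersection algebra: each sample's CNAs fully cover every MRR
    for (s in paste0("S", 1:3)) {
      cs <- cnas[cnas$sample_id == s, ]
      for (i in seq_len(nrow(got)))
        expect_true(any(cs$start <= got$start[i] & cs$end >= got$end[i]))
    }
  }
})

test_that("planted recurrent regions are recovered exactly at full continuity", {
  cfg <- sim_config(seed = 17, continuity = 1, recurrence_prob = 1,
                    n_regions = 8)
  g <- generate_genome(cfg)
  pl <- plant_cnas(cfg, g)
  mrrs <- find_mrrs(build_cnas(pl$snp), pl$snp)
  tru <- unique(pl$truth[, c("region_id", "chrom", "snp_start", "snp_end")])
  expect_equal(nrow(mrrs), nrow(tru))
  expect_setequal(paste(mrrs$chrom, mrrs$start, mrrs$end),
                  paste(tru$chrom, tru$snp_start, tru$snp_end))
  # recurrent SNPs all live inside MRRs here
  rec <- recurrent_altered_snps(pl$snp)
  inside <- mapply(function(ch, p) any(mrrs$chrom == ch & mrrs$start <= p &
                                         mrrs$end >= p),
                   rec$chrom, rec$pos)
  expect_true(all(inside))
})

test_that("MRR summaries average member log2 ratios and flag degenerate tests", {
  probes <- make_probes(2, spacing = 100L)
  st <- cbind(S1 = c(3L, 3L), S2 = c(3L, 3L))
  lr <- cbind(S1 = c(0.2, 0.4), S2 = c(0.2, 0.4))
  snp <- snp_data(probes, st, lr)
  mrrs <- find_mrrs(build_cnas(snp), snp)
  expect_equal(mrrs$mean_log2, 0.3)
  sm <- summarize_mrr(mrrs, snp)
  expect_equal(sm$mean_log2, 0.3)
  expect_false(sm$degenerate)

  # all-zero log2 -> degenerate, p = 1 (-log10 p = 0)
  snp0 <- snp_data(probes, st, lr * 0)
  sm0 <- summarize_mrr(find_mrrs(build_cnas(snp0), snp0), snp0)
  expect_true(sm0$degenerate)
  expect_equal(sm0$neg_log10_p, 0)

  # sampling check: planted N(0.3, 0.05^2) recovered within 3 s.e.
  set.seed(5)
  probes <- make_probes(100, spacing = 100L)
  st <- cbind(S1 = rep(3L, 100), S2 = rep(3L, 100))
  lr0 <- matrix(rnorm(200, 0.3, 0.05), 100, 2)
  snp <- snp_data(probes, st, lr0)
  sm <- summarize_mrr(find_mrrs(build_cnas(snp), snp), snp)
  expect_lt(abs(sm$mean_log2 - 0.3), 3 * 0.05 / sqrt(200))
})
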