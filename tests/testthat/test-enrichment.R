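test_that("the corrected 2x2 chi-square reproduces published cell-line contrasts", {
  # recurrent CN-altered genes 147/783 vs remaining explored 2975/19958
  r1 <- two_by_two_chisq(147, 636, 2975, 16983)
  expect_equal(r1$p, 0.0035, tolerance = 0.01)
  # hot MRR 28/64 vs all-MRR genes 147/783 (background includes the region)
  r2 <- two_by_two_chisq(28, 36, 147, 636)
  expect_equal(r2$p, 4.5e-6, tolerance = 0.02)
})

test_that("chi-square agrees with the textbook formula and stats::chisq.test", {
  # equal proportions, uncorrected -> chi2 0, p 1
  r <- two_by_two_chisq(10, 10, 10, 10, correction = FALSE)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  set.seed(66)
  for (i in 1:50) {
    t <- matrix(sample(20:400, 4), 2)
    mine <- two_by_two_chisq(t[1, 1], t[1, 2], t[2, 1], t[2, 2],
                             correction = FALSE)
    # cell-wise sum((O-E)^2/E)
    E <- outer(rowSums(t), colSums(t)) / sum(t)
    expect_equal(mine$chi2, sum((t - E)^2 / E), tolerance = 1e-10)
    ref <- suppressWarnings(chisq.test(t, correct = FALSE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
    refY <- suppressWarnings(chisq.test(t, correct = TRUE))
    mineY <- two_by_two_chisq(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
    expect_equal(mineY$p, refY$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher fallback engages on small expected counts and tracks chi-square", {
  r <- two_by_two_chisq(2, 3, 4, 100)
  expect_equal(r$method, "fisher")
  expect_equal(r$p, fisher.test(matrix(c(2, 3, 4, 100), 2,
                                       byrow = TRUE))$p.value)
  # zero margin -> fisher
  expect_equal(two_by_two_chisq(0, 0, 5, 10)$method, "fisher")
  # with all expected counts > 20 and no extreme association, fisher and
  # chi-square agree within 20% relative
  set.seed(77)
  for (i in 1:20) {
    p1 <- runif(1, 0.25, 0.75); p2 <- runif(1, 0.25, 0.75)
    t <- matrix(rmultinom(1, 600, c(p1 * p2, p1 * (1 - p2),
                                    (1 - p1) * p2,
                                    (1 - p1) * (1 - p2))), 2, byrow = TRUE)
    if (min(outer(rowSums(t), colSums(t)) / sum(t)) <= 20) next
    pc <- two_by_two_chisq(t[1, 1], t[1, 2], t[2, 1], t[2, 2])$p
    pf <- two_by_two_chisq(t[1, 1], t[1, 2], t[2, 1], t[2, 2],
                           force = "fisher")$p
    expect_lt(abs(pc - pf) / pf, 0.2)
  }
})

test_that("the parametric gene-set Z score follows its defining formula", {
  # a set with Sm = mu scores z = 0, p = 1
  fc <- c(rep(2, 20), rep(0.5, 20))
  dereg <- rep(TRUE, 40)
  region <- rep(c("A", "B"), each = 20)
  # build a symmetric case on the log2 scale: mu = 0
  fc2 <- c(rep(2, 10), rep(0.5, 10), rep(2, 10), rep(0.5, 10))
  ps <- page_scan(fc2, dereg, region, min_m = 10)
  expect_equal(ps$z, c(0, 0))
  expect_equal(ps$p, c(1, 1))

  # direct formula on random data
  set.seed(88)
  fcr <- rlnorm(200, 0, 0.5)
  der <- runif(200) < 0.6
  reg <- sample(c("A", "B", "C"), 200, replace = TRUE)
  ps <- page_scan(fcr, der, reg, min_m = 5)
  lv <- log2(fcr)[der]
  mu <- mean(lv); delta <- sd(lv)
  for (i in seq_len(nrow(ps))) {
    sel <- log2(fcr)[der & reg == ps$region[i]]
    expect_equal(ps$z[i], (mean(sel) - mu) * sqrt(length(sel)) / delta)
  }
  # affine invariance: rescaling every fold change leaves z unchanged
  ps2 <- page_scan(fcr * 3, der, reg, min_m = 5)
  expect_equal(ps2$z, ps$z, tolerance = 1e-12)

  # sets smaller than min_m are reported but skipped
  small <- page_scan(fcr, der & (seq_len(200) <= 9) | der,
                     ifelse(seq_len(200) <= 9, "tiny", "big"), min_m = 10)
  expect_true(is.na(small$z[small$region == "tiny"]))
  expect_match(small$skipped[small$region == "tiny"], "m < 10")
  expect_error(page_scan(rep(2, 20), rep(TRUE, 20), rep("A", 20)),
               "degenerate")
})

test_that("per-region deregulation testing reproduces the hot-region contrast", {
  # region A: 28/64 deregulated; whole set 147/783
  region <- c(rep("A", 64), rep("B", 719))
  dereg <- c(rep(TRUE, 28), rep(FALSE, 36), rep(TRUE, 119), rep(FALSE, 600))
  res <- mrr_deregulation_test(region, dereg)
  a <- res[res$region == "A", ]
  expect_equal(round(a$percent, 1), 43.8)
  expect_equal(a$p, 4.5e-6, tolerance = 0.02)
  # the bulk region close to the global rate is unremarkable
  b <- res[res$region == "B", ]
  expect_gt(b$p, 0.05)
  # excluding the tested region sharpens the contrast
  res2 <- mrr_deregulation_test(region, dereg, include_self = FALSE)
  expect_lt(res2$p[res2$region == "A"], a$p)
})

test_that("the regional scan flags planted hot regions and controls errors", {
  set.seed(101)
  region <- rep(sprintf("arm%02d", 1:10), each = 200)
  hit <- runif(2000) < 0.15
  hit[region == "arm03"] <- runif(200) < 0.5
  res <- regional_enrichment_scan(region, hit)
  expect_true(res$enriched[res$region == "arm03"])
  expect_equal(sum(res$enriched), 1L)

  # uniform hit rate: false flags stay near the nominal level
  flags <- vapply(1:30, function(sd) {
    set.seed(sd)
    h <- runif(2000) < 0.15
    sum(regional_enrichment_scan(region, h)$enriched)
  }, numeric(1))
  expect_lte(mean(flags) / 10, 0.06)    # per-region flag rate vs alpha 0.05

  # single-region input cannot be tested
  one <- regional_enrichment_scan(rep("arm1", 50), runif(50) < 0.2)
  expect_true(is.na(one$p))
})
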