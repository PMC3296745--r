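test_that("trend binning assigns units to ordered bins and keeps empties", {
  tab <- bin_trend_table(c(50, 200, 700), c(TRUE, FALSE, TRUE))
  expect_equal(tab$n, c(1L, 1L, 1L))
  expect_equal(tab$k, c(1L, 0L, 1L))
  # empty bin retained with n = 0
  tab2 <- bin_trend_table(c(50, 60, 700), c(TRUE, FALSE, TRUE))
  expect_equal(tab2$n, c(2L, 0L, 1L))
  expect_true(is.na(tab2$percent[2]))
  # all units in one bin -> degenerate trend
  tab3 <- bin_trend_table(c(10, 20, 30), c(TRUE, FALSE, TRUE))
  expect_true(is.na(linear_by_linear_test(tab3)$m2))
})

test_that("linear-by-linear M2 equals (N-1) r^2 with its closed forms", {
  # perfect gradient: bin 1 all negative, bin 2 all positive, N = 20
  tab <- bin_trend_table(c(rep(50, 10), rep(200, 10)),
                         c(rep(FALSE, 10), rep(TRUE, 10)))
  lt <- linear_by_linear_test(tab)
  expect_equal(lt$r, 1)
  expect_equal(lt$m2, 19)
  # flat proportions -> m2 ~ 0, p ~ 1
  tabf <- bin_trend_table(c(rep(50, 10), rep(200, 10)),
                          rep(c(TRUE, FALSE), 10))
  ltf <- linear_by_linear_test(tabf)
  expect_equal(ltf$m2, 0, tolerance = 1e-12)
  expect_equal(ltf$p, 1)

  # random tables: M2 matches a brute-force expansion from the table counts
  set.seed(202)
  for (i in 1:40) {
    n <- sample(30:120, 1)
    snps <- sample(c(5, 50, 300, 900), n, replace = TRUE)
    de <- runif(n) < 0.4
    tab <- bin_trend_table(snps, de, breaks = c(0, 10, 100, 500, Inf))
    lt <- linear_by_linear_test(tab)
    # expand unit vectors from the *table* alone
    s <- rep(tab$score, tab$n)
    y <- unlist(mapply(function(k, n) c(rep(1, k), rep(0, n - k)),
                       tab$k, tab$n))
    if (sd(s) == 0 || sd(y) == 0) {
      expect_true(is.na(lt$m2))
    } else {
      expect_equal(lt$m2, (length(s) - 1) * cor(s, y)^2, tolerance = 1e-10)
    }
    # affine invariance of the scores
    tab2 <- tab
    attr(tab2, "unit_score") <- 10 + 3 * attr(tab, "unit_score")
    expect_equal(linear_by_linear_test(tab2)$m2, lt$m2, tolerance = 1e-12)
  }
})

test_that("downregulation trend recovers a planted dose-response", {
  # monotone bin fractions -> bin-level rho 1
  set.seed(9)
  k <- rep(c(1, 150, 600), each = 100)
  p <- rep(c(0.1, 0.25, 0.4), each = 100)
  down <- runif(300) < p
  dt <- downregulation_trend(k, down)
  expect_equal(dt$bin_rho, 1)
  # constant fractions -> bin-level rho 0
  down0 <- rep(c(TRUE, FALSE), 150)
  expect_equal(downregulation_trend(k, down0)$bin_rho, 0)
  # ties-only input -> NA
  expect_true(is.na(downregulation_trend(rep(5, 10),
                                         rep(FALSE, 10))$rho))

  # planted P(down | k) increasing in k: rho > 0, p < 0.01, n = 500, 10 seeds
  for (sd in 1:10) {
    set.seed(sd)
    k <- rpois(500, 4)
    down <- runif(500) < pmin(0.05 + 0.06 * k, 0.9)
    dt <- downregulation_trend(k, down, breaks = c(-1, 0, 2, 5, Inf))
    expect_gt(dt$rho, 0)
    expect_lt(dt$p, 0.01)
  }
})

test_that("cluster detection matches a linear-scan oracle", {
  # [up, up, unchanged, down] -> one run of 2, fraction 2/3
  rep0 <- find_gene_clusters(c("up", "up", "unchanged", "down"))
  expect_equal(nrow(rep0$runs), 1L)
  expect_equal(rep0$runs$length, 2L)
  expect_equal(rep0$clustered_fraction, 2 / 3)
  # no deregulated genes -> undefined fraction
  expect_true(is.na(find_gene_clusters(rep("unchanged", 5))$clustered_fraction))
  # mixed-direction runs count as one cluster
  mix <- find_gene_clusters(c("down", "up", "down"))
  expect_equal(mix$runs$length, 3L)

  # random permutations vs a regex-style oracle on the collapsed string
  set.seed(33)
  for (i in 1:50) {
    st <- sample(c("up", "down", "unchanged"), 40, replace = TRUE,
                 prob = c(0.2, 0.2, 0.6))
    rep1 <- find_gene_clusters(st)
    runs <- gregexpr("D{2,}", paste(ifelse(st == "unchanged", "N", "D"),
                                    collapse = ""))[[1]]
    want <- if (runs[1] == -1) 0L else
      sum(attr(runs, "match.length"))
    expect_equal(rep1$clustered, want)
  }
})

test_that("the randomness test rejects planted clustering and holds its level", {
  # one solid block of deregulated genes among many unchanged
  st <- c(rep("up", 12), rep("unchanged", 88))
  rt <- cluster_randomness_test(st, n_monte_carlo = 2000, seed = 4)
  expect_lt(rt$p, 0.05)
  expect_equal(rt$observed, 12)
  # reproducible under the same seed
  rt2 <- cluster_randomness_test(st, n_monte_carlo = 2000, seed = 4)
  expect_equal(rt$p, rt2$p)

  # type-I control: i.i.d. statuses rejected near the nominal rate
  rej <- vapply(1:100, function(sd) {
    set.seed(1000 + sd)
    sti <- sample(c("up", "down", "unchanged"), 60, replace = TRUE,
                  prob = c(0.15, 0.15, 0.7))
    rt <- suppressWarnings(
      cluster_randomness_test(sti, n_monte_carlo = 400, seed = sd))
    rt$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.12)
})
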