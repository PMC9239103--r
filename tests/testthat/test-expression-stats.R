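test_that("TPM normalizes by length and sums to one million per sample", {
  one <- tpm(tibble::tibble(gene_id = "g", length = 500L, s1 = 7L))
  expect_equal(one$s1, 1e6)

  two <- tpm(tibble::tibble(gene_id = c("a", "b"), length = c(100L, 200L),
                            s1 = c(10L, 10L)))
  expect_equal(two$s1, c(2e6 / 3, 1e6 / 3))

  set.seed(13)
  m <- tibble::tibble(gene_id = sprintf("g%d", 1:50),
                      length = sample(200:3000, 50),
                      s1 = rnbinom(50, mu = 100, size = 5),
                      s2 = rnbinom(50, mu = 50, size = 5))
  tp <- tpm(m)
  expect_equal(sum(tp$s1), 1e6, tolerance = 1e-6)
  expect_equal(sum(tp$s2), 1e6, tolerance = 1e-6)
  # scale invariance: doubling all counts leaves TPM unchanged
  m2 <- m; m2$s1 <- m$s1 * 2L
  expect_equal(tpm(m2)$s1, tp$s1)

  expect_warning(tpm(tibble::tibble(gene_id = "g", length = 10L, s1 = 0L)),
                 "all-zero")
  expect_error(tpm(tibble::tibble(gene_id = "g", length = 0L, s1 = 1L)),
               "lengths")
})

test_that("Mann-Whitney U counts exceeding pairs and matches exact enumeration", {
  t0 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 0.1) # 2/20 rank assignments as extreme
  expect_equal(t0$method, "exact")

  expect_equal(mann_whitney_u(c(1, 3), c(2))$statistic, 1)
  a <- c(5, 9, 1, 7)
  expect_equal(mann_whitney_u(a, a)$statistic, length(a)^2 / 2)

  # exact p agrees with full enumeration on random tie-free samples
  set.seed(23)
  for (i in 1:10) {
    x <- runif(sample(3:5, 1), 0, 100)
    y <- runif(sample(3:6, 1), 0, 100)
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_exact_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("U statistic and p-values agree with the stats reference routines", {
  set.seed(29)
  for (i in 1:20) {
    x <- rnorm(sample(10:40, 1)); y <- rnorm(sample(10:40, 1), mean = runif(1, -1, 1))
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # tie-corrected path
  x <- c(1, 2, 2, 3, 5, 5, 5); y <- c(2, 3, 3, 4, 5, 6)
  got <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_match(got$method, "tie-corrected")
})

test_that("U identity and exact/approximate agreement hold across random pairs", {
  set.seed(31)
  for (i in 1:200) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    x <- sample(0:30, n1, replace = TRUE); y <- sample(0:30, n2, replace = TRUE)
    ua <- mann_whitney_u(x, y)$statistic
    ub <- mann_whitney_u(y, x)$statistic
    expect_equal(ua + ub, n1 * n2)
  }
  # for small tie-free samples the normal approximation stays within 0.05
  for (i in 1:50) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    repeat {
      x <- round(runif(n1, 0, 100), 3); y <- round(runif(n2, 0, 100), 3)
      if (!any(duplicated(c(x, y)))) break
    }
    p_exact <- mann_whitney_u(x, y)$p_value
    p_approx <- mann_whitney_u(x, y, exact_limit = 0L)$p_value
    expect_lt(abs(p_exact - p_approx), 0.05)
  }
})

test_that("Levene's W follows the one-way ANOVA form with degenerate guards", {
  a <- rnorm(10)
  expect_equal(levene_test(a, a)$statistic, 0)
  # constant within-group deviations: infinite F ratio, flagged
  deg <- levene_test(c(0, 0, 10, 10), c(4, 4, 6, 6))
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, Inf)
  expect_equal(deg$p_value, 0)

  set.seed(37)
  x <- rnorm(25, sd = 1); y <- rnorm(30, sd = 2.5)
  got <- levene_test(x, y)
  ref <- car::leveneTest(c(x, y), factor(rep(c("x", "y"), c(25, 30))),
                         center = mean)
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # scaling both groups leaves W unchanged
  sc <- levene_test(x * 7, y * 7)
  expect_equal(sc$statistic, got$statistic, tolerance = 1e-10)
  # median-centred variant matches the Brown-Forsythe reference
  got_m <- levene_test(x, y, center = "median")
  ref_m <- car::leveneTest(c(x, y), factor(rep(c("x", "y"), c(25, 30))))
  expect_equal(got_m$statistic, ref_m$`F value`[1], tolerance = 1e-10)
})

test_that("tidy and glance methods return one-row tibbles", {
  mw <- mann_whitney_u(1:5, 2:8)
  expect_s3_class(tidy(mw), "tbl_df")
  expect_equal(nrow(tidy(mw)), 1L)
  lv <- levene_test(rnorm(5), rnorm(6))
  expect_named(glance(lv), c("statistic", "p_value", "df1", "df2", "n1", "n2",
                             "center", "degenerate"))
})

test_that("binding bias detects a planted TPM shift and respects the universe", {
  set.seed(41)
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:2000),
                          length = sample(300:3000, 2000, replace = TRUE))
  bound <- genes$gene_id[1:250]
  sim <- synth_counts(genes, bound, planted_log2fc = 1, n_replicates = 3,
                      condition = "wt_24h", seed = 43)
  tp <- tpm(sim$counts)
  samples <- tibble::tibble(sample = paste0("wt_24h_rep", 1:3), condition = "wt_24h")
  bias <- binding_bias_table(tp, bound, samples)
  expect_equal(bias$n_bound + bias$n_other, 2000L)
  expect_gt(bias$mean_bound, bias$mean_other)
  expect_lt(bias$p_value, 0.01)

  # log2fc rows use their own universe
  lfc <- tibble::tibble(gene_id = genes$gene_id[1:1500], condition = "24h",
                        log2fc = rnorm(1500, 0, 0.1) +
                          ifelse(genes$gene_id[1:1500] %in% bound, 0.5, 0))
  bias2 <- binding_bias_table(tp, bound, samples, log2fc = lfc)
  fc_row <- bias2[bias2$metric == "log2fc", ]
  expect_equal(fc_row$n_bound + fc_row$n_other, 1500L)
  expect_lt(fc_row$p_value, 0.01)

  expect_error(binding_bias_table(tp, character(), samples), "empty")
  # bound set of all-but-one gene: degenerate, flagged rather than tested
  almost_all <- genes$gene_id[-1]
  deg <- binding_bias_table(tp, almost_all, samples)
  expect_true(deg$degenerate)
})

test_that("binding bias p-values are calibrated under the null", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                          length = rep(1000L, 200))
  samples <- tibble::tibble(sample = "null_rep1", condition = "null")
  set.seed(47)
  rej <- vapply(1:1000, function(i) {
    sim <- synth_counts(genes, sample(genes$gene_id, 50), planted_log2fc = 0,
                        n_replicates = 1, condition = "null", seed = 10000 + i)
    tp <- tpm(sim$counts)
    binding_bias_table(tp, sim$truth$bound_set, samples)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("spore ratio comparison has power at study-scale sample sizes", {
  ref0 <- tibble::tibble(length = c(1.5, 1.6, 1.4), width = c(1, 1, 1))
  same <- spore_ratio_compare(ref0, ref0)
  expect_equal(same$u_statistic, 9 / 2)
  expect_equal(same$levene_w, 0)
  expect_error(spore_ratio_compare(ref0,
                                   tibble::tibble(length = 1:2, width = c(1, 0))),
               "non-positive")

  # planted 1.13x median shift at n = 560/332: Mann-Whitney p < 0.01 in
  # >= 95% of 200 simulations
  hits <- vapply(1:200, function(i) {
    ref <- synth_spores(560, 1.49, sigma = 0.17, seed = 20000 + i)
    tst <- synth_spores(332, 1.69, sigma = 0.22, seed = 50000 + i)
    spore_ratio_compare(ref, tst)$u_p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
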