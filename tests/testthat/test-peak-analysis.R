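mk_peaks <- function(starts, ends, fe = NULL, contig = "c1") {
  n <- length(starts)
  tibble::tibble(
    name = sprintf("p%03d", seq_len(n)), contig = contig,
    start = as.integer(starts), end = as.integer(ends),
    fold_enrichment = if (is.null(fe)) rep(1, n) else fe,
    summit = as.integer(starts + (ends - starts) %/% 2L)
  )
}

test_that("strength and width filters use strict inequalities", {
  pk <- mk_peaks(c(0, 100, 200), c(50, 150, 250), fe = c(9.9, 10.0, 10.1))
  expect_equal(filter_strong(pk)$fold_enrichment, 10.1)
  expect_equal(nrow(filter_strong(pk[0, ])), 0L)
  all_strong <- mk_peaks(c(0, 100), c(50, 150), fe = c(67.75, 67.75))
  expect_equal(nrow(filter_strong(all_strong)), 2L)

  w <- mk_peaks(c(0, 1000, 2000), c(399, 1400, 2401))
  expect_equal(filter_narrow(w)$end - filter_narrow(w)$start, 399L)
  expect_equal(nrow(filter_narrow(mk_peaks(5000, 5271))), 1L) # 271 bp kept
  expect_equal(nrow(filter_narrow(w[0, ])), 0L)
})

test_that("common peaks pair by maximal overlap with deterministic ties", {
  a <- mk_peaks(0, 100)
  b <- mk_peaks(50, 150)
  pairs <- common_peaks(a, b)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$overlap_bp, 50L)

  a2 <- mk_peaks(100, 200)
  b2 <- mk_peaks(c(0, 140), c(130, 300)) # overlaps 30 and 60
  expect_equal(common_peaks(a2, b2)$name_b, "p002")

  expect_equal(nrow(common_peaks(mk_peaks(0, 10), mk_peaks(500, 600))), 0L)

  # summit mode: pair iff the A summit falls inside the B interval
  a3 <- mk_peaks(100, 300) # summit 200
  expect_equal(nrow(common_peaks(a3, mk_peaks(150, 250), mode = "summit_in_region")), 1L)
  expect_equal(nrow(common_peaks(a3, mk_peaks(210, 400), mode = "summit_in_region")), 0L)

  # one pair per A peak, never more
  set.seed(21)
  sa <- sort(sample.int(5000, 30)) * 10L
  a4 <- mk_peaks(sa, sa + sample(200:500, 30, replace = TRUE))
  sb <- sort(sample.int(5000, 40)) * 10L
  b4 <- mk_peaks(sb, sb + sample(200:500, 40, replace = TRUE))
  expect_lte(nrow(common_peaks(a4, b4)), nrow(a4))
})

test_that("low-GC colocalization uses union coverage with an inclusive bound", {
  pk <- mk_peaks(0, 100)
  lg <- function(s, e) tibble::tibble(contig = "c1", start = as.integer(s),
                                      end = as.integer(e))
  expect_equal(colocalize_low_gc(pk, lg(0, 80))$n_colocalized, 1L)  # 0.8 >= 0.8
  expect_equal(colocalize_low_gc(pk, lg(0, 79))$n_colocalized, 0L)  # 0.79
  # union of two abutting regions covers fully, without double counting
  expect_equal(colocalize_low_gc(pk, lg(c(0, 50), c(50, 100)))$n_colocalized, 1L)
  # overlapping regions must not double count
  expect_equal(colocalize_low_gc(pk, lg(c(0, 20), c(60, 70)), per_peak = TRUE) |>
                 attr("per_peak") |> (\(x) x$covered_frac)(), 0.7)

  # randomized check against a per-bp union-coverage oracle
  set.seed(31)
  for (i in 1:10) {
    ps <- sample.int(500, 1); pe <- ps + sample(50:200, 1)
    peak <- mk_peaks(ps, pe)
    rs <- sample.int(700, 5); re <- rs + sample(20:120, 5, replace = TRUE)
    cov <- oracle_union_coverage(ps, pe, rs, re) / (pe - ps)
    got <- attr(colocalize_low_gc(peak, lg(rs, re), per_peak = TRUE),
                "per_peak")$covered_frac
    expect_equal(got, cov)
  }
})

test_that("colocalization fraction is monotone in min_frac and recovers a planted split", {
  set.seed(41)
  starts <- seq(0L, 99000L, 1000L)[1:60]
  pk <- mk_peaks(starts, starts + 300L)
  # plant: first 24 peaks fully inside low-GC regions, rest uncovered
  lg <- tibble::tibble(contig = "c1", start = starts[1:24] - 10L,
                       end = starts[1:24] + 310L)
  res <- colocalize_low_gc(pk, lg, min_frac = 0.8)
  expect_equal(res$fraction, 24 / 60)
  fr <- vapply(c(0.2, 0.5, 0.8, 1), function(f) {
    colocalize_low_gc(pk, lg, min_frac = f)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("fold-enrichment correlation behaves like Pearson r", {
  p <- tibble::tibble(fe_a = c(1, 2, 3), fe_b = c(3, 2, 1))
  expect_equal(enrichment_correlation(p), -1)
  expect_equal(enrichment_correlation(tibble::tibble(fe_a = 1:5, fe_b = (1:5) * 2)), 1)
  expect_warning(r <- enrichment_correlation(tibble::tibble(fe_a = 1:3, fe_b = rep(2, 3))),
                 "zero variance")
  expect_true(is.na(r))
  expect_error(enrichment_correlation(p[1, ]), "at least 2")
})
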