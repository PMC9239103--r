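mk_genes <- function(start, end, strand, contig = "c1") {
  tibble::tibble(gene_id = sprintf("g%03d", seq_along(start)), contig = contig,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, feature = "gene", product = NA_character_)
}

test_that("promoter windows follow the -350/+50 strand-aware convention", {
  g <- mk_genes(c(1000, 2000, 100), c(1500, 5000, 400), c("+", "-", "+"))
  pw <- promoter_windows(g)
  expect_equal(pw$start[1], 650L); expect_equal(pw$end[1], 1050L)
  expect_equal(pw$start[2], 4950L); expect_equal(pw$end[2], 5350L)
  # clipping at the contig edge
  expect_equal(pw$start[3], 0L); expect_equal(pw$end[3], 150L)
  expect_true(pw$truncated[3]); expect_false(any(pw$truncated[1:2]))
  expect_equal(pw$end[1] - pw$start[1], 400L)
})

test_that("summit windows cover the summit plus the flank on each side", {
  pk <- tibble::tibble(name = c("a", "b"), contig = "c1",
                       start = c(800L, 0L), end = c(1300L, 300L),
                       summit = c(1000L, 50L), fold_enrichment = c(5, 5))
  sw <- summit_windows(pk)
  expect_equal(sw$start, c(850L, 0L))
  expect_equal(sw$end, c(1151L, 201L))
  expect_equal(sw$truncated, c(FALSE, TRUE))
  expect_equal(summit_windows(pk, flank = 0L)$end - summit_windows(pk, flank = 0L)$start,
               c(1L, 1L))
})

test_that("binding assignment reproduces the promoter / coding / unbound taxonomy", {
  g <- mk_genes(c(10000, 20000, 30000), c(11000, 21000, 31000), c("+", "+", "+"))
  pk <- tibble::tibble(
    name = c("strong_prom", "cds_hit"),
    contig = "c1",
    start = c(9500L, 20150L), end = c(10047L, 20500L),
    summit = c(9674L, 20250L),
    fold_enrichment = c(67.75, 12)
  )
  rec <- assign_binding(g, pk)
  expect_equal(rec$category, c("promoter", "coding_only", "unbound"))
  # relative summit: 0-based summit 9674 against gene start 10000, upstream
  # positions count from -1 with no zero
  expect_equal(rec$summit_rel[1], -326L)
  expect_equal(rec$fold_enrichment[1], 67.75)
  expect_equal(rec$binding_width[1], 547L)
  # summit deep in the gene body: its +/-150 window clears the promoter, so
  # the gene is coding_only
  expect_equal(rec$summit_rel[2], 251L)
  expect_true(is.na(rec$fold_enrichment[3]))
  # provenance retains a justifying overlap for every bound gene
  prov <- attr(rec, "provenance")
  expect_true(all(rec$gene_id[rec$category == "promoter"] %in%
                    prov$gene_id[prov$region == "promoter"]))
})

test_that("minus-strand genes use the gene end as the +1 reference", {
  g <- mk_genes(5000, 6000, "-")
  # summit 150 bp downstream of the TSS-proxy (= last base 5999): inside gene
  pk <- tibble::tibble(name = "p", contig = "c1", start = 5700L, end = 6100L,
                       summit = 5850L, fold_enrichment = 20)
  rec <- assign_binding(g, pk)
  expect_equal(rec$category, "promoter") # summit window reaches [5999-50, ...)
  expect_equal(rec$summit_rel, 150L)
  # summit 100 bp upstream of the gene (past the end): negative offset
  pk2 <- tibble::tibble(name = "p", contig = "c1", start = 6000L, end = 6300L,
                        summit = 6099L, fold_enrichment = 20)
  expect_equal(assign_binding(g, pk2)$summit_rel, -100L)
})

test_that("max-FE peak is reported when several bind one promoter", {
  g <- mk_genes(10000, 11000, "+")
  pk <- tibble::tibble(
    name = c("weak", "strong"), contig = "c1",
    start = c(9600L, 9700L), end = c(9900L, 10000L),
    summit = c(9750L, 9850L), fold_enrichment = c(5, 50)
  )
  rec <- assign_binding(g, pk)
  expect_equal(rec$peak_name, "strong")
  expect_equal(rec$n_promoter_peaks, 2L)
})

test_that("bound-at-both and strong-bound-fraction summarize record sets", {
  g <- mk_genes(c(10000, 20000, 30000), c(11000, 21000, 31000), rep("+", 3))
  mk_rec <- function(bound, fe) {
    r <- tibble::tibble(gene_id = g$gene_id,
                        category = ifelse(g$gene_id %in% bound, "promoter", "unbound"),
                        fold_enrichment = ifelse(g$gene_id %in% bound, fe, NA_real_))
    r
  }
  t1 <- mk_rec(c("g001", "g002"), c(15, 15, NA)[1])
  t2 <- mk_rec(c("g002", "g003"), 15)
  expect_equal(bound_at_both(t1, t2), "g002")
  expect_equal(bound_at_both(t1, t1), sort(c("g001", "g002")))
  expect_equal(bound_at_both(mk_rec("g001", 1), mk_rec("g003", 1)), character(0))

  r <- tibble::tibble(gene_id = c("a", "b", "c"), category = "promoter",
                      fold_enrichment = c(5, 10, 15))
  sf <- strong_bound_fraction(r)
  expect_equal(sf$n_strong, 1L)           # strictly > 10
  expect_equal(sf$fraction, 1 / 3)
  expect_equal(strong_bound_fraction(r, min_fe = 0)$n_strong, 3L)
  none <- strong_bound_fraction(r[0, ])
  expect_true(is.na(none$fraction))
})

test_that("records are invariant under reverse-complementing the whole study", {
  set.seed(77)
  L <- 50000L
  gen <- synth_genome(L, gc_background = 0.6, seed = 3)
  genes <- synth_annotation(gen$genome, n_genes = 12, min_intergenic = 1200,
                            seed = 4)
  pk_raw <- synth_promoter_peaks(genes, genes$gene_id[c(2, 5, 9)],
                                 .contig_lengths(gen$genome), seed = 5)
  pk <- pk_raw$peaks
  lens <- c(synth_1 = L)
  fwd <- assign_binding(genes, pk, contig_lengths = lens)

  flip_genes <- genes
  flip_genes$start <- L - genes$end
  flip_genes$end <- L - genes$start
  flip_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  flip_pk <- pk
  flip_pk$start <- L - pk$end
  flip_pk$end <- L - pk$start
  flip_pk$summit <- L - 1L - pk$summit
  rev_ <- assign_binding(flip_genes, flip_pk, contig_lengths = lens)

  ord <- order(fwd$gene_id); ord2 <- order(rev_$gene_id)
  expect_equal(fwd$category[ord], rev_$category[ord2])
  expect_equal(fwd$summit_rel[ord], rev_$summit_rel[ord2])
  expect_equal(fwd$fold_enrichment[ord], rev_$fold_enrichment[ord2])
})

test_that("planted promoter peaks are recovered as exactly the planted gene set", {
  for (s in c(2, 8)) {
    gen <- synth_genome(60000, gc_background = 0.7, seed = s)
    genes <- synth_annotation(gen$genome, n_genes = 15, min_intergenic = 1200,
                              seed = s + 1)
    lens <- .contig_lengths <- c(synth_1 = 60000L)
    picked <- sort(sample(genes$gene_id, 6))
    pk <- synth_promoter_peaks(genes, picked, lens, seed = s + 2)
    rec <- assign_binding(genes, pk$peaks, contig_lengths = lens)
    expect_setequal(rec$gene_id[rec$category == "promoter"], pk$truth$bound_ids)
    expect_setequal(pk$truth$bound_ids, picked)
  }
})
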