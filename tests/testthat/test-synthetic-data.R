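test_that("generators are pure functions of parameters and seed", {
  g1 <- synth_genome(5000, gc_background = 0.7, n_planted_motifs = 10, seed = 5)
  g2 <- synth_genome(5000, gc_background = 0.7, n_planted_motifs = 10, seed = 5)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$hits, g2$truth$hits)
  g3 <- synth_genome(5000, gc_background = 0.7, n_planted_motifs = 10, seed = 6)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))

  # byte-identical files from the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  st1 <- simulate_study(d1, seed = 11)
  st2 <- simulate_study(d2, seed = 11)
  for (f in c("genome.fasta", "annotation.gff3", "peaks_25h.narrowPeak",
              "counts.tsv", "spores_reference.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_identical(unname(tools::md5sum(file.path(d1, "plate", "frame_010.png"))),
                   unname(tools::md5sum(file.path(d2, "plate", "frame_010.png"))))
})

test_that("planted motifs are all recovered and counted by the scanner", {
  for (s in 1:3) {
    gen <- synth_genome(100000, gc_background = 0.72, n_planted_motifs = 200,
                        seed = s)
    hits <- scan_motif(gen$genome, "GATCWT")
    # ground truth equals the package scan (both verified against the naive
    # oracle elsewhere)
    expect_equal(nrow(hits), nrow(gen$truth$hits))
    expect_gte(nrow(hits), 200L)
    planted_keys <- paste(gen$truth$planted$start, gen$truth$planted$end)
    expect_true(all(planted_keys %in% paste(hits$start, hits$end)))
  }
  # a pure-GC chromosome has no motifs and no low-GC regions
  pure <- synth_genome(2000, gc_background = 1, seed = 1)
  expect_equal(nrow(pure$truth$hits), 0L)
  expect_equal(nrow(low_gc_regions(pure$genome, window = 300)), 0L)
})

test_that("synthetic annotations are non-overlapping, stranded and in-region", {
  gen <- synth_genome(60000, seed = 2)
  genes <- synth_annotation(gen$genome, n_genes = 30, min_intergenic = 400,
                            seed = 3)
  expect_equal(nrow(genes), 30L)
  expect_true(all(genes$start[-1] - genes$end[-30] >= 400L))
  expect_true(all(genes$end <= 60000L))
  expect_true(all(genes$strand %in% c("+", "-")))
  # strand fractions within a generous binomial band around 0.5
  expect_gt(mean(genes$strand == "+"), 0.2)
  expect_lt(mean(genes$strand == "+"), 0.8)
  # the GFF3 writer round-trips through the reader
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, f, contig_lengths = c(synth_1 = 60000L))
  back <- read_gene_gff3(f)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$gene_id, genes$gene_id)
})

test_that("synthetic peaks cover exactly the planted motif fraction", {
  for (s in c(4, 9)) {
    gen <- synth_genome(80000, gc_background = 0.72, n_planted_motifs = 150,
                        seed = s)
    pk <- synth_peaks(gen$genome, gen$truth$hits, frac_motifs_covered = 0.6,
                      n_decoys = 30, seed = s + 1)
    occ <- motif_occupancy(gen$truth$hits, pk$peaks)
    expect_equal(occ$n_hits_in_regions, pk$truth$n_covered)
    expect_equal(occ$n_hits_in_regions,
                 round(0.6 * nrow(gen$truth$hits)))
    expect_equal(occ$frac_hits_in_regions, pk$truth$achieved_frac)
    # region-centric accounting: exactly the non-decoy peaks carry a motif
    expect_equal(occ$n_regions_with_hit, sum(pk$truth$is_real))
    # peaks parse back through the narrowPeak reader unchanged
    f <- withr::local_tempfile(fileext = ".narrowPeak")
    write_narrowpeak(pk$peaks, f)
    back <- read_narrowpeak(f)
    expect_equal(back$summit, pk$peaks$summit)
  }
  # frac 0 gives only decoys
  gen <- synth_genome(30000, n_planted_motifs = 40, seed = 10)
  pk0 <- synth_peaks(gen$genome, gen$truth$hits, frac_motifs_covered = 0,
                     n_decoys = 10, seed = 11)
  expect_equal(motif_occupancy(gen$truth$hits, pk0$peaks)$n_hits_in_regions, 0L)
})

test_that("synthetic counts plant the requested expression shift", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                          length = rep(900L, 300))
  sim <- synth_counts(genes, genes$gene_id[1:60], planted_log2fc = 2,
                      n_replicates = 2, seed = 12)
  expect_true(all(sim$counts[[3]] >= 0))
  tp <- tpm(sim$counts)
  avg <- rowMeans(as.matrix(tp[, 3:4]))
  expect_gt(median(avg[1:60]), median(avg[61:300]))
  expect_error(synth_counts(genes, "nope", seed = 1), "subset")
})

test_that("noise-free plate stacks give back the planted transitions exactly", {
  stack <- synth_plate_stack(c(20, 30), frames = 50, noise_sd = 0, seed = 13)
  s <- brightness_series(stack$images, stack$times)
  ev <- transition_times(s)
  expect_equal(ev$time_h[ev$kind == "brightness_peak"], 20)
  expect_equal(ev$time_h[ev$kind == "brightness_trough"], 30)
})

test_that("synthetic spore ratios hit the requested median", {
  sp <- synth_spores(10000, 1.49, seed = 14)
  expect_lt(abs(median(sp$ratio) - 1.49) / 1.49, 0.02)
  expect_true(all(sp$ratio > 0))
  expect_equal(sp$ratio, sp$length / sp$width)
  expect_identical(synth_spores(50, 1.6, seed = 2), synth_spores(50, 1.6, seed = 2))
})
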