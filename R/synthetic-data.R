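# Seeded generators for every input the pipeline consumes, with ground
# truth sufficient to score each stage. Every generator is a pure function
# of (parameters, seed): it seeds the RNG on entry with a fixed generator
# kind, so outputs are byte-identical across runs and platforms.

.set_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Derive a child seed from a master seed
#'
#' Fixed fan-out scheme: `child_seed(seed, k)` is an LCG step of the master
#' seed offset by `k`, reduced modulo `2^31 - 1`. Used by
#' [simulate_study()] to give every generator its own stream.
#'
#' @param seed Master seed (integer).
#' @param k Child index (integer >= 0).
#' @return Integer child seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1664525 + as.numeric(k) * 1013904223) %% 2147483647)
}

# Internal naive scanner: direct window-by-window comparison against the
# expanded word set. Independent of the Biostrings-backed scan_motif path;
# used to establish generator ground truth.
.naive_scan <- function(chars, pattern, dedup = TRUE) {
  words <- expand_iupac(pattern)
  rc_words <- revcomp(words)
  k <- nchar(pattern)
  purrr::imap_dfr(chars, function(seq, ctg) {
    L <- nchar(seq)
    if (L < k) return(NULL)
    st <- seq_len(L - k + 1L)
    sub <- substring(seq, st, st + k - 1L)
    plus <- sub %in% words
    minus <- sub %in% rc_words
    rows <- list()
    if (any(plus)) {
      rows$p <- tibble(contig = ctg, start = st[plus] - 1L,
                       end = st[plus] - 1L + k, strand = "+", word = sub[plus])
    }
    if (any(minus)) {
      keep <- if (dedup) minus & !plus else minus
      if (any(keep)) {
        rows$m <- tibble(contig = ctg, start = st[keep] - 1L,
                         end = st[keep] - 1L + k, strand = "-",
                         word = revcomp(sub[keep]))
      }
    }
    if (length(rows) == 0L) return(NULL)
    bind_rows(rows)
  }) -> res
  if (nrow(res) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), word = character()))
  }
  res %>% arrange(.data$contig, .data$start, .data$strand)
}

#' Generate a synthetic GC-rich chromosome with planted motifs
#'
#' Background bases are drawn i.i.d. at `gc_background`; AT-rich islands are
#' overwritten at their own GC; concrete words of `motif` are written at
#' sampled positions (random strand, non-overlapping, outside islands).
#' Accidental background occurrences of the motif are allowed: the returned
#' truth records the full hit table established by a naive window-by-window
#' rescan, and generation fails if any planted site is missing from it.
#'
#' @param length Chromosome length in bp.
#' @param gc_background Background GC fraction in `[0, 1]` (default 0.72,
#'   the high-GC regime of streptomycete chromosomes).
#' @param islands Optional tibble with `start` (0-based), `length`, `gc`
#'   rows; must be disjoint and inside the chromosome.
#' @param n_planted_motifs Number of motif words to plant.
#' @param motif IUPAC pattern to plant (default `"GATCWT"`).
#' @param min_spacing Minimum distance in bp between planted sites
#'   (default 40).
#' @param motif_region Optional `c(start, end)` (0-based half-open)
#'   restricting where motifs are planted.
#' @param seed RNG seed.
#' @param contig_id Name of the contig.
#' @return List with `genome` (a [Biostrings::DNAStringSet]) and `truth`
#'   (list: `planted` tibble, `hits` tibble from the naive rescan,
#'   `islands`, `seed`).
#' @export
synth_genome <- function(length, gc_background = 0.72, islands = NULL,
                         n_planted_motifs = 0L, motif = "GATCWT",
                         min_spacing = 40L, motif_region = NULL, seed = 1L,
                         contig_id = "synth_1") {
  .set_seed(seed)
  L <- as.integer(length)
  draw <- function(n, gc) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  }
  b <- draw(L, gc_background)
  if (!is.null(islands) && nrow(islands) > 0L) {
    isl <- islands[order(islands$start), , drop = FALSE]
    if (any(isl$start < 0L) || any(isl$start + isl$length > L)) {
      abort("island outside chromosome")
    }
    if (nrow(isl) > 1L &&
        any(isl$start[-1] < (isl$start + isl$length)[-nrow(isl)])) {
      abort("islands must be disjoint")
    }
    for (i in seq_len(nrow(isl))) {
      idx <- (isl$start[i] + 1L):(isl$start[i] + isl$length[i])
      b[idx] <- draw(isl$length[i], isl$gc[i])
    }
  } else {
    isl <- tibble(start = integer(), length = integer(), gc = numeric())
  }

  k <- nchar(motif)
  words <- expand_iupac(motif)
  planted <- tibble(contig = character(), start = integer(), end = integer(),
                    strand = character(), word = character())
  if (n_planted_motifs > 0L) {
    # allowed starts: outside islands (padded by k) and away from other sites
    forbidden <- rep(FALSE, L)
    if (nrow(isl) > 0L) {
      for (i in seq_len(nrow(isl))) {
        lo <- max(1L, isl$start[i] - k + 1L)
        hi <- min(L, isl$start[i] + isl$length[i] + k)
        forbidden[lo:hi] <- TRUE
      }
    }
    forbidden[(L - k + 1L):L] <- TRUE
    if (!is.null(motif_region)) {
      inside <- rep(TRUE, L)
      inside[(motif_region[1] + 1L):motif_region[2]] <- FALSE
      forbidden[inside] <- TRUE
    }
    chosen <- integer(0)
    tries <- 0L
    while (length(chosen) < n_planted_motifs) {
      tries <- tries + 1L
      if (tries > 50L * n_planted_motifs) {
        abort("could not place all motifs: chromosome too crowded")
      }
      cand <- sample.int(L, 1L)
      if (forbidden[cand]) next
      chosen <- c(chosen, cand)
      lo <- max(1L, cand - min_spacing - k)
      hi <- min(L, cand + min_spacing + k)
      forbidden[lo:hi] <- TRUE
    }
    chosen <- sort(chosen)
    w <- sample(words, n_planted_motifs, replace = TRUE)
    strand <- sample(c("+", "-"), n_planted_motifs, replace = TRUE)
    written <- ifelse(strand == "+", w, revcomp(w))
    for (i in seq_len(n_planted_motifs)) {
      b[chosen[i]:(chosen[i] + k - 1L)] <- strsplit(written[i], "")[[1]]
    }
    planted <- tibble(contig = contig_id, start = chosen - 1L,
                      end = chosen - 1L + k, strand = strand, word = w)
  }

  chars <- setNames(paste(b, collapse = ""), contig_id)
  hits <- .naive_scan(chars, motif, dedup = TRUE)
  # every planted interval must be recovered by the oracle rescan
  key <- paste(hits$start, hits$end)
  if (!all(paste(planted$start, planted$end) %in% key)) {
    abort("internal error: planted motif not recovered by naive rescan")
  }
  genome <- Biostrings::DNAStringSet(chars)
  list(genome = genome,
       truth = list(planted = planted, hits = hits, islands = isl,
                    motif = motif, seed = seed))
}

#' Generate a synthetic non-overlapping gene annotation
#'
#' Genes are laid left to right with at least `min_intergenic` bp between
#' consecutive genes (so 400-bp promoter windows never overlap a neighbour's
#' body when the default spacing is kept), strands drawn i.i.d.
#'
#' @param genome Genome (for contig name and length).
#' @param n_genes Number of genes.
#' @param length_range Gene length range in bp (uniform; default 300-1500).
#' @param strand_prob Probability of the `+` strand (default 0.5).
#' @param min_intergenic Minimum gap between genes in bp (default 400).
#' @param region Optional `c(start, end)` (0-based half-open) restricting
#'   where genes are placed.
#' @param seed RNG seed.
#' @return Gene tibble in the [read_gene_gff3()] layout.
#' @export
synth_annotation <- function(genome, n_genes, length_range = c(300L, 1500L),
                             strand_prob = 0.5, min_intergenic = 400L,
                             region = NULL, seed = 1L) {
  .set_seed(seed)
  lens <- .contig_lengths(genome)
  ctg <- names(lens)[1]
  L <- lens[[1]]
  offset <- 0L
  if (!is.null(region)) {
    offset <- as.integer(region[1])
    L <- as.integer(region[2] - region[1])
  }
  glen <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
  budget <- L - sum(glen) - (n_genes + 1L) * min_intergenic
  if (budget < 0) abort("genes do not fit: reduce n_genes or lengths")
  extra <- rexp(n_genes + 1L)
  extra <- floor(extra / sum(extra) * budget * runif(1, 0.5, 0.9))
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    pos <- pos + min_intergenic + as.integer(extra[i])
    starts[i] <- pos
    pos <- pos + glen[i]
  }
  if (pos > L) abort("genes do not fit: internal placement overflow")
  tibble(
    gene_id = sprintf("SYN%04d", seq_len(n_genes)),
    contig = ctg,
    start = starts + offset,
    end = starts + glen + offset,
    strand = sample(c("+", "-"), n_genes, replace = TRUE,
                    prob = c(strand_prob, 1 - strand_prob)),
    feature = "gene",
    product = "synthetic protein"
  )
}

#' Write a gene tibble as GFF3
#'
#' Deterministic writer (records sorted by contig, start; fixed attribute
#' order) so identical inputs give identical bytes.
#'
#' @param genes Gene tibble (0-based half-open coordinates).
#' @param path Output path.
#' @param contig_lengths Optional named lengths for `##sequence-region`
#'   headers.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, contig_lengths = NULL) {
  g <- genes %>% arrange(.data$contig, .data$start)
  lines <- "##gff-version 3"
  if (!is.null(contig_lengths)) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              names(contig_lengths), contig_lengths))
  }
  prod <- if ("product" %in% names(g)) paste0(";product=", g$product) else ""
  lines <- c(lines, sprintf(
    "%s\tnapchip\t%s\t%d\t%d\t.\t%s\t.\tID=%s%s",
    g$contig, if ("feature" %in% names(g)) g$feature else "gene",
    g$start + 1L, g$end, g$strand, g$gene_id, prod
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Generate synthetic peak calls covering a known fraction of motif hits
#'
#' Builds peaks centred on a sampled fraction of the motif hits (summit =
#' motif midpoint) plus motif-free decoys. Construction guarantees the
#' planted coverage exactly: motif hits are grouped into proximity clusters,
#' clusters are selected until exactly `round(frac_motifs_covered * n_hits)`
#' hits are covered, and each peak is trimmed so it never overlaps an
#' unselected hit; decoys never overlap any hit.
#'
#' @param genome Genome (for bounds).
#' @param motif_hits Hit tibble (e.g. the truth `hits` of [synth_genome()]).
#' @param frac_motifs_covered Target fraction of hits covered by peaks.
#' @param width_range Peak width range in bp (uniform draw; realised widths
#'   may be trimmed near foreign hits).
#' @param fe_meanlog,fe_sdlog Log-normal fold-enrichment parameters
#'   (defaults `log(8)`, 0.55, putting roughly one-third of peaks above
#'   10-fold enrichment).
#' @param n_decoys Number of motif-free decoy peaks.
#' @param seed RNG seed.
#' @return List with `peaks` (peak tibble in [read_narrowpeak()] layout) and
#'   `truth` (list: `covered` hit-index vector into `motif_hits`,
#'   `n_covered`, `achieved_frac`, `is_real` flag per peak, `seed`).
#' @export
synth_peaks <- function(genome, motif_hits, frac_motifs_covered = 0.6,
                        width_range = c(150L, 500L), fe_meanlog = log(8),
                        fe_sdlog = 0.55, n_decoys = 40L, seed = 1L) {
  if (frac_motifs_covered < 0 || frac_motifs_covered > 1) {
    abort("frac_motifs_covered must be in [0, 1]")
  }
  .set_seed(seed)
  lens <- .contig_lengths(genome)
  hits <- motif_hits %>% arrange(.data$contig, .data$start)
  n <- nrow(hits)
  m <- round(frac_motifs_covered * n)

  peaks <- list()
  covered_idx <- integer(0)
  if (m > 0L) {
    # proximity clusters: hits closer than 10 bp end-to-start are inseparable
    gap_new <- c(TRUE, hits$start[-1] - hits$end[-n] >= 10L |
                   hits$contig[-1] != hits$contig[-n])
    cl <- cumsum(gap_new)
    cl_sizes <- as.integer(table(cl))
    k_cl <- length(cl_sizes)
    # select clusters summing exactly to m
    ord <- sample.int(k_cl)
    sel <- logical(k_cl)
    need <- m
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 10000L) abort("could not select clusters summing to target")
      cand <- ord[!sel[ord] & cl_sizes[ord] <= need]
      if (length(cand) == 0L) {
        if (need == 0L) break
        drop <- sample(which(sel), 1L)
        sel[drop] <- FALSE
        need <- need + cl_sizes[drop]
        next
      }
      pick <- cand[1]
      sel[pick] <- TRUE
      need <- need - cl_sizes[pick]
      if (need == 0L) break
    }
    sel_cl <- which(sel)
    covered_idx <- which(cl %in% sel_cl)

    unsel <- which(!(cl %in% sel_cl))
    for (ci in sel_cl) {
      members <- which(cl == ci)
      ctg <- hits$contig[members[1]]
      span_s <- min(hits$start[members])
      span_e <- max(hits$end[members])
      # trim limits: nearest unselected hit on each side (same contig)
      u <- unsel[hits$contig[unsel] == ctg]
      left_lim <- max(c(0L, hits$end[u][hits$end[u] <= span_s]))
      right_lim <- min(c(lens[[ctg]], hits$start[u][hits$start[u] >= span_e]))
      w <- sample(width_range[1]:width_range[2], 1L)
      half <- max((w - (span_e - span_s)) %/% 2L, 5L)
      ps <- max(span_s - half, left_lim)
      pe <- min(span_e + half, right_lim)
      anchor <- members[sample.int(length(members), 1L)]
      summit <- (hits$start[anchor] + hits$end[anchor]) %/% 2L
      peaks[[length(peaks) + 1L]] <- tibble(
        contig = ctg, start = ps, end = pe, summit = summit, is_real = TRUE
      )
    }
  }
  # decoys: uniformly placed, overlapping no hit at all
  if (n_decoys > 0L) {
    placed <- 0L
    tries <- 0L
    while (placed < n_decoys) {
      tries <- tries + 1L
      if (tries > 200L * n_decoys) abort("could not place motif-free decoys")
      ctg <- sample(names(lens), 1L)
      w <- sample(width_range[1]:width_range[2], 1L)
      s <- sample.int(lens[[ctg]] - w, 1L) - 1L
      hi <- hits$contig == ctg & hits$start < s + w & hits$end > s
      if (any(hi)) next
      placed <- placed + 1L
      peaks[[length(peaks) + 1L]] <- tibble(
        contig = ctg, start = s, end = s + w,
        summit = s + w %/% 2L, is_real = FALSE
      )
    }
  }
  pk <- bind_rows(peaks) %>% arrange(.data$contig, .data$start)
  pk$name <- sprintf("synthpeak_%04d", seq_len(nrow(pk)))
  pk$fold_enrichment <- rlnorm(nrow(pk), fe_meanlog, fe_sdlog)
  pk$strand <- "."
  pk$p_value <- -1
  pk$q_value <- -1
  pk$summit_imputed <- FALSE
  is_real <- pk$is_real
  pk$is_real <- NULL
  pk <- pk %>% select("name", "contig", "start", "end", "strand",
                      "fold_enrichment", "p_value", "q_value",
                      "summit", "summit_imputed")

  # construction check: covered set must match the selection exactly
  ov <- .overlap_pairs(hits[, c("contig", "start", "end")],
                       pk[, c("contig", "start", "end")])
  if (!identical(sort(unique(ov$query)), sort(covered_idx))) {
    abort("internal error: peak construction violated planted coverage")
  }
  list(peaks = pk,
       truth = list(covered = sort(covered_idx), n_covered = length(covered_idx),
                    achieved_frac = if (n > 0) length(covered_idx) / n else NA_real_,
                    is_real = is_real, seed = seed))
}

#' Plant promoter-bound peaks for a chosen gene set
#'
#' Places one peak per chosen gene with its summit inside the gene's
#' promoter window, rejecting positions whose summit window would also
#' overlap the promoter window of any gene outside the chosen set (so the
#' planted promoter-bound set is exactly `bound_ids`). Optionally avoids a
#' motif-hit table entirely, so adding these peaks to a peak set does not
#' change its motif coverage.
#'
#' @param genes Gene tibble.
#' @param bound_ids Gene ids to bind.
#' @param contig_lengths Named contig lengths.
#' @param flank Summit window flank (default 150).
#' @param upstream,downstream Promoter extent (350/50).
#' @param width_range,fe_meanlog,fe_sdlog Peak geometry/FE as in
#'   [synth_peaks()]; planted promoter peaks draw FE above 10 by default
#'   (`fe_meanlog = log(25)`).
#' @param avoid_hits Optional hit tibble the peaks must not overlap.
#' @param on_fail `"error"` (default) aborts when a gene admits no valid
#'   placement; `"drop"` skips it and records it in the truth as
#'   `unplaced` (the returned `bound_ids` are always the genes actually
#'   bound).
#' @param seed RNG seed.
#' @return List with `peaks` and `truth` (list: `bound_ids`, `unplaced`,
#'   `seed`).
#' @export
synth_promoter_peaks <- function(genes, bound_ids, contig_lengths,
                                 flank = 150L, upstream = 350L,
                                 downstream = 50L, width_range = c(200L, 400L),
                                 fe_meanlog = log(25), fe_sdlog = 0.4,
                                 avoid_hits = NULL,
                                 on_fail = c("error", "drop"), seed = 1L) {
  on_fail <- match.arg(on_fail)
  .set_seed(seed)
  if (!all(bound_ids %in% genes$gene_id)) abort("bound_ids not all in genes")
  prom <- promoter_windows(genes, upstream, downstream, contig_lengths)
  other <- prom[!(prom$gene_id %in% bound_ids), , drop = FALSE]
  res <- list()
  unplaced <- character(0)
  for (gid in bound_ids) {
    pw <- prom[prom$gene_id == gid, , drop = FALSE]
    ok <- FALSE
    for (try in seq_len(300L)) {
      summit <- sample(pw$start:(pw$end - 1L), 1L)
      sw_s <- max(summit - flank, 0L)
      sw_e <- min(summit + flank + 1L, contig_lengths[[pw$contig]])
      clash <- other$contig == pw$contig & other$start < sw_e & other$end > sw_s
      if (any(clash)) next
      # shrink the peak on late retries: a minimal peak still contains the
      # summit, and narrow peaks dodge motif hits in crowded promoters
      w <- if (try > 200L) 10L else if (try > 100L) 50L else {
        sample(width_range[1]:width_range[2], 1L)
      }
      ps <- max(summit - w %/% 2L, 0L)
      pe <- min(ps + w, contig_lengths[[pw$contig]])
      if (pe <= summit) next
      if (!is.null(avoid_hits) && nrow(avoid_hits) > 0L) {
        hit_clash <- avoid_hits$contig == pw$contig &
          avoid_hits$start < pe & avoid_hits$end > ps
        if (any(hit_clash)) next
      }
      res[[gid]] <- tibble(contig = pw$contig, start = ps, end = pe,
                           summit = summit)
      ok <- TRUE
      break
    }
    if (!ok) {
      if (on_fail == "error") {
        abort(paste0("could not place a promoter peak for gene ", gid))
      }
      unplaced <- c(unplaced, gid)
    }
  }
  placed_ids <- setdiff(bound_ids, unplaced)
  if (length(res) == 0L) abort("no promoter peak could be placed at all")
  pk <- bind_rows(res) %>% arrange(.data$contig, .data$start)
  pk$name <- sprintf("prompeak_%04d", seq_len(nrow(pk)))
  pk$fold_enrichment <- rlnorm(nrow(pk), fe_meanlog, fe_sdlog)
  pk$strand <- "."
  pk$p_value <- -1
  pk$q_value <- -1
  pk$summit_imputed <- FALSE
  pk <- pk %>% select("name", "contig", "start", "end", "strand",
                      "fold_enrichment", "p_value", "q_value",
                      "summit", "summit_imputed")

  # independent geometric check of the planted bound set (plain arithmetic)
  bound_check <- character(0)
  for (i in seq_len(nrow(prom))) {
    sw_s <- pmax(pk$summit - flank, 0L)
    sw_e <- pk$summit + flank + 1L
    if (any(pk$contig == prom$contig[i] & sw_s < prom$end[i] & sw_e > prom$start[i])) {
      bound_check <- c(bound_check, prom$gene_id[i])
    }
  }
  # placed peaks may only bind genes from the requested set, and every gene
  # with a placed peak must be bound
  if (!all(bound_check %in% bound_ids) || !all(placed_ids %in% bound_check)) {
    abort("internal error: planted promoter-bound set is not exact")
  }
  list(peaks = pk,
       truth = list(bound_ids = sort(bound_check), unplaced = unplaced,
                    seed = seed))
}

# Geometric ground truth for promoter binding: plain-arithmetic loop over
# genes x peaks (independent of the IRanges-backed assign_binding path).
.bound_truth <- function(genes, peaks, flank = 150L, upstream = 350L,
                         downstream = 50L, contig_lengths = NULL) {
  sw_s <- pmax(peaks$summit - flank, 0L)
  sw_e <- peaks$summit + flank + 1L
  if (!is.null(contig_lengths)) sw_e <- pmin(sw_e, contig_lengths[peaks$contig])
  bound <- character(0)
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+") {
      ps <- genes$start[i] - upstream; pe <- genes$start[i] + downstream
    } else {
      ps <- genes$end[i] - downstream; pe <- genes$end[i] + upstream
    }
    ps <- max(ps, 0L)
    if (any(peaks$contig == genes$contig[i] & sw_s < pe & sw_e > ps)) {
      bound <- c(bound, genes$gene_id[i])
    }
  }
  sort(bound)
}

#' Generate a negative-binomial count matrix with a planted binding bias
#'
#' Per-gene baseline expression is log-normal; genes in `bound_set` have
#' their mean multiplied by `2^planted_log2fc` (negative values plant the
#' suppression seen for promoter-bound genes). Counts are negative binomial
#' with gene-length-proportional means, so TPM recovers the planted
#' expression levels.
#'
#' @param genes Tibble with `gene_id` and either `length` or `start`/`end`.
#' @param bound_set Gene ids carrying the planted effect.
#' @param base_mean Median baseline expression (arbitrary TPM-like units).
#' @param dispersion NB dispersion (`size = 1/dispersion`).
#' @param planted_log2fc Planted log2 shift for bound genes (default 0).
#' @param n_replicates Replicates (columns) to draw (default 3).
#' @param sdlog_baseline Log-sd of the baseline spread (default 1).
#' @param condition Condition label used in column names.
#' @param seed RNG seed.
#' @return List with `counts` (tibble: `gene_id`, `length`, one column per
#'   replicate named `<condition>_rep<i>`) and `truth` (list: `bound_set`,
#'   `planted_log2fc`, `expr` per-gene means, `seed`).
#' @export
synth_counts <- function(genes, bound_set, base_mean = 100, dispersion = 0.2,
                         planted_log2fc = 0, n_replicates = 3L,
                         sdlog_baseline = 1, condition = "cond1", seed = 1L) {
  .set_seed(seed)
  if (!all(bound_set %in% genes$gene_id)) abort("bound_set must be a subset of genes")
  len <- if ("length" %in% names(genes)) genes$length else genes$end - genes$start
  ng <- nrow(genes)
  expr <- rlnorm(ng, log(base_mean), sdlog_baseline)
  bound <- genes$gene_id %in% bound_set
  expr[bound] <- expr[bound] * 2^planted_log2fc
  mu <- expr * len / mean(len)
  out <- tibble(gene_id = genes$gene_id, length = as.integer(len))
  for (i in seq_len(n_replicates)) {
    out[[paste0(condition, "_rep", i)]] <-
      rnbinom(ng, mu = mu, size = 1 / dispersion)
  }
  list(counts = out,
       truth = list(bound_set = sort(bound_set), planted_log2fc = planted_log2fc,
                    expr = setNames(expr, genes$gene_id), seed = seed))
}

#' Generate a synthetic time-lapse plate image stack
#'
#' A radially uniform plate disc whose brightness follows a piecewise-linear
#' curve through the given transition times (alternating peak/trough,
#' starting with a peak), plus i.i.d. Gaussian pixel noise.
#'
#' @param transitions Numeric vector of transition times (hours), strictly
#'   increasing.
#' @param frames Number of frames (hourly from 0).
#' @param noise_sd Pixel noise sd in normalized units (default 0.02).
#' @param dim Image side in pixels (default 64).
#' @param baseline,peak_level Curve levels in normalized units (0.25/0.9).
#' @param seed RNG seed.
#' @return List with `images` (list of `dim` x `dim` matrices, 0-255),
#'   `times` (hours) and `truth` (list: `transitions`, `kinds`, `seed`).
#' @export
synth_plate_stack <- function(transitions, frames = 50L, noise_sd = 0.02,
                              dim = 64L, baseline = 0.25, peak_level = 0.9,
                              seed = 1L) {
  .set_seed(seed)
  if (any(diff(transitions) <= 0)) abort("transitions must be strictly increasing")
  times <- seq(0, frames - 1)
  kinds <- rep(c("brightness_peak", "brightness_trough"),
               length.out = length(transitions))
  levels <- ifelse(kinds == "brightness_peak", peak_level, baseline)
  x <- c(times[1], transitions, times[length(times)])
  y_end <- if (kinds[length(kinds)] == "brightness_peak") baseline else peak_level
  y <- c(baseline, levels, y_end)
  curve <- stats::approx(x, y, xout = times)$y
  center <- (dim + 1) / 2
  d2 <- outer((seq_len(dim) - center)^2, (seq_len(dim) - center)^2, `+`)
  disc <- d2 <= (0.45 * dim)^2
  images <- lapply(seq_along(times), function(i) {
    img <- matrix(20, dim, dim)
    img[disc] <- curve[i] * 255
    img <- img + rnorm(dim * dim, 0, noise_sd * 255)
    pmin(pmax(img, 0), 255)
  })
  list(images = images, times = times,
       truth = list(transitions = transitions, kinds = kinds, seed = seed))
}

#' Generate synthetic spore morphometry
#'
#' Length-to-width ratios are log-normal with the stated median and log-sd;
#' widths are log-normal around a typical streptomycete spore width and
#' lengths follow as `width * ratio`.
#'
#' @param n Number of spores.
#' @param median_ratio Target median ratio (e.g. 1.49 for a wild type,
#'   1.69 for an elongated mutant).
#' @param sigma Log-sd of the ratio distribution (default 0.17).
#' @param width_mean Median spore width in micrometres (default 0.85).
#' @param width_sigma Log-sd of the width distribution (default 0.07).
#' @param seed RNG seed.
#' @return Tibble with `length`, `width` (micrometres) and `ratio`.
#' @export
synth_spores <- function(n, median_ratio, sigma = 0.17, width_mean = 0.85,
                         width_sigma = 0.07, seed = 1L) {
  .set_seed(seed)
  ratio <- rlnorm(n, log(median_ratio), sigma)
  width <- rlnorm(n, log(width_mean), width_sigma)
  tibble(length = width * ratio, width = width, ratio = ratio)
}
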