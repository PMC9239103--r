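#' Build a pipeline configuration
#'
#' Flat, serializable configuration for [run_all()]. All thresholds default
#' to the standard analysis values: promoter window -350/+50, summit flank
#' 150 bp, GC window 300 bp at a 70% threshold, >= 80% low-GC overlap,
#' strong binding above 10-fold enrichment, narrow peaks under 400 bp, ROI
#' at 70% of the plate diameter.
#'
#' @param genome,annotation,counts,de_table,plate_manifest,spores_reference,spores_test
#'   Input file paths (any may be `NULL`; stages needing a missing input
#'   fail by name).
#' @param peaks Named list of narrowPeak paths, one per time point (e.g.
#'   `list(t25h = ..., t48h = ...)`).
#' @param outdir Output directory for reports.
#' @param seed Seed recorded in the run manifest.
#' @param ... Parameter overrides: `motif`, `strands`, `dedup`, `gc_window`,
#'   `gc_threshold`, `lowgc_min_frac`, `promoter_upstream`,
#'   `promoter_downstream`, `summit_flank`, `strong_fe`, `narrow_width`,
#'   `roi_fraction`, `smooth_window`, `min_prominence`.
#' @return A list of class `"napchip_config"`.
#' @export
napchip_config <- function(genome = NULL, annotation = NULL, peaks = list(),
                           counts = NULL, de_table = NULL,
                           plate_manifest = NULL, spores_reference = NULL,
                           spores_test = NULL, outdir = tempdir(),
                           seed = 1L, ...) {
  params <- list(
    motif = "GATCWT", strands = "both", dedup = TRUE,
    gc_window = 300L, gc_threshold = 70, lowgc_min_frac = 0.8,
    promoter_upstream = 350L, promoter_downstream = 50L, summit_flank = 150L,
    strong_fe = 10, narrow_width = 400L,
    roi_fraction = 0.7, smooth_window = 3L, min_prominence = 0.1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(params))
  if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  params[names(over)] <- over
  structure(
    list(paths = list(genome = genome, annotation = annotation, peaks = peaks,
                      counts = counts, de_table = de_table,
                      plate_manifest = plate_manifest,
                      spores_reference = spores_reference,
                      spores_test = spores_test),
         params = params, seed = as.integer(seed), outdir = outdir),
    class = "napchip_config"
  )
}

#' Write / read a configuration as YAML
#'
#' @param config A `napchip_config`.
#' @param path YAML path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- do.call(napchip_config, c(
    x$paths[setdiff(names(x$paths), "peaks")],
    list(peaks = x$paths$peaks, outdir = x$outdir, seed = x$seed),
    x$params
  ))
  cfg
}

#' Simulate a complete synthetic study
#'
#' Writes every input the pipeline consumes, with ground truth, under `dir`:
#' a GC-rich chromosome with AT-rich islands and planted GATCWT sites, a
#' non-overlapping gene annotation, two time points of peak calls (motif
#' peaks covering a known fraction of sites, motif-free decoys, and
#' promoter peaks planted on a known gene set), a negative-binomial count
#' matrix with planted suppression of the bound genes, a fold-change table,
#' spore morphometry for a reference and an elongated test strain, and a
#' time-lapse plate stack with known transition times.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed; each generator receives a [child_seed()].
#' @param preset Only `"paperlike"` is defined: 100-kb chromosome at 72% GC
#'   with three AT-rich islands, 200 planted motifs, 60% of motif sites
#'   covered by peaks, 45 genes of which 18 are promoter-bound, planted
#'   2-fold expression suppression of bound genes, plate transitions at 20 h
#'   and 30 h, spore-ratio medians 1.49 vs 1.69.
#' @param write_images Write the plate PNG frames (default `TRUE`).
#' @return List with `config` (a ready [napchip_config()]) and `truth`.
#' @export
simulate_study <- function(dir, seed = 1L, preset = "paperlike",
                           write_images = TRUE) {
  if (preset != "paperlike") abort("unknown preset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  # the left chromosome arm carries the planted motif field and the AT-rich
  # islands; genes live on the right arm, so promoter binding stays sparse
  # enough for a two-group expression comparison (accidental background
  # motifs near genes are allowed and enter the recorded truth)
  gen <- synth_genome(
    length = 100000L, gc_background = 0.72,
    islands = tibble(start = c(12000L, 30000L, 46000L),
                     length = c(1500L, 2000L, 1200L),
                     gc = c(0.45, 0.40, 0.45)),
    n_planted_motifs = 200L, motif = "GATCWT",
    motif_region = c(0L, 55000L), seed = child_seed(seed, 1L)
  )
  Biostrings::writeXStringSet(gen$genome, p("genome.fasta"))
  lens <- .contig_lengths(gen$genome)

  genes <- synth_annotation(gen$genome, n_genes = 40L,
                            length_range = c(300L, 800L),
                            min_intergenic = 400L,
                            region = c(58000L, 100000L),
                            seed = child_seed(seed, 2L))
  write_gff3(genes, p("annotation.gff3"), contig_lengths = lens)

  .set_seed(child_seed(seed, 3L))
  planted_ids <- sort(sample(genes$gene_id, 12L))

  motif_pk <- synth_peaks(gen$genome, gen$truth$hits,
                          frac_motifs_covered = 0.6, n_decoys = 40L,
                          seed = child_seed(seed, 4L))
  prom_pk <- synth_promoter_peaks(genes, planted_ids, lens,
                                  avoid_hits = gen$truth$hits,
                                  on_fail = "drop",
                                  seed = child_seed(seed, 5L))
  bound_ids <- prom_pk$truth$bound_ids
  peaks_t1 <- bind_rows(motif_pk$peaks, prom_pk$peaks) %>%
    arrange(.data$contig, .data$start)
  peaks_t1$name <- sprintf("peak25_%04d", seq_len(nrow(peaks_t1)))
  # second time point: same binding landscape, jittered boundaries and
  # correlated fold enrichments, a few peaks dropped
  .set_seed(child_seed(seed, 6L))
  keep <- runif(nrow(peaks_t1)) > 0.05
  peaks_t2 <- peaks_t1[keep, , drop = FALSE]
  jit <- function(x, amt) as.integer(x + round(runif(length(x), -amt, amt)))
  peaks_t2$start <- pmax(jit(peaks_t2$start, 20), 0L)
  peaks_t2$end <- pmin(jit(peaks_t2$end, 20), lens[peaks_t2$contig])
  peaks_t2$end <- pmax(peaks_t2$end, peaks_t2$summit + 1L)
  peaks_t2$start <- pmin(peaks_t2$start, peaks_t2$summit)
  peaks_t2$fold_enrichment <- peaks_t2$fold_enrichment * exp(rnorm(nrow(peaks_t2), 0, 0.1))
  peaks_t2$name <- sprintf("peak48_%04d", seq_len(nrow(peaks_t2)))
  write_narrowpeak(peaks_t1, p("peaks_25h.narrowPeak"))
  write_narrowpeak(peaks_t2, p("peaks_48h.narrowPeak"))

  # full geometric truth: motif-centred peaks can fall in promoters too, so
  # the true bound set is a superset of the planted promoter-peak genes
  bound_t1 <- .bound_truth(genes, peaks_t1, contig_lengths = lens)
  bound_t2 <- .bound_truth(genes, peaks_t2, contig_lengths = lens)

  cnt <- synth_counts(genes, bound_t1, base_mean = 100, dispersion = 0.2,
                      planted_log2fc = -1, n_replicates = 3L,
                      condition = "wt_24h", seed = child_seed(seed, 7L))
  readr::write_tsv(cnt$counts, p("counts.tsv"), progress = FALSE)

  .set_seed(child_seed(seed, 8L))
  de <- tibble(
    gene_id = genes$gene_id, condition = "24h",
    log2fc = rnorm(nrow(genes), 0, 0.2) +
      ifelse(genes$gene_id %in% bound_t1, 0.4, 0)
  )
  readr::write_tsv(de, p("de_table.tsv"), progress = FALSE)

  sp_ref <- synth_spores(560L, 1.49, sigma = 0.17, seed = child_seed(seed, 9L))
  sp_test <- synth_spores(332L, 1.69, sigma = 0.22, seed = child_seed(seed, 10L))
  readr::write_csv(sp_ref, p("spores_reference.csv"), progress = FALSE)
  readr::write_csv(sp_test, p("spores_test.csv"), progress = FALSE)

  plate <- synth_plate_stack(c(20, 30), frames = 50L, noise_sd = 0.02,
                             seed = child_seed(seed, 11L))
  manifest <- NULL
  if (write_images) {
    dir.create(p("plate"), showWarnings = FALSE)
    paths <- vapply(seq_along(plate$images), function(i) {
      fp <- p("plate", sprintf("frame_%03d.png", i))
      png::writePNG(plate$images[[i]] / 255, fp)
      fp
    }, character(1))
    manifest <- tibble(path = paths, time_h = plate$times)
    readr::write_csv(manifest, p("plate_manifest.csv"), progress = FALSE)
  }

  truth <- list(
    genome = gen$truth, peaks = motif_pk$truth, promoter = prom_pk$truth,
    planted_promoter_ids = bound_ids,
    bound_ids = bound_t1, bound_ids_t2 = bound_t2,
    counts = cnt$truth,
    plate = plate$truth,
    spores = list(median_ref = 1.49, median_test = 1.69),
    seed = seed
  )
  jsonlite::write_json(
    list(bound_ids = bound_t1, n_motif_hits = nrow(gen$truth$hits),
         n_covered = motif_pk$truth$n_covered,
         achieved_frac = motif_pk$truth$achieved_frac,
         plate_transitions = plate$truth$transitions, seed = seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA
  )

  cfg <- napchip_config(
    genome = p("genome.fasta"), annotation = p("annotation.gff3"),
    peaks = list(t25h = p("peaks_25h.narrowPeak"),
                 t48h = p("peaks_48h.narrowPeak")),
    counts = p("counts.tsv"), de_table = p("de_table.tsv"),
    plate_manifest = if (write_images) p("plate_manifest.csv") else NULL,
    spores_reference = p("spores_reference.csv"),
    spores_test = p("spores_test.csv"),
    outdir = file.path(dir, "reports"), seed = seed
  )
  list(config = cfg, truth = truth)
}

ALL_STAGES <- c("motif", "gc", "peaks", "binding", "expression", "plate", "spores")

#' Run the full analysis pipeline
#'
#' Executes the requested stages against the configured inputs and writes
#' fixed-name reports under `config$outdir`: `motif_occupancy.tsv`,
#' `low_gc_colocalization.tsv`, `common_peaks.tsv`, `gene_binding.tsv`,
#' `expression_bias.tsv`, `spore_morphometry.tsv`,
#' `plate_transitions.csv`, and a `run_manifest.json` recording the
#' configuration hash. Identical configuration and inputs give
#' byte-identical reports.
#'
#' @param config A [napchip_config()].
#' @param stages Stages to run (default: all).
#' @return Named list of the report tibbles, invisibly; reports are written
#'   to `config$outdir`.
#' @export
run_all <- function(config, stages = ALL_STAGES) {
  stages <- match.arg(stages, ALL_STAGES, several.ok = TRUE)
  pp <- config$paths
  pars <- config$params
  need <- function(stage, what, x) {
    if (is.null(x)) abort(paste0("stage '", stage, "': missing input '", what, "'"))
    x
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  genome <- NULL
  peaks <- NULL
  if (any(c("motif", "gc", "peaks", "binding") %in% stages)) {
    genome <- read_genome_fasta(need("motif/gc", "genome", pp$genome))
  }
  if (any(c("motif", "peaks", "binding") %in% stages)) {
    if (length(pp$peaks) == 0L) abort("stage 'peaks': missing input 'peaks'")
    peaks <- lapply(pp$peaks, read_narrowpeak)
  }

  if ("motif" %in% stages) {
    hits <- scan_motif(genome, pars$motif, strands = pars$strands,
                       dedup = pars$dedup)
    occ <- purrr::imap_dfr(peaks, function(pk, tp) {
      motif_occupancy(hits, pk) %>% mutate(time_point = tp, .before = 1)
    })
    out$motif_occupancy <- occ
    readr::write_tsv(occ, file.path(config$outdir, "motif_occupancy.tsv"),
                     progress = FALSE)
  }

  lowgc <- NULL
  if (any(c("gc", "peaks") %in% stages)) {
    lowgc <- low_gc_regions(genome, window = pars$gc_window,
                            threshold = pars$gc_threshold)
  }

  if ("peaks" %in% stages) {
    if (length(peaks) >= 2L) {
      pairs <- common_peaks(peaks[[1]], peaks[[2]])
      r <- if (nrow(pairs) >= 2L) enrichment_correlation(pairs) else NA_real_
      cp <- tibble(
        n_peaks_a = nrow(peaks[[1]]), n_peaks_b = nrow(peaks[[2]]),
        n_common = nrow(pairs),
        frac_common = nrow(pairs) / nrow(peaks[[1]]),
        pearson_fe = r
      )
      common <- peaks[[1]][.peak_names(peaks[[1]]) %in% pairs$name_a, , drop = FALSE]
    } else {
      cp <- tibble(n_peaks_a = nrow(peaks[[1]]), n_peaks_b = NA_integer_,
                   n_common = NA_integer_, frac_common = NA_real_,
                   pearson_fe = NA_real_)
      common <- peaks[[1]]
    }
    out$common_peaks <- cp
    readr::write_tsv(cp, file.path(config$outdir, "common_peaks.tsv"),
                     progress = FALSE)
    narrow <- filter_narrow(common, pars$narrow_width)
    coloc <- colocalize_low_gc(narrow, lowgc, min_frac = pars$lowgc_min_frac) %>%
      mutate(n_common = nrow(common), n_narrow = nrow(narrow), .before = 1)
    out$low_gc_colocalization <- coloc
    readr::write_tsv(coloc, file.path(config$outdir, "low_gc_colocalization.tsv"),
                     progress = FALSE)
  }

  records <- NULL
  if ("binding" %in% stages) {
    genes <- read_gene_gff3(need("binding", "annotation", pp$annotation))
    lens <- .contig_lengths(genome)
    records <- lapply(peaks, function(pk) {
      assign_binding(genes, pk, flank = pars$summit_flank,
                     upstream = pars$promoter_upstream,
                     downstream = pars$promoter_downstream,
                     contig_lengths = lens)
    })
    gb <- purrr::imap_dfr(records, function(r, tp) {
      mutate(r, time_point = tp, .before = 1)
    })
    out$gene_binding <- gb
    readr::write_tsv(gb, file.path(config$outdir, "gene_binding.tsv"),
                     progress = FALSE)
  }

  if ("expression" %in% stages) {
    counts <- readr::read_tsv(need("expression", "counts", pp$counts),
                              show_col_types = FALSE, progress = FALSE)
    if (is.null(records)) {
      abort("stage 'expression': requires stage 'binding' for the bound gene set")
    }
    bound <- records[[1]]$gene_id[records[[1]]$category == "promoter"]
    tp <- tpm(counts)
    sample_cols <- setdiff(names(counts), c("gene_id", "length"))
    samples <- tibble(sample = sample_cols,
                      condition = sub("_rep[0-9]+$", "", sample_cols))
    lfc <- if (!is.null(pp$de_table)) {
      readr::read_tsv(pp$de_table, show_col_types = FALSE, progress = FALSE)
    } else NULL
    bias <- binding_bias_table(tp, bound, samples, log2fc = lfc)
    out$expression_bias <- bias
    readr::write_tsv(bias, file.path(config$outdir, "expression_bias.tsv"),
                     progress = FALSE)
  }

  if ("plate" %in% stages) {
    man <- readr::read_csv(need("plate", "plate_manifest", pp$plate_manifest),
                           show_col_types = FALSE, progress = FALSE)
    series <- brightness_series(man$path, man$time_h,
                                diameter_fraction = pars$roi_fraction)
    ev <- transition_times(series, smooth_window = pars$smooth_window,
                           min_prominence = pars$min_prominence)
    out$plate_transitions <- ev
    readr::write_csv(ev, file.path(config$outdir, "plate_transitions.csv"),
                     progress = FALSE)
    readr::write_csv(tidy(series), file.path(config$outdir, "plate_series.csv"),
                     progress = FALSE)
  }

  if ("spores" %in% stages) {
    ref <- readr::read_csv(need("spores", "spores_reference", pp$spores_reference),
                           show_col_types = FALSE, progress = FALSE)
    tst <- readr::read_csv(need("spores", "spores_test", pp$spores_test),
                           show_col_types = FALSE, progress = FALSE)
    sm <- spore_ratio_compare(ref, tst)
    out$spore_morphometry <- sm
    readr::write_tsv(sm, file.path(config$outdir, "spore_morphometry.tsv"),
                     progress = FALSE)
  }

  manifest <- list(
    package = "napchip",
    version = as.character(utils::packageVersion("napchip")),
    config_hash = rlang::hash(list(config$paths, config$params, config$seed)),
    seed = config$seed,
    stages = stages,
    report_rows = lapply(out, nrow)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
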