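#' Strand-aware promoter windows
#'
#' For a `+` strand gene the promoter window is
#' `[start - upstream, start + downstream)`; for a `-` strand gene it is
#' `[end - downstream, end + upstream)` — i.e. `-upstream` to `+downstream`
#' around the annotated gene start used as a proxy for the transcription
#' start site. Windows are clipped at contig bounds and flagged when
#' truncated.
#'
#' @param genes Gene tibble (see [read_gene_gff3()]).
#' @param upstream,downstream Window extent in bp (defaults 350 and 50).
#' @param contig_lengths Optional named vector of contig lengths for
#'   right-edge clipping.
#' @return Tibble `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `truncated`.
#' @export
promoter_windows <- function(genes, upstream = 350L, downstream = 50L,
                             contig_lengths = NULL) {
  if (any(!genes$strand %in% c("+", "-"))) abort("genes must be stranded (+/-)")
  plus <- genes$strand == "+"
  s <- ifelse(plus, genes$start - upstream, genes$end - downstream)
  e <- ifelse(plus, genes$start + downstream, genes$end + upstream)
  cs <- pmax(s, 0L)
  ce <- if (is.null(contig_lengths)) e else pmin(e, unname(contig_lengths[genes$contig]))
  tibble(
    gene_id = genes$gene_id, contig = genes$contig,
    start = as.integer(cs), end = as.integer(ce), strand = genes$strand,
    truncated = cs != s | ce != e
  )
}

#' Summit windows around peak summits
#'
#' The window `[summit - flank, summit + flank + 1)` covers the summit base
#' plus `flank` bp on each side (301 bp for the default `flank = 150`),
#' clipped at contig bounds.
#'
#' @param peaks Peak tibble with `summit`.
#' @param flank Flank in bp (default 150).
#' @inheritParams promoter_windows
#' @return Tibble `name`, `contig`, `start`, `end`, `summit`, `truncated`.
#' @export
summit_windows <- function(peaks, flank = 150L, contig_lengths = NULL) {
  s <- peaks$summit - flank
  e <- peaks$summit + flank + 1L
  cs <- pmax(s, 0L)
  ce <- if (is.null(contig_lengths)) e else pmin(e, unname(contig_lengths[peaks$contig]))
  tibble(
    name = .peak_names(peaks), contig = peaks$contig,
    start = as.integer(cs), end = as.integer(ce),
    summit = peaks$summit, truncated = cs != s | ce != e
  )
}

#' Assign binding peaks to genes
#'
#' Classifies every gene by where peak summits fall relative to it. A gene
#' is `promoter`-bound iff any summit window ([summit_windows()]) overlaps
#' its promoter window ([promoter_windows()]) by at least 1 bp;
#' `coding_only` iff it is not promoter-bound and a summit window overlaps
#' the coding interval (`+50` from the gene start, strand-aware, to the gene
#' end); `unbound` otherwise. For bound genes the record reports the
#' maximum-fold-enrichment assigned peak: its width, fold enrichment, and
#' strand-aware summit offset relative to the gene start, where `+1` is the
#' first base of the gene and there is no position 0 (`-1` is the base just
#' upstream).
#'
#' @param genes Gene tibble.
#' @param peaks Peak tibble with `summit` and `fold_enrichment`.
#' @param flank Summit window flank (default 150).
#' @param upstream,downstream Promoter extent (defaults 350/50).
#' @param contig_lengths Optional named contig lengths for clipping.
#' @return Tibble with one row per gene: `gene_id`, `category`, `peak_name`,
#'   `binding_width`, `summit_rel`, `fold_enrichment`, `n_promoter_peaks`,
#'   `coding_clipped`. The full gene-by-peak overlap table is attached as
#'   attribute `"provenance"` for audit.
#' @export
assign_binding <- function(genes, peaks, flank = 150L,
                           upstream = 350L, downstream = 50L,
                           contig_lengths = NULL) {
  prom <- promoter_windows(genes, upstream, downstream, contig_lengths)
  sw <- summit_windows(peaks, flank, contig_lengths)

  plus <- genes$strand == "+"
  cod_s <- ifelse(plus, genes$start + downstream, genes$start)
  cod_e <- ifelse(plus, genes$end, genes$end - downstream)
  coding_clipped <- cod_e <= cod_s

  ov_p <- .overlap_pairs(prom[, c("contig", "start", "end")],
                         sw[, c("contig", "start", "end")])
  cod <- tibble(contig = genes$contig,
                start = as.integer(pmin(cod_s, cod_e)),
                end = as.integer(pmax(cod_e, cod_s + 1L)))
  ov_c <- .overlap_pairs(cod[!coding_clipped, , drop = FALSE][, c("contig", "start", "end")],
                         sw[, c("contig", "start", "end")])
  if (nrow(ov_c) > 0L) ov_c$query <- which(!coding_clipped)[ov_c$query]

  prov <- bind_rows(
    if (nrow(ov_p)) mutate(ov_p, region = "promoter") else NULL,
    if (nrow(ov_c)) mutate(ov_c, region = "coding") else NULL
  )
  if (is.null(prov) || nrow(prov) == 0L) {
    prov <- tibble(query = integer(), subject = integer(),
                   overlap_bp = integer(), region = character())
  }
  prov <- prov %>%
    mutate(gene_id = genes$gene_id[.data$query],
           peak_name = sw$name[.data$subject],
           fold_enrichment = peaks$fold_enrichment[.data$subject])

  rel_offset <- function(gi, si) {
    # signed position of summit relative to the gene start on its strand;
    # +1 is the first gene base, there is no 0.
    if (genes$strand[gi] == "+") {
      d <- peaks$summit[si] - genes$start[gi]
      ifelse(d >= 0L, d + 1L, d)
    } else {
      d <- (genes$end[gi] - 1L) - peaks$summit[si]
      ifelse(d >= 0L, d + 1L, d)
    }
  }

  n_genes <- nrow(genes)
  category <- rep("unbound", n_genes)
  peak_name <- rep(NA_character_, n_genes)
  binding_width <- rep(NA_integer_, n_genes)
  summit_rel <- rep(NA_integer_, n_genes)
  fe <- rep(NA_real_, n_genes)
  n_prom <- rep(0L, n_genes)

  pick <- function(df) {
    # max-FE assigned peak, deterministic tie-break on peak start then name
    ord <- order(-df$fold_enrichment, peaks$start[df$subject], df$peak_name)
    df[ord[1], , drop = FALSE]
  }
  prom_hits <- prov[prov$region == "promoter", , drop = FALSE]
  if (nrow(prom_hits) > 0L) {
    for (gi in unique(prom_hits$query)) {
      sub <- prom_hits[prom_hits$query == gi, , drop = FALSE]
      best <- pick(sub)
      category[gi] <- "promoter"
      peak_name[gi] <- best$peak_name
      binding_width[gi] <- as.integer(peaks$end[best$subject] - peaks$start[best$subject])
      summit_rel[gi] <- as.integer(rel_offset(gi, best$subject))
      fe[gi] <- best$fold_enrichment
      n_prom[gi] <- nrow(sub)
    }
  }
  cod_hits <- prov[prov$region == "coding", , drop = FALSE]
  if (nrow(cod_hits) > 0L) {
    for (gi in setdiff(unique(cod_hits$query), which(category == "promoter"))) {
      sub <- cod_hits[cod_hits$query == gi, , drop = FALSE]
      best <- pick(sub)
      category[gi] <- "coding_only"
      peak_name[gi] <- best$peak_name
      binding_width[gi] <- as.integer(peaks$end[best$subject] - peaks$start[best$subject])
      summit_rel[gi] <- as.integer(rel_offset(gi, best$subject))
      fe[gi] <- best$fold_enrichment
    }
  }

  out <- tibble(
    gene_id = genes$gene_id, category = category, peak_name = peak_name,
    binding_width = binding_width, summit_rel = summit_rel,
    fold_enrichment = fe, n_promoter_peaks = n_prom,
    coding_clipped = coding_clipped
  )
  attr(out, "provenance") <- prov %>%
    select("gene_id", "peak_name", "region", "overlap_bp", "fold_enrichment")
  out
}

#' Genes promoter-bound at both time points
#'
#' @param records_t1,records_t2 Outputs of [assign_binding()] over the same
#'   annotation.
#' @return Sorted character vector of gene ids promoter-bound in both.
#' @export
bound_at_both <- function(records_t1, records_t2) {
  sort(intersect(records_t1$gene_id[records_t1$category == "promoter"],
                 records_t2$gene_id[records_t2$category == "promoter"]))
}

#' Fraction of promoter-bound genes with a strong binding event
#'
#' @param records Output of [assign_binding()].
#' @param min_fe Fold-enrichment threshold, strictly exceeded (default 10).
#' @return One-row tibble `n_bound`, `n_strong`, `fraction` (`NA` when no
#'   gene is promoter-bound).
#' @export
strong_bound_fraction <- function(records, min_fe = 10) {
  bound <- records[records$category == "promoter", , drop = FALSE]
  n_strong <- sum(bound$fold_enrichment > min_fe, na.rm = TRUE)
  tibble(
    n_bound = nrow(bound), n_strong = n_strong,
    fraction = if (nrow(bound) > 0L) n_strong / nrow(bound) else NA_real_
  )
}
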