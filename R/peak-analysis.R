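#' Keep strong peaks
#'
#' Filters peaks by fold enrichment with a strict inequality
#' (`fold_enrichment > min_fe`); "strong" binding sites are conventionally
#' those with more than 10-fold enrichment.
#'
#' @param peaks Tibble of peaks with a `fold_enrichment` column.
#' @param min_fe Threshold (default 10); strictly exceeded to keep.
#' @return Filtered tibble, input order preserved.
#' @export
filter_strong <- function(peaks, min_fe = 10) {
  if (!"fold_enrichment" %in% names(peaks)) abort("peaks lack fold_enrichment")
  peaks[peaks$fold_enrichment > min_fe, , drop = FALSE]
}

#' Keep narrow peaks
#'
#' Keeps peaks strictly narrower than `max_width` bp.
#'
#' @param peaks Tibble of peaks with `start`, `end`.
#' @param max_width Width cutoff (default 400); widths `< max_width` kept.
#' @return Filtered tibble, input order preserved.
#' @export
filter_narrow <- function(peaks, max_width = 400) {
  peaks[(peaks$end - peaks$start) < max_width, , drop = FALSE]
}

#' Pair peaks across two samples
#'
#' Matches each peak in `peaks_a` with a peak in `peaks_b`. In
#' `mode = "any_overlap"` each A peak is paired with the B peak of maximal
#' overlap (at least 1 bp; one pair per A peak). In
#' `mode = "summit_in_region"` a pair is formed iff the A summit lies inside
#' the B interval. Ties are broken deterministically by the lowest B start.
#'
#' @param peaks_a,peaks_b Peak tibbles (same genome).
#' @param mode `"any_overlap"` (default) or `"summit_in_region"`.
#' @return Tibble with one row per paired A peak: `name_a`, `name_b`,
#'   `contig`, `overlap_bp`, `fe_a`, `fe_b`.
#' @export
common_peaks <- function(peaks_a, peaks_b,
                         mode = c("any_overlap", "summit_in_region")) {
  mode <- match.arg(mode)
  if (nrow(peaks_a) == 0L || nrow(peaks_b) == 0L) {
    return(tibble(name_a = character(), name_b = character(), contig = character(),
                  overlap_bp = integer(), fe_a = numeric(), fe_b = numeric()))
  }
  qa <- if (mode == "summit_in_region") {
    tibble(contig = peaks_a$contig, start = peaks_a$summit, end = peaks_a$summit + 1L)
  } else {
    peaks_a[, c("contig", "start", "end")]
  }
  ov <- .overlap_pairs(qa, peaks_b[, c("contig", "start", "end")])
  if (nrow(ov) == 0L) {
    return(tibble(name_a = character(), name_b = character(), contig = character(),
                  overlap_bp = integer(), fe_a = numeric(), fe_b = numeric()))
  }
  ov %>%
    mutate(b_start = peaks_b$start[.data$subject]) %>%
    group_by(.data$query) %>%
    arrange(dplyr::desc(.data$overlap_bp), .data$b_start, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    mutate(
      name_a = .peak_names(peaks_a)[.data$query],
      name_b = .peak_names(peaks_b)[.data$subject],
      contig = peaks_a$contig[.data$query],
      overlap_bp = if (mode == "summit_in_region") {
        as.integer(pmin(peaks_a$end[.data$query], peaks_b$end[.data$subject]) -
                     pmax(peaks_a$start[.data$query], peaks_b$start[.data$subject]))
      } else .data$overlap_bp,
      fe_a = peaks_a$fold_enrichment[.data$query],
      fe_b = peaks_b$fold_enrichment[.data$subject]
    ) %>%
    arrange(.data$contig, peaks_a$start[.data$query]) %>%
    select("name_a", "name_b", "contig", "overlap_bp", "fe_a", "fe_b")
}

.peak_names <- function(peaks) {
  if ("name" %in% names(peaks)) peaks$name else paste0("peak_", seq_len(nrow(peaks)))
}

#' Colocalization of peaks with low-GC regions
#'
#' A peak colocalizes with the low-GC landscape iff the fraction of its
#' width covered by the union of low-GC regions is at least `min_frac`
#' (union coverage: overlapping regions are never double-counted).
#'
#' @param peaks Peak tibble.
#' @param low_gc Tibble of low-GC intervals (see [low_gc_regions()]).
#' @param min_frac Minimum covered fraction in `(0, 1]` (default 0.8).
#' @param per_peak Also return the per-peak covered fractions.
#' @return One-row tibble `n_input_peaks`, `n_colocalized`, `fraction`,
#'   `min_frac`; with `per_peak = TRUE` the per-peak tibble is attached as
#'   attribute `"per_peak"`.
#' @export
colocalize_low_gc <- function(peaks, low_gc, min_frac = 0.8, per_peak = FALSE) {
  if (min_frac <= 0 || min_frac > 1) abort("min_frac must be in (0, 1]")
  n <- nrow(peaks)
  covered <- numeric(n)
  if (n > 0L && nrow(low_gc) > 0L) {
    for (ctg in intersect(unique(peaks$contig), unique(low_gc$contig))) {
      pi <- which(peaks$contig == ctg)
      li <- which(low_gc$contig == ctg)
      irp <- IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi])
      irl <- IRanges::reduce(IRanges::IRanges(start = low_gc$start[li] + 1L,
                                              end = low_gc$end[li]))
      ov <- IRanges::findOverlaps(irp, irl)
      if (length(ov) == 0L) next
      w <- IRanges::width(IRanges::pintersect(irp[S4Vectors::queryHits(ov)],
                                              irl[S4Vectors::subjectHits(ov)]))
      covered[pi] <- covered[pi] +
        as.numeric(tapply(w, factor(S4Vectors::queryHits(ov), levels = seq_along(pi)),
                          sum, default = 0))
    }
  }
  frac <- if (n > 0L) covered / (peaks$end - peaks$start) else numeric()
  coloc <- frac >= min_frac
  out <- tibble(
    n_input_peaks = n,
    n_colocalized = sum(coloc),
    fraction = if (n > 0L) sum(coloc) / n else NA_real_,
    min_frac = min_frac
  )
  if (per_peak) {
    attr(out, "per_peak") <- tibble(
      name = .peak_names(peaks), contig = peaks$contig,
      start = peaks$start, end = peaks$end,
      covered_frac = frac, colocalized = coloc
    )
  }
  out
}

#' Fold-enrichment correlation between matched peaks
#'
#' Pearson correlation of fold enrichments across peak pairs produced by
#' [common_peaks()].
#'
#' @param pairs Tibble with `fe_a`, `fe_b` columns.
#' @return Pearson r (scalar). Zero variance on either side gives `NA` with
#'   a warning.
#' @export
enrichment_correlation <- function(pairs) {
  if (nrow(pairs) < 2L) abort("need at least 2 peak pairs")
  if (any(!is.finite(pairs$fe_a)) || any(!is.finite(pairs$fe_b))) {
    abort("non-finite fold enrichment")
  }
  if (sd(pairs$fe_a) == 0 || sd(pairs$fe_b) == 0) {
    warn("zero variance in fold enrichments; correlation undefined")
    return(NA_real_)
  }
  cor(pairs$fe_a, pairs$fe_b, method = "pearson")
}
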