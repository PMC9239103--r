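#' Sliding-window GC content track
#'
#' Computes GC percentage in sliding windows across every contig. The value
#' of a window is `100 * (#G + #C) / (#A + #C + #G + #T)`; `N` bases are
#' excluded from the denominator, and an all-`N` window gets `NA` and is
#' flagged. With `anchor = "left"` windows start at positions
#' `0, step, 2*step, ...` and only full windows are emitted (a contig
#' shorter than the window yields a single truncated, flagged window). With
#' `anchor = "center"` a window is computed per anchored position `p` as
#' `[p - window/2, p + window/2)`, truncated at contig edges.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param window Window width in bp (>= 1).
#' @param step Step between anchored positions in bp (>= 1). Use `step = 1`
#'   for a per-bp track.
#' @param anchor `"left"` (default) or `"center"`.
#' @return Tibble with `contig`, `pos` (anchored 0-based position), `start`,
#'   `end` (realised window, 0-based half-open), `gc` (percent, `NA` for
#'   all-N windows), `truncated`.
#' @export
gc_track <- function(genome, window = 5000L, step = 500L,
                     anchor = c("left", "center")) {
  anchor <- match.arg(anchor)
  if (window < 1L || step < 1L) abort("window and step must be >= 1")
  chars <- .genome_chars(genome)
  purrr::imap_dfr(chars, function(seq, ctg) {
    L <- nchar(seq)
    b <- strsplit(seq, "")[[1]]
    cg <- cumsum(b == "G" | b == "C")
    cn <- cumsum(b != "N")
    # cumulative counts over [s, e) with 0-based s,e
    cnt <- function(cum, s, e) cum[e] - ifelse(s > 0L, cum[s], 0L)
    if (anchor == "left") {
      if (L < window) {
        pos <- 0L
      } else {
        pos <- seq.int(0L, L - window, by = step)
      }
      ws <- pos
      we <- pmin(pos + window, L)
    } else {
      half <- window %/% 2L
      pos <- seq.int(0L, L - 1L, by = step)
      ws <- pmax(pos - half, 0L)
      we <- pmin(pos + (window - half), L)
    }
    gc_n <- cnt(cg, ws, we)
    at_n <- cnt(cn, ws, we)
    tibble(
      contig = ctg, pos = pos, start = ws, end = we,
      gc = ifelse(at_n > 0L, 100 * gc_n / at_n, NA_real_),
      truncated = (we - ws) < window
    )
  })
}

#' Segment a genome into low-GC regions
#'
#' Computes a per-base centered GC track (window `window`, step 1) and merges
#' maximal runs of consecutive positions whose window GC is at or below
#' `threshold` into intervals. Positions whose window is all `N` never enter
#' a region.
#'
#' @inheritParams gc_track
#' @param threshold GC percentage cutoff (default 70): a position belongs to
#'   a low-GC run iff its window GC is `<= threshold`.
#' @param min_length Drop regions shorter than this many bp (default 1).
#' @return Tibble of disjoint, sorted intervals: `contig`, `start`, `end`,
#'   `width`.
#' @export
low_gc_regions <- function(genome, window = 300L, threshold = 70,
                           min_length = 1L, anchor = c("center", "left")) {
  anchor <- match.arg(anchor)
  track <- gc_track(genome, window = window, step = 1L, anchor = anchor)
  track %>%
    group_by(.data$contig) %>%
    group_modify(function(df, key) {
      low <- !is.na(df$gc) & df$gc <= threshold
      if (!any(low)) {
        return(tibble(start = integer(), end = integer(), width = integer()))
      }
      r <- rle(low)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      idx <- which(r$values)
      tibble(
        start = df$pos[starts[idx]],
        end = df$pos[ends[idx]] + 1L
      ) %>% mutate(width = .data$end - .data$start)
    }) %>%
    ungroup() %>%
    filter(.data$width >= min_length) %>%
    arrange(.data$contig, .data$start)
}

#' Plot a GC track
#'
#' Draws the GC landscape as bars around a reference level, the usual display
#' for high-GC genomes: windows above `midline` plot upward, below it
#' downward.
#'
#' @param track Output of [gc_track()].
#' @param midline Reference GC percent (default 70).
#' @return A ggplot object.
#' @export
plot_gc_track <- function(track, midline = 70) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$pos, y = .data$gc - midline)) +
    ggplot2::geom_col(width = max(1, stats::median(diff(track$pos)))) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~contig, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = sprintf("GC%% - %g", midline)) +
    ggplot2::theme_minimal()
}
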