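IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC pattern into concrete words
#'
#' @param pattern A degenerate nucleotide pattern over the IUPAC alphabet,
#'   e.g. `"GATCWT"`.
#' @return Character vector of all concrete A/C/G/T words matching the
#'   pattern; its length is the product of the per-letter degeneracies.
#' @examples
#' expand_iupac("GATCWT") # GATCAT, GATCTT
#' @export
expand_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    abort("pattern must be a single non-empty string")
  }
  letters <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_CODES))
  if (length(bad)) abort(paste0("illegal IUPAC code(s): ", paste(bad, collapse = ", ")))
  sets <- IUPAC_CODES[letters]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  words <- do.call(paste0, rev(grid))
  sort(unique(words))
}

#' Scan a genome exhaustively for an IUPAC motif
#'
#' Tests every window of every contig (both strands by default); overlapping
#' occurrences are all reported — no masking. `N` in the genome matches no
#' motif letter. With `dedup = TRUE`, hits whose (contig, start, end)
#' coincide on both strands (palindromic occurrences) are collapsed to a
#' single `"+"` record.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param pattern IUPAC pattern (see [expand_iupac()]).
#' @param strands `"both"` (default) or `"forward"`.
#' @param dedup Collapse palindromic double-strand hits (default `TRUE`).
#' @return Tibble with columns `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `word` (matched sequence 5'->3' on its own strand), sorted by
#'   (contig, start, strand).
#' @export
scan_motif <- function(genome, pattern, strands = c("both", "forward"),
                       dedup = TRUE) {
  strands <- match.arg(strands)
  words <- expand_iupac(pattern) # validates the pattern
  k <- nchar(pattern)
  chars <- .genome_chars(genome)
  if (any(nchar(chars) < k)) abort("pattern is longer than the shortest contig")
  dna <- Biostrings::DNAStringSet(chars)

  one_strand <- function(pat, strand_label) {
    hits <- Biostrings::vmatchPattern(pat, dna, fixed = "subject")
    purrr::imap_dfr(as.list(hits), function(ir, contig) {
      if (length(ir) == 0L) return(NULL)
      st <- BiocGenerics::start(ir) - 1L
      sub <- substring(chars[[contig]], st + 1L, st + k)
      tibble(
        contig = contig, start = st, end = st + k,
        strand = strand_label,
        word = if (strand_label == "+") sub else revcomp(sub)
      )
    })
  }

  res <- one_strand(pattern, "+")
  if (strands == "both") {
    rc_pat <- .revcomp_iupac(pattern)
    res <- bind_rows(res, one_strand(rc_pat, "-"))
  }
  if (nrow(res) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), word = character()))
  }
  if (dedup) {
    res <- res %>%
      group_by(.data$contig, .data$start, .data$end) %>%
      arrange(.data$strand, .by_group = TRUE) %>%
      slice(1L) %>%
      ungroup()
  }
  res %>% arrange(.data$contig, .data$start, .data$strand)
}

# Reverse complement of an IUPAC pattern (complement table over codes).
.revcomp_iupac <- function(pattern) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(pattern))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Count motif occurrences
#'
#' `count_motif(...)` equals `nrow(scan_motif(...))`.
#'
#' @inheritParams scan_motif
#' @return Integer count.
#' @export
count_motif <- function(genome, pattern, strands = c("both", "forward"),
                        dedup = TRUE) {
  nrow(scan_motif(genome, pattern, strands = strands, dedup = dedup))
}

#' Motif occupancy of a region set
#'
#' Accounts, in both directions, for how motif hits and regions (typically
#' ChIP peak calls) cover one another: the fraction of hits lying in a
#' region, and the fraction of regions containing at least one hit. A hit is
#' "in" a region if it overlaps the region by at least 1 bp
#' (`mode = "any"`), or only if fully contained (`mode = "within"`).
#'
#' @param hits Tibble of motif hits (from [scan_motif()]).
#' @param regions Tibble of intervals with `contig`, `start`, `end`.
#' @param mode `"any"` (default, >= 1 bp overlap) or `"within"` (full
#'   containment).
#' @return One-row tibble: `n_hits_total`, `n_hits_in_regions`,
#'   `frac_hits_in_regions`, `n_regions`, `n_regions_with_hit`,
#'   `frac_regions_with_hit`.
#' @export
motif_occupancy <- function(hits, regions, mode = c("any", "within")) {
  mode <- match.arg(mode)
  n_hits <- nrow(hits)
  n_regions <- nrow(regions)
  if (n_hits > 0L && n_regions > 0L &&
      length(intersect(unique(hits$contig), unique(regions$contig))) == 0L) {
    abort("motif_occupancy: hits and regions share no contig (contig mismatch)")
  }
  if (n_hits == 0L || n_regions == 0L) {
    return(tibble(
      n_hits_total = n_hits, n_hits_in_regions = 0L,
      frac_hits_in_regions = if (n_hits > 0L) 0 else NA_real_,
      n_regions = n_regions, n_regions_with_hit = 0L,
      frac_regions_with_hit = if (n_regions > 0L) 0 else NA_real_
    ))
  }
  ov <- .overlap_pairs(hits, regions, type = if (mode == "within") "within" else "any")
  tibble(
    n_hits_total = n_hits,
    n_hits_in_regions = length(unique(ov$query)),
    frac_hits_in_regions = length(unique(ov$query)) / n_hits,
    n_regions = n_regions,
    n_regions_with_hit = length(unique(ov$subject)),
    frac_regions_with_hit = length(unique(ov$subject)) / n_regions
  )
}

# Overlap pairs between two interval tibbles (0-based half-open), via
# IRanges per shared contig. Returns tibble(query, subject, overlap_bp)
# of row indices into x and y.
.overlap_pairs <- function(x, y, type = "any", minoverlap = 1L) {
  res <- list()
  for (ctg in intersect(unique(x$contig), unique(y$contig))) {
    xi <- which(x$contig == ctg)
    yi <- which(y$contig == ctg)
    irx <- IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi])
    iry <- IRanges::IRanges(start = y$start[yi] + 1L, end = y$end[yi])
    ov <- IRanges::findOverlaps(irx, iry, type = type, minoverlap = minoverlap)
    if (length(ov) == 0L) next
    qi <- xi[S4Vectors::queryHits(ov)]
    si <- yi[S4Vectors::subjectHits(ov)]
    wbp <- IRanges::width(IRanges::pintersect(irx[S4Vectors::queryHits(ov)],
                                              iry[S4Vectors::subjectHits(ov)]))
    res[[ctg]] <- tibble(query = qi, subject = si, overlap_bp = wbp)
  }
  if (length(res) == 0L) {
    return(tibble(query = integer(), subject = integer(), overlap_bp = integer()))
  }
  bind_rows(res)
}
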