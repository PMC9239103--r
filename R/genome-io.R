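#' Read a genome from a FASTA file
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet].
#' Sequences are uppercased and `U` is mapped to `T`. Ambiguity codes other
#' than `N` are rejected by default, or collapsed to `N` with
#' `ambiguity = "to_n"`.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity Either `"error"` (default) or `"to_n"`. Governs how IUPAC
#'   ambiguity letters other than `N` in the input are treated.
#' @return A named [Biostrings::DNAStringSet]; names are contig ids.
#' @export
read_genome_fasta <- function(path, ambiguity = c("error", "to_n")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("FASTA parse error in '", path, "': ", conditionMessage(e)))
  )
  if (length(seqs) == 0L) abort(paste0("FASTA file '", path, "' contains no records"))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate contig id(s) in '", path, "': ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  chars <- toupper(as.character(seqs))
  chars <- chartr("U", "T", chars)
  bad <- gsub("[ACGTN]", "", chars)
  if (any(nchar(bad) > 0L)) {
    letters_seen <- sort(unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
    if (ambiguity == "error") {
      first_bad <- which(nchar(bad) > 0L)[1]
      abort(paste0("illegal character(s) ", paste(letters_seen, collapse = ""),
                   " in record '", ids[first_bad], "' of '", path,
                   "' (use ambiguity = \"to_n\" to mask IUPAC codes)"))
    }
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
    if (!all(letters_seen %in% iupac)) {
      abort(paste0("non-nucleotide character(s) in '", path, "': ",
                   paste(setdiff(letters_seen, iupac), collapse = "")))
    }
    chars <- chartr(paste(iupac, collapse = ""), strrep("N", length(iupac)), chars)
  }
  if (any(nchar(chars) == 0L)) {
    abort(paste0("empty record(s) in '", path, "': ",
                 paste(ids[nchar(chars) == 0L], collapse = ", ")))
  }
  genome <- Biostrings::DNAStringSet(chars)
  names(genome) <- ids
  genome
}

# Normalize a genome argument to a named uppercase character vector.
.genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet") || methods::is(genome, "BStringSet")) {
    x <- as.character(genome)
  } else if (is.character(genome)) {
    x <- toupper(genome)
  } else {
    abort("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    if (length(x) == 1L) names(x) <- "contig_1" else abort("genome contigs must be named")
  }
  bad <- gsub("[ACGTN]", "", x)
  if (any(nchar(bad) > 0L)) abort("genome contains characters outside {A,C,G,T,N}")
  x
}

.contig_lengths <- function(genome) {
  x <- .genome_chars(genome)
  setNames(nchar(x), names(x))
}

#' Reverse complement of nucleotide sequences
#'
#' @param seq Character vector over the alphabet `{A,C,G,T,N}` (lowercase
#'   accepted).
#' @return Character vector of reverse complements (uppercase).
#' @examples
#' revcomp("GATCAT") # "ATGATC"
#' @export
revcomp <- function(seq) {
  if (!is.character(seq)) abort("seq must be a character vector")
  up <- toupper(seq)
  if (any(nchar(gsub("[ACGTN]", "", up)) > 0L)) {
    abort("revcomp: illegal character (alphabet is A,C,G,T,N)")
  }
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Read a GFF3 gene annotation
#'
#' Parses a GFF3 file into a tibble of gene models. Coordinates are converted
#' from GFF's 1-based inclusive convention to the package-internal 0-based
#' half-open convention (`start = gff_start - 1`, `end = gff_end`).
#'
#' @param path Path to a GFF3 file.
#' @param features Feature types to keep (default `c("gene","CDS","tRNA")`).
#'   Records of other types are dropped silently.
#' @param require_strand Genes must be stranded; a `.` strand raises an error
#'   unless this is `FALSE`.
#' @return A tibble with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `feature`, `product`.
#' @export
read_gene_gff3 <- function(path, features = c("gene", "CDS", "tRNA"),
                           require_strand = TRUE) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste0("GFF3 parse error in '", path, "': ", conditionMessage(e)))
  )
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  keep <- type %in% features
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) abort(paste0("no features of type ", paste(features, collapse = "/"),
                                     " in '", path, "'"))
  ids <- if ("ID" %in% colnames(meta)) as.character(meta$ID) else NA_character_
  if (all(is.na(ids)) && "Name" %in% colnames(meta)) ids <- as.character(meta$Name)
  if (any(is.na(ids))) {
    abort(paste0("record(s) without ID attribute in '", path, "' (record ",
                 paste(which(is.na(ids)), collapse = ","), ")"))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate feature id(s) in '", path, "': ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (require_strand && any(strand == "*")) {
    bad <- which(strand == "*")[1]
    abort(paste0("unstranded gene record in '", path, "': '", ids[bad],
                 "' (record ", bad, ")"))
  }
  product <- if ("product" %in% colnames(meta)) as.character(meta$product) else NA_character_
  tibble(
    gene_id = ids,
    contig  = as.character(GenomicRanges::seqnames(gr)),
    start   = BiocGenerics::start(gr) - 1L,
    end     = BiocGenerics::end(gr),
    strand  = strand,
    feature = type[keep],
    product = product
  ) %>% arrange(.data$contig, .data$start)
}

#' Read ENCODE narrowPeak peak calls
#'
#' Reads a MACS2-style narrowPeak (BED6+4) file into a tibble of peaks.
#' Column 7 (signalValue) is used as the fold enrichment by default; column
#' 10 is the summit offset from the peak start. An offset of `-1` (summit not
#' called) is replaced by the interval midpoint (floor) and flagged in
#' `summit_imputed`.
#'
#' @param path Path to a narrowPeak file (no header).
#' @param fe_column Which column holds fold enrichment: `"signalValue"`
#'   (column 7, default), `"pValue"` or `"qValue"`.
#' @return A tibble with columns `name`, `contig`, `start`, `end`, `strand`,
#'   `fold_enrichment`, `p_value`, `q_value`, `summit`, `summit_imputed`.
#'   Coordinates 0-based half-open; `summit` is an absolute 0-based position.
#' @export
read_narrowpeak <- function(path, fe_column = c("signalValue", "pValue", "qValue")) {
  fe_column <- match.arg(fe_column)
  if (!file.exists(path)) abort(paste0("narrowPeak file not found: ", path))
  cols <- c("contig", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  df <- tryCatch(
    readr::read_tsv(path, col_names = cols,
                    col_types = "ciicncnnni", progress = FALSE),
    error = function(e) abort(paste0("narrowPeak parse error in '", path, "': ",
                                     conditionMessage(e)))
  )
  if (nrow(df) == 0L) abort(paste0("narrowPeak file '", path, "' is empty"))
  if (any(is.na(df$start) | is.na(df$end) | is.na(df$signalValue) | is.na(df$peak))) {
    abort(paste0("non-numeric coordinate/signal/summit column in '", path, "' (row ",
                 which(is.na(df$start) | is.na(df$end) | is.na(df$signalValue) | is.na(df$peak))[1],
                 ")"))
  }
  if (any(df$end <= df$start)) {
    abort(paste0("interval with end <= start in '", path, "' (row ",
                 which(df$end <= df$start)[1], ")"))
  }
  width <- df$end - df$start
  if (any(df$peak >= width)) {
    abort(paste0("summit offset >= peak width in '", path, "' (row ",
                 which(df$peak >= width)[1], ")"))
  }
  if (any(df$peak < -1L)) {
    abort(paste0("summit offset < -1 in '", path, "' (row ", which(df$peak < -1L)[1], ")"))
  }
  imputed <- df$peak == -1L
  summit <- ifelse(imputed, df$start + width %/% 2L, df$start + df$peak)
  fe <- df[[fe_column]]
  tibble(
    name = df$name,
    contig = df$contig,
    start = df$start,
    end = df$end,
    strand = df$strand,
    fold_enrichment = fe,
    p_value = df$pValue,
    q_value = df$qValue,
    summit = as.integer(summit),
    summit_imputed = imputed
  ) %>% arrange(.data$contig, .data$start)
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_narrowpeak()]: writes a tibble of peaks (0-based
#' half-open, absolute summit) as ENCODE narrowPeak with deterministic
#' (contig, start) ordering.
#'
#' @param peaks Tibble with columns `contig`, `start`, `end`, `name`,
#'   `fold_enrichment`, `summit`; optional `strand`, `p_value`, `q_value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  p <- peaks %>% arrange(.data$contig, .data$start)
  strand <- if ("strand" %in% names(p)) p$strand else "."
  out <- data.frame(
    contig = p$contig, start = p$start, end = p$end,
    name = if ("name" %in% names(p)) p$name else paste0("peak_", seq_len(nrow(p))),
    score = 0L, strand = strand,
    signalValue = p$fold_enrichment,
    pValue = if ("p_value" %in% names(p)) p$p_value else -1,
    qValue = if ("q_value" %in% names(p)) p$q_value else -1,
    peak = p$summit - p$start
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param x Tibble with `contig`, `start`, `end`; optional `name`, `score`,
#'   `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- x %>% arrange(.data$contig, .data$start)
  out <- data.frame(
    contig = x$contig, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0L,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a per-window track as bedGraph
#'
#' @param track Tibble with `contig`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default `"gc"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "gc") {
  t <- track %>% arrange(.data$contig, .data$start)
  out <- data.frame(contig = t$contig, start = t$start, end = t$end, value = t[[value]])
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Length of a 1-based inclusive coordinate range
#'
#' Report-boundary helper: GenBank/GFF-style ranges are 1-based inclusive, so
#' the span `a..b` contains `b - a + 1` bases.
#'
#' @param first,last 1-based inclusive endpoints.
#' @return Integer width(s).
#' @examples
#' inclusive_length(5052200, 5052548) # 349
#' @export
inclusive_length <- function(first, last) {
  if (any(last < first)) abort("last < first in 1-based inclusive range")
  as.integer(last - first + 1)
}
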