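# Independent oracles used to freeze expected values. These deliberately
# use the slowest, most literal formulation (per-window loops, pair
# counting) and share no code with the package implementation.

# Naive per-window motif scan: test every window of every contig on both
# strands against the IUPAC pattern, letter by letter.
oracle_scan <- function(chars, pattern, strands = "both", dedup = TRUE) {
  code <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  pat <- strsplit(toupper(pattern), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  k <- length(pat)
  rows <- list()
  for (ctg in names(chars)) {
    s <- strsplit(chars[[ctg]], "")[[1]]
    L <- length(s)
    for (i in seq_len(L - k + 1L)) {
      win <- s[i:(i + k - 1L)]
      fwd <- all(vapply(seq_len(k), function(j) win[j] %in% code[[pat[j]]], logical(1)))
      rcwin <- rev(unname(comp[win]))
      rev_ <- all(vapply(seq_len(k), function(j) rcwin[j] %in% code[[pat[j]]], logical(1)))
      if (fwd) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = i - 1L, end = i - 1L + k, strand = "+",
          word = paste(win, collapse = ""), stringsAsFactors = FALSE)
      }
      if (strands == "both" && rev_ && !(dedup && fwd)) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = i - 1L, end = i - 1L + k, strand = "-",
          word = paste(rcwin, collapse = ""), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), word = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# Random test sequence at a given GC fraction.
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Per-bp union coverage of an interval by a region set (same contig).
oracle_union_coverage <- function(start, end, reg_starts, reg_ends) {
  pos <- start:(end - 1L)
  cov <- rep(FALSE, length(pos))
  for (i in seq_along(reg_starts)) {
    cov <- cov | (pos >= reg_starts[i] & pos < reg_ends[i])
  }
  sum(cov)
}

# Whole-sequence GC percent by direct counting.
oracle_gc <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  s <- s[s != "N"]
  100 * sum(s %in% c("G", "C")) / length(s)
}
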