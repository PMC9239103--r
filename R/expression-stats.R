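#' Transcripts per million (TPM)
#'
#' Length-normalizes counts per sample: `rate_g = count_g / length_g`,
#' `TPM_g = 1e6 * rate_g / sum(rate)`. Every sample column of the result
#' sums to `1e6` (up to floating-point error). An all-zero sample is
#' undefined: its TPMs are `NaN` and a warning names it.
#'
#' @param counts Tibble with a gene id column, a gene length column (bp) and
#'   one numeric column of non-negative counts per sample.
#' @param gene_col,length_col Names of the id and length columns (defaults
#'   `"gene_id"`, `"length"`).
#' @return Tibble of the same shape with counts replaced by TPM values.
#' @export
tpm <- function(counts, gene_col = "gene_id", length_col = "length") {
  if (!all(c(gene_col, length_col) %in% names(counts))) {
    abort(paste0("counts must have '", gene_col, "' and '", length_col, "' columns"))
  }
  len <- counts[[length_col]]
  if (any(len <= 0)) abort("gene lengths must be > 0")
  sample_cols <- setdiff(names(counts), c(gene_col, length_col))
  if (length(sample_cols) == 0L) abort("no sample columns found")
  out <- counts
  dead <- character()
  for (s in sample_cols) {
    cts <- counts[[s]]
    if (any(cts < 0)) abort(paste0("negative counts in sample '", s, "'"))
    rate <- cts / len
    tot <- sum(rate)
    if (tot == 0) dead <- c(dead, s)
    out[[s]] <- 1e6 * rate / tot
  }
  if (length(dead)) warn(paste0("all-zero sample(s), TPM undefined: ",
                                paste(dead, collapse = ", ")))
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two samples. The U
#' statistic counts pairs `(a_i, b_j)` with `a_i > b_j`, ties counting one
#' half. For tie-free data with `n1 + n2 <= exact_limit` the p-value comes
#' from the exact U distribution; otherwise from the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @param exact_limit Largest `n1 + n2` for which the exact tie-free
#'   distribution is used (default 12).
#' @return An object of class `"mw_test"`; see [tidy.mw_test()].
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1 (exact)
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "greater", "less"),
                           exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) abort("non-finite values")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1L)

  if (!has_ties && N <= exact_limit) {
    method <- "exact"
    p_le <- pwilcox(U, n1, n2)
    p_ge <- 1 - pwilcox(U - 1, n1, n2)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le
    )
  } else {
    method <- if (has_ties) "normal-approx tie-corrected" else "normal-approx"
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      # all observations identical
      p <- 1
      z <- 0
    } else {
      sigma <- sqrt(sigma2)
      z <- switch(alternative,
        two.sided = (U - mu - sign(U - mu) * 0.5) / sigma,
        greater = (U - mu - 0.5) / sigma,
        less = (U - mu + 0.5) / sigma
      )
      p <- switch(alternative,
        two.sided = min(1, 2 * pnorm(-abs(z))),
        greater = pnorm(z, lower.tail = FALSE),
        less = pnorm(z)
      )
    }
  }
  structure(
    list(statistic = U, p_value = p, n1 = n1, n2 = n2,
         alternative = alternative, method = method),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat("U = ", format(x$statistic), ", n = ", x$n1, "/", x$n2,
      ", p = ", format.pval(x$p_value, digits = 3), " (", x$alternative, ")\n",
      sep = "")
  invisible(x)
}

#' Tidy a Mann-Whitney test
#'
#' @param x An `"mw_test"` object.
#' @param ... Unused.
#' @return One-row tibble `statistic`, `p_value`, `n1`, `n2`, `method`,
#'   `alternative`.
#' @export
tidy.mw_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n1 = x$n1, n2 = x$n2,
         method = x$method, alternative = x$alternative)
}

#' @rdname tidy.mw_test
#' @export
glance.mw_test <- function(x, ...) tidy(x, ...)

#' Levene's test for equality of variances (two groups)
#'
#' Classic Levene: absolute deviations from the group center (mean by
#' default, median for the Brown-Forsythe variant) are compared between
#' groups with a one-way ANOVA F statistic `W` on `(1, n1 + n2 - 2)` degrees
#' of freedom.
#'
#' Degenerate inputs are flagged: if all deviations are equal in both groups
#' `W = 0`, `p = 1`; if deviations are constant within groups but differ
#' between them the F ratio is infinite (`W = Inf`, `p = 0`).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param center `"mean"` (default) or `"median"`.
#' @return An object of class `"levene_test"` with fields `statistic` (W),
#'   `p_value`, `df`, `n1`, `n2`, `center`, `degenerate`.
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(a) < 2L || length(b) < 2L) abort("each group needs n >= 2")
  cf <- if (center == "mean") mean else median
  za <- abs(a - cf(a)); zb <- abs(b - cf(b))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  z <- c(za, zb); g <- factor(rep(c("a", "b"), c(n1, n2)))
  ssb <- n1 * (mean(za) - mean(z))^2 + n2 * (mean(zb) - mean(z))^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  degenerate <- ssw == 0
  if (degenerate) {
    W <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    fit <- stats::anova(stats::lm(z ~ g))
    W <- fit[["F value"]][1]
    p <- fit[["Pr(>F)"]][1]
  }
  structure(
    list(statistic = W, p_value = p, df = c(1L, N - 2L), n1 = n1, n2 = n2,
         center = center, degenerate = degenerate),
    class = "levene_test"
  )
}

#' @export
print.levene_test <- function(x, ...) {
  cat("Levene's test (center = ", x$center, ")\n", sep = "")
  cat("W = ", format(x$statistic), " on (", x$df[1], ", ", x$df[2],
      ") df, p = ", format.pval(x$p_value, digits = 3),
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a Levene test
#'
#' @param x A `"levene_test"` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.levene_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         df1 = x$df[1], df2 = x$df[2], n1 = x$n1, n2 = x$n2,
         center = x$center, degenerate = x$degenerate)
}

#' @rdname tidy.levene_test
#' @export
glance.levene_test <- function(x, ...) tidy(x, ...)

#' Binding-versus-expression bias table
#'
#' For each condition, compares the expression of promoter-bound genes
#' against all other genes (genes with no binding at all, or binding only
#' outside the promoter) with a Mann-Whitney U test. Expression is
#' replicate-averaged TPM; optionally, rows comparing an externally supplied
#' log2 fold change are appended (the differential-expression model is
#' consumed, never refit).
#'
#' @param tpm_tbl TPM tibble from [tpm()] (gene id + length + sample
#'   columns).
#' @param bound_genes Character vector of promoter-bound gene ids.
#' @param samples Tibble mapping `sample` (column name in `tpm_tbl`) to
#'   `condition` labels; replicates share a condition.
#' @param log2fc Optional tibble with `gene_id`, `condition`, `log2fc` rows
#'   to test the same bias on fold changes.
#' @param universe Optional character vector restricting the analysed gene
#'   set (defaults to all genes in `tpm_tbl`; the log2fc rows use all genes
#'   present in `log2fc` intersected with this universe).
#' @param gene_col,length_col Column names in `tpm_tbl`.
#' @return Tibble with one row per condition and metric: `metric`,
#'   `condition`, `n_bound`, `n_other`, `mean_bound`, `mean_other`,
#'   `median_bound`, `median_other`, `statistic` (U), `p_value`,
#'   `degenerate`.
#' @export
binding_bias_table <- function(tpm_tbl, bound_genes, samples, log2fc = NULL,
                               universe = NULL, gene_col = "gene_id",
                               length_col = "length") {
  if (length(bound_genes) == 0L) abort("bound gene set is empty")
  genes_all <- tpm_tbl[[gene_col]]
  if (is.null(universe)) universe <- genes_all
  universe <- intersect(universe, genes_all)
  bound <- intersect(bound_genes, universe)
  if (length(bound) == 0L) abort("no bound gene is in the analysed universe")
  other <- setdiff(universe, bound)

  one_row <- function(vals_bound, vals_other, metric, condition) {
    degenerate <- length(vals_other) < 2L || length(vals_bound) < 2L
    mw <- if (degenerate) NULL else mann_whitney_u(vals_bound, vals_other)
    tibble(
      metric = metric, condition = condition,
      n_bound = length(vals_bound), n_other = length(vals_other),
      mean_bound = mean(vals_bound), mean_other = mean(vals_other),
      median_bound = median(vals_bound), median_other = median(vals_other),
      statistic = if (degenerate) NA_real_ else mw$statistic,
      p_value = if (degenerate) NA_real_ else mw$p_value,
      degenerate = degenerate
    )
  }

  rows <- list()
  if (!is.null(samples)) {
    missing_s <- setdiff(samples$sample, names(tpm_tbl))
    if (length(missing_s)) {
      abort(paste0("sample(s) not in tpm table: ", paste(missing_s, collapse = ", ")))
    }
    idx <- match(universe, genes_all)
    for (cond in unique(samples$condition)) {
      cols <- samples$sample[samples$condition == cond]
      m <- as.matrix(tpm_tbl[idx, cols, drop = FALSE])
      avg <- rowMeans(m)
      names(avg) <- universe
      rows[[length(rows) + 1L]] <-
        one_row(avg[bound], avg[other], "tpm", cond)
    }
  }
  if (!is.null(log2fc)) {
    for (cond in unique(log2fc$condition)) {
      sub <- log2fc[log2fc$condition == cond, , drop = FALSE]
      uni_fc <- intersect(sub$gene_id, union(bound, other))
      v <- setNames(sub$log2fc, sub$gene_id)[uni_fc]
      b <- v[names(v) %in% bound]; o <- v[!(names(v) %in% bound)]
      rows[[length(rows) + 1L]] <- one_row(b, o, "log2fc", cond)
    }
  }
  if (length(rows) == 0L) abort("neither samples nor log2fc provided")
  bind_rows(rows)
}

#' Compare spore length-to-width ratios between two strains
#'
#' Mirrors the standard spore-morphometry comparison: per-spore ratio
#' (length/width), its median and sample variance per strain, a Mann-Whitney
#' U test of location against the reference, and Levene's test of equal
#' variance.
#'
#' @param reference,test Tibbles with per-spore `length` and `width` columns
#'   (same units, e.g. micrometres), or a precomputed `ratio` column.
#' @return One-row tibble: `n_ref`, `n_test`, `median_ref`, `median_test`,
#'   `u_statistic`, `u_p_value`, `var_ref`, `var_test`, `levene_w`,
#'   `levene_p_value`.
#' @export
spore_ratio_compare <- function(reference, test) {
  ratio_of <- function(df, label) {
    if ("ratio" %in% names(df)) return(df$ratio)
    if (!all(c("length", "width") %in% names(df))) {
      abort(paste0(label, " needs length+width or ratio columns"))
    }
    if (any(df$width <= 0) || any(df$length <= 0)) {
      abort(paste0("non-positive spore dimension in ", label))
    }
    df$length / df$width
  }
  r_ref <- ratio_of(reference, "reference")
  r_test <- ratio_of(test, "test")
  if (length(r_ref) < 2L || length(r_test) < 2L) abort("each strain needs n >= 2 spores")
  mw <- mann_whitney_u(r_test, r_ref)
  lv <- levene_test(r_test, r_ref)
  tibble(
    n_ref = length(r_ref), n_test = length(r_test),
    median_ref = median(r_ref), median_test = median(r_test),
    u_statistic = mw$statistic, u_p_value = mw$p_value,
    var_ref = var(r_ref), var_test = var(r_test),
    levene_w = lv$statistic, levene_p_value = lv$p_value
  )
}
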