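# Pairwise differential expression between two pooled libraries: TPM
# normalization, log2 fold change with a zero-count pseudocount, and the
# Audic-Claverie count-ratio P-value.

#' TPM normalization
#'
#' @param count raw read count (>= 0).
#' @param library_total total high-quality (or novel) read count (> 0).
#' @return normalized expression in transcripts per million.
#' @export
normalize_tpm <- function(count, library_total) {
  if (any(count < 0)) stop("negative count")
  stopifnot(all(library_total > 0))
  count / library_total * 1e6
}

#' Log2 fold change of normalized expressions
#'
#' @param ne_a,ne_b normalized expressions (> 0 after pseudocounting).
#' @return `log2(ne_a / ne_b)`; antisymmetric under swapping the libraries.
#' @export
log2_fold_change <- function(ne_a, ne_b) {
  stopifnot(all(ne_a > 0), all(ne_b > 0))
  log2(ne_a / ne_b)
}

#' Audic-Claverie count-ratio P-value
#'
#' Under the null that a species is equally represented in two libraries of
#' totals `N1` and `N2`, the count `y` in library 2 conditional on count `x`
#' in library 1 follows
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`,
#' a negative binomial with size `x+1` and success probability
#' `N1/(N1+N2)`.  The two-sided P-value doubles the smaller tail (capped at
#' 1); because the conditional tails are not themselves exchangeable in
#' `(x, N1)` and `(y, N2)`, the statistic is evaluated in both orientations
#' and the smaller value reported, which makes the result exactly symmetric
#' under swapping the libraries.  Computed in log space via the stable
#' `pnbinom` tails.
#'
#' @param x,y integer counts in libraries 1 and 2.
#' @param n1,n2 library totals (> 0).
#' @return two-sided P-value(s) in `[0, 1]`.
#' @export
count_ratio_pvalue <- function(x, y, n1, n2) {
  if (any(x != round(x)) || any(y != round(y)))
    stop("counts must be integers")
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  two_sided <- function(x, y, n1, n2) {
    p <- n1 / (n1 + n2)
    lower <- pnbinom(y, size = x + 1, prob = p)
    upper <- pnbinom(y - 1, size = x + 1, prob = p, lower.tail = FALSE)
    pmin(1, 2 * pmin(lower, upper))
  }
  pmin(two_sided(x, y, n1, n2), two_sided(y, x, n2, n1))
}

#' Significance classing
#'
#' Extremely significant: `p < p_ext` and `|log2fc| >= lfc_gate`;
#' significant: `p_ext <= p < p_sig` with the same fold gate; otherwise not
#' significant.  The thresholds (0.01 / 0.05, fold gate 1) are the
#' conventional ones for pooled-library pipelines and are configurable.
#'
#' @param p P-values.
#' @param log2fc log2 fold changes.
#' @param p_ext,p_sig P-value thresholds.
#' @param lfc_gate minimal absolute log2 fold change.
#' @return factor over `extremely_significant`, `significant`,
#'   `not_significant`.
#' @export
classify_significance <- function(p, log2fc, p_ext = 0.01, p_sig = 0.05,
                                  lfc_gate = 1) {
  stopifnot(all(p >= 0 & p <= 1))
  cls <- ifelse(p < p_ext & abs(log2fc) >= lfc_gate, "extremely_significant",
         ifelse(p < p_sig & abs(log2fc) >= lfc_gate, "significant",
                "not_significant"))
  factor(cls, levels = c("extremely_significant", "significant",
                         "not_significant"))
}

#' Pairwise differential-expression table
#'
#' One row per miRNA present in either library: raw counts, TPM, log2 fold
#' change (zero counts replaced by a configurable pseudocount in TPM space
#' for the ratio), Audic-Claverie P-value on the raw counts, significance
#' class, and the scatter-plot band (fold change > 2, between, <= 1/2).
#'
#' @param profile miRNA x library count matrix.
#' @param totals named library totals (high-quality read counts).
#' @param pair character of length 2, `c(A, B)`; fold change is
#'   `log2(A/B)`.
#' @param pseudo TPM pseudocount for zero counts (default 0.01).
#' @param ... passed to [classify_significance()].
#' @return data.frame of class `mirflow_de`, one row per miRNA, plus a
#'   `band_counts` attribute.
#' @export
de_table <- function(profile, totals, pair, pseudo = 0.01, ...) {
  if (!all(pair %in% colnames(profile)) || !all(pair %in% names(totals)))
    stop("pair labels not found in profile/totals")
  A <- pair[1]; B <- pair[2]
  x <- profile[, A]; y <- profile[, B]
  present <- x > 0 | y > 0
  x <- x[present]; y <- y[present]
  ne_a <- normalize_tpm(x, totals[[A]])
  ne_b <- normalize_tpm(y, totals[[B]])
  ra <- ifelse(ne_a == 0, pseudo, ne_a)
  rb <- ifelse(ne_b == 0, pseudo, ne_b)
  lfc <- log2_fold_change(ra, rb)
  p <- count_ratio_pvalue(x, y, totals[[A]], totals[[B]])
  fc <- ra / rb
  band <- factor(ifelse(fc > 2, "fc_gt_2",
                 ifelse(fc <= 0.5, "fc_le_half", "between")),
                 levels = c("fc_gt_2", "between", "fc_le_half"))
  out <- data.frame(mirna = rownames(profile)[present],
                    count_a = x, count_b = y, ne_a = ne_a, ne_b = ne_b,
                    log2fc = lfc, p_value = p,
                    class = classify_significance(p, lfc, ...),
                    band = band, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pair") <- pair
  attr(out, "band_counts") <- table(band)
  class(out) <- c("mirflow_de", class(out))
  out
}

#' @export
print.mirflow_de <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("Differential expression %s vs %s: %d miRNAs\n",
              pair[1], pair[2], nrow(x)))
  print(table(x$class))
  NextMethod()
}
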