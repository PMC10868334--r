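#' TPR / observed-FDR curve against simulation truth
#'
#' At each FDR threshold `q`, genes with `fdr <= q` are called; the true
#' positive rate is the fraction of true SVGs called and the observed FDR is
#' the fraction of calls that are truth-negative (0 when nothing is called).
#' NA adjusted values are never called.
#'
#' @param results An `svg_results` table (one row per gene).
#' @param truth A truth table with `gene_id` and `is_svg`.
#' @param thresholds FDR thresholds (default `c(0.01, 0.05, 0.1, 0.2)`).
#' @return A data.frame with columns `threshold`, `n_called`, `tpr`, `fdr`.
#'   `tpr` is NA when the truth contains no SVGs.
#' @export
tpr_fdr <- function(results, truth, thresholds = c(0.01, 0.05, 0.1, 0.2)) {
  stopifnot(is.data.frame(results), is.data.frame(truth))
  i <- match(results$gene_id, truth$gene_id)
  if (anyNA(i)) stop("truth is missing gene(s): ",
                     paste(utils::head(results$gene_id[is.na(i)], 5),
                           collapse = ", "))
  is_svg <- truth$is_svg[i]
  n_svg <- sum(is_svg)
  out <- lapply(thresholds, function(q) {
    called <- !is.na(results$fdr) & results$fdr <= q
    data.frame(threshold = q,
               n_called = sum(called),
               tpr = if (n_svg == 0) NA_real_
                     else sum(called & is_svg) / n_svg,
               fdr = sum(called & !is_svg) / max(1L, sum(called)))
  })
  do.call(rbind, out)
}

#' Jaccard concordance of top-k gene rankings across samples
#'
#' For every unordered pair of samples, computes the Jaccard index
#' `|A n B| / |A u B|` between their top-k gene sets, plus the mean over
#' pairs.
#'
#' @param rankings List (length >= 2) of character vectors of gene ids,
#'   ordered best-first.
#' @param k Number of top genes per sample (must be positive and no larger
#'   than the shortest ranking).
#' @return A list with `matrix` (pairwise Jaccard, 1 on the diagonal) and
#'   `mean` (average over unordered pairs).
#' @export
jaccard_top_k <- function(rankings, k) {
  stopifnot(is.list(rankings), length(rankings) >= 2L)
  if (k <= 0) stop("k must be positive")
  if (k > min(lengths(rankings)))
    stop("k exceeds the length of the shortest ranking")
  tops <- lapply(rankings, utils::head, k)
  n <- length(tops)
  jm <- diag(1, n)
  nm <- names(rankings) %||% paste0("sample", seq_len(n))
  dimnames(jm) <- list(nm, nm)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    j <- length(intersect(tops[[a]], tops[[b]])) /
      length(union(tops[[a]], tops[[b]]))
    jm[a, b] <- jm[b, a] <- j
  }
  list(matrix = jm, mean = mean(jm[upper.tri(jm)]))
}

#' Kolmogorov-Smirnov uniformity check of null p-values
#'
#' One-sample KS test of the p-values of truth-negative genes against
#' U(0, 1); a well-calibrated test yields approximately uniform nulls.
#'
#' @param pvalues P-values of truth-negative (uniform) genes; NAs dropped.
#' @return A list with `statistic` and `pvalue` of the KS test.
#' @export
null_uniformity <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) stop("no non-NA p-values supplied")
  if (length(p) < 20L) stop("need at least 20 null p-values")
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(statistic = unname(ks$statistic), pvalue = ks$p.value)
}

#' Key-cluster identification accuracy
#'
#' Fraction of true SVGs whose predicted key cluster matches the simulated
#' key region.
#'
#' @param predicted Output of [identify_key_cluster()] (columns `gene_id`,
#'   `key_cluster`).
#' @param truth A truth table with `gene_id`, `is_svg`, `key_region`.
#' @return A single fraction in `[0, 1]`, or NA if the truth has no SVGs.
#' @export
key_cluster_accuracy <- function(predicted, truth) {
  stopifnot(is.data.frame(predicted), is.data.frame(truth))
  tv <- truth[truth$is_svg, , drop = FALSE]
  if (!nrow(tv)) return(NA_real_)
  i <- match(tv$gene_id, predicted$gene_id)
  pred <- as.character(predicted$key_cluster[i])
  mean(!is.na(pred) & pred == tv$key_region)
}
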