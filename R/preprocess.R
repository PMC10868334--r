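#' Filter lowly expressed genes and shallow spots
#'
#' Genes are filtered first (total count and number of expressing spots),
#' then spots (total count over the retained genes). The operation is
#' idempotent for fixed thresholds.
#'
#' @param cm A [count_matrix].
#' @param min_gene_count Minimum total count for a gene to be retained.
#' @param min_gene_spots Minimum number of spots with a positive count.
#' @param min_spot_count Minimum total count (over retained genes) for a spot.
#' @return A filtered [count_matrix].
#' @export
filter_counts <- function(cm, min_gene_count = 20, min_gene_spots = 10,
                          min_spot_count = 10) {
  stopifnot(inherits(cm, "count_matrix"),
            min_gene_count >= 0, min_gene_spots >= 0, min_spot_count >= 0)
  x <- cm$counts
  keep_g <- colSums(x) >= min_gene_count &
    colSums(x > 0) >= min_gene_spots
  if (!any(keep_g))
    stop("gene filter (min_gene_count=", min_gene_count,
         ", min_gene_spots=", min_gene_spots, ") removed all genes")
  x <- x[, keep_g, drop = FALSE]
  keep_s <- rowSums(x) >= min_spot_count
  if (!any(keep_s))
    stop("spot filter (min_spot_count=", min_spot_count,
         ") removed all spots")
  count_matrix(x[keep_s, , drop = FALSE])
}

#' TMM normalization factors and effective library sizes
#'
#' Computes per-spot scaling factors by the trimmed mean of M-values: a
#' reference spot is chosen as the one whose upper-quartile count fraction is
#' closest to the mean upper-quartile fraction; for every other spot the
#' factor is 2 to the precision-weighted mean of gene-wise log2 ratios
#' (M-values), after trimming `trim_m` of the M distribution and `trim_a` of
#' the A (average log abundance) distribution from each tail. Genes with a
#' zero count in either spot are excluded. Factors are rescaled to have
#' geometric mean 1, so they encode composition, not depth.
#'
#' @param cm A [count_matrix] with at least two spots.
#' @param trim_m Fraction of M-values trimmed from each tail (default 0.30).
#' @param trim_a Fraction of A-values trimmed from each tail (default 0.05).
#' @param method `"tmm"` (default) or `"libsize"`, the latter setting all
#'   factors to 1 (library-size-only normalization).
#' @return A `norm_factors` data.frame with columns `spot_id`, `lib_size`,
#'   `tmm_factor` and `effective_size`.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05,
                        method = c("tmm", "libsize")) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  x <- cm$counts
  if (nrow(x) < 2L) stop("TMM requires at least two spots")
  lib <- rowSums(x)
  if (any(lib == 0)) stop("spot(s) with zero total count: ",
                          paste(cm$spot_ids[lib == 0], collapse = ", "))
  if (method == "libsize") {
    f <- rep(1, nrow(x))
  } else {
    # upper-quartile count fraction over expressed genes, per spot
    uq <- vapply(seq_len(nrow(x)), function(i) {
      y <- x[i, ]
      stats::quantile(y[y > 0], 0.75, names = FALSE) / lib[i]
    }, numeric(1))
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(nrow(x)), function(i)
      .tmm_pair(x[i, ], x[ref, ], lib[i], lib[ref], trim_m, trim_a,
                spot = cm$spot_ids[i]),
      numeric(1))
    f <- f / exp(mean(log(f)))
  }
  structure(
    data.frame(spot_id = cm$spot_ids, lib_size = as.numeric(lib),
               tmm_factor = f, effective_size = as.numeric(lib) * f,
               stringsAsFactors = FALSE),
    class = c("norm_factors", "data.frame"))
}

# One spot against the reference: doubly trimmed, precision-weighted mean of
# M-values (rank-based trimming on both M and A).
.tmm_pair <- function(yk, yr, nk, nr, trim_m, trim_a, spot = "?") {
  keep <- yk > 0 & yr > 0
  if (!any(keep)) {
    warning("spot '", spot,
            "' shares no expressed genes with the reference; factor set to 1")
    return(1)
  }
  yk <- yk[keep]; yr <- yr[keep]
  m <- log2((yk / nk) / (yr / nr))
  a <- 0.5 * log2((yk / nk) * (yr / nr))
  v <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(sel) || sum(1 / v[sel]) == 0) return(1)
  2 ^ (sum(m[sel] / v[sel]) / sum(1 / v[sel]))
}

#' Effective library sizes
#'
#' The effective library size of a spot is its total count multiplied by its
#' TMM factor; its log is the GLM offset used throughout the package.
#'
#' @param cm A [count_matrix].
#' @param nf A `norm_factors` table from [tmm_factors()].
#' @return Named numeric vector of effective sizes, one per spot.
#' @export
effective_sizes <- function(cm, nf) {
  stopifnot(inherits(cm, "count_matrix"), inherits(nf, "norm_factors"))
  i <- match(cm$spot_ids, nf$spot_id)
  if (anyNA(i)) stop("norm factors missing for spot(s): ",
                     paste(cm$spot_ids[is.na(i)], collapse = ", "))
  stats::setNames(nf$lib_size[i] * nf$tmm_factor[i], cm$spot_ids)
}
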