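#' Global test for spatially variable genes
#'
#' For every gene, fits the negative binomial GLM with spatial-cluster
#' covariates (and sample covariates when replicates are present) and tests
#' whether the cluster coefficients differ, via a likelihood-ratio test with
#' `C - 1` degrees of freedom. Dispersions are tagwise Cox-Reid estimates
#' shared between the full and reduced fits; p-values are BH-adjusted across
#' all tested genes.
#'
#' @param cm A [count_matrix].
#' @param spots A `spot_table` with matching spot ids.
#' @param model `"auto"` (multi-sample when a `sample` column with >= 2
#'   levels is present), `"single"`, or `"multi"`.
#' @param filter Apply [filter_counts()] first (default TRUE).
#' @param min_gene_count,min_gene_spots,min_spot_count Filter thresholds.
#' @param normalize `"tmm"` (default) or `"libsize"`.
#' @param prior_df Dispersion shrinkage prior df (see
#'   [estimate_dispersions()]).
#' @return An `svg_results` data.frame with columns `gene_id`, `lrt_stat`,
#'   `df`, `pvalue`, `fdr`, `mean_logcpm`, ordered by ascending p-value.
#'   Dispersion estimates and offsets are attached as attributes
#'   `"dispersion"` and `"offsets"` for reuse.
#' @export
test_global <- function(cm, spots, model = c("auto", "single", "multi"),
                        filter = TRUE, min_gene_count = 20,
                        min_gene_spots = 10, min_spot_count = 10,
                        normalize = c("tmm", "libsize"), prior_df = 10) {
  model <- match.arg(model)
  normalize <- match.arg(normalize)
  prep <- .prepare_inputs(cm, spots, filter, min_gene_count, min_gene_spots,
                          min_spot_count, normalize)
  design <- build_design(prep$spots, model)
  disp <- estimate_dispersions(prep$counts, design, prep$offsets,
                               prior_df = prior_df)
  phi <- disp$tagwise
  phi[disp$zero_gene] <- disp$common
  Y <- t(prep$counts$counts)
  if (!is.null(design$group_full)) {
    full <- .fit_groups_nb(Y, design$group_full, prep$offsets, phi)
    red <- .fit_groups_nb(Y, design$group_reduced, prep$offsets, phi)
    llf <- full$loglik; llr <- red$loglik
  } else {
    lls <- .fit_general_pair(Y, design$X_full, design$X_reduced,
                             prep$offsets, phi)
    llf <- lls$full; llr <- lls$reduced
  }
  test <- lrt(llf, llr, df = design$df_test)
  p <- test$pvalue
  p[disp$zero_gene] <- NA_real_
  res <- data.frame(gene_id = prep$counts$gene_ids,
                    lrt_stat = test$statistic,
                    df = design$df_test,
                    pvalue = p,
                    fdr = adjust_bh(p),
                    mean_logcpm = disp$mean_logcpm,
                    stringsAsFactors = FALSE)
  res <- res[order(res$pvalue, res$gene_id, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("svg_results", "data.frame")
  attr(res, "dispersion") <- disp
  attr(res, "offsets") <- prep$offsets
  attr(res, "model") <- design$model
  attr(res, "cluster_levels") <- design$cluster_levels
  res
}

#' Individual-cluster tests for spatially variable genes
#'
#' Tests, for every gene and every spatial cluster, whether mean abundance
#' inside the cluster differs from the rest of the tissue (one-vs-rest
#' contrast on spot-level counts, 1 df likelihood-ratio test). `mode =
#' "full"` re-estimates dispersions under each one-vs-rest design; `mode =
#' "fast"` recycles the tagwise dispersions from the global cluster design.
#' BH adjustment is applied within each cluster's gene vector.
#'
#' @inheritParams test_global
#' @param mode `"fast"` (recycle global-design dispersions, default) or
#'   `"full"` (re-estimate per one-vs-rest design).
#' @return An `svg_cluster_results` data.frame with one row per gene and
#'   cluster: `gene_id`, `cluster`, `lrt_stat`, `df`, `pvalue`, `fdr`,
#'   `coef` (log-fold difference in vs rest), `sign` (`"high"`/`"low"`),
#'   `mean_logcpm`.
#' @export
test_cluster <- function(cm, spots, mode = c("fast", "full"),
                         model = c("auto", "single", "multi"),
                         filter = TRUE, min_gene_count = 20,
                         min_gene_spots = 10, min_spot_count = 10,
                         normalize = c("tmm", "libsize"), prior_df = 10) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  normalize <- match.arg(normalize)
  prep <- .prepare_inputs(cm, spots, filter, min_gene_count, min_gene_spots,
                          min_spot_count, normalize)
  design <- build_design(prep$spots, model)
  C <- length(design$cluster_levels)
  if (C < 3L)
    stop("individual-cluster testing requires >= 3 clusters; with 2 ",
         "clusters it coincides with the global test, use test_global()")
  Y <- t(prep$counts$counts)
  cl <- droplevels(prep$spots$cluster)
  multi <- design$model == "multi"
  if (mode == "fast") {
    disp <- estimate_dispersions(prep$counts, design, prep$offsets,
                                 prior_df = prior_df)
  }
  out <- vector("list", C)
  for (k in seq_len(C)) {
    lev <- design$cluster_levels[k]
    ind <- as.integer(cl == lev)
    sp_k <- prep$spots
    sp_k$cluster <- factor(ifelse(ind == 1L, "in", "rest"),
                           levels = c("rest", "in"))
    des_k <- build_design(sp_k, if (multi) "multi" else "single")
    if (mode == "full") {
      disp_k <- estimate_dispersions(prep$counts, des_k, prep$offsets,
                                     prior_df = prior_df)
    } else {
      disp_k <- disp
    }
    phi <- disp_k$tagwise
    phi[disp_k$zero_gene] <- disp_k$common
    if (!multi) {
      full <- .fit_groups_nb(Y, des_k$group_full, prep$offsets, phi)
      red <- .fit_groups_nb(Y, des_k$group_reduced, prep$offsets, phi)
      # groups sorted: 1 = rest, 2 = in
      coef <- full$beta[, 2L] - full$beta[, 1L]
      llf <- full$loglik; llr <- red$loglik
    } else {
      lls <- .fit_general_pair(Y, des_k$X_full, des_k$X_reduced,
                               prep$offsets, phi, coef_col = "cluster_in")
      coef <- lls$coef
      llf <- lls$full; llr <- lls$reduced
    }
    test <- lrt(llf, llr, df = 1L)
    p <- test$pvalue
    p[disp_k$zero_gene] <- NA_real_
    out[[k]] <- data.frame(
      gene_id = prep$counts$gene_ids,
      cluster = lev,
      lrt_stat = test$statistic,
      df = 1L,
      pvalue = p,
      fdr = adjust_bh(p),
      coef = coef,
      sign = ifelse(coef > 0, "high", "low"),
      mean_logcpm = .mean_logcpm(Y, exp(prep$offsets)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$cluster <- factor(res$cluster, levels = design$cluster_levels)
  res <- res[order(res$cluster, res$pvalue, res$gene_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("svg_cluster_results", "svg_results", "data.frame")
  attr(res, "cluster_levels") <- design$cluster_levels
  res
}

# Per-gene IRLS for general (non-partition) designs; returns log-likelihood
# vectors for the full and reduced fits, plus one named coefficient.
.fit_general_pair <- function(Y, X_full, X_reduced, offsets, phi,
                              coef_col = NULL) {
  G <- nrow(Y)
  llf <- numeric(G); llr <- numeric(G); coef <- rep(NA_real_, G)
  j <- if (!is.null(coef_col)) match(coef_col, colnames(X_full)) else NA
  for (g in seq_len(G)) {
    y <- Y[g, ]
    ff <- fit_gene_glm(y, X_full, offsets, phi[g])
    fr <- fit_gene_glm(y, X_reduced, offsets, phi[g])
    llf[g] <- ff$loglik; llr[g] <- fr$loglik
    if (!is.na(j)) coef[g] <- ff$beta[j]
  }
  list(full = llf, reduced = llr, coef = coef)
}

# shared preprocessing: align, filter, normalize, offsets
.prepare_inputs <- function(cm, spots, filter, min_gene_count,
                            min_gene_spots, min_spot_count, normalize) {
  al <- align_spots(cm, spots)
  cmf <- if (filter)
    filter_counts(al$counts, min_gene_count, min_gene_spots, min_spot_count)
  else al$counts
  sp <- al$spots[match(cmf$spot_ids, al$spots$spot_id), , drop = FALSE]
  lost <- setdiff(levels(sp$cluster), unique(as.character(sp$cluster)))
  if (length(lost)) {
    warning("cluster level(s) emptied by spot filtering: ",
            paste(lost, collapse = ", "))
    sp$cluster <- droplevels(sp$cluster)
  }
  rownames(sp) <- NULL
  nf <- tmm_factors(cmf, method = normalize)
  offsets <- log(effective_sizes(cmf, nf))
  list(counts = cmf, spots = sp, norm = nf, offsets = offsets)
}

#' Identify each gene's key spatial cluster
#'
#' The key cluster is the one with the smallest individual-cluster p-value;
#' ties are broken by the larger absolute coefficient, then by cluster
#' order.
#'
#' @param cluster_results An `svg_cluster_results` table from
#'   [test_cluster()].
#' @return A data.frame with one row per gene: `gene_id`, `key_cluster`,
#'   `sign`, `pvalue`, `coef`. Genes with all-NA p-values get an NA key
#'   cluster.
#' @export
identify_key_cluster <- function(cluster_results) {
  stopifnot(inherits(cluster_results, "svg_cluster_results"))
  cr <- cluster_results
  ord <- order(cr$gene_id, cr$pvalue, -abs(cr$coef),
               as.integer(cr$cluster), na.last = TRUE)
  cr <- cr[ord, , drop = FALSE]
  first <- !duplicated(cr$gene_id)
  res <- cr[first, c("gene_id", "cluster", "sign", "pvalue", "coef")]
  names(res)[2] <- "key_cluster"
  na_gene <- is.na(res$pvalue)
  res$key_cluster[na_gene] <- NA
  res$sign[na_gene] <- NA
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- "data.frame"
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; NA values are
#' passed through and excluded from the ranking.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of BH-adjusted values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Extract top spatially variable genes
#'
#' @param results An `svg_results` table.
#' @param fdr_threshold Keep genes with `fdr <= fdr_threshold`
#'   (default 0.05).
#' @param n If given, return the first `n` genes by p-value regardless of
#'   the threshold.
#' @return Character vector of gene ids ordered by ascending p-value (ties
#'   by gene id).
#' @export
top_svgs <- function(results, fdr_threshold = 0.05, n = NULL) {
  stopifnot(is.data.frame(results))
  ord <- order(results$pvalue, results$gene_id, na.last = TRUE)
  r <- results[ord, , drop = FALSE]
  if (!is.null(n)) return(utils::head(r$gene_id, n))
  r$gene_id[!is.na(r$fdr) & r$fdr <= fdr_threshold]
}
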