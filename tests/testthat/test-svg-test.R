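test_that("global test finds cluster effects and controls errors", {
  # moderately expressed genes: with half the genes 4-fold DE, spot-level
  # TMM needs non-sparse counts to resolve the trimming reliably
  sim <- simulate_synthetic(n_spots = 400, n_genes = 200, n_clusters = 2,
                            prop_svg = 0.5, pattern = "annotations",
                            log2fc = c(strong = 2, weak = 2), phi = 0.3,
                            baseline_meanlog = log(20),
                            baseline_sdlog = 0.5, seed = 101)
  res <- test_global(sim$counts, sim$spots, min_gene_count = 1,
                     min_gene_spots = 1, min_spot_count = 1)
  perf <- tpr_fdr(res, sim$truth, thresholds = 0.05)
  expect_gte(perf$tpr, 0.9)
  expect_lte(perf$fdr, 0.10)

  # shuffling cluster labels destroys the signal
  sp_perm <- sim$spots
  set.seed(1)
  sp_perm$cluster <- sample(sp_perm$cluster)
  res_perm <- test_global(sim$counts, sp_perm, min_gene_count = 1,
                          min_gene_spots = 1, min_spot_count = 1)
  expect_lte(length(top_svgs(res_perm, 0.05)), 10)
})

test_that("a spatially constant gene is not flagged", {
  set.seed(102)
  n <- 300
  sp <- toy_spots(n, clusters = rep(c("A", "B", "C"), each = 100))
  m <- matrix(rnbinom(n * 30, mu = 5, size = 2), n, 30,
              dimnames = list(sp$spot_id, paste0("g", 1:30)))
  res <- test_global(count_matrix(m), sp, min_gene_count = 1,
                     min_gene_spots = 1, min_spot_count = 1)
  expect_lt(mean(res$pvalue < 0.05), 0.2)
})

test_that("single-gene results are invariant to input permutations", {
  sim <- simulate_synthetic(n_spots = 120, n_genes = 40, n_clusters = 3,
                            prop_svg = 0.5, pattern = "mixture", seed = 103)
  res <- test_global(sim$counts, sim$spots, min_gene_count = 1,
                     min_gene_spots = 1, min_spot_count = 1)
  set.seed(2)
  pi_s <- sample(nrow(sim$counts$counts))
  pi_g <- sample(ncol(sim$counts$counts))
  cm_p <- count_matrix(sim$counts$counts[pi_s, pi_g])
  sp_p <- spot_table(as.data.frame(sim$spots)[pi_s, ])
  res_p <- test_global(cm_p, sp_p, min_gene_count = 1,
                       min_gene_spots = 1, min_spot_count = 1)
  i <- match(res$gene_id, res_p$gene_id)
  # agreement up to floating-point noise: permuting rows reorders sums,
  # whose rounding propagates through the dispersion optimizer
  expect_equal(res$lrt_stat, res_p$lrt_stat[i], tolerance = 1e-5)
  expect_equal(res$pvalue, res_p$pvalue[i], tolerance = 1e-5)
})

test_that("two-cluster global test equals the one-vs-rest contrast", {
  sim <- simulate_synthetic(n_spots = 150, n_genes = 30, n_clusters = 2,
                            prop_svg = 0.5, pattern = "annotations",
                            seed = 104)
  res_ab <- test_global(sim$counts, sim$spots, min_gene_count = 1,
                        min_gene_spots = 1, min_spot_count = 1)
  sp_ovr <- sim$spots
  sp_ovr$cluster <- factor(ifelse(sp_ovr$cluster == "cl1", "in", "rest"),
                           levels = c("rest", "in"))
  res_ovr <- test_global(sim$counts, sp_ovr, min_gene_count = 1,
                         min_gene_spots = 1, min_spot_count = 1)
  i <- match(res_ab$gene_id, res_ovr$gene_id)
  expect_equal(res_ab$lrt_stat, res_ovr$lrt_stat[i], tolerance = 1e-8)
})

test_that("cluster test localizes an effect with the right sign", {
  set.seed(105)
  n <- 300
  sp <- toy_spots(n, clusters = rep(c("c1", "c2", "c3"), each = 100))
  mu <- matrix(4, n, 20)
  mu[101:200, 1:5] <- 16   # genes 1-5 high only in cluster c2
  m <- matrix(rnbinom(n * 20, mu = mu, size = 3), n, 20,
              dimnames = list(sp$spot_id, sprintf("g%02d", 1:20)))
  cr <- test_cluster(count_matrix(m), sp, mode = "fast",
                     min_gene_count = 1, min_gene_spots = 1,
                     min_spot_count = 1)
  key <- identify_key_cluster(cr)
  hits <- key[key$gene_id %in% sprintf("g%02d", 1:5), ]
  expect_true(all(hits$key_cluster == "c2"))
  expect_true(all(hits$sign == "high"))
  expect_error(test_cluster(count_matrix(m),
                            toy_spots(n, rep(c("A", "B"), n / 2)),
                            min_gene_count = 1, min_gene_spots = 1,
                            min_spot_count = 1),
               "test_global")
})

test_that("uniform genes are rarely flagged by per-cluster tests", {
  set.seed(106)
  n <- 240
  sp <- toy_spots(n, clusters = rep(c("c1", "c2", "c3"), each = 80))
  m <- matrix(rnbinom(n * 50, mu = 5, size = 2.5), n, 50,
              dimnames = list(sp$spot_id, paste0("g", 1:50)))
  cr <- test_cluster(count_matrix(m), sp, mode = "fast",
                     min_gene_count = 1, min_gene_spots = 1,
                     min_spot_count = 1)
  sig <- tapply(cr$fdr <= 0.05, cr$gene_id, any)
  expect_lte(mean(sig), 0.1)
})

test_that("key-cluster tie-breaks follow p, then |coef|, then order", {
  df <- data.frame(
    gene_id = rep("g1", 3),
    cluster = factor(c("c1", "c2", "c3"), levels = c("c1", "c2", "c3")),
    lrt_stat = 1, df = 1L,
    pvalue = c(0.001, 0.5, 0.9), fdr = c(0.003, 0.5, 0.9),
    coef = c(1, 2, 3), sign = "high", mean_logcpm = 1,
    stringsAsFactors = FALSE)
  class(df) <- c("svg_cluster_results", "svg_results", "data.frame")
  expect_equal(as.character(identify_key_cluster(df)$key_cluster), "c1")

  df$pvalue <- c(0.2, 0.2, 0.9)
  df$coef <- c(0.1, 2.0, 5)
  expect_equal(as.character(identify_key_cluster(df)$key_cluster), "c2")
})

test_that("BH adjustment matches hand-computed values and passes NAs", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  out <- adjust_bh(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], c(0.02, 0.04))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # fdr >= pvalue and monotone in p
  set.seed(107)
  p <- runif(50)
  f <- adjust_bh(p)
  expect_true(all(f >= p))
  expect_true(all(diff(f[order(p)]) >= -1e-12))
})

test_that("top_svgs honors thresholds, n, and tie order", {
  res <- data.frame(gene_id = c("b", "a", "c"),
                    pvalue = c(0.01, 0.01, 0.9),
                    fdr = c(0.03, 0.03, 0.9), stringsAsFactors = FALSE)
  expect_equal(top_svgs(res, 1.0), c("a", "b", "c"))
  expect_equal(top_svgs(res, 0.05), c("a", "b"))
  expect_equal(top_svgs(res, 0.05, n = 0), character(0))
  expect_equal(top_svgs(res, 0, ), character(0))
  expect_equal(top_svgs(res, n = 1), "a")
})
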