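grid_spots_fixture <- function(n = 100) {
  spot_table(expand.grid(x = 1:10, y = 1:10)[seq_len(n), ] |>
               transform(spot_id = paste0("s", seq_len(n)),
                         cluster = rep(c("A", "B"), length.out = n)))
}

test_that("bottom/right mask splits a grid in half", {
  sp <- grid_spots_fixture(100)
  m <- make_mask(sp, "bottom_right")
  expect_equal(sum(m$region == "in"), 50)
  m2 <- make_mask(sp, "bottom_right", params = list(axis = "x"))
  expect_equal(sum(m2$region == "in"), 50)
})

test_that("circular mask encloses about half the spots", {
  sp <- grid_spots_fixture(100)
  m <- make_mask(sp, "circular")
  frac <- mean(m$region == "in")
  expect_gte(frac, 0.45)
  expect_lte(frac, 0.55)
})

test_that("mixture masks default to the smallest cluster", {
  cl <- rep(c("big", "mid", "tiny"), c(80, 15, 5))
  sp <- toy_spots(100, clusters = cl)
  m <- make_mask(sp, "mixture")
  expect_equal(sum(m$region == "in"), 5)
  expect_true(attr(m, "per_gene_keys"))
  # pinning a cluster switches off per-gene keys
  m2 <- make_mask(sp, "mixture", params = list(cluster = "mid"))
  expect_equal(sum(m2$region == "in"), 15)
  expect_equal(attr(m2, "key_cluster"), "mid")
  expect_false(attr(m2, "per_gene_keys"))
})

test_that("patterns needing clusters reject coordinate-only tables", {
  sp <- grid_spots_fixture(20)
  sp2 <- sp
  sp2$cluster[3] <- NA
  expect_error(make_mask(sp2, "mixture"), "cluster labels")
})

test_that("anchor rearrangement preserves per-gene count multisets", {
  cm <- toy_counts(40, 25, seed = 201, mean = 8)
  sp <- toy_spots(40, clusters = rep(c("A", "B", "C", "D"), 10))
  m <- make_mask(sp, "mixture")
  sim <- simulate_from_anchor(cm, m, seed = 1)
  expect_equal(dim(sim$counts), dim(cm))
  for (g in seq_along(cm$gene_ids)) {
    expect_equal(sort(sim$counts$counts[, g]), sort(cm$counts[, g]),
                 ignore_attr = TRUE)
  }
  # high-direction SVGs have key-region mean >= rest by construction
  cl <- as.character(sp$cluster)
  tr <- sim$truth
  for (g in which(tr$is_svg & tr$direction == "high")) {
    inside <- cl == tr$key_region[g]
    expect_gte(mean(sim$counts$counts[inside, g]),
               mean(sim$counts$counts[!inside, g]))
  }
})

test_that("truth proportions and tiers match the request exactly", {
  sim <- simulate_synthetic(n_spots = 90, n_genes = 57, n_clusters = 3,
                            prop_svg = 1 / 3, pattern = "mixture",
                            seed = 202)
  expect_equal(sum(sim$truth$is_svg), round(57 / 3))
  expect_equal(sum(sim$truth$tier == "strong", na.rm = TRUE),
               round(0.5 * round(57 / 3)))
  sim0 <- simulate_synthetic(n_spots = 60, n_genes = 20, prop_svg = 0,
                             seed = 203)
  expect_false(any(sim0$truth$is_svg))
})

test_that("identical seeds reproduce identical outputs", {
  a <- simulate_synthetic(n_spots = 80, n_genes = 30, seed = 204)
  b <- simulate_synthetic(n_spots = 80, n_genes = 30, seed = 204)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_synthetic(n_spots = 80, n_genes = 30, seed = 205)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("realized fold changes match the requested effect size", {
  sim <- simulate_synthetic(n_spots = 1000, n_genes = 120, n_clusters = 4,
                            prop_svg = 0.5, pattern = "mixture",
                            tier_props = c(strong = 1, weak = 0),
                            phi = 0.2, seed = 206)
  cl <- as.character(sim$spots$cluster)
  depth <- rowSums(sim$counts$counts)
  norm <- sweep(sim$counts$counts, 1, depth / mean(depth), "/")
  lfc <- sapply(which(sim$truth$is_svg), function(g) {
    inside <- cl == sim$truth$key_region[g]
    log2(mean(norm[inside, g]) / mean(norm[!inside, g]))
  })
  expect_equal(median(lfc), 1, tolerance = 0.1)
})

test_that("zero effect size makes designated SVGs indistinguishable", {
  sim <- simulate_synthetic(n_spots = 300, n_genes = 100, n_clusters = 3,
                            prop_svg = 0.5, pattern = "mixture",
                            log2fc = c(strong = 0, weak = 0), seed = 207)
  res <- test_global(sim$counts, sim$spots, min_gene_count = 1,
                     min_gene_spots = 1, min_spot_count = 1)
  expect_lte(length(top_svgs(res, 0.05)), 5)
})

test_that("multi-sample simulation shares truth across samples", {
  anchors <- lapply(1:3, function(j) {
    cm <- toy_counts(60, 30, seed = 210 + j, mean = 10)
    sp <- toy_spots(60, clusters = rep(c("A", "B", "C"), 20))
    list(counts = cm, spots = sp)
  })
  sims <- simulate_multisample(anchors, "mixture", seed = 3)
  expect_identical(sims[[1]]$truth, sims[[2]]$truth)
  expect_identical(sims[[1]]$truth, sims[[3]]$truth)
  expect_false(identical(sims[[1]]$counts$counts,
                         sims[[2]]$counts$counts))
  # gene universe mismatch is an error
  anchors[[2]]$counts <- count_matrix(
    anchors[[2]]$counts$counts[, 1:20, drop = FALSE])
  expect_error(simulate_multisample(anchors, "mixture", seed = 3),
               "gene universe")
})

test_that("cluster perturbation relabels the requested fraction", {
  sp <- toy_spots(100, clusters = rep(c("A", "B", "C", "D"), 25))
  pert <- perturb_clusters(sp, 0.2, seed = 4)
  expect_equal(sum(pert$cluster != sp$cluster), 20)
  expect_identical(levels(pert$cluster), levels(sp$cluster))
  expect_identical(perturb_clusters(sp, 0, seed = 4)$cluster, sp$cluster)
})
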