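test_that("single-sample design uses cluster-means coding", {
  sp <- toy_spots(4, clusters = c("A", "A", "B", "B"))
  d <- build_design(sp, "single")
  expect_equal(dim(d$X_full), c(4L, 2L))
  expect_equal(unname(d$X_full[, 1]), c(1, 1, 0, 0))
  expect_equal(ncol(d$X_reduced), 1L)
  expect_equal(d$df_test, 1L)
})

test_that("multi-sample design has intercept, cluster and sample dummies", {
  sp <- toy_spots(12, clusters = rep(c("A", "B", "C"), 4),
                  sample = rep(c("s1", "s2"), each = 6))
  d <- build_design(sp, "multi")
  expect_equal(ncol(d$X_full), 4L)  # 1 + (C-1) + (J-1)
  expect_equal(ncol(d$X_reduced), 2L)
  expect_equal(d$df_test, 2L)
  expect_equal(colnames(d$X_full),
               c("intercept", "cluster_B", "cluster_C", "sample_s2"))
})

test_that("degenerate designs are rejected", {
  expect_error(build_design(toy_spots(3, clusters = rep("A", 3))),
               "one cluster")
  sp <- toy_spots(4, clusters = c("A", "A", "B", "B"),
                  sample = c("s1", "s1", "s2", "s2"))
  expect_error(build_design(sp, "multi"), "confounded")
})

test_that("nb_loglik matches closed forms and the direct pmf formula", {
  # Poisson limit: log P(2; mu=2) = 2 log 2 - 2 - log 2!
  expect_equal(nb_loglik(2, 2, 0), 2 * log(2) - 2 - log(2))
  # NB(size 1, mean 1) at zero has probability 1/2
  expect_equal(nb_loglik(0, 1, 1), log(0.5))
  set.seed(21)
  for (phi in c(0, 0.1, 0.7, 2)) {
    y <- rpois(15, 4)
    mu <- runif(15, 0.5, 8)
    expect_equal(nb_loglik(y, mu, phi), oracle_nb_logpmf(y, mu, phi),
                 tolerance = 1e-10)
  }
  # pmf sums to one over its support
  probs <- sapply(0:500, function(k) exp(nb_loglik(k, 3, 0.5)))
  expect_equal(sum(probs), 1, tolerance = 1e-10)
})

test_that("Poisson group MLE has the closed form log(sum y / sum M)", {
  set.seed(31)
  sp <- toy_spots(12, clusters = rep(c("A", "B", "C"), each = 4))
  d <- build_design(sp, "single")
  y <- rpois(12, 6)
  offsets <- log(runif(12, 50, 150))
  fit <- fit_gene_glm(y, d$X_full, offsets, phi = 0)
  M <- exp(offsets)
  for (k in 1:3) {
    idx <- ((k - 1) * 4 + 1):(k * 4)
    expect_equal(unname(fit$beta[k]), log(sum(y[idx]) / sum(M[idx])),
                 tolerance = 1e-7)
  }
})

test_that("constant counts with equal offsets give the sample mean", {
  y <- rep(5L, 8)
  X <- matrix(1, 8, 1)
  fit <- fit_gene_glm(y, X, offsets = rep(0, 8), phi = 0.3)
  expect_equal(unname(fit$mu[1]), 5, tolerance = 1e-7)
})

test_that("IRLS log-likelihood matches a derivative-free optimizer", {
  set.seed(41)
  sp <- toy_spots(60, clusters = rep(c("A", "B", "C"), 20))
  d <- build_design(sp, "single")
  offsets <- log(runif(60, 80, 120))
  for (rep in 1:5) {
    y <- rnbinom(60, mu = exp(rnorm(1, 1.5, 0.5)), size = 2)
    phi <- runif(1, 0.05, 1)
    ll_irls <- fit_gene_glm(y, d$X_full, offsets, phi)$loglik
    ll_opt <- oracle_glm_loglik(y, d$X_full, offsets, phi)
    expect_equal(ll_irls, ll_opt, tolerance = 1e-6)
  }
})

test_that("all-zero genes are flagged and fitted at the boundary", {
  X <- matrix(1, 6, 1)
  fit <- fit_gene_glm(rep(0L, 6), X, rep(log(100), 6), phi = 0.4)
  expect_true(fit$boundary)
  expect_lt(abs(fit$loglik), 1e-4)
})

test_that("LRT statistic is invariant to cluster coding", {
  set.seed(51)
  sp <- toy_spots(30, clusters = rep(c("A", "B", "C"), 10))
  d <- build_design(sp, "single")
  offsets <- log(runif(30, 50, 200))
  X_dummy <- model.matrix(~cluster, data = sp)  # treatment coding
  X_int <- matrix(1, 30, 1)
  for (rep in 1:5) {
    y <- rnbinom(30, mu = 5, size = 2)
    phi <- 0.4
    ll_means <- fit_gene_glm(y, d$X_full, offsets, phi)$loglik
    ll_dummy <- fit_gene_glm(y, X_dummy, offsets, phi)$loglik
    ll_red <- fit_gene_glm(y, X_int, offsets, phi)$loglik
    s1 <- lrt(ll_means, ll_red, 2)$statistic
    s2 <- lrt(ll_dummy, ll_red, 2)$statistic
    expect_equal(s1, s2, tolerance = 1e-8)
  }
})

test_that("shifting all offsets leaves the LRT statistic unchanged", {
  set.seed(61)
  sp <- toy_spots(24, clusters = rep(c("A", "B"), 12))
  d <- build_design(sp, "single")
  offsets <- log(runif(24, 50, 200))
  y <- rnbinom(24, mu = 6, size = 2)
  stat <- function(off) {
    llf <- fit_gene_glm(y, d$X_full, off, 0.3)$loglik
    llr <- fit_gene_glm(y, d$X_reduced, off, 0.3)$loglik
    lrt(llf, llr, 1)$statistic
  }
  expect_equal(stat(offsets), stat(offsets + 2.5), tolerance = 1e-8)
})

test_that("vectorized group fitter agrees with per-gene IRLS", {
  set.seed(71)
  n <- 40
  sp <- toy_spots(n, clusters = rep(c("A", "B", "C", "D"), 10))
  d <- build_design(sp, "single")
  offsets <- log(runif(n, 50, 150))
  Y <- matrix(rnbinom(8 * n, mu = 4, size = 2), 8, n)
  phi <- runif(8, 0.1, 0.8)
  grp <- spaceLRT:::.fit_groups_nb(Y, d$group_full, offsets, phi)
  for (g in 1:8) {
    fit <- fit_gene_glm(Y[g, ], d$X_full, offsets, phi[g])
    expect_equal(grp$loglik[g], fit$loglik, tolerance = 1e-7)
  }
})

test_that("lrt computes chi-square tails and flags negative statistics", {
  r <- lrt(10, 10, 2)
  expect_equal(r$statistic, 0)
  expect_equal(r$pvalue, 1)
  expect_equal(lrt(10 + 5.991 / 2, 10, 2)$pvalue, 0.05, tolerance = 1e-3)
  bad <- lrt(10, 10.1, 2)
  expect_true(bad$flagged)
  expect_true(is.na(bad$pvalue))
})
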