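# fixture builders shared across test files

# small dense count matrix with reproducible NB counts
toy_counts <- function(n_spots = 6, n_genes = 4, seed = 11, mean = 5,
                       phi = 0.3) {
  set.seed(seed)
  m <- matrix(rnbinom(n_spots * n_genes, mu = mean, size = 1 / phi),
              n_spots, n_genes,
              dimnames = list(paste0("s", seq_len(n_spots)),
                              paste0("g", seq_len(n_genes))))
  count_matrix(m)
}

toy_spots <- function(n = 6, clusters = rep(c("A", "B"), length.out = n),
                      sample = NULL) {
  df <- data.frame(spot_id = paste0("s", seq_len(n)),
                   x = seq_len(n), y = rep(1, n),
                   cluster = clusters, stringsAsFactors = FALSE)
  if (!is.null(sample)) df$sample <- sample
  spot_table(df)
}

# independent brute-force TMM oracle: direct formula evaluation with
# explicit order-based trimming (package code uses rank-based selection)
oracle_tmm <- function(x, trim_m = 0.30, trim_a = 0.05) {
  lib <- rowSums(x)
  uq <- sapply(seq_len(nrow(x)), function(i) {
    y <- x[i, ]
    quantile(y[y > 0], 0.75, names = FALSE) / lib[i]
  })
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(nrow(x)), function(i) {
    yk <- x[i, ]; yr <- x[ref, ]
    keep <- yk > 0 & yr > 0
    yk <- yk[keep]; yr <- yr[keep]
    m <- log2((yk / lib[i]) / (yr / lib[ref]))
    a <- 0.5 * log2((yk / lib[i]) * (yr / lib[ref]))
    v <- (lib[i] - yk) / (lib[i] * yk) + (lib[ref] - yr) / (lib[ref] * yr)
    n <- length(m)
    sel_m <- order(m)[(floor(n * trim_m) + 1):(n - floor(n * trim_m))]
    sel_a <- order(a)[(floor(n * trim_a) + 1):(n - floor(n * trim_a))]
    sel <- intersect(sel_m, sel_a)
    2 ^ (sum(m[sel] / v[sel]) / sum(1 / v[sel]))
  })
  f / exp(mean(log(f)))
}

# direct NB log-pmf from the Gamma-function formula (oracle for nb_loglik)
oracle_nb_logpmf <- function(y, mu, phi) {
  if (phi == 0) return(sum(-mu + y * log(mu) - lfactorial(y)))
  r <- 1 / phi
  sum(lgamma(y + r) - lgamma(r) - lfactorial(y) +
        y * log(mu / (mu + r)) + r * log(r / (mu + r)))
}

# derivative-free maximization of the NB GLM log-likelihood (oracle for
# the IRLS fitter); Nelder-Mead from a crude start, restarted once
oracle_glm_loglik <- function(y, X, offsets, phi) {
  negll <- function(b) {
    mu <- pmax(exp(offsets + drop(X %*% b)), 1e-10)
    -nb_loglik(y, mu, phi)
  }
  o1 <- optim(rep(0, ncol(X)), negll, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  o2 <- optim(o1$par, negll, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  -o2$value
}
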