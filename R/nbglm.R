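#' Build full and reduced design matrices for the spatial test
#'
#' Single-sample designs use cluster-means coding (one indicator column per
#' cluster, no intercept) against an intercept-only reduced model.
#' Multi-sample designs use an intercept, C-1 cluster dummies and J-1 sample
#' dummies (first sample as baseline); the reduced model keeps intercept and
#' sample dummies and the cluster dummies are the tested set.
#'
#' @param spots A `spot_table` (see [spot_table()]).
#' @param model `"single"` or `"multi"`. `"auto"` picks `"multi"` when a
#'   `sample` column with two or more levels is present.
#' @return An `svg_design` list: `X_full`, `X_reduced`, `df_test`,
#'   `cluster_levels`, `sample_levels`, `model`, and `group_full` /
#'   `group_reduced` (integer partition labels when the design is a pure
#'   grouping, NULL otherwise).
#' @export
build_design <- function(spots, model = c("auto", "single", "multi")) {
  stopifnot(inherits(spots, "spot_table"))
  model <- match.arg(model)
  cl <- droplevels(spots$cluster)
  C <- nlevels(cl)
  if (C < 2L) stop("spatial test undefined with one cluster")
  has_sample <- "sample" %in% names(spots) &&
    nlevels(droplevels(spots$sample)) >= 2L
  if (model == "auto") model <- if (has_sample) "multi" else "single"
  if (model == "multi" && !has_sample)
    stop("multi-sample model requires a 'sample' column with >= 2 levels")
  if (model == "single") {
    X_full <- stats::model.matrix(~ 0 + cl)
    colnames(X_full) <- paste0("cluster_", levels(cl))
    X_red <- matrix(1, nrow(X_full), 1, dimnames = list(NULL, "intercept"))
    des <- list(X_full = X_full, X_reduced = X_red, df_test = C - 1L,
                cluster_levels = levels(cl), sample_levels = NULL,
                model = "single",
                group_full = as.integer(cl),
                group_reduced = rep(1L, length(cl)))
  } else {
    sm <- droplevels(spots$sample)
    X_full <- stats::model.matrix(~ cl + sm)
    X_red <- stats::model.matrix(~ sm)
    qr_full <- qr(X_full)
    if (qr_full$rank < ncol(X_full)) {
      tab <- table(cl, sm)
      confounded <- rownames(tab)[rowSums(tab > 0) == 1L]
      stop("design is rank deficient: cluster and sample are confounded",
           if (length(confounded))
             paste0(" (cluster(s) present in a single sample: ",
                    paste(confounded, collapse = ", "), ")"))
    }
    colnames(X_full) <- c("intercept",
                          paste0("cluster_", levels(cl)[-1]),
                          paste0("sample_", levels(sm)[-1]))
    colnames(X_red) <- c("intercept", paste0("sample_", levels(sm)[-1]))
    des <- list(X_full = X_full, X_reduced = X_red, df_test = C - 1L,
                cluster_levels = levels(cl), sample_levels = levels(sm),
                model = "multi", group_full = NULL, group_reduced = NULL)
  }
  structure(des, class = "svg_design")
}

#' Negative binomial log-likelihood
#'
#' Sum of the exact NB log pmf with mean `mu` and dispersion `phi`
#' (variance `mu * (1 + mu * phi)`); `phi = 0` is the Poisson limit, handled
#' analytically.
#'
#' @param y Integer counts.
#' @param mu Positive means (recycled to `length(y)`).
#' @param phi Dispersion, a single value >= 0.
#' @return The summed log-likelihood.
#' @export
nb_loglik <- function(y, mu, phi) {
  stopifnot(all(mu > 0), length(phi) == 1L, phi >= 0)
  if (phi == 0)
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  else
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# Row-wise NB log-likelihood for a genes x spots matrix with per-gene phi.
.nb_loglik_rows <- function(Y, Mu, phi) {
  ll <- numeric(nrow(Y))
  pois <- phi == 0
  if (any(pois))
    ll[pois] <- rowSums(stats::dpois(Y[pois, , drop = FALSE],
                                     Mu[pois, , drop = FALSE], log = TRUE))
  if (any(!pois)) {
    # size = 1/phi recycles down columns, matching genes in rows
    ll[!pois] <- rowSums(stats::dnbinom(
      Y[!pois, , drop = FALSE], size = 1 / phi[!pois],
      mu = Mu[!pois, , drop = FALSE], log = TRUE))
  }
  ll
}

#' Fit a per-gene NB GLM with log link and fixed dispersion
#'
#' Iteratively reweighted least squares with step-halving; the linear
#' predictor is `offset + X beta`. Convergence is declared when the relative
#' deviance change falls below `tol` (default 1e-8) or after `max_iter`
#' iterations.
#'
#' @param y Counts for one gene, length N.
#' @param X Design matrix (N x P), full column rank.
#' @param offsets Log effective library sizes, length N.
#' @param phi Fixed dispersion (>= 0).
#' @param tol Relative deviance convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @param beta_init Optional starting coefficients (warm start).
#' @return A `gene_fit` list: `beta`, `mu`, `loglik`, `converged`,
#'   `iterations`, `boundary` (TRUE for an all-zero gene fitted at the mean
#'   floor).
#' @export
fit_gene_glm <- function(y, X, offsets, phi, tol = 1e-8, max_iter = 50L,
                         beta_init = NULL) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(offsets) == nrow(X),
            all(is.finite(offsets)), phi >= 0)
  mu_floor <- 1e-8
  all_zero <- all(y == 0)
  if (is.null(beta_init)) {
    # init from log counts (continuity-shimmed) regressed on X
    eta0 <- log(y + 1 / 6) - offsets
    beta <- qr.solve(X, eta0)
  } else {
    stopifnot(length(beta_init) == ncol(X))
    beta <- beta_init
  }
  eta <- offsets + drop(X %*% beta)
  mu <- pmax(exp(eta), mu_floor)
  ll <- nb_loglik(y, mu, phi)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- mu / (1 + phi * mu)
    z <- (eta - offsets) + (y - mu) / mu
    xtwx <- crossprod(X, X * w)
    beta_new <- tryCatch(
      solve(xtwx, crossprod(X, w * z))[, 1L],
      error = function(e) NULL)
    if (is.null(beta_new)) break
    step <- 1
    ok <- FALSE
    for (h in seq_len(10L)) {
      b <- beta + step * (beta_new - beta)
      eta_try <- offsets + drop(X %*% b)
      mu_try <- pmax(pmin(exp(eta_try), 1e10), mu_floor)
      ll_try <- nb_loglik(y, mu_try, phi)
      if (is.finite(ll_try) && ll_try >= ll - 1e-12) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break
    dev_old <- -2 * ll
    beta <- b; eta <- eta_try; mu <- mu_try; ll <- ll_try
    if (abs(-2 * ll - dev_old) / (abs(-2 * ll) + 0.1) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(beta = beta, mu = mu, loglik = ll,
                 converged = converged || all_zero, iterations = it,
                 boundary = all_zero),
            class = "gene_fit")
}

# Vectorized fitter for partition ("grouping") designs: all genes at once.
# Y: genes x spots; group: integer partition over spots; offsets: length N;
# phi: per-gene dispersion (scalar recycled). Solves, per group and gene, the
# 1-D score equation sum((y - mu)/(1 + phi mu)) = 0 with mu = M_i exp(beta)
# by Newton iterations (the score is monotone in beta).
.fit_groups_nb <- function(Y, group, offsets, phi, cr_adjust = FALSE) {
  G <- nrow(Y); N <- ncol(Y)
  if (length(phi) == 1L) phi <- rep(phi, G)
  M <- exp(offsets)
  groups <- sort(unique(group))
  C <- length(groups)
  beta <- matrix(NA_real_, G, C)
  Mu <- matrix(0, G, N)
  cradj <- if (cr_adjust) numeric(G) else NULL
  for (k in seq_along(groups)) {
    idx <- which(group == groups[k])
    Yc <- Y[, idx, drop = FALSE]
    Mc <- M[idx]
    tot <- rowSums(Yc)
    sM <- sum(Mc)
    b <- log((tot + 1 / 6) / sM)
    zero <- tot == 0
    b[zero] <- log(1e-8 / sM)
    live <- which(!zero)
    if (length(live)) {
      bl <- b[live]
      Yl <- Yc[live, , drop = FALSE]
      pl <- phi[live]
      for (iter in seq_len(60L)) {
        mu <- exp(bl) %o% Mc
        den <- 1 + pl * mu
        f <- rowSums((Yl - mu) / den)
        fp <- -rowSums(mu * (1 + pl * Yl) / (den * den))
        stepv <- f / fp
        stepv[!is.finite(stepv)] <- 0
        stepv <- pmax(pmin(stepv, 3), -3)
        bl <- bl - stepv
        if (max(abs(stepv)) < 1e-12) break
      }
      b[live] <- bl
    }
    beta[, k] <- b
    Mu[, idx] <- exp(b) %o% Mc
  }
  Mu <- pmax(Mu, 1e-10)
  ll <- .nb_loglik_rows(Y, Mu, phi)
  if (cr_adjust) {
    W <- Mu / (1 + phi * Mu)
    for (k in seq_along(groups)) {
      idx <- which(group == groups[k])
      cradj <- cradj +
        0.5 * log(pmax(rowSums(W[, idx, drop = FALSE]), 1e-10))
    }
  }
  list(beta = beta, mu = Mu, loglik = ll, cr_adjustment = cradj,
       groups = groups)
}

#' Likelihood-ratio test between nested fits
#'
#' The statistic is `2 * (loglik_full - loglik_reduced)`, clipped at zero;
#' the p-value is the upper tail of a chi-square with `df` degrees of
#' freedom. Both fits must share the same dispersion and offsets. A
#' statistic below -1e-6 signals non-convergence and yields `p = NA`.
#'
#' @param full,reduced `gene_fit` objects (or their log-likelihoods).
#' @param df Degrees of freedom (number of tested coefficients).
#' @return An `lrt_result` list: `statistic`, `df`, `pvalue`, `flagged`.
#' @export
lrt <- function(full, reduced, df) {
  llf <- if (inherits(full, "gene_fit")) full$loglik else full
  llr <- if (inherits(reduced, "gene_fit")) reduced$loglik else reduced
  stat <- 2 * (llf - llr)
  flagged <- is.na(stat) | stat < -1e-6
  stat <- pmax(stat, 0)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  p[flagged] <- NA_real_
  structure(list(statistic = stat, df = df, pvalue = p, flagged = flagged),
            class = "lrt_result")
}
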