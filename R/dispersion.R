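#' Estimate NB dispersions by Cox-Reid adjusted profile likelihood
#'
#' For every gene the adjusted profile log-likelihood
#' `APL(phi) = loglik(beta_hat(phi); phi) - 0.5 * logdet(X' W X)` is
#' evaluated on a log-spaced dispersion grid (mean-model coefficients are
#' re-fitted at every grid point; the determinant term is the Cox-Reid
#' correction for their estimation). Three estimators are derived:
#'
#' * `common`: maximizer of the APL summed over genes;
#' * `trended`: a lowess fit of per-gene APL maximizers against mean
#'   log2-CPM, evaluated at each gene's abundance;
#' * `tagwise`: empirical-Bayes shrinkage, maximizing
#'   `APL_g(log phi) - (prior_df / 4) * (log phi - log trend_g)^2`,
#'   i.e. a Gaussian prior with precision `prior_df / 2` on the log
#'   dispersion centered at the trend. As `prior_df -> Inf` the tagwise
#'   estimates collapse onto the trend.
#'
#' Grid maxima are refined by golden-section search on a cubic-spline
#' interpolant of the APL over log dispersion. All-zero genes are excluded
#' from the trend and get `NA` tagwise values.
#'
#' @param cm A [count_matrix].
#' @param design An `svg_design` from [build_design()]; its full model is
#'   used.
#' @param offsets Log effective library sizes, length N.
#' @param prior_df Prior degrees of freedom for the shrinkage (default 10).
#' @param grid_length Number of grid points (default 21).
#' @param grid_range Dispersion grid range (default `c(1e-4, 10)`).
#' @param trend_span Lowess span for the abundance trend (default 0.3).
#' @return A `dispersion_estimates` list: `common`, `trended`, `tagwise`,
#'   `phi_mle` (per-gene unshrunk maximizers), `prior_df`, `mean_logcpm`,
#'   `gene_ids`, `zero_gene`.
#' @export
estimate_dispersions <- function(cm, design, offsets, prior_df = 10,
                                 grid_length = 21L,
                                 grid_range = c(1e-4, 10),
                                 trend_span = 0.3) {
  stopifnot(inherits(cm, "count_matrix"), inherits(design, "svg_design"))
  Y <- t(cm$counts)
  G <- nrow(Y); N <- ncol(Y)
  P <- ncol(design$X_full)
  if (N <= P) stop("need more spots than model coefficients (N > P)")
  grid_phi <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                      length.out = grid_length))
  lphi <- log(grid_phi)
  zero <- rowSums(Y) == 0
  A <- .apl_grid(Y, design, offsets, grid_phi)
  use <- which(!zero)
  if (!length(use)) stop("all genes have zero counts")

  mlc <- .mean_logcpm(Y, exp(offsets))

  # per-gene interpolants and unshrunk maximizers
  splines <- vector("list", G)
  phi_mle <- rep(NA_real_, G)
  for (g in use) {
    sf <- stats::splinefun(lphi, A[g, ], method = "fmm")
    splines[[g]] <- sf
    phi_mle[g] <- exp(.max_interp(sf, A[g, ], lphi))
  }

  # common dispersion from the summed APL
  Acom <- colSums(A[use, , drop = FALSE])
  sf_com <- stats::splinefun(lphi, Acom, method = "fmm")
  common <- exp(.max_interp(sf_com, Acom, lphi))

  # abundance trend of the per-gene maximizers
  trended <- rep(NA_real_, G)
  if (length(use) < 10L) {
    warning("fewer than 10 usable genes; dispersion trend set to common")
    trended[use] <- common
  } else {
    # sort by (abundance, estimate) so the fit is permutation-invariant
    ord <- order(mlc[use], phi_mle[use])
    lw <- stats::lowess(mlc[use][ord], log(phi_mle[use][ord]),
                        f = trend_span)
    trended[use] <- exp(stats::approx(lw$x, lw$y, xout = mlc[use],
                                      rule = 2, ties = mean)$y)
  }

  # EB shrinkage toward the trend
  tagwise <- rep(NA_real_, G)
  rng <- range(lphi)
  for (g in use) {
    sf <- splines[[g]]
    lt <- log(trended[g])
    obj <- function(x) sf(x) - (prior_df / 4) * (x - lt)^2
    opt <- stats::optimize(obj, interval = rng, maximum = TRUE,
                           tol = 1e-10)
    tagwise[g] <- exp(opt$maximum)
  }

  structure(list(common = common, trended = trended, tagwise = tagwise,
                 phi_mle = phi_mle, prior_df = prior_df,
                 mean_logcpm = mlc, gene_ids = cm$gene_ids,
                 zero_gene = zero, grid = grid_phi),
            class = "dispersion_estimates")
}

# APL matrix (genes x grid) for either a grouping design (vectorized Newton)
# or a general design (per-gene IRLS with warm starts across the grid).
.apl_grid <- function(Y, design, offsets, grid_phi) {
  G <- nrow(Y)
  A <- matrix(NA_real_, G, length(grid_phi))
  if (!is.null(design$group_full)) {
    for (k in seq_along(grid_phi)) {
      fit <- .fit_groups_nb(Y, design$group_full, offsets, grid_phi[k],
                            cr_adjust = TRUE)
      A[, k] <- fit$loglik - fit$cr_adjustment
    }
  } else {
    X <- design$X_full
    for (g in seq_len(G)) {
      y <- Y[g, ]
      if (all(y == 0)) next
      beta <- NULL
      for (k in seq_along(grid_phi)) {
        fit <- fit_gene_glm(y, X, offsets, grid_phi[k], beta_init = beta)
        beta <- fit$beta
        w <- fit$mu / (1 + grid_phi[k] * fit$mu)
        xtwx <- crossprod(X, X * w)
        ld <- determinant(xtwx, logarithm = TRUE)$modulus
        A[g, k] <- fit$loglik - 0.5 * as.numeric(ld)
      }
    }
  }
  A
}

# golden-section/parabolic refinement of a grid maximum on the interpolant
.max_interp <- function(sf, vals, lphi) {
  i <- which.max(vals)
  lo <- lphi[max(1L, i - 1L)]
  hi <- lphi[min(length(lphi), i + 1L)]
  if (lo == hi) return(lo)
  stats::optimize(sf, interval = c(lo, hi), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# mean log2 counts-per-million with the standard 0.5 / 1 continuity offsets;
# Y genes x spots, M per-spot effective sizes
.mean_logcpm <- function(Y, M) {
  L <- log2(1e6 * sweep(Y + 0.5, 2L, M + 1, "/"))
  rowMeans(L)
}
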