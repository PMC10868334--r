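# run code under a local seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Build a spatial pattern mask over a set of spots
#'
#' Partitions the tissue into a key region (`"in"`) and its complement
#' (`"out"`), following one of five profiles:
#'
#' * `bottom_right`: split at the median of one coordinate (default `y`);
#' * `circular`: disk around the coordinate centroid whose radius is found
#'   by bisection so that about half the spots (configurable) fall inside;
#' * `annotations`: a designated set of cluster labels vs the rest;
#' * `mixture`: cluster-based, highly abundant key regions;
#' * `inverted_mixture`: cluster-based, lowly abundant key regions.
#'
#' For the mixture-type patterns the returned `region` column marks the
#' designated cluster (`params$cluster`, defaulting to the smallest one),
#' but the simulators treat these patterns as a mixture of cluster-based
#' profiles: unless `params$cluster` pins a single cluster, every SVG gene
#' is assigned its own key cluster, so different genes follow different
#' spatial structures (the mask carries the full cluster labeling for this
#' purpose).
#'
#' @param spots A `spot_table`.
#' @param pattern One of `"bottom_right"`, `"circular"`, `"annotations"`,
#'   `"mixture"`, `"inverted_mixture"`.
#' @param params Optional list: `axis` (`"y"`/`"x"`, bottom_right),
#'   `target_frac` (circular, default 0.5), `clusters` (annotations),
#'   `cluster` (mixture patterns; default smallest cluster).
#' @return A `pattern_mask` data.frame with columns `spot_id` and `region`
#'   (factor, levels `out`/`in`), with attributes `pattern`, `key_cluster`
#'   (cluster label when the region is cluster-based) and
#'   `default_direction`.
#' @export
make_mask <- function(spots,
                      pattern = c("bottom_right", "circular", "annotations",
                                  "mixture", "inverted_mixture"),
                      params = list()) {
  stopifnot(inherits(spots, "spot_table"))
  pattern <- match.arg(pattern)
  key_cluster <- NA_character_
  per_gene_keys <- FALSE
  if (pattern == "bottom_right") {
    axis <- params$axis %||% "y"
    v <- spots[[axis]]
    inside <- v <= stats::median(v)
  } else if (pattern == "circular") {
    target <- params$target_frac %||% 0.5
    d <- sqrt((spots$x - mean(spots$x))^2 + (spots$y - mean(spots$y))^2)
    lo <- 0; hi <- max(d)
    for (i in seq_len(60L)) {
      mid <- (lo + hi) / 2
      if (mean(d <= mid) < target) lo <- mid else hi <- mid
    }
    inside <- d <= hi
  } else {
    if (!("cluster" %in% names(spots)) || anyNA(spots$cluster))
      stop("pattern '", pattern, "' requires cluster labels for all spots")
    if (pattern == "annotations") {
      sel <- params$clusters %||% levels(spots$cluster)[1L]
    } else {
      if (is.null(params$cluster)) {
        per_gene_keys <- TRUE
        sizes <- table(spots$cluster)
        sel <- names(sizes)[which.min(sizes)]
      } else {
        sel <- params$cluster
        key_cluster <- sel[1L]
      }
    }
    bad <- setdiff(sel, levels(spots$cluster))
    if (length(bad)) stop("unknown cluster label(s): ",
                          paste(bad, collapse = ", "))
    inside <- spots$cluster %in% sel
  }
  if (!any(inside) || all(inside))
    stop("degenerate mask: the key region must be a strict subset of spots")
  structure(
    data.frame(spot_id = spots$spot_id,
               region = factor(ifelse(inside, "in", "out"),
                               levels = c("out", "in")),
               stringsAsFactors = FALSE),
    pattern = pattern,
    key_cluster = key_cluster,
    per_gene_keys = per_gene_keys,
    clusters = if ("cluster" %in% names(spots))
      stats::setNames(as.character(spots$cluster), spots$spot_id),
    cluster_levels = if ("cluster" %in% names(spots))
      levels(spots$cluster),
    default_direction = switch(pattern, mixture = "high",
                               inverted_mixture = "low", "both"),
    class = c("pattern_mask", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Semi-simulate spatially variable genes by rearranging anchor counts
#'
#' For each designated SVG the gene's observed counts are rank-split so that
#' the largest (direction `"high"`) or smallest (`"low"`) values land in the
#' mask's key region, in uniformly random order within each region; uniform
#' genes are randomly permuted across the whole tissue. Every gene's count
#' multiset — and hence its marginal distribution — is preserved exactly.
#'
#' Under geometric patterns half of the SVGs are assigned `"high"` and half
#' `"low"` direction; mixture / inverted-mixture patterns fix the direction.
#'
#' @param cm Anchor [count_matrix] covering the mask spots.
#' @param mask A `pattern_mask` from [make_mask()].
#' @param prop_svg Proportion of genes designated SVG; defaults to 0.5 for
#'   mixture-type patterns and 1/3 otherwise.
#' @param seed Integer seed (reproducible output).
#' @return A list: `counts` (rearranged [count_matrix]) and `truth`
#'   (data.frame `gene_id`, `is_svg`, `pattern`, `key_region`, `tier`,
#'   `direction`).
#' @export
simulate_from_anchor <- function(cm, mask, prop_svg = NULL, seed = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(mask, "pattern_mask"))
  if (!setequal(cm$spot_ids, mask$spot_id))
    stop("anchor counts do not cover the mask spots")
  .with_seed(seed, {
    truth <- .draw_truth(cm$gene_ids, mask, prop_svg)
    counts <- .rearrange_counts(cm, mask, truth)
    list(counts = counts, truth = truth)
  })
}

.draw_truth <- function(gene_ids, mask, prop_svg = NULL) {
  pattern <- attr(mask, "pattern")
  if (is.null(prop_svg))
    prop_svg <- if (pattern %in% c("mixture", "inverted_mixture")) 0.5
                else 1 / 3
  G <- length(gene_ids)
  n_svg <- round(prop_svg * G)
  if (n_svg > G) stop("prop_svg requests more SVGs than genes available")
  is_svg <- rep(FALSE, G)
  is_svg[sample.int(G, n_svg)] <- TRUE
  svg_idx <- which(is_svg)
  dirs <- rep(NA_character_, G)
  dd <- attr(mask, "default_direction")
  if (n_svg > 0) {
    if (dd == "both") {
      hi <- sample(svg_idx, floor(n_svg / 2))
      dirs[svg_idx] <- "low"
      dirs[hi] <- "high"
    } else dirs[svg_idx] <- dd
  }
  key <- rep(NA_character_, G)
  if (isTRUE(attr(mask, "per_gene_keys"))) {
    # mixture of cluster-based profiles: every SVG gets its own key cluster
    key[svg_idx] <- sample(attr(mask, "cluster_levels"), n_svg,
                           replace = TRUE)
  } else {
    kc <- attr(mask, "key_cluster")
    key[svg_idx] <- if (is.na(kc)) "in" else kc
  }
  data.frame(gene_id = gene_ids, is_svg = is_svg,
             pattern = pattern, key_region = key,
             tier = NA_character_, direction = dirs,
             stringsAsFactors = FALSE)
}

.rearrange_counts <- function(cm, mask, truth) {
  x <- cm$counts
  region_in <- mask$region[match(cm$spot_ids, mask$spot_id)] == "in"
  clusters <- attr(mask, "clusters")
  if (!is.null(clusters)) clusters <- clusters[cm$spot_ids]
  lev <- attr(mask, "cluster_levels")
  out <- x
  all_idx <- seq_len(nrow(x))
  for (g in seq_len(ncol(x))) {
    y <- x[, g]
    if (truth$is_svg[g]) {
      key <- truth$key_region[g]
      inside <- if (!is.null(clusters) && key %in% lev) clusters == key
                else region_in
      idx_in <- which(inside)
      idx_out <- which(!inside)
      n_in <- length(idx_in)
      ys <- sort(y, decreasing = truth$direction[g] == "high")
      out[idx_in[sample.int(n_in)], g] <- ys[seq_len(n_in)]
      out[idx_out[sample.int(length(idx_out))], g] <-
        ys[(n_in + 1):length(ys)]
    } else {
      out[, g] <- y[sample.int(length(y))]
    }
  }
  count_matrix(out)
}

#' Fully synthetic NB spatial simulation with ground truth
#'
#' Places spots on a square grid, partitions them into vertical-band
#' clusters, draws per-gene baseline abundances from a log-normal, applies a
#' multiplicative spatial effect (`2^log2fc`, up or down depending on the
#' pattern direction) to SVG genes inside their key region, and samples
#' counts from a negative binomial with per-spot depths uniform in
#' `lib_size_range`. Half of the SVGs carry the strong and half the weak
#' effect tier by default. For mixture-type patterns every SVG is assigned
#' its own key cluster, so the dataset mixes cluster-based profiles;
#' geometric patterns share one key region, with half the SVGs high and
#' half low inside it.
#'
#' With `n_samples > 1`, independent replicate samples sharing the same
#' truth (same SVG genes, tiers, directions, key region) are generated and
#' stacked, with a `sample` column in the spot table.
#'
#' @param n_spots Spots per sample (default 1000).
#' @param n_genes Number of genes (default 1000).
#' @param n_clusters Number of spatial clusters (vertical bands).
#' @param cluster_props Optional band size proportions (length
#'   `n_clusters`); default equal, except mixture-type patterns where the
#'   first band shrinks to 10% to provide a small key region.
#' @param prop_svg Proportion of SVG genes (default 0.5).
#' @param log2fc Named vector `c(strong=, weak=)` of log2 fold changes
#'   (defaults 1.0 and 0.5).
#' @param tier_props Proportions of SVGs in the strong/weak tiers
#'   (default 0.5/0.5).
#' @param phi NB dispersion (default 0.4; 0 gives Poisson counts).
#' @param lib_size_range Range of per-spot sequencing depths (default
#'   `c(10000, 40000)`; only their relative values matter).
#' @param pattern Spatial profile, as in [make_mask()].
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   per-spot gene abundance (defaults 0 and 1).
#' @param n_samples Number of replicate samples (default 1).
#' @param seed Integer seed.
#' @return A list: `counts` ([count_matrix]), `spots` (`spot_table`),
#'   `truth` (see [simulate_from_anchor()], plus `tier`), `mask`.
#' @export
simulate_synthetic <- function(n_spots = 1000L, n_genes = 1000L,
                               n_clusters = 5L, cluster_props = NULL,
                               prop_svg = 0.5,
                               log2fc = c(strong = 1.0, weak = 0.5),
                               tier_props = c(strong = 0.5, weak = 0.5),
                               phi = 0.4,
                               lib_size_range = c(10000, 40000),
                               pattern = "mixture",
                               baseline_meanlog = 0, baseline_sdlog = 1,
                               n_samples = 1L, seed = NULL) {
  stopifnot(prop_svg >= 0, prop_svg <= 1, phi >= 0, n_clusters >= 2)
  .with_seed(seed, {
    if (is.null(cluster_props))
      cluster_props <- rep(1 / n_clusters, n_clusters)
    stopifnot(length(cluster_props) == n_clusters)
    cluster_props <- cluster_props / sum(cluster_props)

    base_spots <- .grid_spots(n_spots, cluster_props)
    mask <- make_mask(base_spots, pattern)

    # gene-level truth, shared across replicate samples
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    truth <- .draw_truth(gene_ids, mask, prop_svg)
    svg_idx <- which(truth$is_svg)
    n_svg <- length(svg_idx)
    if (n_svg > 0) {
      tier_props <- tier_props / sum(tier_props)
      n_strong <- round(tier_props[["strong"]] * n_svg)
      tiers <- rep("weak", n_svg)
      tiers[sample.int(n_svg, n_strong)] <- "strong"
      truth$tier[svg_idx] <- tiers
    }
    lambda <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)

    lfc <- rep(0, n_genes)
    lfc[svg_idx] <- log2fc[truth$tier[svg_idx]]
    sign_dir <- ifelse(truth$direction == "high", 1, -1)
    sign_dir[is.na(sign_dir)] <- 0
    # per-gene key-region membership over spots (spots x genes)
    cl_chr <- as.character(base_spots$cluster)
    region_in <- mask$region[match(base_spots$spot_id, mask$spot_id)] == "in"
    inside <- matrix(FALSE, n_spots, n_genes)
    for (g in svg_idx) {
      key <- truth$key_region[g]
      inside[, g] <- if (key %in% levels(base_spots$cluster))
        cl_chr == key else region_in
    }

    samples <- vector("list", n_samples)
    for (j in seq_len(n_samples)) {
      sp <- base_spots
      if (n_samples > 1L) {
        sp$spot_id <- paste0("s", j, "_", sp$spot_id)
        sp$sample <- paste0("sample", j)
      }
      depth <- stats::runif(n_spots, lib_size_range[1], lib_size_range[2])
      s <- depth / mean(depth)
      # mu[spot, gene] = lambda_g * depth_i * effect
      mu <- outer(s, lambda)
      eff <- 2 ^ (inside * rep(sign_dir * lfc, each = n_spots))
      mu <- mu * eff
      counts <- if (phi == 0) stats::rpois(length(mu), mu)
                else stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
      m <- matrix(as.integer(counts), n_spots, n_genes,
                  dimnames = list(sp$spot_id, truth$gene_id))
      samples[[j]] <- list(counts = m, spots = sp)
    }
    counts <- do.call(rbind, lapply(samples, `[[`, "counts"))
    spots_df <- do.call(rbind, lapply(samples, `[[`, "spots"))
    spots <- spot_table(as.data.frame(spots_df))
    list(counts = count_matrix(counts), spots = spots, truth = truth,
         mask = mask)
  })
}

# square grid of spots cut into vertical bands with given size proportions
.grid_spots <- function(n_spots, cluster_props) {
  side <- ceiling(sqrt(n_spots))
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n_spots), ]
  ord <- order(xy$x, xy$y)
  sizes <- diff(round(cumsum(c(0, cluster_props)) * n_spots))
  labels <- rep(paste0("cl", seq_along(cluster_props)), times = sizes)
  cl <- character(n_spots)
  cl[ord] <- labels
  spot_table(data.frame(spot_id = paste0("spot", seq_len(n_spots)),
                        x = xy$x, y = xy$y, cluster = cl,
                        stringsAsFactors = FALSE))
}

#' Multi-sample semi-simulation with consistent SVGs
#'
#' Applies the anchor-rearrangement simulation to each sample of a list,
#' with a single shared gene-level truth: the same genes are SVGs, with the
#' same pattern and direction, in every sample; within-region placement is
#' re-randomized independently per sample.
#'
#' @param anchors List of samples, each a list with elements `counts`
#'   ([count_matrix]) and `spots` (`spot_table`). All samples must share the
#'   same gene universe.
#' @param pattern Spatial profile, as in [make_mask()].
#' @param prop_svg Proportion of SVG genes (pattern-dependent default).
#' @param params Mask parameters, see [make_mask()].
#' @param seed Integer seed.
#' @return A list with one element per sample, each containing `counts` and
#'   `truth`; truth tables are identical across samples.
#' @export
simulate_multisample <- function(anchors, pattern, prop_svg = NULL,
                                 params = list(), seed = NULL) {
  stopifnot(length(anchors) >= 2L)
  genes <- anchors[[1L]]$counts$gene_ids
  for (j in seq_along(anchors)) {
    gj <- anchors[[j]]$counts$gene_ids
    if (!setequal(gj, genes))
      stop("gene universe mismatch between samples 1 and ", j)
  }
  .with_seed(seed, {
    masks <- lapply(anchors, function(a)
      make_mask(a$spots, pattern, params))
    lev1 <- attr(masks[[1L]], "cluster_levels")
    if (isTRUE(attr(masks[[1L]], "per_gene_keys"))) {
      for (j in seq_along(masks)[-1L]) {
        if (!setequal(attr(masks[[j]], "cluster_levels"), lev1))
          stop("cluster labels must match across samples for a ",
               "consistent mixture-type simulation")
      }
    }
    truth <- .draw_truth(genes, masks[[1L]], prop_svg)
    lapply(seq_along(anchors), function(j) {
      cm <- anchors[[j]]$counts
      # align gene order to the shared truth
      x <- cm$counts[, match(genes, cm$gene_ids), drop = FALSE]
      list(counts = .rearrange_counts(count_matrix(x), masks[[j]], truth),
           truth = truth)
    })
  })
}

#' Randomly relabel a fraction of spots
#'
#' Emulates imperfect spatially resolved clustering by reassigning a random
#' subset of spots to a different, randomly chosen cluster.
#'
#' @param spots A `spot_table`.
#' @param fraction Fraction of spots to relabel (in `[0, 1]`).
#' @param seed Integer seed.
#' @return The perturbed `spot_table`.
#' @export
perturb_clusters <- function(spots, fraction, seed = NULL) {
  stopifnot(inherits(spots, "spot_table"), fraction >= 0, fraction <= 1)
  .with_seed(seed, {
    n <- nrow(spots)
    k <- round(fraction * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      lev <- levels(spots$cluster)
      cur <- as.character(spots$cluster[idx])
      new <- vapply(cur, function(l) sample(setdiff(lev, l), 1L),
                    character(1))
      spots$cluster[idx] <- factor(new, levels = lev)
    }
    spots
  })
}
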