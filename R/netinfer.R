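#' Configuration for the B-spline mutual-information estimator
#'
#' @param n_bins number of B-spline basis functions / bins; NULL (default)
#'   adapts to the sample size as `max(10, ceiling(1.2 * n^(1/3)))`, i.e. 10
#'   bins at the 100-500 arrays typical of a category dataset, finer for
#'   large samples so the estimator's resolution (and hence its bias at
#'   strong dependence) tracks n.
#' @param spline_order B-spline order (degree + 1; default 3).
#' @param permutations permutation draws for the pooled null (default 1000,
#'   minimum 100).
#' @param significance_level per-pair significance for the global MI threshold
#'   (default 0.01).
#' @param dpi_tolerance data-processing-inequality tolerance in \[0,1\]
#'   (default 0, strict DPI).
#' @param seed integer seed; mandatory, every stochastic step derives from it.
#' @return list of class `mi_config`.
#' @export
mi_config <- function(n_bins = NULL, spline_order = 3, permutations = 1000,
                      significance_level = 0.01, dpi_tolerance = 0,
                      seed = NULL) {
  if (is.null(seed)) np_abort("mi_config requires an explicit seed", "config_error")
  stopifnot(spline_order >= 1, is.null(n_bins) || spline_order <= n_bins,
            permutations >= 100,
            significance_level > 0, dpi_tolerance >= 0, dpi_tolerance <= 1)
  structure(list(n_bins = if (!is.null(n_bins)) as.integer(n_bins),
                 spline_order = spline_order,
                 permutations = permutations,
                 significance_level = significance_level,
                 dpi_tolerance = dpi_tolerance, seed = as.integer(seed)),
            class = "mi_config")
}

#' Configuration for PCC significance thresholding
#'
#' @param permutations permutation rounds (default 100, minimum 10).
#' @param fdr_level empirical false-discovery target (default 0.01).
#' @param seed integer seed; mandatory.
#' @return list of class `pcc_config`.
#' @export
pcc_config <- function(permutations = 100, fdr_level = 0.01, seed = NULL) {
  if (is.null(seed)) np_abort("pcc_config requires an explicit seed", "config_error")
  stopifnot(permutations >= 10, fdr_level > 0)
  structure(list(permutations = permutations, fdr_level = fdr_level,
                 seed = as.integer(seed)),
            class = "pcc_config")
}

#' All-pairs Pearson correlation
#'
#' @param mat `expr_mat` with at least 3 arrays. Genes with zero variance are
#'   excluded with a warning.
#' @return symmetric correlation matrix over the retained genes.
#' @export
pcc_all_pairs <- function(mat) {
  if (ncol(mat) < 3) np_abort("need at least 3 arrays", "validation_error")
  v <- unclass(mat)
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(paste0(sum(sds == 0), " zero-variance gene(s) excluded"))
    v <- v[sds > 0, , drop = FALSE]
  }
  stats::cor(t(v))
}

#' Permutation FDR threshold for correlation networks
#'
#' Each permutation round independently shuffles every gene's values, giving a
#' pooled null distribution of absolute correlations. The threshold is the
#' smallest t for which the expected number of null pairs at or above t,
#' divided by the observed number at or above t, does not exceed `fdr_level`.
#'
#' @param mat `expr_mat`.
#' @param cfg a `pcc_config`.
#' @return threshold on |r| in \[0,1\]; 1 with a warning when no t satisfies
#'   the bound.
#' @export
pcc_threshold <- function(mat, cfg) {
  stopifnot(inherits(cfg, "pcc_config"))
  if (cfg$fdr_level >= 1) return(0)
  v <- unclass(mat)
  v <- v[apply(v, 1, stats::sd) > 0, , drop = FALSE]
  obs <- abs(offdiag(stats::cor(t(v))))
  null <- local_seed(cfg$seed, {
    unlist(lapply(seq_len(cfg$permutations), function(b) {
      pv <- t(apply(v, 1, sample))
      abs(offdiag(stats::cor(t(pv))))
    }))
  })
  cand <- sort(unique(c(0, obs)))
  n_obs <- length(obs)
  obs_ge <- n_obs - findInterval(cand - 1e-15, sort(obs))
  null_ge <- (length(null) - findInterval(cand - 1e-15, sort(null))) /
    cfg$permutations
  ok <- obs_ge > 0 & (null_ge / obs_ge) <= cfg$fdr_level
  if (!any(ok)) {
    rlang::warn("no threshold satisfies the FDR bound; returning 1 (empty network)")
    return(1)
  }
  cand[which(ok)[1]]
}

offdiag <- function(m) m[upper.tri(m)]

# evaluate code with a local RNG state derived from seed
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Build a PCC network
#'
#' Edges are gene pairs whose absolute correlation reaches the permutation
#' FDR threshold; edge scores are the signed correlations.
#'
#' @param mat `expr_mat`.
#' @param cfg a `pcc_config`.
#' @param provenance provenance tag for the network.
#' @return a `gene_network` (method `"pcc"`); attribute `threshold` records
#'   the cutoff used.
#' @export
pcc_network <- function(mat, cfg, provenance = "complete") {
  r <- pcc_all_pairs(mat)
  thr <- pcc_threshold(mat, cfg)
  idx <- which(upper.tri(r) & abs(r) >= thr & thr < 1, arr.ind = TRUE)
  edges <- tibble(from = rownames(r)[idx[, 1]], to = colnames(r)[idx[, 2]],
                  score = r[idx])
  net <- gene_network(edges, rownames(mat), "pcc", provenance)
  attr(net, "threshold") <- thr
  net
}

# bin count for a sample size: 10 up to ~500 samples, then ~1.2 n^(1/3)
adaptive_bins <- function(n_bins, n) {
  n_bins %||% max(10L, as.integer(ceiling(1.2 * n^(1/3))))
}

# B-spline fractional membership weights on rank-scaled data: n x n_bins,
# rows sum to 1.
bspline_weights <- function(x, n_bins = 10, spline_order = 3) {
  n <- length(x)
  z <- (rank(x, ties.method = "average") - 1) / (n - 1)
  z <- pmin(pmax(z, 0), 1 - 1e-12)
  k <- spline_order
  inner <- if (n_bins > k) seq_len(n_bins - k) / (n_bins - k + 1) else numeric()
  knots <- c(rep(0, k), inner, rep(1, k))
  w <- splines::splineDesign(knots, z, ord = k)
  w / rowSums(w)
}

#' B-spline mutual information between two vectors
#'
#' Both vectors are rank-scaled to \[0,1\] (making the estimate invariant to
#' strictly monotone transforms), assigned fractional membership over `n_bins`
#' B-spline basis functions, and plugged into the discrete MI formula on the
#' weighted marginal and joint histograms. Reported in nats, clamped at 0.
#'
#' @param x,y numeric vectors of equal length (>= 20 recommended).
#' @param cfg an `mi_config`.
#' @return mutual information estimate in nats.
#' @export
bspline_mi <- function(x, y, cfg) {
  stopifnot(inherits(cfg, "mi_config"), length(x) == length(y))
  if (length(x) < 4) np_abort("too few observations for MI", "validation_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("constant vector: MI is 0")
    return(0)
  }
  m <- adaptive_bins(cfg$n_bins, length(x))
  wx <- bspline_weights(x, m, cfg$spline_order)
  wy <- bspline_weights(y, m, cfg$spline_order)
  mi_from_weights(wx, wy)
}

mi_from_weights <- function(wx, wy) {
  n <- nrow(wx)
  joint <- crossprod(wx, wy) / n
  px <- colSums(wx) / n
  py <- colSums(wy) / n
  pos <- joint > 0
  mi <- sum(joint[pos] * log(joint[pos] / outer(px, py)[pos]))
  max(mi, 0)
}

#' Build an MI network with a pooled permutation null
#'
#' Computes B-spline MI for every gene pair. The global threshold is the
#' (1 - significance_level) quantile of a pooled null formed by MI values of
#' randomly chosen pairs with one member's sample order permuted
#' (`cfg$permutations` draws). Edges are pairs with MI above the threshold.
#'
#' @param mat `expr_mat` with at least 2 genes.
#' @param cfg an `mi_config`.
#' @param provenance provenance tag.
#' @return a `gene_network` (method `"mi"`); attribute `threshold` records the
#'   MI cutoff.
#' @export
mi_network <- function(mat, cfg, provenance = "complete") {
  stopifnot(inherits(cfg, "mi_config"))
  v <- unclass(mat)
  if (nrow(v) < 2) np_abort("need at least 2 genes", "validation_error")
  keep <- apply(v, 1, stats::sd) > 0
  if (!all(keep)) rlang::warn(paste0(sum(!keep), " constant gene(s) excluded"))
  vv <- v[keep, , drop = FALSE]
  G <- nrow(vv); n <- ncol(vv)
  m_bins <- adaptive_bins(cfg$n_bins, n)
  W <- lapply(seq_len(G), function(i)
    bspline_weights(vv[i, ], m_bins, cfg$spline_order))
  thr <- if (cfg$significance_level >= 1) -Inf else local_seed(cfg$seed, {
    null <- vapply(seq_len(cfg$permutations), function(b) {
      ij <- sample.int(G, 2)
      mi_from_weights(W[[ij[1]]][sample.int(n), , drop = FALSE], W[[ij[2]]])
    }, 0)
    stats::quantile(null, 1 - cfg$significance_level, names = FALSE, type = 7)
  })
  rows <- vector("list", G * (G - 1) / 2)
  k <- 0L
  for (i in seq_len(G - 1)) {
    for (j in seq(i + 1, G)) {
      mi <- mi_from_weights(W[[i]], W[[j]])
      if (mi > thr) {
        k <- k + 1L
        rows[[k]] <- c(i, j, mi)
      }
    }
  }
  edges <- if (k > 0) {
    m <- do.call(rbind, rows[seq_len(k)])
    tibble(from = rownames(vv)[m[, 1]], to = rownames(vv)[m[, 2]],
           score = m[, 3])
  } else NULL
  net <- gene_network(edges, rownames(v), "mi", provenance)
  attr(net, "threshold") <- thr
  net
}

#' Data-processing-inequality pruning
#'
#' For every triangle in the network, the strictly weakest edge is removed
#' when its score falls below `min(other two) * (1 - tolerance)`. All
#' triangles are examined against the original scores in a single pass, so the
#' result is independent of edge order; ties (no strict minimum) remove
#' nothing.
#'
#' @param net an MI-scored `gene_network`.
#' @param tolerance proportion in \[0,1\] (default 0, strict DPI).
#' @return pruned `gene_network` (vertex set unchanged).
#' @export
dpi_prune <- function(net, tolerance = 0) {
  stopifnot(inherits(net, "gene_network"), tolerance >= 0, tolerance <= 1)
  e <- net$edges
  if (nrow(e) < 3) return(net)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE)
  tri <- matrix(igraph::vertex_attr(g, "name")[igraph::triangles(g)], nrow = 3)
  if (ncol(tri) == 0) return(net)
  key <- function(a, b) paste0(pmin(a, b), "\r", pmax(a, b))
  score <- stats::setNames(e$score, key(e$from, e$to))
  drop <- character()
  for (t in seq_len(ncol(tri))) {
    ks <- c(key(tri[1, t], tri[2, t]), key(tri[1, t], tri[3, t]),
            key(tri[2, t], tri[3, t]))
    s <- score[ks]
    w <- which.min(s)
    if (s[w] < min(s[-w]) * (1 - tolerance)) drop <- c(drop, ks[w])
  }
  keep <- !(key(e$from, e$to) %in% drop)
  gene_network(e[keep, ], net$vertices, net$method, net$provenance)
}
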