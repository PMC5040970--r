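#' Per-gene interquartile range
#'
#' IQR = Q3 - Q1 with linearly interpolated quantiles (type 7), the dominant
#' convention in both major statistics ecosystems. IQR values are convention
#' sensitive, so the rule is pinned here and used everywhere in the package.
#'
#' @param mat `expr_mat` (any space; normally the normalized matrix).
#' @return tibble `gene`, `iqr`, ordered as the matrix rows.
#' @export
gene_iqr <- function(mat) {
  n <- ncol(mat)
  if (n < 2) np_abort("IQR needs at least 2 arrays", "validation_error")
  if (n < 4) rlang::warn("fewer than 4 arrays: IQR estimates are degenerate")
  v <- unclass(mat)
  q <- t(apply(v, 1, stats::quantile, probs = c(0.25, 0.75), type = 7,
               names = FALSE))
  tibble(gene = rownames(v), iqr = unname(q[, 2] - q[, 1]))
}

#' Survivor profile over IQR thresholds
#'
#' For each grid point t, counts the genes with IQR >= t, plus the
#' central-difference derivative at interior grid points. The grid runs from 0
#' to just past the largest IQR in steps of `grid_step`.
#'
#' @param iqrs tibble from [gene_iqr()] (or numeric vector of IQR values).
#' @param grid_step grid spacing in log2 units (default 0.01).
#' @return tibble of class `iqr_profile`: `threshold`, `survivors`,
#'   `derivative` (NA at the end points).
#' @export
build_iqr_profile <- function(iqrs, grid_step = 0.01) {
  x <- if (is.data.frame(iqrs)) iqrs$iqr else iqrs
  if (!length(x)) np_abort("no IQR values", "validation_error")
  if (grid_step <= 0) np_abort("grid_step must be > 0", "config_error")
  grid <- seq(0, max(x) + grid_step, by = grid_step)
  surv <- vapply(grid, function(t) sum(x >= t), 0L)
  n <- length(grid)
  deriv <- rep(NA_real_, n)
  if (n >= 3)
    deriv[2:(n - 1)] <- (surv[3:n] - surv[1:(n - 2)]) / (2 * grid_step)
  out <- tibble(threshold = grid, survivors = surv, derivative = deriv)
  class(out) <- c("iqr_profile", class(out))
  out
}

#' Derivative-minimum threshold selector
#'
#' Picks the grid point where the survivor profile drops fastest (the minimum
#' of its first derivative, i.e. the steepest slope). Ties break toward the
#' smallest grid value; a flat profile returns the first grid point with a
#' warning.
#'
#' @param profile an `iqr_profile`.
#' @return threshold q in log2 units.
#' @export
derivative_threshold <- function(profile) {
  d <- profile$derivative
  interior <- which(!is.na(d))
  if (length(interior) < 1)
    np_abort("profile needs at least 3 grid points", "validation_error")
  dv <- d[interior]
  if (diff(range(dv)) == 0) {
    rlang::warn("flat IQR profile: derivative has no unique minimum")
    return(profile$threshold[1])
  }
  profile$threshold[interior[which.min(dv)]]
}

#' IQR histogram and histogram-mode threshold selector
#'
#' Bins the per-gene IQR values (bins anchored at 0) and selects q as the
#' centre of the bin holding the most genes -- the dataset's characteristic
#' IQR. Ties break toward the lowest-IQR bin.
#'
#' @param iqrs tibble from [gene_iqr()] or numeric vector.
#' @param bin_width bin width in log2 units (default 0.025).
#' @return for [build_iqr_histogram()], a tibble of class `iqr_histogram`
#'   (`bin_left`, `bin_center`, `count`); for [histogram_threshold()], the
#'   selected q.
#' @export
build_iqr_histogram <- function(iqrs, bin_width = 0.025) {
  x <- if (is.data.frame(iqrs)) iqrs$iqr else iqrs
  if (!length(x)) np_abort("no IQR values", "validation_error")
  if (bin_width <= 0) np_abort("bin_width must be > 0", "config_error")
  idx <- floor(x / bin_width)
  tab <- table(factor(idx, levels = 0:max(idx)))
  out <- tibble(bin_left = as.integer(names(tab)) * bin_width,
                bin_center = (as.integer(names(tab)) + 0.5) * bin_width,
                count = as.integer(tab))
  stopifnot(sum(out$count) == length(x))
  class(out) <- c("iqr_histogram", class(out))
  out
}

#' @rdname build_iqr_histogram
#' @export
histogram_threshold <- function(iqrs, bin_width = 0.025) {
  h <- build_iqr_histogram(iqrs, bin_width)
  h$bin_center[which.max(h$count)]   # which.max takes the first (lowest) tie
}

#' Apply an IQR filter
#'
#' Keeps genes whose IQR is at least q (genes with IQR strictly below q are
#' eliminated).
#'
#' @param mat `expr_mat`.
#' @param q threshold (>= 0).
#' @param iqrs optional precomputed [gene_iqr()] table for `mat`.
#' @return list with `matrix` (filtered `expr_mat`) and `report` (tibble
#'   `gene`, `iqr`, `retained`).
#' @export
apply_filter <- function(mat, q, iqrs = NULL) {
  stopifnot(q >= 0)
  iqrs <- iqrs %||% gene_iqr(mat)
  keep <- iqrs$iqr >= q
  if (!any(keep)) rlang::warn("IQR filter eliminated every gene")
  report <- tibble(gene = iqrs$gene, iqr = iqrs$iqr, retained = keep)
  class(report) <- c("filter_report", class(report))
  list(matrix = expr_subset(mat, rows = which(keep)), report = report)
}

#' @export
autoplot.iqr_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$survivors)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "IQR threshold (log2 units)",
                  y = "surviving genes", title = "IQR profile")
}

#' @export
autoplot.iqr_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_center[1:2]) * 0.95,
                      fill = "steelblue") +
    ggplot2::labs(x = "gene IQR (log2 units)", y = "genes",
                  title = "IQR histogram")
}
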