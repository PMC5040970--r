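#' Summarize probe-level intensities into probe-set signals
#'
#' One-step Tukey biweight of the log2 probe intensities within each probe-set,
#' per array; the signal is reported back on the raw intensity scale
#' (2^biweight). This is a deliberately simple robust summarization front end:
#' it downweights outlying probes the way the classic Affymetrix signal
#' computation does, without mismatch-probe background handling.
#'
#' @param mat probe-level raw `expr_mat`.
#' @param probe_map tibble with columns `probe_id`, `probe_set_id` covering
#'   every row of `mat`.
#' @return probe-set level raw `expr_mat` (rows ordered by probe-set id).
#' @export
summarize_probesets <- function(mat, probe_map) {
  stopifnot(expr_space(mat) == "raw")
  pm <- probe_map[match(rownames(mat), probe_map$probe_id), ]
  if (anyNA(pm$probe_set_id))
    np_abort("probe rows missing from probe_map", "validation_error")
  sets <- split(seq_len(nrow(mat)), pm$probe_set_id)
  if (any(lengths(sets) == 0)) np_abort("empty probe-set", "validation_error")
  lg <- log2(pmax(unclass(mat), 2^-20))
  out <- t(vapply(sets, function(idx) {
    sub <- lg[idx, , drop = FALSE]
    if (nrow(sub) == 1L) return(sub[1, ])
    biweight_cols(sub)
  }, numeric(ncol(mat))))
  dimnames(out) <- list(names(sets), colnames(mat))
  expr_mat(2^out, "raw")
}

# column-wise one-step Tukey biweight of a small matrix, vectorized over columns
biweight_cols <- function(m, c = 5, eps = 1e-4) {
  med <- fast_col_medians(m)
  s <- fast_col_medians(abs(sweep(m, 2, med)))
  u <- sweep(sweep(m, 2, med), 2, c * s + eps, `/`)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sw <- colSums(w)
  ifelse(sw == 0, med, colSums(w * m) / pmax(sw, .Machine$double.eps))
}

#' Scale every array to a common trimmed-mean target
#'
#' Each column is multiplied by its scale factor `target / trimmed_mean`, the
#' MAS-style global scaling step, so all arrays share trimmed mean `target`.
#'
#' @param mat raw probe-set `expr_mat`.
#' @param target target intensity (default 1000).
#' @param trim trim fraction per tail (default 0.02).
#' @return scaled raw `expr_mat`; attribute `scale_factors` is a named vector.
#' @export
global_scale <- function(mat, target = 1000, trim = 0.02) {
  stopifnot(expr_space(mat) == "raw")
  tm <- apply(unclass(mat), 2, trimmed_mean, trim = trim)
  if (any(tm <= 0))
    np_abort(paste0("zero trimmed mean for array: ", colnames(mat)[tm <= 0][1]),
             "normalization_error")
  sf <- target / tm
  out <- expr_mat(sweep(unclass(mat), 2, sf, `*`), "raw")
  attr(out, "scale_factors") <- sf
  out
}

#' Log2 transform and per-gene mean centering
#'
#' Values are floored at `eps` (default 1e-6 of the scaling target, guarding
#' against underflow from background-free summarization), log2 transformed,
#' then each gene row is centred on its across-array mean.
#'
#' @param mat scaled raw `expr_mat`.
#' @param eps positive floor applied before the log (default 1e-3).
#' @return `expr_mat` in space `log2_centered`; attribute `gene_means` holds
#'   the per-gene log2 means that were subtracted.
#' @export
log2_and_center <- function(mat, eps = 1e-3) {
  stopifnot(expr_space(mat) == "raw", eps > 0)
  lg <- log2(pmax(unclass(mat), eps))
  m <- rowMeans(lg)
  out <- expr_mat(lg - m, "log2_centered", allow_na = TRUE)
  attr(out, "gene_means") <- m
  out
}

#' Quantile normalization
#'
#' Forces every array to share one empirical distribution: the mean of the
#' sorted columns. Tied values within a column receive the mean of the
#' reference values at their tied ranks, so the map is deterministic.
#'
#' @param mat `expr_mat` without missing values (any space; the result is
#'   tagged `normalized`).
#' @return quantile-normalized `expr_mat`.
#' @export
quantile_normalize <- function(mat) {
  v <- unclass(mat)
  if (anyNA(v)) np_abort("quantile normalization requires complete data", "validation_error")
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(x) {
    assigned <- ref[order(order(x))]          # i-th order stat of ref to i-th of x
    stats::ave(assigned, match(x, x), FUN = mean)  # average over tied ranks
  })
  dimnames(out) <- dimnames(v)
  expr_mat(out, "normalized")
}

#' Run the full normalization chain with a stage trace
#'
#' Applies, in order: probe-set summarization, global scaling, log2 + mean
#' centering, quantile normalization. The order of centering and quantile
#' normalization can be swapped with `quantile_first = TRUE` (the conventional
#' order); the default applies quantile normalization last.
#'
#' @param mat probe-level raw `expr_mat`.
#' @param probe_map probe to probe-set map (see [summarize_probesets()]).
#' @param target scaling target intensity.
#' @param quantile_first if TRUE, quantile-normalize the log2 matrix before
#'   mean centering.
#' @return normalized `expr_mat`; attribute `trace` is a tibble recording each
#'   stage, its output checksum and summary statistics.
#' @export
normalize_expression <- function(mat, probe_map, target = 1000,
                                 quantile_first = FALSE) {
  trace <- list()
  note <- function(stage, m, extra = NA_real_) {
    trace[[length(trace) + 1]] <<- tibble(
      stage = stage, checksum = rlang::hash(round(unclass(m), 9)),
      mean_value = mean(unclass(m)), extra = extra)
  }
  s1 <- summarize_probesets(mat, probe_map); note("summarize", s1)
  s2 <- global_scale(s1, target = target); note("scale", s2)
  if (quantile_first) {
    lg <- log2(pmax(unclass(s2), 1e-3))
    qn <- quantile_normalize(expr_mat(lg, "log2")); note("quantile", qn)
    ctr <- unclass(qn) - rowMeans(unclass(qn))
    out <- expr_mat(ctr, "normalized"); note("center", out)
  } else {
    s3 <- log2_and_center(s2); note("log2_center", s3)
    out <- quantile_normalize(s3); note("quantile", out)
  }
  attr(out, "trace") <- dplyr::bind_rows(trace)
  out
}
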