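#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trimmed mean of a numeric vector
#'
#' Two-tailed trimmed mean as used for array scale factors: the MAS convention
#' of trimming 2% from each tail before averaging.
#'
#' @param x numeric vector.
#' @param trim proportion trimmed from each tail (default 0.02).
#' @return scalar mean of the central values.
#' @export
trimmed_mean <- function(x, trim = 0.02) {
  stopifnot(is.numeric(x), trim >= 0, trim < 0.5)
  mean(x, trim = trim)
}

#' One-step Tukey biweight location estimate
#'
#' Robust average used to summarize log2 probe intensities into one probe-set
#' signal. Follows the MAS convention: centre at the median, scale by the MAD,
#' tuning constant `c`, small `eps` guard against zero scale. Points further
#' than `c` scaled deviations get zero weight.
#'
#' @param x numeric vector.
#' @param c tuning constant (default 5).
#' @param eps guard added to the denominator (default 1e-4).
#' @return scalar location estimate.
#' @export
tukey_biweight <- function(x, c = 5, eps = 1e-4) {
  stopifnot(is.numeric(x), length(x) >= 1)
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  u <- (x - m) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(m)
  sum(w * x) / sum(w)
}

#' Content hash of an array's value column
#'
#' Digest used for exact-duplicate detection; two arrays collide iff their
#' value columns are byte-identical.
#'
#' @param x numeric vector of raw intensities.
#' @return character digest.
#' @export
content_hash <- function(x) {
  rlang::hash(as.numeric(x))
}

# internal: consistent stop with class
np_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "netprep_error"))
}

# sort the rows of a matrix column-wise (each column ends up ascending) using
# a vectorized exchange network; fast for matrices with few rows and many
# columns, which is the shape of all per-probe-set computations here.
sort_within_columns <- function(m) {
  p <- nrow(m)
  for (i in seq_len(max(p - 1, 0))) {
    for (j in seq_len(p - i)) {
      a <- m[j, ]; b <- m[j + 1, ]
      m[j, ] <- pmin(a, b); m[j + 1, ] <- pmax(a, b)
    }
  }
  m
}

# column medians, vectorized for small row counts
fast_col_medians <- function(m) {
  p <- nrow(m)
  if (p == 1) return(m[1, ])
  if (p > 64) return(apply(m, 2, stats::median))
  s <- sort_within_columns(m)
  if (p %% 2 == 1) s[(p + 1) / 2, ] else (s[p / 2, ] + s[p / 2 + 1, ]) / 2
}
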