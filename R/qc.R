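#' Per-array scale factors
#'
#' The multiplier bringing each array's trimmed-mean probe-set signal to the
#' target intensity. Arrays whose trimmed mean is not positive get `NA` and an
#' error record.
#'
#' @param mat probe-set level raw `expr_mat`.
#' @param target target intensity (default 1000).
#' @param trim trim fraction per tail (default 0.02).
#' @return tibble `array_id`, `trimmed_mean`, `scale_factor`, `ok`.
#' @export
compute_scale_factors <- function(mat, target = 1000, trim = 0.02) {
  stopifnot(expr_space(mat) == "raw")
  tm <- unname(apply(unclass(mat), 2, trimmed_mean, trim = trim))
  tibble(array_id = colnames(mat), trimmed_mean = tm,
         scale_factor = ifelse(tm > 0, target / tm, NA_real_),
         ok = tm > 0)
}

#' Spike-in presence calls from control probe-sets
#'
#' A hybridization control is called present on an array when the mean log2
#' intensity of the control probe-sets exceeds `min_log2`.
#'
#' @param mat probe-set level raw `expr_mat`.
#' @param control_ids row ids of the control (spike-in) probe-sets.
#' @param min_log2 detection threshold on mean log2 control intensity
#'   (default 6, i.e. intensity 64).
#' @return tibble `array_id`, `control_log2`, `spikein_present`.
#' @export
detect_spikeins <- function(mat, control_ids, min_log2 = 6) {
  missing <- setdiff(control_ids, rownames(mat))
  if (length(missing))
    np_abort(paste0("control probe-set absent: ", missing[1]), "validation_error")
  ctl <- log2(pmax(unclass(mat)[control_ids, , drop = FALSE], 2^-20))
  m <- colMeans(ctl)
  tibble(array_id = colnames(mat), control_log2 = m,
         spikein_present = m > min_log2)
}

#' Scale-factor and spike-in QC rules
#'
#' An array fails when its scale factor exceeds three times the mean scale
#' factor of its submission, or when no spike-in signal is detected. A
#' single-array submission is its own mean, so it can never fail the 3x rule.
#'
#' @param submissions a `submission_set`.
#' @param scale_factors output of [compute_scale_factors()].
#' @param spikein_flags output of [detect_spikeins()].
#' @param multiplier scale-factor multiplier (default 3).
#' @return tibble `array_id`, `submission_id`, `scale_factor`,
#'   `submission_mean_factor`, `spikein_present`, `verdict` (`pass`,
#'   `fail_scale`, `fail_spikein`).
#' @export
filter_scale_and_spikein <- function(submissions, scale_factors, spikein_flags,
                                     multiplier = 3) {
  flat <- tibble(
    submission_id = rep(submissions$submission_id,
                        lengths(submissions$array_ids)),
    array_id = unlist(submissions$array_ids))
  flat <- dplyr::left_join(flat, scale_factors, by = "array_id") |>
    dplyr::left_join(spikein_flags[, c("array_id", "spikein_present")],
                     by = "array_id")
  if (anyNA(flat$scale_factor) && any(flat$ok %in% FALSE))
    flat$spikein_present[is.na(flat$spikein_present)] <- FALSE
  flat |>
    dplyr::group_by(.data$submission_id) |>
    dplyr::mutate(submission_mean_factor = mean(.data$scale_factor)) |>
    dplyr::ungroup() |>
    dplyr::mutate(verdict = dplyr::case_when(
      !.data$ok | is.na(.data$scale_factor) ~ "fail_scale",
      !.data$spikein_present ~ "fail_spikein",
      .data$scale_factor > multiplier * .data$submission_mean_factor ~ "fail_scale",
      TRUE ~ "pass")) |>
    dplyr::select("array_id", "submission_id", "scale_factor",
                  "submission_mean_factor", "spikein_present", "verdict")
}

# median polish on a stack of equally sized probe-sets, one submission's arrays.
# x: P x G x A array (probes within set, probe-sets, arrays). Alternates
# probe-direction and array-direction median sweeps, accumulating effects, as
# the classic iterative row/column median-sweep fit. Returns the chip-level
# fit (overall + array effect, G x A) and residuals (P x G x A).
polish_stack <- function(x, max_iter = 5L, eps = 0.01) {
  P <- dim(x)[1]; G <- dim(x)[2]; A <- dim(x)[3]
  t_overall <- numeric(G)
  row_eff <- matrix(0, P, G); col_eff <- matrix(0, G, A)
  r <- x
  for (it in seq_len(max_iter)) {
    rm_ <- matrix(fast_col_medians(t(matrix(r, P * G, A))), P, G)
    r <- r - as.vector(rm_)                     # recycled over arrays
    row_eff <- row_eff + rm_
    cm <- fast_col_medians(row_eff)             # recentre row effects
    row_eff <- sweep(row_eff, 2, cm); t_overall <- t_overall + cm
    cm_ <- matrix(fast_col_medians(matrix(r, P, G * A)), G, A)
    r <- r - rep(cm_, each = P)                 # recycled over probes
    col_eff <- col_eff + cm_
    cc <- fast_col_medians(t(col_eff))
    col_eff <- col_eff - cc                     # column-major recycle over arrays
    t_overall <- t_overall + cc
    if (max(abs(rm_)) + max(abs(cm_)) < eps) break
  }
  list(expression = col_eff + t_overall, residuals = r)
}

#' Probe-level model: RLE and NUSE
#'
#' Fits, within each submission and probe-set, the additive two-way model
#' (probe effect + array effect) by median polish on log2 probe intensities.
#' RLE is the fitted array-level expression minus its median across the
#' submission's arrays. The unscaled standard error of the array effect is
#' taken from the residual spread (`sd(residuals)/sqrt(P)` per array); NUSE
#' divides it by the probe-set's median standard error across arrays, with the
#' convention that an all-equal (including all-zero) standard-error profile
#' gives NUSE 1.
#'
#' @param mat probe-level `expr_mat`; raw values are log2-transformed first.
#' @param probe_map tibble `probe_id`, `probe_set_id`.
#' @param submissions a `submission_set`; the model is fitted per submission.
#'   If NULL, all arrays are treated as one submission.
#' @param polish_iter,polish_eps iteration cap and stopping tolerance (largest
#'   median moved in a sweep) for the median polish.
#' @return list with tibbles `rle` and `nuse`, each with `probe_set_id`,
#'   `array_id`, `value`, plus `low_confidence` (single-probe sets) on `nuse`.
#' @export
fit_probe_level_model <- function(mat, probe_map, submissions = NULL,
                                  polish_iter = 5L, polish_eps = 0.01) {
  v <- unclass(mat)
  if (expr_space(mat) == "raw") v <- log2(pmax(v, 2^-20))
  pm <- probe_map[match(rownames(v), probe_map$probe_id), ]
  if (anyNA(pm$probe_set_id))
    np_abort("probe rows missing from probe_map", "validation_error")
  groups <- if (is.null(submissions)) list(all = colnames(v)) else
    stats::setNames(submissions$array_ids, submissions$submission_id)
  sets <- split(seq_len(nrow(v)), pm$probe_set_id)
  sizes <- lengths(sets)
  rle_rows <- list(); nuse_rows <- list()
  for (sub_arrays in groups) {
    sub_arrays <- intersect(sub_arrays, colnames(v))
    if (length(sub_arrays) == 0) next
    A <- length(sub_arrays)
    for (P in sort(unique(sizes))) {
      idx_sets <- sets[sizes == P]
      G <- length(idx_sets)
      x <- array(t(v[unlist(idx_sets), sub_arrays, drop = FALSE]),
                 dim = c(A, P, G))
      x <- aperm(x, c(2, 3, 1))                # P x G x A
      fit <- polish_stack(x, max_iter = polish_iter, eps = polish_eps)
      expr <- fit$expression                   # G x A
      rle <- expr - fast_col_medians(t(expr))
      se <- sqrt(matrix(colSums(matrix(fit$residuals^2, P, G * A)), G, A) /
                   (P * max(P - 1, 1)))        # G x A unscaled SE
      med_se <- fast_col_medians(t(se))
      nuse <- se / ifelse(med_se > 0, med_se, 1)
      nuse[se == rep(med_se, A)] <- 1          # all-equal SE profile -> 1
      ids <- names(idx_sets)
      rle_rows[[length(rle_rows) + 1]] <- tibble(
        probe_set_id = rep(ids, A),
        array_id = rep(sub_arrays, each = G),
        value = as.vector(rle))
      nuse_rows[[length(nuse_rows) + 1]] <- tibble(
        probe_set_id = rep(ids, A),
        array_id = rep(sub_arrays, each = G),
        value = as.vector(nuse),
        low_confidence = P == 1L)
    }
  }
  list(rle = dplyr::bind_rows(rle_rows), nuse = dplyr::bind_rows(nuse_rows))
}

#' RLE/NUSE outlier rules
#'
#' Per array, over probe-sets: fail when the interquartile range of RLE or
#' NUSE exceeds `max_iqr`, or when the median RLE deviates from 0 (median NUSE
#' from 1) by strictly more than `max_center_dev`.
#'
#' @param rle,nuse tibbles from [fit_probe_level_model()].
#' @param max_iqr spread limit (default 0.75).
#' @param max_center_dev centre deviation limit (default 0.075).
#' @return tibble `array_id`, `rle_median`, `rle_iqr`, `nuse_median`,
#'   `nuse_iqr`, `verdict` (`pass`, `fail_rle`, `fail_nuse`).
#' @export
qc_outliers <- function(rle, nuse, max_iqr = 0.75, max_center_dev = 0.075) {
  iqr7 <- function(x) diff(stats::quantile(x, c(0.25, 0.75), type = 7,
                                           names = FALSE))
  a <- rle |> dplyr::group_by(.data$array_id) |>
    dplyr::summarise(rle_median = stats::median(.data$value),
                     rle_iqr = iqr7(.data$value), .groups = "drop")
  b <- nuse |> dplyr::group_by(.data$array_id) |>
    dplyr::summarise(nuse_median = stats::median(.data$value),
                     nuse_iqr = iqr7(.data$value), .groups = "drop")
  dplyr::left_join(a, b, by = "array_id") |>
    dplyr::mutate(verdict = dplyr::case_when(
      .data$rle_iqr > max_iqr | abs(.data$rle_median) > max_center_dev ~ "fail_rle",
      .data$nuse_iqr > max_iqr | abs(.data$nuse_median - 1) > max_center_dev ~ "fail_nuse",
      TRUE ~ "pass"))
}

#' Full array QC ledger
#'
#' Combines duplicate detection, the scale/spike-in rules and the RLE/NUSE
#' outlier rules into one per-array report; the first failing rule wins, with
#' duplicates taking precedence.
#'
#' @param mat probe-level raw `expr_mat`.
#' @param probe_map probe to probe-set map.
#' @param submissions a `submission_set` (hashes filled in if absent).
#' @param control_ids control probe-set ids for spike-in calls (optional).
#' @param exclude array ids excluded by manual inspection (optional).
#' @return tibble of class `qc_report`: one row per array with every rule's
#'   statistic and a final `verdict`.
#' @export
qc_report <- function(mat, probe_map, submissions, control_ids = NULL,
                      exclude = character()) {
  if (any(vapply(submissions$content_hashes, is.null, TRUE)))
    submissions <- hash_submissions(submissions, mat)
  dup <- find_exact_duplicates(submissions)
  smat <- summarize_probesets(mat, probe_map)
  sf <- compute_scale_factors(smat)
  spike <- if (is.null(control_ids))
    tibble(array_id = colnames(mat), control_log2 = NA_real_,
           spikein_present = TRUE)
  else detect_spikeins(smat, control_ids)
  rule1 <- filter_scale_and_spikein(submissions, sf, spike)
  plm <- fit_probe_level_model(mat, probe_map, submissions)
  rule2 <- qc_outliers(plm$rle, plm$nuse)
  out <- dplyr::left_join(rule1, rule2, by = "array_id") |>
    dplyr::left_join(spike[, c("array_id", "control_log2")], by = "array_id") |>
    dplyr::mutate(verdict = dplyr::case_when(
      .data$array_id %in% dup$duplicate ~ "duplicate",
      .data$array_id %in% exclude ~ "excluded",
      .data$verdict.x != "pass" ~ .data$verdict.x,
      .data$verdict.y != "pass" ~ .data$verdict.y,
      TRUE ~ "pass")) |>
    dplyr::select(-"verdict.x", -"verdict.y")
  class(out) <- c("qc_report", class(out))
  out
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble(n_arrays = nrow(x),
         n_pass = sum(x$verdict == "pass"),
         n_duplicate = sum(x$verdict == "duplicate"),
         n_fail = sum(!x$verdict %in% c("pass", "duplicate")))
}
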