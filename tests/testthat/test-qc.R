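test_that("scale factors are target over trimmed mean", {
  m <- tiny_expr(cbind(a1 = rep(500, 50), a2 = rep(1000, 50),
                       a3 = rep(0, 50)), "raw", cols = c("a1", "a2", "a3"))
  sf <- compute_scale_factors(m, target = 1000)
  expect_equal(sf$scale_factor[sf$array_id == "a1"], 2)
  expect_equal(sf$scale_factor[sf$array_id == "a2"], 1)
  expect_true(is.na(sf$scale_factor[sf$array_id == "a3"]))
  expect_false(sf$ok[sf$array_id == "a3"])
})

test_that("the three-times-mean scale rule works on the stated examples", {
  mk <- function(factors) {
    ids <- sprintf("a%02d", seq_along(factors))
    subs <- submission_set("S1", "GEO", "d", list(ids))
    sf <- tibble::tibble(array_id = ids, trimmed_mean = 1000 / factors,
                         scale_factor = factors, ok = TRUE)
    spike <- tibble::tibble(array_id = ids, control_log2 = 10,
                            spikein_present = TRUE)
    filter_scale_and_spikein(subs, sf, spike)
  }
  r1 <- mk(c(rep(1, 9), 4))           # mean 1.3, threshold 3.9
  expect_equal(r1$verdict[r1$scale_factor == 4], "fail_scale")
  expect_true(all(r1$verdict[r1$scale_factor == 1] == "pass"))

  r2 <- mk(c(1, 1, 2))                # mean 4/3, threshold 4: none fail
  expect_true(all(r2$verdict == "pass"))
})

test_that("missing spike-ins fail an array regardless of scale factor", {
  subs <- submission_set("S1", "GEO", "d", list(c("a1", "a2")))
  sf <- tibble::tibble(array_id = c("a1", "a2"), trimmed_mean = 1000,
                       scale_factor = 1, ok = TRUE)
  spike <- tibble::tibble(array_id = c("a1", "a2"), control_log2 = c(10, 2),
                          spikein_present = c(TRUE, FALSE))
  out <- filter_scale_and_spikein(subs, sf, spike)
  expect_equal(out$verdict, c("pass", "fail_spikein"))
})

test_that("a single-array submission cannot fail the 3x rule", {
  subs <- submission_set("S1", "GEO", "d", list("a1"))
  sf <- tibble::tibble(array_id = "a1", trimmed_mean = 10,
                       scale_factor = 100, ok = TRUE)
  spike <- tibble::tibble(array_id = "a1", control_log2 = 10,
                          spikein_present = TRUE)
  expect_equal(filter_scale_and_spikein(subs, sf, spike)$verdict, "pass")
})

test_that("identical columns give RLE 0 and NUSE 1 exactly", {
  col <- c(5, 6, 7, 8.5)
  m <- tiny_expr(cbind(a1 = col, a2 = col, a3 = col), "log2",
                 rows = paste0("ps1.p", 1:4), cols = c("a1", "a2", "a3"))
  pm <- tibble::tibble(probe_id = rownames(m), probe_set_id = "ps1")
  fit <- fit_probe_level_model(m, pm)
  expect_equal(fit$rle$value, rep(0, 3))
  expect_equal(fit$nuse$value, rep(1, 3))
})

test_that("the probe-level model matches an independent median-sweep oracle", {
  set.seed(21)
  for (i in 1:8) {
    P <- sample(2:5, 1); A <- sample(3:5, 1)
    x <- matrix(rnorm(P * A), P, A)
    m <- tiny_expr(x, "log2", rows = paste0("ps1.p", 1:P),
                   cols = paste0("a", 1:A))
    pm <- tibble::tibble(probe_id = rownames(m), probe_set_id = "ps1")
    fit <- fit_probe_level_model(m, pm, polish_iter = 20L, polish_eps = 0)
    oracle <- sweep_median_polish(x)
    want_rle <- (oracle$overall + oracle$col) -
      median(oracle$overall + oracle$col)
    expect_equal(fit$rle$value, unname(want_rle), tolerance = 1e-6)
    # and against the reference implementation; stopping rules differ, so
    # fitted values agree only to the convergence scale, not exactly
    mp <- suppressWarnings(
      stats::medpolish(x, trace.iter = FALSE, eps = 1e-9, maxiter = 50))
    ref_rle <- (mp$overall + mp$col) - median(mp$overall + mp$col)
    expect_equal(fit$rle$value, unname(ref_rle), tolerance = 2e-3)
  }
})

test_that("a +1 log2 global shift shows up as RLE median near +1", {
  set.seed(4)
  P <- 8; G <- 40; A <- 10
  base <- matrix(rnorm(P * G * A, rep(runif(G, 4, 8), each = P), 0.1),
                 P * G, A)
  base[, A] <- base[, A] + 1
  m <- tiny_expr(base, "log2",
                 rows = paste0(rep(sprintf("ps%02d", 1:G), each = P),
                               ".p", 1:P),
                 cols = paste0("a", 1:A))
  pm <- tibble::tibble(probe_id = rownames(m),
                       probe_set_id = rep(sprintf("ps%02d", 1:G), each = P))
  fit <- fit_probe_level_model(m, pm)
  med <- tapply(fit$rle$value, fit$rle$array_id, median)
  expect_equal(unname(med[paste0("a", A)]), 1, tolerance = 0.1)
  expect_lt(max(abs(med[paste0("a", 1:(A - 1))])), 0.2)
})

test_that("outlier rules use strict thresholds per array", {
  rle <- tibble::tibble(
    probe_set_id = rep(paste0("ps", 1:101), 3),
    array_id = rep(c("good", "shifted", "spread"), each = 101),
    value = c(seq(-0.1, 0.1, length.out = 101),
              seq(-0.1, 0.1, length.out = 101) + 0.10,
              seq(-1, 1, length.out = 101)))
  nuse <- rle
  nuse$value <- rep(seq(0.95, 1.05, length.out = 101), 3)
  out <- qc_outliers(rle, nuse)
  expect_equal(out$verdict[out$array_id == "good"], "pass")
  expect_equal(out$verdict[out$array_id == "shifted"], "fail_rle")  # 0.10 > 0.075
  expect_equal(out$verdict[out$array_id == "spread"], "fail_rle")   # IQR 1 > 0.75
})

test_that("an exactly-at-threshold array passes (strictly greater fails)", {
  mk <- function(center) tibble::tibble(
    probe_set_id = paste0("ps", 1:3), array_id = "a1",
    value = center + c(-0.01, 0, 0.01))
  out <- qc_outliers(mk(0.075), mk(1))
  expect_equal(out$verdict, "pass")
  out2 <- qc_outliers(mk(0.076), mk(1))
  expect_equal(out2$verdict, "fail_rle")
})

test_that("synthetic outliers are flagged and clean arrays nearly all pass", {
  comp <- fixture_compendium()
  qc <- fixture_qc()
  truth <- comp$truth
  expect_true(all(qc$verdict[qc$array_id %in% truth$outlier_array_ids] ==
                    "fail_rle"))
  expect_true(all(qc$verdict[qc$array_id %in% truth$spikein_absent_arrays] ==
                    "fail_spikein"))
  planted_bad <- c(truth$outlier_array_ids, truth$spikein_absent_arrays,
                   truth$duplicate_pairs$array_b,
                   truth$duplicate_pairs$array_a)
  clean <- qc[!qc$array_id %in% planted_bad, ]
  expect_gte(mean(clean$verdict == "pass"), 0.99)
})

test_that("QC verdicts ignore probe-row and array-column order", {
  comp <- fixture_compendium()
  qc1 <- fixture_qc()
  set.seed(8)
  m <- comp$matrix
  m2 <- expr_mat(unclass(m)[sample(nrow(m)), sample(ncol(m))], "raw")
  qc2 <- qc_report(m2, comp$probe_map, comp$submissions,
                   control_ids = comp$truth$control_probe_sets)
  merged <- merge(as.data.frame(qc1[, c("array_id", "verdict")]),
                  as.data.frame(qc2[, c("array_id", "verdict")]),
                  by = "array_id")
  expect_equal(merged$verdict.x, merged$verdict.y)
})
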