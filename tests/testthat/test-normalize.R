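test_that("probe-set summarization is a one-step Tukey biweight", {
  # constant probes pass through
  m <- tiny_expr(matrix(100, 4, 2), "raw", rows = paste0("ps1.p", 1:4))
  pm <- tibble::tibble(probe_id = rownames(m), probe_set_id = "ps1")
  expect_equal(unname(unclass(summarize_probesets(m, pm))[1, ]), c(100, 100))

  # single-probe set equals that probe
  m1 <- tiny_expr(matrix(c(7, 9), 1, 2), "raw", rows = "ps1.p1")
  pm1 <- tibble::tibble(probe_id = "ps1.p1", probe_set_id = "ps1")
  expect_equal(unname(unclass(summarize_probesets(m1, pm1))[1, ]), c(7, 9))

  # outlier probe is downweighted toward the majority
  probes <- c(100, 100, 100, 10000)
  m2 <- tiny_expr(matrix(probes, 4, 1), "raw", rows = paste0("ps1.p", 1:4))
  pm2 <- tibble::tibble(probe_id = rownames(m2), probe_set_id = "ps1")
  sig <- unclass(summarize_probesets(m2, pm2))[1, 1]
  expect_lt(abs(sig - 100), abs(sig - mean(probes)))
  # exact value from the definition, computed independently
  x <- log2(probes)
  med <- median(x); s <- median(abs(x - med))
  u <- (x - med) / (5 * s + 1e-4)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  expect_equal(sig, 2^(sum(w * x) / sum(w)), tolerance = 1e-12)
  expect_equal(tukey_biweight(x), sum(w * x) / sum(w), tolerance = 1e-12)
})

test_that("global scaling brings every column's trimmed mean to target", {
  m <- tiny_expr(matrix(rep(c(500, 1000), each = 60), 60, 2), "raw")
  out <- global_scale(m, target = 1000)
  expect_equal(unname(unclass(out)[1, ]), c(1000, 1000))
  expect_equal(unname(attr(out, "scale_factors")), c(2, 1))

  set.seed(2)
  r <- tiny_expr(matrix(rexp(300, 1 / 800), 100, 3), "raw")
  sc <- global_scale(r)
  tm <- apply(unclass(sc), 2, mean, trim = 0.02)
  expect_equal(unname(tm), rep(1000, 3), tolerance = 1e-6)

  z <- tiny_expr(matrix(0, 10, 1), "raw")
  expect_error(global_scale(z), class = "normalization_error")
})

test_that("log2 + centring zeroes every gene mean", {
  m <- tiny_expr(matrix(c(2, 8, 5, 5), 2, 2, byrow = TRUE), "raw")
  out <- log2_and_center(m)
  expect_equal(unname(unclass(out)[1, ]), c(-1, 1))
  expect_equal(unname(unclass(out)[2, ]), c(0, 0))

  set.seed(3)
  r <- tiny_expr(matrix(rexp(200, 1 / 500), 20, 10), "raw")
  out2 <- log2_and_center(r)
  expect_lt(max(abs(rowMeans(unclass(out2)))), 1e-9)
  expect_equal(expr_space(out2), "log2_centered")
})

test_that("quantile normalization matches the worked mean-of-sorted example", {
  m <- tiny_expr(cbind(A = c(2, 6, 10), B = c(4, 8, 6)), "log2",
                 cols = c("A", "B"))
  out <- unclass(quantile_normalize(m))
  expect_equal(unname(out[, "A"]), c(3, 6, 9))
  expect_equal(unname(out[, "B"]), c(3, 9, 6))
})

test_that("quantile normalization averages the reference over tied ranks", {
  m <- tiny_expr(cbind(A = c(1, 1, 5), B = c(2, 3, 4)), "log2",
                 cols = c("A", "B"))
  out <- unclass(quantile_normalize(m))
  ref <- rowMeans(cbind(sort(c(1, 1, 5)), sort(c(2, 3, 4))))
  expect_equal(unname(out[, "A"]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("identical columns are unchanged and any result has equal column multisets", {
  m <- tiny_expr(cbind(a = c(1, 3, 2), b = c(1, 3, 2)), "log2",
                 cols = c("a", "b"))
  expect_equal(unclass(quantile_normalize(m)), unclass(m),
               ignore_attr = TRUE)
  set.seed(6)
  r <- random_expr(15, 4, "log2")
  out <- unclass(quantile_normalize(r))
  for (j in 2:4) expect_equal(unname(sort(out[, j])),
                              unname(sort(out[, 1])))
})

test_that("quantile normalization is idempotent", {
  set.seed(7)
  r <- random_expr(30, 5, "log2")
  once <- quantile_normalize(r)
  twice <- quantile_normalize(once)
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-12)
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(8)
  for (i in 1:5) {
    v <- matrix(rnorm(20 * 4), 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("a", 1:4)))
    mine <- unclass(quantile_normalize(expr_mat(v, "log2")))
    ref <- limma::normalizeQuantiles(v)
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("scaling then log2 equals log2 then an additive shift", {
  set.seed(9)
  m <- tiny_expr(matrix(rexp(200, 1 / 700), 50, 4), "raw")
  sc <- global_scale(m)
  lhs <- log2(unclass(sc))
  sf <- attr(sc, "scale_factors")
  rhs <- sweep(log2(unclass(m)), 2, log2(sf), `+`)
  expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the full normalization chain runs in the stated order with a trace", {
  comp <- fixture_compendium()
  sub <- expr_subset(comp$matrix, cols = colnames(comp$matrix)[1:30])
  out <- normalize_expression(sub, comp$probe_map)
  tr <- attr(out, "trace")
  expect_equal(tr$stage, c("summarize", "scale", "log2_center", "quantile"))
  expect_equal(expr_space(out), "normalized")
  # swapped order is available but not the default
  out2 <- normalize_expression(sub, comp$probe_map, quantile_first = TRUE)
  expect_equal(attr(out2, "trace")$stage,
               c("summarize", "scale", "quantile", "center"))
})
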