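test_that("all-pairs PCC matches the textbook formula", {
  set.seed(20)
  m <- random_expr(10, 15)
  r <- pcc_all_pairs(m)
  v <- unclass(m)
  for (i in 1:9) for (j in (i + 1):10) {
    xi <- v[i, ]; xj <- v[j, ]
    want <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(r[i, j], want, tolerance = 1e-12)
  }
  expect_equal(diag(r), rep(1, 10), ignore_attr = TRUE)
  expect_equal(r, t(r))
  expect_true(all(abs(r) <= 1 + 1e-12))
})

test_that("exact linear relations give r of +1 and -1", {
  x <- c(1, 2, 3, 4, 5)
  m <- tiny_expr(rbind(a = x, b = 2 * x, c = -x), "normalized",
                 rows = c("a", "b", "c"))
  r <- pcc_all_pairs(m)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
})

test_that("zero-variance genes are excluded with a warning", {
  m <- tiny_expr(rbind(a = rnorm(5), flat = rep(2, 5)), "normalized",
                 rows = c("a", "flat"))
  expect_warning(r <- pcc_all_pairs(m), regexp = "zero-variance")
  expect_equal(rownames(r), "a")
})

test_that("unseeded network configs are rejected", {
  expect_error(pcc_config(), class = "config_error")
  expect_error(mi_config(), class = "config_error")
})

test_that("the FDR threshold behaves across regimes", {
  expect_equal(pcc_threshold(random_expr(5, 10),
                             pcc_config(fdr_level = 1, seed = 1)), 0)
  set.seed(21)
  for (s in 1:3) {
    v <- matrix(rnorm(20 * 200), 20, 200,
                dimnames = list(paste0("g", 1:20), paste0("a", 1:200)))
    em <- expr_mat(v, "normalized")
    net <- suppressWarnings(pcc_network(em, pcc_config(seed = s)))
    expect_lte(nrow(net$edges), 0.01 * choose(20, 2) * 2)  # nearly empty

    v2 <- v
    v2["g2", ] <- 0.95 * scale(v["g1", ])[, 1] + sqrt(1 - 0.95^2) * rnorm(200)
    net2 <- suppressWarnings(
      pcc_network(expr_mat(v2, "normalized"), pcc_config(seed = s)))
    expect_true(any(net2$edges$from == "g1" & net2$edges$to == "g2"))
  }
})

test_that("B-spline MI approaches the Gaussian closed form", {
  set.seed(22)
  n <- 5000; rho <- 0.9
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  est <- bspline_mi(x, y, mi_config(seed = 1))
  expect_lt(abs(est - (-0.5 * log(1 - rho^2))), 0.1)
})

test_that("MI is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rnorm(200); y <- x^2 + rnorm(200, sd = 0.2)
  cfg <- mi_config(seed = 1)
  base <- bspline_mi(x, y, cfg)
  expect_lt(abs(bspline_mi(exp(x), y, cfg) - base), 1e-9)
  expect_lt(abs(bspline_mi(x, y^3 + 10, cfg) - base), 1e-9)
})

test_that("independent data falls below its own permutation null tail", {
  set.seed(24)
  x <- runif(1000); y <- runif(1000)
  cfg <- mi_config(seed = 1)
  obs <- bspline_mi(x, y, cfg)
  null <- vapply(1:99, function(i) bspline_mi(x, sample(y), cfg), 0)
  expect_lt(obs, quantile(null, 0.95) + 0.02)
})

test_that("self-MI is the estimator's ceiling for a variable", {
  set.seed(25)
  x <- rnorm(300)
  cfg <- mi_config(seed = 1)
  self <- bspline_mi(x, x, cfg)
  for (i in 1:5) {
    y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(300)
    expect_gt(self, bspline_mi(x, y, cfg))
  }
  expect_warning(z <- bspline_mi(rep(1, 50), rnorm(50), cfg))
  expect_equal(z, 0)
})

test_that("MI networks are sparse under independence and complete at level 1", {
  set.seed(26)
  for (s in 1:3) {
    m <- random_expr(12, 100)
    net <- mi_network(m, mi_config(seed = s))
    expect_lte(nrow(net$edges), 0.01 * choose(12, 2) * 2)
  }
  m <- random_expr(6, 50)
  full <- mi_network(m, mi_config(significance_level = 1, seed = 1))
  expect_equal(nrow(full$edges), choose(6, 2))
})

test_that("MI finds a planted quadratic relation that PCC misses", {
  set.seed(27)
  n <- 300
  v <- matrix(rnorm(8 * n), 8, n,
              dimnames = list(paste0("g", 1:8), paste0("a", 1:n)))
  v["g2", ] <- (v["g1", ]^2 - 1) / sqrt(2) * 0.9 +
    sqrt(1 - 0.81) * rnorm(n)
  em <- expr_mat(v, "normalized")
  minet <- mi_network(em, mi_config(seed = 5))
  expect_true(any(minet$edges$from == "g1" & minet$edges$to == "g2"))
  pnet <- suppressWarnings(pcc_network(em, pcc_config(seed = 5)))
  expect_false(any(pnet$edges$from == "g1" & pnet$edges$to == "g2"))
})

test_that("DPI prunes the weakest edge of a triangle, keeping ties", {
  tri <- gene_network(tibble::tibble(from = c("X", "Y", "X"),
                                     to = c("Y", "Z", "Z"),
                                     score = c(0.8, 0.7, 0.2)), method = "mi")
  out <- dpi_prune(tri, 0)
  expect_equal(nrow(out$edges), 2L)
  expect_false(any(out$edges$from == "X" & out$edges$to == "Z"))

  eq <- gene_network(tibble::tibble(from = c("X", "Y", "X"),
                                    to = c("Y", "Z", "Z"),
                                    score = c(0.5, 0.5, 0.5)), method = "mi")
  expect_equal(nrow(dpi_prune(eq, 0)$edges), 3L)
})

test_that("DPI matches an all-triangles brute force on random graphs", {
  set.seed(28)
  for (i in 1:10) {
    vs <- paste0("G", 1:8)
    pairs <- t(combn(vs, 2))
    keep <- runif(nrow(pairs)) < 0.5
    net <- gene_network(tibble::tibble(from = pairs[keep, 1],
                                       to = pairs[keep, 2],
                                       score = round(runif(sum(keep), 0.05, 1), 3)),
                        vertices = vs, method = "mi")
    tol <- sample(c(0, 0.1), 1)
    got <- dpi_prune(net, tol)
    want <- brute_dpi(net, tol)
    expect_equal(got$edges, want$edges)
    # the strongest edge of every triangle always survives in got
    expect_true(all(net$edges$score[which.max(net$edges$score)] %in%
                      got$edges$score | nrow(net$edges) == 0))
  }
})

test_that("strict DPI is idempotent", {
  set.seed(29)
  vs <- paste0("G", 1:8)
  pairs <- t(combn(vs, 2))
  keep <- runif(nrow(pairs)) < 0.6
  net <- gene_network(tibble::tibble(from = pairs[keep, 1],
                                     to = pairs[keep, 2],
                                     score = runif(sum(keep))),
                      vertices = vs, method = "mi")
  once <- dpi_prune(net, 0)
  twice <- dpi_prune(once, 0)
  expect_equal(twice$edges, once$edges)
})
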