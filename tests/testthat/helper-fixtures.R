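# shared fixture builders; heavyweight objects are generated once per run

tiny_expr <- function(values, space = "raw",
                      rows = paste0("g", seq_len(nrow(values))),
                      cols = paste0("a", seq_len(ncol(values)))) {
  dimnames(values) <- list(rows, cols)
  expr_mat(values, space)
}

random_expr <- function(n_genes, n_arrays, space = "normalized", sd = 1) {
  tiny_expr(matrix(rnorm(n_genes * n_arrays, sd = sd), n_genes, n_arrays),
            space = space)
}

gene_id_at <- function(i) {
  sprintf("AT%dG%05d", (i - 1) %% 5 + 1, ((i - 1) %/% 5 + 1) * 10)
}

# 20-gene single-category compendium hosting planted relations, the
# structure-recovery scenario
recovery_config <- function(seed) {
  synth_config(
    n_genes = 20,
    categories = tibble::tibble(basis = "process", class_name = "Mixed",
                                n_submissions = 12L,
                                arrays_per_submission = 25L),
    frac_category_specific_genes = 0,
    tier_fractions = c(1, 0, 0),
    planted_edges = tibble::tibble(
      gene_a = gene_id_at(c(1, 2, 3, 5, 6)),
      gene_b = gene_id_at(c(2, 3, 4, 6, 7)),
      relation = c("linear", "linear", "quadratic", "sinusoidal", "linear"),
      strength = 0.9),
    n_exact_duplicates = 0, n_near_duplicates = 0,
    n_outlier_arrays = 0, n_spikein_absent = 0, seed = seed)
}

# log2 + centring is the appropriate normalization for a small planted panel
# (scaling and quantile normalization need compendium-scale gene counts)
recovery_matrix <- function(comp) {
  sm <- summarize_probesets(comp$matrix, comp$probe_map)
  cl <- cluster_and_select(clean_annotation(comp$annotation))
  log2_and_center(collapse_matrix(sm, cl))
}

.fixture_env <- new.env(parent = emptyenv())

# default compendium (seed 42), generated once
fixture_compendium <- function() {
  if (is.null(.fixture_env$comp))
    .fixture_env$comp <- generate_compendium(synth_config(seed = 42))
  .fixture_env$comp
}

# its QC report, computed once
fixture_qc <- function() {
  if (is.null(.fixture_env$qc)) {
    comp <- fixture_compendium()
    .fixture_env$qc <- qc_report(comp$matrix, comp$probe_map,
                                 comp$submissions,
                                 control_ids = comp$truth$control_probe_sets)
  }
  .fixture_env$qc
}

# full partitioned run without networks, computed once
fixture_partitioned <- function() {
  if (is.null(.fixture_env$part)) {
    comp <- fixture_compendium()
    .fixture_env$part <- suppressWarnings(
      run_partitioned(comp, filter_method = "histogram",
                      control_ids = comp$truth$control_probe_sets))
  }
  .fixture_env$part
}

# independent small-scale median polish: plain iterative row/column median
# sweeps on one two-way table, mirroring the textbook procedure
sweep_median_polish <- function(x, iter = 20) {
  row_eff <- rep(0, nrow(x)); col_eff <- rep(0, ncol(x)); overall <- 0
  r <- x
  for (i in seq_len(iter)) {
    rm_ <- apply(r, 1, median); r <- sweep(r, 1, rm_); row_eff <- row_eff + rm_
    m <- median(col_eff); col_eff <- col_eff - m; overall <- overall + m
    cm <- apply(r, 2, median); r <- sweep(r, 2, cm); col_eff <- col_eff + cm
    m <- median(row_eff); row_eff <- row_eff - m; overall <- overall + m
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r)
}

# brute-force union-find for the probe-cluster oracle
uf_clusters <- function(map) {
  n <- nrow(map)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && length(intersect(map$genes[[i]], map$genes[[j]])) > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(lapply(split(map$probe_set_id, roots), sort))
}

# brute-force DPI: enumerate all vertex triples
brute_dpi <- function(net, tolerance = 0) {
  e <- net$edges
  key <- function(a, b) paste0(pmin(a, b), "\r", pmax(a, b))
  score <- setNames(e$score, key(e$from, e$to))
  vs <- net$vertices
  drop <- character()
  if (length(vs) >= 3) {
    combs <- combn(vs, 3)
    for (i in seq_len(ncol(combs))) {
      tr <- combs[, i]
      ks <- c(key(tr[1], tr[2]), key(tr[1], tr[3]), key(tr[2], tr[3]))
      if (!all(ks %in% names(score))) next
      s <- score[ks]
      w <- which.min(s)
      if (s[w] < min(s[-w]) * (1 - tolerance)) drop <- c(drop, ks[w])
    }
  }
  keep <- !(key(e$from, e$to) %in% drop)
  gene_network(e[keep, ], net$vertices, net$method, net$provenance)
}
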