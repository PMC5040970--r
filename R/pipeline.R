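#' Run the full pipeline on the complete dataset
#'
#' Executes dedup + QC, probe-set summarization, annotation collapsing,
#' normalization, IQR filtering and both network constructions on the whole
#' compendium, and returns every intermediate plus a run ledger.
#'
#' @param compendium list as returned by [generate_compendium()] (or an
#'   equivalent assembled from files): `matrix`, `submissions`, `probe_map`,
#'   `annotation`.
#' @param filter_method `"histogram"`, `"derivative"` or `"fixed"`.
#' @param q fixed threshold (required when `filter_method = "fixed"`).
#' @param control_ids spike-in control probe-set ids (NULL skips the rule).
#' @param exclude manually excluded array ids.
#' @param pcc,mi configs from [pcc_config()] / [mi_config()]; NULL skips that
#'   network.
#' @param apply_dpi prune the MI network by the data-processing inequality
#'   (default TRUE).
#' @return list of class `pipeline_run`: `qc`, `normalized`, `iqr`, `q`,
#'   `filtered`, `filter_report`, `networks` (list), `ledger` (tibble).
#' @export
run_complete <- function(compendium, filter_method = c("histogram",
                                                       "derivative", "fixed"),
                         q = NULL, control_ids = NULL, exclude = character(),
                         pcc = NULL, mi = NULL, apply_dpi = TRUE) {
  filter_method <- match.arg(filter_method)
  stages <- prep_stages(compendium, control_ids, exclude)
  flt <- filter_stage(stages$normalized, filter_method, q)
  networks <- network_stage(flt$matrix, pcc, mi, apply_dpi, "complete")
  ledger <- run_ledger(stages, flt, networks, dataset = "complete")
  structure(list(qc = stages$qc, gene_matrix = stages$gene_matrix,
                 normalized = stages$normalized, iqr = flt$iqr, q = flt$q,
                 filtered = flt$matrix, filter_report = flt$report,
                 networks = networks, ledger = ledger),
            class = "pipeline_run")
}

# shared front end: QC, summarization, annotation collapse (raw gene-level),
# then the complete-dataset normalization
prep_stages <- function(compendium, control_ids, exclude) {
  mat <- compendium$matrix
  if (!all(c("matrix", "submissions", "probe_map", "annotation") %in%
           names(compendium)))
    np_abort("compendium must have matrix, submissions, probe_map, annotation",
             "validation_error")
  qc <- qc_report(mat, compendium$probe_map, compendium$submissions,
                  control_ids = control_ids, exclude = exclude)
  desc_dupes <- match_descriptions(compendium$submissions)
  auto <- desc_dupes$submission_b[desc_dupes$status == "auto_duplicate"]
  drop_arrays <- unlist(compendium$submissions$array_ids[
    compendium$submissions$submission_id %in% auto])
  kept <- setdiff(qc$array_id[qc$verdict == "pass"], drop_arrays)
  if (length(kept) < 4) np_abort("QC left fewer than 4 arrays", "pipeline_error")
  clean_mat <- expr_subset(mat, cols = kept)
  smat <- summarize_probesets(clean_mat, compendium$probe_map)
  ann <- clean_annotation(compendium$annotation)
  clusters <- cluster_and_select(ann)
  gene_raw <- collapse_matrix(smat, clusters)
  normalized <- normalize_gene_matrix(gene_raw)
  list(qc = qc, desc_dupes = desc_dupes, kept_arrays = kept,
       n_collected = nrow(qc),
       n_duplicates = sum(qc$verdict == "duplicate") + length(drop_arrays),
       n_qc_failed = sum(!qc$verdict %in% c("pass", "duplicate") &
                           !qc$array_id %in% drop_arrays),
       clusters = clusters, gene_matrix = gene_raw, normalized = normalized)
}

# gene-level raw -> normalized (scale, log2 + centre, quantile)
normalize_gene_matrix <- function(gene_raw, target = 1000) {
  s <- global_scale(gene_raw, target = target)
  quantile_normalize(log2_and_center(s))
}

filter_stage <- function(normalized, filter_method, q_fixed) {
  iqr <- gene_iqr(normalized)
  q <- switch(filter_method,
              histogram = histogram_threshold(iqr),
              derivative = derivative_threshold(build_iqr_profile(iqr)),
              fixed = q_fixed %||%
                np_abort("fixed filtering needs `q`", "config_error"))
  out <- apply_filter(normalized, q, iqr)
  list(iqr = iqr, q = q, matrix = out$matrix, report = out$report)
}

network_stage <- function(mat, pcc, mi, apply_dpi, provenance) {
  nets <- list()
  if (!is.null(pcc)) nets$pcc <- pcc_network(mat, pcc, provenance)
  if (!is.null(mi)) {
    net <- mi_network(mat, mi, provenance)
    if (apply_dpi) net <- dpi_prune(net, mi$dpi_tolerance)
    nets$mi <- net
  }
  nets
}

run_ledger <- function(stages, flt, networks, dataset) {
  base <- tibble(
    dataset = dataset,
    arrays_collected = stages$n_collected,
    duplicates_removed = stages$n_duplicates,
    qc_failed = stages$n_qc_failed,
    arrays_remaining = stages$n_collected - stages$n_duplicates -
      stages$n_qc_failed,
    genes_before_filter = nrow(flt$report),
    genes_after_filter = sum(flt$report$retained),
    q = flt$q)
  for (m in names(networks)) {
    s <- network_stats(networks[[m]])
    base[[paste0(m, "_vertices")]] <- s$n_connected
    base[[paste0(m, "_edges")]] <- s$n_edges
  }
  base
}

#' Run the partitioned pipeline
#'
#' After shared dedup/QC/summarization, submissions are classified by keyword
#' into tissue- and process-specific datasets, and each class is put through
#' an independent normalization + filtering + network run. Union networks
#' (tissue, process, full) are assembled per method, alongside a
#' complete-dataset run for comparison.
#'
#' @inheritParams run_complete
#' @param keyword_cfg a [keyword_config()]; default classes are used when NULL.
#' @param overrides optional manual override table (see [apply_overrides()]).
#' @param min_class_arrays classes with fewer surviving arrays are skipped
#'   with a warning (default 8).
#' @return list of class `partitioned_run`: `complete` (a `pipeline_run`),
#'   `assignments`, `class_runs` (per-class filter + networks), `unions`
#'   (per method: tissue, process, full), `ledger`, `gene_sets` (list:
#'   aggregate and per-class retained genes).
#' @export
run_partitioned <- function(compendium, filter_method = c("histogram",
                                                          "derivative", "fixed"),
                            q = NULL, control_ids = NULL, exclude = character(),
                            keyword_cfg = NULL, overrides = NULL,
                            min_class_arrays = 8,
                            pcc = NULL, mi = NULL, apply_dpi = TRUE) {
  filter_method <- match.arg(filter_method)
  stages <- prep_stages(compendium, control_ids, exclude)
  flt <- filter_stage(stages$normalized, filter_method, q)
  complete_networks <- network_stage(flt$matrix, pcc, mi, apply_dpi, "complete")
  complete <- structure(
    list(qc = stages$qc, gene_matrix = stages$gene_matrix,
         normalized = stages$normalized, iqr = flt$iqr, q = flt$q,
         filtered = flt$matrix, filter_report = flt$report,
         networks = complete_networks,
         ledger = run_ledger(stages, flt, complete_networks, "complete")),
    class = "pipeline_run")

  cfg <- keyword_cfg %||% keyword_config()
  assignments <- keyword_assign(compendium$submissions, cfg)
  if (!is.null(overrides))
    assignments <- apply_overrides(assignments, overrides,
                                   compendium$submissions$submission_id)
  class_mats <- partition_matrices(stages$gene_matrix, assignments,
                                   compendium$submissions)

  class_runs <- list(); ledgers <- list(complete = complete$ledger)
  gene_sets <- list(aggregate = flt$report$gene[flt$report$retained])
  for (nm in names(class_mats)) {
    cm <- class_mats[[nm]]
    if (ncol(cm) < min_class_arrays) {
      rlang::warn(sprintf("class %s skipped: only %d arrays", nm, ncol(cm)))
      next
    }
    norm_c <- normalize_gene_matrix(cm)
    flt_c <- filter_stage(norm_c, filter_method, q)
    nets_c <- network_stage(flt_c$matrix, reseed(pcc, nm), reseed(mi, nm),
                            apply_dpi, nm)
    class_runs[[nm]] <- list(filtered = flt_c$matrix, q = flt_c$q,
                             report = flt_c$report, networks = nets_c,
                             n_arrays = ncol(cm))
    gene_sets[[nm]] <- flt_c$report$gene[flt_c$report$retained]
    lrow <- tibble(dataset = nm, arrays_collected = ncol(cm),
                   duplicates_removed = 0L, qc_failed = 0L,
                   arrays_remaining = ncol(cm),
                   genes_before_filter = nrow(flt_c$report),
                   genes_after_filter = sum(flt_c$report$retained),
                   q = flt_c$q)
    for (m in names(nets_c)) {
      s <- network_stats(nets_c[[m]])
      lrow[[paste0(m, "_vertices")]] <- s$n_connected
      lrow[[paste0(m, "_edges")]] <- s$n_edges
    }
    ledgers[[nm]] <- lrow
  }

  unions <- list()
  for (m in c("pcc", "mi")) {
    per_class <- lapply(class_runs, function(cr) cr$networks[[m]])
    per_class <- per_class[!vapply(per_class, is.null, TRUE)]
    if (!length(per_class)) next
    basis_of <- sub("/.*$", "", names(per_class))
    u <- list()
    if (any(basis_of == "tissue"))
      u$tissue <- union_networks(per_class[basis_of == "tissue"])
    if (any(basis_of == "process"))
      u$process <- union_networks(per_class[basis_of == "process"])
    u$full <- union_networks(per_class)
    unions[[m]] <- u
  }

  structure(list(complete = complete, assignments = assignments,
                 class_runs = class_runs, unions = unions,
                 ledger = dplyr::bind_rows(ledgers), gene_sets = gene_sets),
            class = "partitioned_run")
}

# derive a class-specific seed so per-class permutation nulls differ but stay
# reproducible; keeps within 32-bit integer range
reseed <- function(cfg, label) {
  if (is.null(cfg)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  cfg$seed <- as.integer((cfg$seed + h * 7919L) %% .Machine$integer.max)
  cfg
}

#' Union-vs-complete comparison arithmetic
#'
#' The reporting step behind published union-network comparisons: per method,
#' the union network's gene count against both the complete-dataset network
#' and the complete dataset's filtered input, plus per-dataset coverage gaps
#' (genes in the input that the network fails to cover).
#'
#' @param union_vertices named numeric: genes in the full union network per
#'   method.
#' @param complete_vertices named numeric: genes in the complete-dataset
#'   network per method.
#' @param complete_input_genes genes surviving filtering on the complete
#'   dataset (scalar).
#' @return tibble `method`, `union_vertices`, `complete_vertices`,
#'   `complete_input_genes`, `gain_vs_network`, `gain_vs_input`,
#'   `coverage_gap` (input minus complete network).
#' @export
gain_report <- function(union_vertices, complete_vertices,
                        complete_input_genes) {
  methods <- union(names(union_vertices), names(complete_vertices))
  if (!length(methods)) np_abort("no methods to report", "validation_error")
  uv <- as.numeric(union_vertices[methods])
  cv <- as.numeric(complete_vertices[methods])
  tibble(method = methods,
         union_vertices = uv,
         complete_vertices = cv,
         complete_input_genes = complete_input_genes,
         gain_vs_network = uv - cv,
         gain_vs_input = uv - complete_input_genes,
         coverage_gap = complete_input_genes - cv)
}

#' @rdname gain_report
#' @param run a `partitioned_run`.
#' @export
gain_report_from_run <- function(run) {
  stopifnot(inherits(run, "partitioned_run"))
  uv <- vapply(run$unions, function(u) network_stats(u$full)$n_connected, 0)
  cv <- vapply(names(run$unions), function(m)
    network_stats(run$complete$networks[[m]])$n_connected, 0)
  gain_report(uv, cv, sum(run$complete$filter_report$retained))
}

#' Summarize a collection census table
#'
#' Totals for a per-repository census (experiments, arrays collected, arrays
#' failing QC) and the post-QC array count.
#'
#' @param census tibble with columns `database`, `experiments`, `cel_files`,
#'   `qc_filtered`.
#' @return one-row tibble with totals and `arrays_post_qc`.
#' @export
summarize_collection <- function(census) {
  stopifnot(all(c("experiments", "cel_files", "qc_filtered") %in% names(census)))
  tibble(experiments_total = sum(census$experiments),
         cel_files_total = sum(census$cel_files),
         qc_filtered_total = sum(census$qc_filtered),
         arrays_post_qc = sum(census$cel_files) - sum(census$qc_filtered))
}

#' Path to a bundled census table
#'
#' The package ships small TSV census tables for a published large Arabidopsis
#' ATH1 compendium (per-repository collection counts, per-class dataset sizes,
#' and network sizes) used by the reporting examples and the acceptance
#' script.
#'
#' @param file file name under `extdata`; with no argument, lists the
#'   available files.
#' @return path (or vector of file names).
#' @export
netprep_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "netprep")))
  system.file("extdata", file, package = "netprep", mustWork = TRUE)
}
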