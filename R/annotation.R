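#' Read a probe-set to gene annotation map
#'
#' TSV with two columns: probe-set id and a separator-delimited list of gene
#' ids, or the literal `no_match` for probe-sets with no gene assignment.
#'
#' @param path file path.
#' @param sep separator inside the gene-id list (default `,`).
#' @return an annotation tibble with columns `probe_set_id` and `genes`
#'   (list-column of character vectors; `"no_match"` kept verbatim).
#' @export
read_annotation <- function(path, sep = ",") {
  if (!file.exists(path)) np_abort(paste0("no such file: ", path), "io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  names(df)[1:2] <- c("probe_set_id", "genes")
  if (anyDuplicated(df$probe_set_id))
    np_abort(paste0("duplicate probe-set row: ",
                    df$probe_set_id[duplicated(df$probe_set_id)][1]),
             "validation_error")
  out <- tibble(probe_set_id = df$probe_set_id,
                genes = strsplit(df$genes, sep, fixed = TRUE))
  n_no_match <- sum(vapply(out$genes, function(g) identical(g, "no_match"), TRUE))
  attr(out, "n_no_match") <- n_no_match
  class(out) <- c("annotation_map", class(out))
  out
}

#' Write an annotation map
#' @param map annotation tibble (see [read_annotation()]).
#' @param path output path.
#' @param sep separator for gene lists.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(map, path, sep = ",") {
  df <- data.frame(probe_set_id = map$probe_set_id,
                   genes = vapply(map$genes, paste, "", collapse = sep))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build an annotation map in memory
#' @param entries named list: probe-set id -> character vector of gene ids.
#' @return annotation tibble.
#' @export
annotation_map <- function(entries) {
  if (anyDuplicated(names(entries)))
    np_abort("duplicate probe-set id", "validation_error")
  out <- tibble(probe_set_id = names(entries), genes = unname(entries))
  class(out) <- c("annotation_map", class(out))
  out
}

#' Remove unusable annotation entries
#'
#' Drops probe-sets annotated `no_match` and probe-sets mapping to more than
#' `max_agis` gene identifiers (promiscuous probes that cannot be attributed
#' to a single locus).
#'
#' @param map annotation tibble.
#' @param max_agis maximum allowed gene ids per probe-set (default 3; the
#'   boundary count is kept).
#' @return cleaned annotation tibble; attribute `removal_report` is a tibble
#'   counting each removal class.
#' @export
clean_annotation <- function(map, max_agis = 3) {
  no_match <- vapply(map$genes, function(g) any(g == "no_match"), TRUE)
  too_many <- !no_match & lengths(map$genes) > max_agis
  out <- map[!no_match & !too_many, ]
  attr(out, "removal_report") <- tibble(
    reason = c("no_match", "too_many_agis", "retained"),
    n = c(sum(no_match), sum(too_many), nrow(out)))
  out
}

#' Cluster probe-sets sharing gene ids and pick representatives
#'
#' Two probe-sets belong to the same cluster when they share at least one gene
#' id (transitively). Each cluster is represented by the member mapping to the
#' fewest gene ids, ties broken by lexicographically smallest probe-set id.
#'
#' @param map cleaned annotation tibble (see [clean_annotation()]).
#' @return tibble with one row per cluster: `cluster_id`, `members`
#'   (list-column), `representative`, `agi_union` (list-column), and `label`
#'   (lexicographically smallest gene id of the representative).
#' @export
cluster_and_select <- function(map) {
  n <- nrow(map)
  if (n == 0)
    return(tibble(cluster_id = integer(), members = list(),
                  representative = character(), agi_union = list(),
                  label = character()))
  # bipartite probe/gene graph; probe clusters = components restricted to probes
  probe_v <- paste0("p\r", map$probe_set_id)
  gene_v <- paste0("g\r", unique(unlist(map$genes)))
  edges <- cbind(rep(probe_v, lengths(map$genes)),
                 paste0("g\r", unlist(map$genes)))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = c(probe_v, gene_v)))
  comp <- igraph::components(g)$membership[probe_v]
  split_idx <- split(seq_len(n), comp)
  rows <- lapply(seq_along(split_idx), function(k) {
    idx <- split_idx[[k]]
    ids <- map$probe_set_id[idx]
    counts <- lengths(map$genes[idx])
    ord <- order(counts, ids)
    rep_id <- ids[ord[1]]
    rep_genes <- map$genes[idx][[ord[1]]]
    tibble(cluster_id = k, members = list(sort(ids)),
           representative = rep_id,
           agi_union = list(sort(unique(unlist(map$genes[idx])))),
           label = min(rep_genes))
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$representative)
}

#' Collapse a probe-set matrix to gene level
#'
#' Keeps one row per cluster (the representative probe-set) and relabels it
#' with the cluster's gene label; all non-representative rows are dropped.
#'
#' @param mat probe-set level `expr_mat`.
#' @param clusters output of [cluster_and_select()].
#' @return gene-level `expr_mat` in the same space.
#' @export
collapse_matrix <- function(mat, clusters) {
  missing <- setdiff(clusters$representative, rownames(mat))
  if (length(missing))
    np_abort(paste0("representative probe-set absent from matrix: ", missing[1]),
             "validation_error")
  v <- unclass(mat)[clusters$representative, , drop = FALSE]
  rownames(v) <- clusters$label
  if (anyDuplicated(rownames(v)))
    np_abort("two clusters collapse to the same gene label", "validation_error")
  expr_mat(v, expr_space(mat), allow_na = TRUE)
}
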