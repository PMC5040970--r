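#' Gene network container
#'
#' An undirected, simple, weighted graph: a vertex set plus an edge tibble.
#' Edges are stored with the lexicographically smaller gene first, one row per
#' unordered pair. Scores are Pearson correlations (method `"pcc"`) or mutual
#' information in nats (method `"mi"`).
#'
#' @param edges tibble/data frame with columns `from`, `to`, `score` (may be
#'   empty).
#' @param vertices character vector of gene ids; defaults to the edge
#'   endpoints. Isolated vertices are kept.
#' @param method `"pcc"` or `"mi"`.
#' @param provenance category name, `"complete"`, or `"union"`.
#' @return a `gene_network`.
#' @export
gene_network <- function(edges = NULL, vertices = NULL,
                         method = c("pcc", "mi"), provenance = "complete") {
  method <- match.arg(method)
  if (is.null(edges)) edges <- tibble(from = character(), to = character(),
                                      score = numeric())
  edges <- tibble::as_tibble(edges)[, c("from", "to", "score")]
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) np_abort("self-edges not allowed", "validation_error")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  if (anyDuplicated(paste0(edges$from, "\r", edges$to)))
    np_abort("duplicate edge", "validation_error")
  if (is.null(vertices)) {
    vertices <- sort(unique(c(edges$from, edges$to)))
  } else {
    vertices <- sort(unique(as.character(vertices)))
    if (!all(c(edges$from, edges$to) %in% vertices))
      np_abort("edge endpoints must be in the vertex set", "validation_error")
  }
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(vertices = vertices, edges = edges, method = method,
                 provenance = provenance),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network:%s> %d vertices, %d edges (%s)\n",
              x$method, length(x$vertices), nrow(x$edges), x$provenance))
  invisible(x)
}

#' @export
tidy.gene_network <- function(x, ...) x$edges

#' @export
glance.gene_network <- function(x, ...) {
  s <- network_stats(x)
  tibble(method = x$method, provenance = x$provenance,
         n_vertices = s$n_vertices, n_connected = s$n_connected,
         n_edges = s$n_edges)
}

#' Vertex and edge counts of a network
#'
#' Reports total vertices, non-isolated ("connected") vertices and edge count.
#' Published network-size tables usually count a gene as "in the network" only
#' when it has at least one edge, so both vertex counts are given.
#'
#' @param net a `gene_network`.
#' @return one-row tibble with `n_vertices`, `n_connected`, `n_edges`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  tibble(n_vertices = length(net$vertices),
         n_connected = length(unique(c(net$edges$from, net$edges$to))),
         n_edges = nrow(net$edges))
}

#' Union of gene networks
#'
#' Set union of vertices and edges across networks sharing one method tag.
#' An edge present in several constituents keeps its maximum score.
#'
#' @param nets list of `gene_network` objects with identical `method`.
#' @return a `gene_network` with provenance `"union"`.
#' @export
union_networks <- function(nets) {
  stopifnot(length(nets) >= 1, all(vapply(nets, inherits, TRUE, "gene_network")))
  methods <- unique(vapply(nets, `[[`, "", "method"))
  if (length(methods) != 1)
    np_abort("cannot union networks with mixed method tags", "validation_error")
  edges <- dplyr::bind_rows(lapply(nets, `[[`, "edges"))
  if (nrow(edges))
    edges <- edges |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  vertices <- unique(unlist(lapply(nets, `[[`, "vertices")))
  gene_network(edges, vertices, methods, provenance = "union")
}

#' Write a network to disk
#'
#' `tsv_edgelist` writes a tab-separated table `from to score` preceded by a
#' `#vertex` section listing every vertex (so isolated vertices survive a round
#' trip). `sif` writes the Cytoscape SIF interaction format with a `.sif.nodes`
#' sidecar for the vertex set and scores.
#'
#' @param net a `gene_network`.
#' @param path output path.
#' @param format `"tsv_edgelist"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv_edgelist", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "gene_network"))
  sc <- sprintf("%.6f", net$edges$score)
  if (format == "tsv_edgelist") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("#method\t%s", net$method), con)
    writeLines(sprintf("#provenance\t%s", net$provenance), con)
    writeLines(sprintf("#vertex\t%s", net$vertices), con)
    writeLines("from\tto\tscore", con)
    if (nrow(net$edges))
      writeLines(paste(net$edges$from, net$edges$to, sc, sep = "\t"), con)
  } else {
    lines <- if (nrow(net$edges))
      paste(net$edges$from, net$method, net$edges$to) else character()
    writeLines(lines, path)
    side <- paste0(path, ".nodes")
    utils::write.table(
      data.frame(vertex = net$vertices), side,
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(from = net$edges$from, to = net$edges$to, score = sc),
      paste0(path, ".scores"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param format `"tsv_edgelist"` or `"sif"`.
#' @param method,provenance tags for the `sif` format, whose files do not carry
#'   them; ignored for `tsv_edgelist`.
#' @return a `gene_network`.
#' @export
read_network <- function(path, format = c("tsv_edgelist", "sif"),
                         method = "pcc", provenance = "complete") {
  format <- match.arg(format)
  if (!file.exists(path)) np_abort(paste0("no such file: ", path), "io_error")
  if (format == "tsv_edgelist") {
    lines <- readLines(path)
    meta <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    get1 <- function(key) sub(paste0("^#", key, "\t"), "",
                              meta[startsWith(meta, paste0("#", key, "\t"))])
    vertices <- get1("vertex")
    edges <- if (length(body) > 1) {
      parts <- strsplit(body[-1], "\t", fixed = TRUE)
      tibble(from = vapply(parts, `[[`, "", 1),
             to = vapply(parts, `[[`, "", 2),
             score = as.numeric(vapply(parts, `[[`, "", 3)))
    } else NULL
    gene_network(edges, vertices, get1("method"), get1("provenance"))
  } else {
    nodes <- utils::read.table(paste0(path, ".nodes"), header = TRUE,
                               sep = "\t", colClasses = "character")
    sc <- utils::read.table(paste0(path, ".scores"), header = TRUE, sep = "\t",
                            colClasses = c("character", "character", "numeric"))
    gene_network(sc, nodes$vertex, method, provenance)
  }
}

#' @export
autoplot.gene_network <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$edges, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey20") +
    ggplot2::labs(
      title = sprintf("%s network (%s): %d genes, %d edges",
                      toupper(object$method), object$provenance,
                      g$n_connected, g$n_edges),
      x = if (object$method == "pcc") "Pearson correlation" else
        "mutual information (nats)",
      y = "edges")
}
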