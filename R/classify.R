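#' Keyword configuration for tissue/process classification
#'
#' Each class (a `basis`/`class_name` pair) carries a non-empty list of
#' lowercase keywords or phrases. The default configuration seeds the standard
#' tissue classes (Flower, Leaf, Root, Seedling, Whole Plant) and process
#' classes (Chemical, Development, Hormone, Light, Metabolism, Pathogen,
#' Stress) with simple keyword lists; they are configuration, not ground
#' truth, and are meant to be edited per compendium.
#'
#' @param classes named nested list: `tissue` and/or `process`, each a named
#'   list of keyword character vectors.
#' @return tibble `basis`, `class_name`, `keywords` (list-column).
#' @export
keyword_config <- function(classes = default_keyword_classes()) {
  rows <- list()
  for (basis in names(classes)) {
    cls <- classes[[basis]]
    if (anyDuplicated(names(cls)))
      np_abort("duplicate class within a basis", "validation_error")
    for (cn in names(cls)) {
      kw <- tolower(cls[[cn]])
      if (!length(kw)) np_abort("empty keyword list", "validation_error")
      rows[[length(rows) + 1]] <- tibble(basis = basis, class_name = cn,
                                         keywords = list(kw))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("keyword_config", class(out))
  out
}

#' @rdname keyword_config
#' @export
default_keyword_classes <- function() {
  list(
    tissue = list(
      Flower = c("flower", "floral", "inflorescence"),
      Leaf = c("leaf", "leaves", "rosette leaf"),
      Root = c("root"),
      Seedling = c("seedling"),
      `Whole Plant` = c("whole plant", "whole-plant", "whole seedling rosette")),
    process = list(
      Chemical = c("chemical", "herbicide", "inhibitor"),
      Development = c("development", "developmental", "differentiation"),
      Hormone = c("hormone", "auxin", "cytokinin", "gibberellin",
                  "abscisic acid", "ethylene", "jasmonate"),
      Light = c("light", "uv", "shade", "photoperiod", "circadian"),
      Metabolism = c("metabolism", "metabolic", "metabolite", "starch",
                     "nitrogen", "sulfur"),
      Pathogen = c("pathogen", "infection", "bacterial", "fungal", "elicitor"),
      Stress = c("stress", "drought", "salt", "cold", "heat", "osmotic",
                 "wounding")))
}

#' Read/write a keyword configuration as YAML
#' @param path file path.
#' @return a `keyword_config` tibble (reader) or `path` (writer).
#' @export
read_keyword_config <- function(path) {
  keyword_config(yaml::read_yaml(path))
}

#' @rdname read_keyword_config
#' @param cfg a `keyword_config`.
#' @export
write_keyword_config <- function(cfg, path) {
  nested <- lapply(split(cfg, cfg$basis), function(df)
    stats::setNames(df$keywords, df$class_name))
  yaml::write_yaml(nested, path)
  invisible(path)
}

# normalize text to matching form: lowercase word tokens with plural 's'
# stripped (length > 3 so "has"/"was" are untouched and "leaves" stays put)
normalize_tokens <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9-]+")[[1]]
  toks <- toks[nzchar(toks)]
  ifelse(nchar(toks) > 3 & grepl("s$", toks) & !grepl("ss$", toks),
         sub("s$", "", toks), toks)
}

matches_keyword <- function(tokens, keyword) {
  kw <- normalize_tokens(keyword)
  if (length(kw) == 0) return(FALSE)
  if (length(kw) == 1) return(kw %in% tokens)
  n <- length(tokens) - length(kw) + 1
  if (n < 1) return(FALSE)
  any(vapply(seq_len(n), function(i)
    all(tokens[i:(i + length(kw) - 1)] == kw), TRUE))
}

#' Assign submissions to categories by keyword match
#'
#' Descriptions are lowercased, tokenized on non-alphanumerics, and plural 's'
#' is stripped from tokens; a submission joins every class with at least one
#' keyword (or phrase) hit. Multi-label assignment is expected. Submissions
#' with no hits are reported unassigned.
#'
#' @param submissions a `submission_set`.
#' @param cfg a `keyword_config`.
#' @return tibble of class `category_assignment`: `basis`, `class_name`,
#'   `submission_id`; attribute `unassigned` lists hit-less submissions.
#' @export
keyword_assign <- function(submissions, cfg) {
  rows <- list()
  hit_any <- logical(nrow(submissions))
  for (i in seq_len(nrow(submissions))) {
    tokens <- normalize_tokens(submissions$description[i])
    for (k in seq_len(nrow(cfg))) {
      if (any(vapply(cfg$keywords[[k]], function(kw)
        matches_keyword(tokens, kw), TRUE))) {
        rows[[length(rows) + 1]] <- tibble(
          basis = cfg$basis[k], class_name = cfg$class_name[k],
          submission_id = submissions$submission_id[i])
        hit_any[i] <- TRUE
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(basis = character(), class_name = character(),
           submission_id = character())
  attr(out, "unassigned") <- submissions$submission_id[!hit_any]
  class(out) <- c("category_assignment", class(out))
  out
}

#' Apply manual overrides to a classification
#'
#' Overrides are applied in order, last action winning, and every change is
#' audited. This is the programmatic stand-in for manual curation of the
#' keyword-derived classes.
#'
#' @param assignments a `category_assignment`.
#' @param overrides tibble with `submission_id`, `action` (`add`/`remove`),
#'   `basis`, `class_name`; or a path to such a TSV.
#' @param known_submissions character vector used to validate override ids
#'   (defaults to ids present in `assignments`).
#' @return updated `category_assignment`; attribute `audit` records changes.
#' @export
apply_overrides <- function(assignments, overrides,
                            known_submissions = NULL) {
  if (is.character(overrides) && length(overrides) == 1)
    overrides <- readr::read_tsv(overrides, show_col_types = FALSE)
  known <- known_submissions %||% unique(assignments$submission_id)
  cur <- assignments
  audit <- list()
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    if (!o$submission_id %in% known)
      np_abort(paste0("override names unknown submission: ", o$submission_id),
               "validation_error")
    at <- cur$basis == o$basis & cur$class_name == o$class_name &
      cur$submission_id == o$submission_id
    if (o$action == "remove") {
      cur <- cur[!at, ]
      audit[[length(audit) + 1]] <- dplyr::mutate(o, applied = any(at))
    } else if (o$action == "add") {
      if (!any(at))
        cur <- dplyr::bind_rows(cur, tibble(
          basis = o$basis, class_name = o$class_name,
          submission_id = o$submission_id))
      audit[[length(audit) + 1]] <- dplyr::mutate(o, applied = !any(at))
    } else np_abort("override action must be add or remove", "validation_error")
  }
  attr(cur, "unassigned") <- attr(assignments, "unassigned")
  attr(cur, "audit") <- if (length(audit)) dplyr::bind_rows(audit) else NULL
  class(cur) <- unique(c("category_assignment", class(cur)))
  cur
}

#' Split an expression matrix into per-class matrices
#'
#' Each class receives exactly the columns belonging to its submissions'
#' arrays (intersected with the columns present, e.g. post-QC). A column can
#' appear in several class matrices; classes with no surviving arrays are
#' dropped with a warning.
#'
#' @param mat `expr_mat`.
#' @param assignments a `category_assignment`.
#' @param submissions a `submission_set` providing the array ids.
#' @return named list of `expr_mat`, names `basis/class_name`.
#' @export
partition_matrices <- function(mat, assignments, submissions) {
  arr <- stats::setNames(submissions$array_ids, submissions$submission_id)
  keys <- unique(assignments[, c("basis", "class_name")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    subs <- assignments$submission_id[
      assignments$basis == keys$basis[i] &
        assignments$class_name == keys$class_name[i]]
    cols <- intersect(unique(unlist(arr[subs])), colnames(mat))
    nm <- paste(keys$basis[i], keys$class_name[i], sep = "/")
    if (length(cols) == 0) {
      rlang::warn(paste0("class with no arrays dropped: ", nm))
      next
    }
    out[[nm]] <- expr_subset(mat, cols = cols)
  }
  out
}

#' Class membership summary
#'
#' The classification report: per class, the number of experiments
#' (submissions) and arrays, mirroring a compendium census table.
#'
#' @param assignments a `category_assignment`.
#' @param submissions a `submission_set`.
#' @return tibble `basis`, `class_name`, `n_experiments`, `n_arrays`.
#' @export
classification_summary <- function(assignments, submissions) {
  arr <- stats::setNames(lengths(submissions$array_ids),
                         submissions$submission_id)
  assignments |>
    dplyr::group_by(.data$basis, .data$class_name) |>
    dplyr::summarise(n_experiments = dplyr::n_distinct(.data$submission_id),
                     n_arrays = sum(arr[unique(.data$submission_id)]),
                     .groups = "drop")
}
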