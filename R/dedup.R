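#' Submission records
#'
#' One row per repository submission: id, source repository, free-text
#' description and the member array ids. `content_hashes` is a list-column of
#' named character vectors (array id -> digest of the array's raw column),
#' populated by [hash_submissions()] before duplicate detection.
#'
#' @param submission_id character ids.
#' @param source repository of origin (`ArrayExpress`, `GEO`, `NASC`, `other`).
#' @param description free text.
#' @param array_ids list-column: character array ids per submission (non-empty).
#' @param content_hashes optional list-column of named digests.
#' @return a tibble of class `submission_set`.
#' @export
submission_set <- function(submission_id, source, description, array_ids,
                           content_hashes = NULL) {
  stopifnot(length(submission_id) == length(array_ids))
  if (any(lengths(array_ids) == 0))
    np_abort("submission with no arrays", "validation_error")
  ok <- source %in% c("ArrayExpress", "GEO", "NASC", "other")
  if (!all(ok)) np_abort("unknown source repository", "validation_error")
  out <- tibble(submission_id = as.character(submission_id),
                source = source, description = description,
                array_ids = array_ids,
                content_hashes = content_hashes %||%
                  rep(list(NULL), length(submission_id)))
  class(out) <- c("submission_set", class(out))
  out
}

#' Fill in content hashes from the expression matrix
#'
#' @param submissions a `submission_set`.
#' @param mat probe-level raw `expr_mat` whose columns cover every array id.
#' @return `submissions` with `content_hashes` populated.
#' @export
hash_submissions <- function(submissions, mat) {
  missing <- setdiff(unlist(submissions$array_ids), colnames(mat))
  if (length(missing))
    np_abort(paste0("array absent from matrix: ", missing[1]), "validation_error")
  submissions$content_hashes <- lapply(submissions$array_ids, function(a) {
    vapply(a, function(id) content_hash(unclass(mat)[, id]), "")
  })
  submissions
}

#' Find exact duplicate arrays by content digest
#'
#' Arrays with identical digests form a duplicate group. Within each group the
#' array belonging to the earliest-sorting submission id is kept; every other
#' member is reported as a duplicate of it.
#'
#' @param submissions a `submission_set` with hashes populated.
#' @return tibble with columns `kept`, `duplicate` (array ids), and
#'   `kept_submission`, `duplicate_submission`.
#' @export
find_exact_duplicates <- function(submissions) {
  if (any(vapply(submissions$content_hashes, is.null, TRUE)))
    np_abort("content hashes missing; run hash_submissions() first",
             "validation_error")
  flat <- tibble(
    submission_id = rep(submissions$submission_id,
                        lengths(submissions$array_ids)),
    array_id = unlist(submissions$array_ids),
    hash = unlist(submissions$content_hashes))
  flat <- dplyr::arrange(flat, .data$submission_id, .data$array_id)
  groups <- split(flat, flat$hash)
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 2) return(NULL)
    tibble(kept = g$array_id[1], duplicate = g$array_id[-1],
           kept_submission = g$submission_id[1],
           duplicate_submission = g$submission_id[-1])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble(kept = character(), duplicate = character(),
                  kept_submission = character(),
                  duplicate_submission = character())
  dplyr::arrange(out, .data$kept, .data$duplicate)
}

# lowercase word tokens
tokenize_description <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) unique(t[nzchar(t)]))
}

#' Flag submissions with matching descriptions
#'
#' Exact description matches are marked `auto_duplicate`; pairs whose token-set
#' Jaccard similarity reaches `similarity_cutoff` are marked `flagged` for
#' manual review (they are never auto-removed).
#'
#' @param submissions a `submission_set`.
#' @param similarity_cutoff Jaccard similarity in \[0,1\] (default 0.8).
#' @return tibble with `submission_a`, `submission_b`, `jaccard`, `status`.
#' @export
match_descriptions <- function(submissions, similarity_cutoff = 0.8) {
  n <- nrow(submissions)
  desc <- submissions$description
  toks <- tokenize_description(desc)
  rows <- list()
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, n)) {
    if (identical(desc[i], desc[j]) && nzchar(trimws(desc[i]))) {
      rows[[length(rows) + 1]] <- tibble(
        submission_a = submissions$submission_id[i],
        submission_b = submissions$submission_id[j],
        jaccard = 1, status = "auto_duplicate")
    } else {
      u <- length(union(toks[[i]], toks[[j]]))
      if (u == 0) next
      jac <- length(intersect(toks[[i]], toks[[j]])) / u
      if (jac >= similarity_cutoff)
        rows[[length(rows) + 1]] <- tibble(
          submission_a = submissions$submission_id[i],
          submission_b = submissions$submission_id[j],
          jaccard = jac, status = "flagged")
    }
  }
  if (!length(rows))
    return(tibble(submission_a = character(), submission_b = character(),
                  jaccard = numeric(), status = character()))
  dplyr::bind_rows(rows)
}
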