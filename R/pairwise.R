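# Pairwise comparison primitives.
#
# The aligner is a free-end-gap ("overlap") global alignment with affine
# gaps: match +1, mismatch 0, first position of an internal gap -0.5, each
# additional position -0.1. Terminal gaps in either sequence score 0 and
# are classed as overhang. The nucleotide distance of an alignment counts
# mismatch and internal gap columns only, so distance 0 holds exactly when
# one sequence equals, or is a contiguous substring of, the other. This is
# the metric used throughout for database comparison and gene grouping.

.column_classes <- c(M = "match", X = "mismatch", I = "gap_in_a",
                     D = "gap_in_b", A = "terminal_overhang",
                     B = "terminal_overhang")

.as_pairwise_result <- function(al, query_id, target_id) {
  cols <- strsplit(al$transcript, "")[[1]]
  res <- list(
    score = al$score,
    aligned_columns = unname(.column_classes[cols]),
    transcript = al$transcript,
    distance_nt = al$distance,
    query_id = query_id,
    target_id = target_id,
    query_span = c(al$a_start, al$a_end),
    target_span = c(al$b_start, al$b_end),
    query_overhang = al$a_overhang,
    target_overhang = al$b_overhang
  )
  class(res) <- "pairwise_result"
  res
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("pairwise_result %s vs %s: score %.1f, distance %d nt\n",
              x$query_id, x$target_id, x$score, x$distance_nt))
  cat("columns:", x$transcript, "\n")
  invisible(x)
}

#' Free-end-gap global alignment of two nucleotide sequences
#'
#' Aligns `a` against `b` over their entire lengths with free (zero-cost)
#' end gaps, affine internal gaps (open -0.5, extension -0.1 per further
#' position), match +1 and mismatch 0. Among equal-scoring alignments a
#' deterministic traceback preference match > mismatch > gap-in-b >
#' gap-in-a is applied.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param query_id,target_id Labels carried into the result.
#' @return A `pairwise_result` with elements `score`, `aligned_columns`
#'   (classes `match`, `mismatch`, `gap_in_a`, `gap_in_b`,
#'   `terminal_overhang`), `distance_nt` (mismatch + internal gap columns;
#'   terminal overhang excluded) and 0-based half-open spans of the
#'   internal region on each sequence.
#' @export
global_align <- function(a, b, query_id = "a", target_id = "b") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  al <- .cpp_align_pair(toupper(a), toupper(b), band = -1L)
  .as_pairwise_result(al, query_id, target_id)
}

#' Levenshtein distance
#'
#' Standard unit-cost edit distance (via `utils::adist`).
#'
#' @param a,b Character strings.
#' @return Integer edit distance.
#' @export
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Best-scoring database match for a query allele
#'
#' Aligns the query against every allele of `db` with [global_align()] and
#' returns the best-scoring hit. Ties are broken by smaller distance, then
#' lexicographically smaller allele id.
#'
#' @param query A single-row allele (list/data.frame row with `allele_id`
#'   and `sequence`), or a plain named character of length 1.
#' @param db A `germline_db`.
#' @return List with `allele_id`, `distance_nt` and the full
#'   `pairwise_result`.
#' @export
best_match <- function(query, db) {
  stopifnot(inherits(db, "germline_db"))
  if (nrow(db$alleles) == 0) stop("empty database")
  if (is.character(query)) {
    qseq <- unname(query[1])
    qid <- names(query)[1] %||% "query"
  } else {
    qseq <- query$sequence
    qid <- query$allele_id
  }
  sc <- drop(.cpp_score_scan(qseq, db$alleles$sequence, band = -1L))
  cand <- which(sc == max(sc))
  res <- lapply(cand, function(i)
    .as_pairwise_result(.cpp_align_pair(qseq, db$alleles$sequence[i], -1L),
                        qid, db$alleles$allele_id[i]))
  dist <- vapply(res, `[[`, integer(1), "distance_nt")
  ids <- db$alleles$allele_id[cand]
  pick <- order(dist, ids)[1]
  list(allele_id = ids[pick], distance_nt = dist[pick], result = res[[pick]])
}

#' Within- and between-gene distance distributions per family
#'
#' The within-gene set holds Levenshtein distances over all unordered
#' allele pairs sharing a gene; the between-gene set holds distances over
#' allele pairs from different genes of the same family. Medians are
#' reported per family; an empty set yields `NA`.
#'
#' @param db A `germline_db`.
#' @return Data frame with columns `family`, `n_within`,
#'   `within_gene_median`, `n_between`, `between_gene_median`.
#' @export
distance_distributions <- function(db) {
  stopifnot(inherits(db, "germline_db"))
  al <- db$alleles
  fams <- sort(unique(al$family))
  rows <- lapply(fams, function(f) {
    sub <- al[al$family == f, , drop = FALSE]
    d <- utils::adist(sub$sequence)
    same_gene <- outer(sub$gene_id, sub$gene_id, "==")
    ut <- upper.tri(d)
    within <- d[ut & same_gene]
    between <- d[ut & !same_gene]
    data.frame(
      family = f,
      n_within = length(within),
      within_gene_median = if (length(within)) stats::median(within) else NA_real_,
      n_between = length(between),
      between_gene_median = if (length(between)) stats::median(between) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Export pairwise results as a TSV-ready data frame
#'
#' @param results List of `pairwise_result` objects.
#' @param path Optional path; when given, written as TSV.
#' @return Data frame with query, target, score, distance and the column
#'   transcript string.
#' @export
pairwise_table <- function(results, path = NULL) {
  if (inherits(results, "pairwise_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(query_id = r$query_id, target_id = r$target_id,
               score = r$score, distance_nt = r$distance_nt,
               columns = r$transcript, stringsAsFactors = FALSE)))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
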