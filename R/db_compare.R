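# Database-vs-database comparison: exact/substring allele overlap (Venn
# counts stratified by the functionality labels of the second database)
# and per-gene best-match distance tables in either direction.

#' Exact and substring allele overlap between two databases
#'
#' An allele of `dbA` matches an allele of `dbB` iff their sequences are
#' equal, or one is a contiguous substring of the other (accommodating
#' truncated records). Each A allele is paired with at most one B allele:
#' the match with the longest shared sequence, ties broken by
#' lexicographic B allele id. Shared counts are tallied per functionality
#' class of the B side; the A side is treated as one class.
#'
#' @param dbA,dbB `germline_db` objects.
#' @return List of class `overlap_report`: `counts` (named integer vector
#'   with `shared_<class>` per B functionality class, `A_only`, and
#'   `B_only_<class>`), and `shared_pairs`, a data frame of
#'   (`allele_id_A`, `allele_id_B`, `containment_direction` in
#'   `equal`/`A_in_B`/`B_in_A`).
#' @export
exact_overlap <- function(dbA, dbB) {
  stopifnot(inherits(dbA, "germline_db"), inherits(dbB, "germline_db"))
  a <- dbA$alleles; b <- dbB$alleles
  pairs <- vector("list", nrow(a))
  b_matched <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(a))) {
    sa <- a$sequence[i]
    a_in_b <- vapply(b$sequence, function(s)
      grepl(sa, s, fixed = TRUE), logical(1), USE.NAMES = FALSE)
    b_in_a <- vapply(b$sequence, function(s)
      grepl(s, sa, fixed = TRUE), logical(1), USE.NAMES = FALSE)
    hit <- which(a_in_b | b_in_a)
    if (length(hit) == 0) next
    b_matched[hit] <- TRUE
    shared_len <- pmin(nchar(sa), b$seq_length[hit])
    pick <- hit[order(-shared_len, b$allele_id[hit])[1]]
    dir <- if (nchar(sa) == b$seq_length[pick]) "equal"
           else if (nchar(sa) < b$seq_length[pick]) "A_in_B" else "B_in_A"
    pairs[[i]] <- data.frame(allele_id_A = a$allele_id[i],
                             allele_id_B = b$allele_id[pick],
                             containment_direction = dir,
                             functionality_B = b$functionality[pick],
                             stringsAsFactors = FALSE)
  }
  shared_pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(shared_pairs))
    shared_pairs <- data.frame(allele_id_A = character(),
                               allele_id_B = character(),
                               containment_direction = character(),
                               functionality_B = character(),
                               stringsAsFactors = FALSE)
  classes <- sort(unique(b$functionality))
  counts <- c(
    stats::setNames(
      vapply(classes, function(cl)
        sum(shared_pairs$functionality_B == cl), integer(1)),
      paste0("shared_", classes)),
    A_only = nrow(a) - nrow(shared_pairs),
    stats::setNames(
      vapply(classes, function(cl)
        sum(!b_matched & b$functionality == cl), integer(1)),
      paste0("B_only_", classes))
  )
  out <- list(counts = counts, shared_pairs = shared_pairs,
              n_A = nrow(a), n_B = nrow(b))
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: %d A alleles, %d B alleles\n", x$n_A, x$n_B))
  print(x$counts)
  invisible(x)
}

# per-A-gene best hit against all B alleles, by score then distance then id
.gene_best_hits <- function(dbA, dbB) {
  gi <- gene_index(dbA)
  b <- dbB$alleles
  rows <- lapply(names(gi), function(g) {
    qa <- dbA$alleles[dbA$alleles$gene_id == g, , drop = FALSE]
    sc <- .cpp_stats_scan(qa$sequence, b$sequence, band = -1L)
    score <- sc$score; dist <- sc$distance
    flat <- data.frame(
      q = rep(qa$allele_id, times = ncol(score)),
      t = rep(b$allele_id, each = nrow(score)),
      t_gene = rep(b$gene_id, each = nrow(score)),
      score = as.vector(score),
      dist = as.vector(dist),
      stringsAsFactors = FALSE
    )
    best <- flat[order(-flat$score, flat$dist, flat$t, flat$q)[1], ]
    data.frame(gene_id = g,
               best_query_allele = best$q,
               best_target_gene = best$t_gene,
               best_target_allele = best$t,
               score = best$score,
               distance_nt = best$dist,
               min_distance_nt = min(flat$dist),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene best-match distance table between two databases
#'
#' For each gene of `dbA`, all its alleles are aligned against all alleles
#' of `dbB`; the best-scoring pair (ties: smaller distance, then target
#' allele id) defines the matched B gene and the reported distance. A gene
#' is called present in `dbB` iff its minimal distance is at most
#' `threshold` nucleotides, i.e. at least one allele pair differs by fewer
#' than `threshold + 1` nucleotides.
#'
#' @param dbA,dbB `germline_db` objects.
#' @param threshold Presence threshold in nucleotides (default 5).
#' @param evidence Optional data frame with columns `gene_id`,
#'   `in_assembly`, `sanger_validated`, merged onto the result.
#' @return Data frame (one row per `dbA` gene): `gene_id`,
#'   `best_query_allele`, `best_target_gene`, `best_target_allele`,
#'   `score`, `distance_nt`, `min_distance_nt`, `present`, plus evidence
#'   flags (`NA` when not supplied).
#' @export
gene_content_compare <- function(dbA, dbB, threshold = 5L, evidence = NULL) {
  stopifnot(inherits(dbA, "germline_db"), inherits(dbB, "germline_db"))
  if (nrow(dbB$alleles) == 0) stop("empty target database")
  tab <- .gene_best_hits(dbA, dbB)
  tab$present <- tab$min_distance_nt <= threshold
  if (is.null(evidence)) {
    tab$in_assembly <- NA
    tab$sanger_validated <- NA
  } else {
    tab <- merge(tab, evidence, by = "gene_id", all.x = TRUE, sort = FALSE)
  }
  tab[order(tab$gene_id), , drop = FALSE]
}

#' Genes of one database with no close counterpart in another
#'
#' @param dbA,dbB `germline_db` objects.
#' @param threshold Distance above which a gene counts as unmatched
#'   (default 5 nt).
#' @return Data frame of `dbA` genes whose best-match distance to `dbB`
#'   exceeds `threshold`, ordered by distance descending.
#' @export
reciprocal_unmatched <- function(dbA, dbB, threshold = 5L) {
  stopifnot(threshold >= 0)
  tab <- gene_content_compare(dbA, dbB, threshold = threshold)
  out <- tab[!tab$present,
             c("gene_id", "best_target_gene", "min_distance_nt"),
             drop = FALSE]
  out[order(-out$min_distance_nt, out$gene_id), , drop = FALSE]
}
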