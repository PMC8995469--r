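#' @useDynLib ighvaudit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Allele naming grammar: everything before the first "*" is the gene id;
# the family is the text up to the first hyphen, or failing that the leading
# letters+digits token (e.g. "IGHV3"). This accommodates both plain
# ("IGHV3-12*01") and suffix-carrying ("IGHV4-NL_28*01") naming styles.
gene_of <- function(allele_id) sub("\\*.*$", "", allele_id)

family_of <- function(gene_id) {
  fam <- sub("-.*$", "", gene_id)           # text up to the first hyphen
  m <- regexpr("^[A-Za-z]+[0-9]+", fam)     # else leading letters+digits
  hit <- m > 0
  fam[hit] <- substr(fam[hit], 1, attr(m, "match.length")[hit])
  fam
}

new_germline_db <- function(name, alleles) {
  stopifnot(is.character(name), nchar(name) > 0, is.data.frame(alleles))
  rownames(alleles) <- NULL
  db <- list(name = name, alleles = alleles)
  class(db) <- "germline_db"
  db
}

#' Construct a germline database from sequences
#'
#' Builds a `germline_db` object from a named character vector of allele
#' sequences. Allele ids follow the `GENE*ALLELE` grammar; ids lacking a
#' `*` suffix are given allele number `01` and flagged.
#'
#' @param sequences Named character vector; names are allele ids, values
#'   nucleotide sequences over `A`,`C`,`G`,`T` (and `N` if `allow_n`).
#' @param name Database label (non-empty string).
#' @param functionality Optional character vector of functionality labels
#'   (`"F"`, `"ORF"`, `"P"`); missing/NA entries become `"unlabeled"`.
#' @param allow_n Permit `N` bases in allele sequences (default `FALSE`:
#'   germline references are expected to be unambiguous).
#' @return A `germline_db` object.
#' @export
germline_db <- function(sequences, name = "db", functionality = NULL,
                        allow_n = FALSE) {
  if (length(sequences) == 0) stop("database '", name, "' has no sequences")
  ids <- names(sequences)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("all sequences must be named with allele ids")
  seqs <- toupper(gsub("[.\\-]", "", as.character(sequences)))
  if (any(!nzchar(seqs)))
    stop("empty sequence for: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, seqs)
  if (any(bad))
    stop("non-nucleotide characters in: ", paste(ids[bad], collapse = ", "))
  flagged <- !grepl("\\*", ids)
  ids[flagged] <- paste0(ids[flagged], "*01")
  dup <- duplicated(ids)
  if (any(dup))
    stop("duplicate allele id: ", paste(unique(ids[dup]), collapse = ", "))
  fun <- if (is.null(functionality)) rep(NA_character_, length(ids))
         else as.character(functionality)
  fun[is.na(fun) | !fun %in% c("F", "ORF", "P")] <- "unlabeled"
  genes <- gene_of(ids)
  alleles <- data.frame(
    allele_id = ids,
    gene_id = genes,
    family = family_of(genes),
    sequence = unname(seqs),
    seq_length = nchar(seqs),
    functionality = fun,
    source_db = name,
    no_allele_suffix = unname(flagged),
    stringsAsFactors = FALSE
  )
  new_germline_db(name, alleles)
}

#' Read a germline gene database from FASTA
#'
#' Parses a FASTA file of germline alleles into a [germline_db()] object.
#' Gap characters (`.`, `-`) carried over from gapped alignments are
#' stripped and sequences are uppercased.
#'
#' Two header dialects are supported: `"plain"`, where the first
#' whitespace-delimited token is the allele id, and `"imgt"`, the
#' pipe-delimited convention where field 2 is the allele name and field 4
#' the functionality label (F/ORF/P).
#'
#' @param path FASTA file path.
#' @param source_name Database label; defaults to the file name.
#' @param dialect Header dialect, `"plain"` or `"imgt"`.
#' @param allow_n Permit `N` bases in sequences.
#' @return A `germline_db` object.
#' @export
parse_fasta_db <- function(path, source_name = NULL,
                           dialect = c("plain", "imgt"), allow_n = FALSE) {
  dialect <- match.arg(dialect)
  if (is.null(source_name))
    source_name <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  fun <- NULL
  if (dialect == "imgt") {
    fields <- strsplit(headers, "|", fixed = TRUE)
    ids <- vapply(fields, function(f)
      if (length(f) >= 2) trimws(f[2]) else trimws(f[1]), character(1))
    fun <- vapply(fields, function(f)
      if (length(f) >= 4) trimws(f[4]) else NA_character_, character(1))
    fun <- sub("^\\((.*)\\)$", "\\1", fun)  # "(F)" style qualifiers
    fun <- sub("^\\[(.*)\\]$", "\\1", fun)
  } else {
    ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  germline_db(seqs, name = source_name, functionality = fun,
              allow_n = allow_n)
}

#' Write a germline database to FASTA
#'
#' Sequences are wrapped at 60 columns. Round-trips through
#' [parse_fasta_db()] reproduce allele ids and sequences exactly.
#'
#' @param db A `germline_db`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta_db <- function(db, path) {
  stopifnot(inherits(db, "germline_db"))
  if (!nzchar(db$name)) stop("database name must be non-empty")
  set <- Biostrings::DNAStringSet(db$alleles$sequence)
  names(set) <- db$alleles$allele_id
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' @export
print.germline_db <- function(x, ...) {
  cat(sprintf("germline_db '%s': %d alleles, %d genes, %d families\n",
              x$name, nrow(x$alleles), length(unique(x$alleles$gene_id)),
              length(unique(x$alleles$family))))
  fn <- table(x$alleles$functionality)
  cat("functionality:", paste(names(fn), fn, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Gene index of a database
#'
#' @param db A `germline_db`.
#' @return Named list mapping gene id to the character vector of its
#'   allele ids.
#' @export
gene_index <- function(db) {
  stopifnot(inherits(db, "germline_db"))
  split(db$alleles$allele_id, db$alleles$gene_id)
}

#' Subset a database
#'
#' @param db A `germline_db`.
#' @param alleles Allele ids to keep (either this or `drop_genes`).
#' @param drop_genes Gene ids whose alleles are removed.
#' @param name Optional new database label.
#' @return A `germline_db`.
#' @export
subset_db <- function(db, alleles = NULL, drop_genes = NULL, name = NULL) {
  stopifnot(inherits(db, "germline_db"))
  keep <- rep(TRUE, nrow(db$alleles))
  if (!is.null(alleles)) {
    missing <- setdiff(alleles, db$alleles$allele_id)
    if (length(missing))
      stop("unknown allele id: ", paste(missing, collapse = ", "))
    keep <- db$alleles$allele_id %in% alleles
  }
  if (!is.null(drop_genes)) {
    missing <- setdiff(drop_genes, db$alleles$gene_id)
    if (length(missing))
      stop("unknown gene id: ", paste(missing, collapse = ", "))
    keep <- keep & !(db$alleles$gene_id %in% drop_genes)
  }
  if (!any(keep)) stop("subset would leave an empty database")
  new_germline_db(name %||% db$name, db$alleles[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group alleles into putative genes by edit distance
#'
#' Single-linkage clustering on Levenshtein distance: two alleles share a
#' cluster iff they are connected by a chain of pairs each within
#' `threshold` nucleotides. With the default threshold of 5 this groups
#' sequences likely to be allelic variants of one gene, since alleles of a
#' gene typically differ by ~5 nt while genes of a family differ by 14 nt
#' or more.
#'
#' @param db A `germline_db`.
#' @param threshold Maximum within-cluster link distance in nucleotides
#'   (default 5, i.e. "fewer than 6 differences").
#' @return Named list mapping cluster id to a sorted character vector of
#'   allele ids. Cluster ids are assigned in order of each cluster's
#'   lexicographically smallest member, so the result is invariant to the
#'   input order of alleles.
#' @export
cluster_alleles_into_genes <- function(db, threshold = 5L) {
  stopifnot(inherits(db, "germline_db"), threshold >= 0)
  ids <- db$alleles$allele_id
  n <- length(ids)
  if (n == 0) return(list())
  d <- utils::adist(db$alleles$sequence)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (d[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  if (n == 1) roots <- 1L else roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, roots)
  groups <- lapply(groups, sort)
  ord <- order(vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]
  names(groups) <- sprintf("cluster_%03d", seq_along(groups))
  groups
}
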