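# Locating germline database sequences in genomic assembly contigs.
#
# Exact occurrences are found on both strands with Biostrings pattern
# matching. Approximate occurrences use exact k-mer seeds to locate
# candidate windows, which are then aligned with the free-end-gap aligner;
# the reported distance follows the convention for local genomic matches:
# unaligned query residues plus aligned residues differing from the
# genomic sequence, gaps counted as differences. Hits are filtered at a
# maximum distance (default 5 nt) to remove spurious matches.

.load_contigs <- function(contigs) {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs))
    contigs <- Biostrings::readDNAStringSet(contigs)
  if (is.character(contigs))
    contigs <- Biostrings::DNAStringSet(contigs)
  stopifnot(methods::is(contigs, "DNAStringSet"))
  if (length(contigs) == 0) stop("no contigs supplied")
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig_", seq_along(contigs))
  contigs
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.empty_hits <- function() {
  data.frame(allele_id = character(), contig_id = character(),
             strand = character(), start = integer(), end = integer(),
             distance_nt = integer(), stringsAsFactors = FALSE)
}

#' Exact occurrences of database alleles in assembly contigs
#'
#' Finds every exact substring occurrence of each allele sequence, forward
#' and reverse complement. Coordinates are 0-based half-open on the
#' forward strand of the contig.
#'
#' @param db A `germline_db`.
#' @param contigs Contigs as a `DNAStringSet`, named character vector, or
#'   FASTA path.
#' @return Data frame of hits: `allele_id`, `contig_id`, `strand`
#'   (`+`/`-`), `start`, `end`, `distance_nt` (always 0).
#' @export
exact_search <- function(db, contigs) {
  stopifnot(inherits(db, "germline_db"))
  contigs <- .load_contigs(contigs)
  rows <- list()
  for (i in seq_len(nrow(db$alleles))) {
    aid <- db$alleles$allele_id[i]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") db$alleles$sequence[i]
             else .revcomp(db$alleles$sequence[i])
      m <- Biostrings::vmatchPattern(pat, contigs)
      for (ci in seq_along(contigs)) {
        r <- m[[ci]]
        if (length(r) == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          allele_id = aid, contig_id = names(contigs)[ci], strand = strand,
          start = IRanges::start(r) - 1L, end = IRanges::end(r),
          distance_nt = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(.empty_hits())
  out <- do.call(rbind, rows)
  out[order(out$allele_id, out$contig_id, out$start), , drop = FALSE]
}

# seed-and-extend scan of one query against one contig on one strand;
# returns candidate hit rows (unfiltered coordinates are forward-strand).
.scan_one <- function(qseq, aid, contig, contig_id, strand, max_distance,
                      seed_k) {
  L <- nchar(qseq)
  ctg_len <- length(contig)
  starts <- seq_len(L - seed_k + 1)
  kmers <- Biostrings::DNAStringSet(substring(qseq, starts,
                                              starts + seed_k - 1))
  pd <- Biostrings::PDict(kmers)
  m <- Biostrings::matchPDict(pd, contig)
  st <- Biostrings::startIndex(m)
  diags <- integer(0)
  for (qi in seq_along(st))
    if (!is.null(st[[qi]]) && length(st[[qi]]))
      diags <- c(diags, st[[qi]] - (starts[qi] - 1L))
  if (length(diags) == 0) return(NULL)
  diags <- sort(unique(diags))
  grp <- cumsum(c(1L, diff(diags) > max_distance + 2L))
  margin <- max_distance + 2L
  rows <- list()
  for (g in unique(grp)) {
    d0 <- round(stats::median(diags[grp == g]))
    ws <- max(1L, d0 - margin)
    we <- min(ctg_len, d0 + L - 1L + margin)
    if (we < ws) next
    win <- as.character(Biostrings::subseq(contig, ws, we))
    al <- .cpp_align_pair(qseq, win, band = -1L)
    dist <- al$distance + al$a_overhang  # unaligned query residues count
    if (dist > max_distance) next
    rows[[length(rows) + 1]] <- data.frame(
      allele_id = aid, contig_id = contig_id, strand = strand,
      start = ws - 1L + al$b_start, end = ws - 1L + al$b_end,
      distance_nt = as.integer(dist), stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# merge overlapping hits of one allele on one contig, keeping the smaller
# distance (gene presence, not copy number, is what is reported)
.dedup_hits <- function(hits, min_overlap = 0.5) {
  if (nrow(hits) < 2) return(hits)
  hits <- hits[order(hits$distance_nt, hits$start, hits$strand), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- hits[keep, , drop = FALSE]
      ov <- pmin(prev$end, hits$end[i]) - pmax(prev$start, hits$start[i])
      len <- pmin(prev$end - prev$start, hits$end[i] - hits$start[i])
      if (any(ov > min_overlap * len)) ok <- FALSE
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Approximate occurrences of database alleles in assembly contigs
#'
#' Seed-and-extend search: exact `seed_k`-mers of each allele locate
#' candidate windows on both strands; each window (query length plus a
#' margin) is aligned to the query with free end gaps on the window side,
#' and the distance is computed as unaligned query residues plus differing
#' aligned residues, gaps included. Hits exceeding `max_distance` are
#' discarded; overlapping hits of one allele are merged keeping the
#' minimal distance.
#'
#' With `max_distance` 5 and ~300-nt queries, any true hit necessarily
#' contains an exact 20-mer, so seeding does not cost sensitivity at the
#' distance filter used here.
#'
#' @param db A `germline_db`.
#' @param contigs Contigs (`DNAStringSet`, named character, or FASTA path).
#' @param max_distance Maximum distance in nucleotides (default 5).
#' @param seed_k Seed length (default 20); must not exceed the shortest
#'   allele.
#' @return Data frame of hits as in [exact_search()], with `distance_nt`
#'   up to `max_distance`.
#' @export
approximate_search <- function(db, contigs, max_distance = 5L, seed_k = 20L) {
  stopifnot(inherits(db, "germline_db"), max_distance >= 0)
  contigs <- .load_contigs(contigs)
  if (seed_k > min(db$alleles$seq_length))
    stop("seed_k (", seed_k, ") exceeds the shortest allele (",
         min(db$alleles$seq_length), " nt)")
  all_rows <- list()
  for (i in seq_len(nrow(db$alleles))) {
    aid <- db$alleles$allele_id[i]
    fwd <- db$alleles$sequence[i]
    rev <- .revcomp(fwd)
    per_allele <- list()
    for (ci in seq_along(contigs)) {
      ctg <- contigs[[ci]]
      cid <- names(contigs)[ci]
      h1 <- .scan_one(fwd, aid, ctg, cid, "+", max_distance, seed_k)
      h2 <- .scan_one(rev, aid, ctg, cid, "-", max_distance, seed_k)
      h <- rbind(h1, h2)
      if (!is.null(h) && nrow(h)) per_allele[[cid]] <- .dedup_hits(h)
    }
    if (length(per_allele))
      all_rows[[aid]] <- do.call(rbind, per_allele)
  }
  if (length(all_rows) == 0) return(.empty_hits())
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  out[order(out$allele_id, out$contig_id, out$start), , drop = FALSE]
}

#' Gene presence matrix across assemblies
#'
#' A gene is present in an assembly iff any of its alleles has a hit with
#' distance at most `threshold`. A union column reports presence in any
#' assembly.
#'
#' @param db A `germline_db`.
#' @param assemblies Named list of contig sets (each a `DNAStringSet`,
#'   named character vector, or FASTA path).
#' @param threshold Presence threshold in nucleotides (default 5).
#' @param seed_k Seed length passed to [approximate_search()].
#' @return Data frame: `gene_id`, one logical column per assembly, and
#'   `any_assembly`.
#' @export
presence_matrix <- function(db, assemblies, threshold = 5L, seed_k = 20L) {
  stopifnot(inherits(db, "germline_db"), length(assemblies) > 0,
            !is.null(names(assemblies)))
  genes <- sort(unique(db$alleles$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (an in names(assemblies)) {
    hits <- approximate_search(db, assemblies[[an]],
                               max_distance = threshold, seed_k = seed_k)
    present_genes <- unique(gene_of(hits$allele_id[hits$distance_nt <= threshold]))
    out[[an]] <- genes %in% present_genes
  }
  out$any_assembly <- Reduce(`|`, out[names(assemblies)])
  out
}
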