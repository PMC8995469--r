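# Simplified individualized genotype inference from IgM, and inferred
# haplotyping anchored on a heterozygous J gene.
#
# Genotype inference is deliberately simple and fully specified: an allele
# is called when the same germline-region sequence is observed exactly in
# enough reads spanning enough distinct junctions, the junction diversity
# guaranteeing independent VDJ recombination events rather than clonal
# expansion of a single mutated cell. IgM reads are near-germline, so each
# expressed allele leaves a large group of identical observations while
# mutated reads scatter into singleton sequences.

#' Infer an individualized germline V genotype from an IgM library
#'
#' Candidate alleles are the distinct observed germline-region sequences
#' (`v_sequence`) supported by at least `min_reads` identical reads
#' spanning at least `min_junctions` distinct junctions. Candidates whose
#' sequence matches a starting-database allele keep its name; the rest are
#' named `<gene>*S<number>` after the gene their reads were assigned to
#' and flagged novel. An allele observed only through mutated reads (no
#' identical observations) is not called: a documented limitation.
#'
#' @param igm An `assignment_table` from an IgM library, with `junction`
#'   available (assign with a J database).
#' @param starting_db The `germline_db` the library was assigned to.
#' @param min_reads Minimum identical supporting reads (default 5).
#' @param min_junctions Minimum distinct junctions (default 3).
#' @param db_name Name for the individualized database.
#' @return List of class `genotype_call`: `calls` (data frame `allele_id`,
#'   `sequence`, `n_exact_reads`, `n_distinct_junctions`, `novel`) and
#'   `db`, the individualized `germline_db`.
#' @export
infer_genotype <- function(igm, starting_db, min_reads = 5L,
                           min_junctions = 3L, db_name = "individualized") {
  stopifnot(inherits(starting_db, "germline_db"))
  if (!all(c("v_sequence", "junction", "v_call") %in% names(igm)))
    stop("assignment table lacks v_sequence/junction columns")
  if (all(is.na(igm$junction)))
    stop("assignment table lacks junction information; ",
         "assign the library with a J database")
  groups <- split(igm, igm$v_sequence)
  rows <- lapply(groups, function(g) {
    data.frame(sequence = g$v_sequence[1],
               n_exact_reads = nrow(g),
               n_distinct_junctions = length(unique(g$junction)),
               gene_hint = names(sort(table(gene_of(g$v_call)),
                                      decreasing = TRUE))[1],
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  cand <- cand[cand$n_exact_reads >= min_reads &
                 cand$n_distinct_junctions >= min_junctions, , drop = FALSE]
  if (nrow(cand) == 0) stop("no alleles pass the support thresholds")
  idx <- match(cand$sequence, starting_db$alleles$sequence)
  cand$novel <- is.na(idx)
  cand$allele_id <- ifelse(cand$novel, NA_character_,
                           starting_db$alleles$allele_id[idx])
  novel_i <- which(cand$novel)
  if (length(novel_i))
    cand$allele_id[novel_i] <- paste0(cand$gene_hint[novel_i], "*S",
                                      sprintf("%04d", seq_along(novel_i)))
  cand <- cand[order(cand$allele_id), , drop = FALSE]
  seqs <- stats::setNames(cand$sequence, cand$allele_id)
  db <- germline_db(seqs, name = db_name)
  calls <- data.frame(allele_id = cand$allele_id, sequence = cand$sequence,
                      n_exact_reads = cand$n_exact_reads,
                      n_distinct_junctions = cand$n_distinct_junctions,
                      novel = cand$novel, stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  out <- list(calls = calls, db = db,
              min_reads = min_reads, min_junctions = min_junctions)
  class(out) <- "genotype_call"
  out
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("genotype_call: %d alleles (%d novel), thresholds %d reads / %d junctions\n",
              nrow(x$calls), sum(x$calls$novel), x$min_reads,
              x$min_junctions))
  invisible(x)
}

#' Inferred haplotype analysis anchored on a heterozygous J gene
#'
#' In VDJ recombination the V and J segments of one read come from the
#' same chromosome, so for an animal heterozygous at a J gene the two J
#' alleles separate V alleles by haplotype. Near-germline reads
#' (`v_errors` at most `max_v_errors`) carrying either anchor allele are
#' counted per V allele; a V allele is exclusive to an anchor when at
#' least `purity` of its reads carry that anchor.
#'
#' Per-gene zygosity: `heterozygous` when distinct alleles are exclusive
#' to opposite anchors; `homozygous` when a single allele is seen on both
#' anchors; `hemizygous_J1`/`hemizygous_J2` when all the gene's alleles
#' are exclusive to one anchor; `absent` below the read-count floor;
#' `ambiguous` otherwise.
#'
#' @param igm An `assignment_table` with `j_call` available.
#' @param anchor_gene The heterozygous J gene id.
#' @param allele1,allele2 Its two anchor alleles (distinct; both must be
#'   observed in the library).
#' @param min_count Per-gene read-count floor (default 10).
#' @param purity Anchor-exclusivity fraction (default 0.9).
#' @param max_v_errors Maximum V errors for a read to be counted
#'   (default 1; tolerates one sequencing error without cross-allele
#'   bleed, alleles being ~5 nt apart).
#' @return List of class `haplotype_table`: `alleles` (per V allele:
#'   `count_J1`, `count_J2`, `side` in `J1`/`J2`/`both`) and `genes`
#'   (per gene: `n_reads`, `zygosity`).
#' @export
haplotype_by_j_anchor <- function(igm, anchor_gene, allele1, allele2,
                                  min_count = 10L, purity = 0.9,
                                  max_v_errors = 1L) {
  if (identical(allele1, allele2)) stop("anchor alleles identical")
  if (!all(c("j_call", "v_call", "v_errors") %in% names(igm)) ||
      all(is.na(igm$j_call)))
    stop("assignment table lacks J calls")
  if (gene_of(allele1) != anchor_gene || gene_of(allele2) != anchor_gene)
    stop("anchor alleles must belong to gene ", anchor_gene)
  observed <- unique(igm$j_call[gene_of(igm$j_call) %in% anchor_gene])
  if (!all(c(allele1, allele2) %in% observed))
    stop("anchoring requires heterozygous J: both anchor alleles must be ",
         "observed in the library")
  sel <- igm$v_errors <= max_v_errors & igm$j_call %in% c(allele1, allele2)
  sub <- igm[sel, , drop = FALSE]
  valleles <- sort(unique(sub$v_call))
  n1 <- vapply(valleles, function(a)
    sum(sub$v_call == a & sub$j_call == allele1), integer(1))
  n2 <- vapply(valleles, function(a)
    sum(sub$v_call == a & sub$j_call == allele2), integer(1))
  p1 <- n1 / (n1 + n2)
  side <- ifelse(p1 >= purity, "J1", ifelse(p1 <= 1 - purity, "J2", "both"))
  alleles <- data.frame(v_allele = valleles, gene = gene_of(valleles),
                        count_J1 = unname(n1), count_J2 = unname(n2),
                        side = unname(side), stringsAsFactors = FALSE)
  rownames(alleles) <- NULL
  genes <- sort(unique(alleles$gene))
  zyg <- vapply(genes, function(g) {
    ga <- alleles[alleles$gene == g, , drop = FALSE]
    total <- sum(ga$count_J1 + ga$count_J2)
    if (total < min_count) return("absent")
    sides <- ga$side
    if (nrow(ga) >= 2 && "J1" %in% sides && "J2" %in% sides &&
        !"both" %in% sides) return("heterozygous")
    if (all(sides == "both")) return("homozygous")
    if (all(sides == "J1")) return("hemizygous_J1")
    if (all(sides == "J2")) return("hemizygous_J2")
    "ambiguous"
  }, character(1))
  gene_tab <- data.frame(
    gene_id = genes,
    n_reads = vapply(genes, function(g)
      sum(alleles$count_J1[alleles$gene == g] +
            alleles$count_J2[alleles$gene == g]), integer(1)),
    zygosity = unname(zyg), stringsAsFactors = FALSE)
  rownames(gene_tab) <- NULL
  out <- list(alleles = alleles, genes = gene_tab,
              anchors = c(J1 = allele1, J2 = allele2),
              min_count = min_count, purity = purity)
  class(out) <- "haplotype_table"
  out
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table anchored on %s / %s\n",
              x$anchors["J1"], x$anchors["J2"]))
  print(table(x$genes$zygosity))
  invisible(x)
}
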