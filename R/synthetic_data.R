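# Synthetic germline loci, diploid genotypes with structural variation,
# and SHM-bearing repertoires with full ground truth.
#
# The generator emulates the statistical structure the audit rests on:
# a multi-family V locus where alleles of a gene differ by a median of
# ~5 nt while genes of a family differ by family-specific medians
# (defaults 42/21/49/21/14 nt for families 1-5), diploid genotypes with
# per-haplotype gene deletions, and IgM (low-SHM) / IgG (high-SHM)
# recombined reads carrying a heterozygous J anchor. Substitution-only
# SHM with uniform placement keeps the planted-mutation audit exact.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.bases <- c("A", "C", "G", "T")

random_nt <- function(n)
  paste(sample(.bases, n, replace = TRUE), collapse = "")

# plant n substitutions at distinct positions, each to one of the three
# alternative bases; returns the sequence and the positions
plant_substitutions <- function(seq, n) {
  L <- nchar(seq)
  n <- min(n, L)
  if (n == 0) return(list(sequence = seq, positions = integer(0)))
  pos <- sort(sample.int(L, n))
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(.bases, ch[p]), 1)
  list(sequence = paste(ch, collapse = ""), positions = pos)
}

#' Simulate a multi-family germline V locus
#'
#' Family ancestors are i.i.d. uniform nucleotide sequences; genes of a
#' family each carry ~`between_target`/2 substitutions relative to the
#' ancestor (so gene pairs differ by roughly the family target). Allele
#' `*01` of each gene is its ancestral base; further alleles radiate from
#' it by 2 + Poisson(`within_target`/2 - 1) substitutions capped at
#' `within_target`, so allele pairs differ by up to ~`within_target`
#' while every allele stays within the allelic-distance criterion of its
#' `*01`, keeping distance-threshold gene grouping well posed. The J
#' locus holds `n_j_genes` genes, the last of which is the heterozygous
#' anchor with two alleles. Realized medians are validated against the
#' targets (within ±2 nt, between ±5 nt per family) and the locus is
#' resampled up to 10 times if violated.
#'
#' @param seed Integer seed; identical seeds give identical loci.
#' @param n_families Number of V families (default 5).
#' @param genes_per_family Genes per family (scalar or vector).
#' @param allele_counts Alleles per gene (scalar or vector over all
#'   genes).
#' @param within_target Target within-gene median distance in nt
#'   (default 5).
#' @param between_targets Target between-gene within-family medians, one
#'   per family (defaults 42, 21, 49, 21, 14 recycled as needed).
#' @param gene_length V gene length in nt (default 296).
#' @param n_j_genes Number of J genes (default 2, minimum 2).
#' @param j_gene_length J gene length in nt (default 50).
#' @return List of class `simulated_locus`: `v_db`, `j_db`
#'   (`germline_db`s), `anchor_gene`, `anchor_alleles`, `params`.
#' @export
simulate_locus <- function(seed, n_families = 5L, genes_per_family = 6L,
                           allele_counts = 3L, within_target = 5,
                           between_targets = c(42, 21, 49, 21, 14),
                           gene_length = 296L, n_j_genes = 2L,
                           j_gene_length = 50L) {
  stopifnot(n_families >= 1, n_j_genes >= 2, within_target > 0)
  genes_per_family <- rep_len(genes_per_family, n_families)
  between_targets <- rep_len(between_targets, n_families)
  if (any(between_targets <= 0) || within_target >= min(between_targets))
    stop("infeasible divergence targets: within_target must be below ",
         "every between_target")
  with_seed(seed, {
    n_genes_total <- sum(genes_per_family)
    counts <- rep_len(allele_counts, n_genes_total)
    for (attempt in 1:10) {
      seqs <- character(0)
      gene_no <- 0L
      for (f in seq_len(n_families)) {
        fam <- paste0("IGHV", f)
        ancestor <- random_nt(gene_length)
        m_gene <- max(1L, round(between_targets[f] / 2))
        for (g in seq_len(genes_per_family[f])) {
          gene_no <- gene_no + 1L
          base <- plant_substitutions(ancestor, m_gene)$sequence
          # allele *01 is the ancestral allele (the gene base); further
          # alleles radiate from it by 1 + Poisson(within/2 - 1)
          # substitutions, capped at within_target so every allele stays
          # within the allelic-distance criterion of *01
          seqs[sprintf("%s-%d*01", fam, g)] <- base
          for (a in seq_len(counts[gene_no])[-1]) {
            nm <- sprintf("%s-%d*%02d", fam, g, a)
            k <- min(2L + stats::rpois(1, max(0, within_target / 2 - 1)),
                     within_target)
            seqs[nm] <- plant_substitutions(base, k)$sequence
          }
        }
      }
      if (anyDuplicated(names(seqs))) next
      v_db <- germline_db(seqs, name = "sim_locus")
      dd <- distance_distributions(v_db)
      within_ok <- all(is.na(dd$within_gene_median) |
                         abs(dd$within_gene_median - within_target) <= 2)
      between_ok <- all(is.na(dd$between_gene_median) |
                          abs(dd$between_gene_median - between_targets) <= 5)
      if (within_ok && between_ok) break
      if (attempt == 10)
        stop("could not realize divergence targets in 10 attempts")
    }
    j_seqs <- character(0)
    for (j in seq_len(n_j_genes - 1))
      j_seqs[sprintf("IGHJ%d*01", j)] <- random_nt(j_gene_length)
    anchor_gene <- sprintf("IGHJ%d", n_j_genes)
    j_base <- random_nt(j_gene_length)
    j_seqs[paste0(anchor_gene, "*01")] <- j_base
    j_seqs[paste0(anchor_gene, "*02")] <-
      plant_substitutions(j_base, 2)$sequence
    j_db <- germline_db(j_seqs, name = "sim_j_locus")
    out <- list(
      v_db = v_db, j_db = j_db,
      anchor_gene = anchor_gene,
      anchor_alleles = paste0(anchor_gene, c("*01", "*02")),
      params = list(seed = seed, n_families = n_families,
                    genes_per_family = genes_per_family,
                    allele_counts = allele_counts,
                    within_target = within_target,
                    between_targets = between_targets,
                    gene_length = gene_length))
    class(out) <- "simulated_locus"
    out
  })
}

#' @export
print.simulated_locus <- function(x, ...) {
  cat(sprintf("simulated_locus: %d V alleles / %d genes, anchor %s\n",
              nrow(x$v_db$alleles), length(unique(x$v_db$alleles$gene_id)),
              x$anchor_gene))
  invisible(x)
}

#' Simulate a diploid genotype with structural variation
#'
#' Each haplotype retains each locus gene independently with probability
#' `1 - deletion_prob` and carries one uniformly chosen allele per
#' retained gene, plus one anchor-J allele (the two haplotypes carry
#' different anchor alleles when heterozygosity is requested).
#'
#' @param locus A `simulated_locus`.
#' @param seed Integer seed.
#' @param deletion_prob Per-gene, per-haplotype deletion probability in
#'   `[0, 1)` (default 0.1).
#' @param heterozygous_anchor Give the two haplotypes different anchor-J
#'   alleles (default `TRUE`).
#' @return List of class `simulated_genotype`: `haplotypes` (two data
#'   frames of `gene_id`, `allele_id`), `anchor_alleles`, `zygosity`
#'   (truth per gene: homozygous / heterozygous / hemizygous_J1 /
#'   hemizygous_J2 / absent), `locus`.
#' @export
simulate_genotype <- function(locus, seed, deletion_prob = 0.1,
                              heterozygous_anchor = TRUE) {
  stopifnot(inherits(locus, "simulated_locus"),
            deletion_prob >= 0, deletion_prob < 1)
  genes <- unique(locus$v_db$alleles$gene_id)
  gi <- gene_index(locus$v_db)
  with_seed(seed, {
    haps <- lapply(1:2, function(h) {
      kept <- genes[stats::runif(length(genes)) >= deletion_prob]
      data.frame(gene_id = kept,
                 allele_id = vapply(kept, function(g) {
                   a <- gi[[g]]
                   a[sample.int(length(a), 1)]
                 }, character(1)),
                 stringsAsFactors = FALSE)
    })
    anchor <- if (heterozygous_anchor) locus$anchor_alleles
              else rep(locus$anchor_alleles[1], 2)
    zyg <- vapply(genes, function(g) {
      in1 <- g %in% haps[[1]]$gene_id
      in2 <- g %in% haps[[2]]$gene_id
      if (!in1 && !in2) return("absent")
      if (in1 && !in2) return("hemizygous_J1")
      if (!in1 && in2) return("hemizygous_J2")
      a1 <- haps[[1]]$allele_id[haps[[1]]$gene_id == g]
      a2 <- haps[[2]]$allele_id[haps[[2]]$gene_id == g]
      if (a1 == a2) "homozygous" else "heterozygous"
    }, character(1))
    if (all(vapply(haps, nrow, integer(1)) == 0))
      warning("both haplotypes are empty at deletion_prob = ",
              deletion_prob)
    out <- list(haplotypes = haps,
                anchor_alleles = stats::setNames(anchor, c("J1", "J2")),
                zygosity = data.frame(gene_id = genes,
                                      zygosity = unname(zyg),
                                      stringsAsFactors = FALSE),
                locus = locus, deletion_prob = deletion_prob)
    class(out) <- "simulated_genotype"
    out
  })
}

#' Simulate an SHM-bearing VDJ repertoire with ground truth
#'
#' Per read: a haplotype is drawn fair-coin; a V gene uniformly from that
#' haplotype (using its allele); the J segment is that haplotype's anchor
#' allele, or with probability `non_anchor_j_rate` a non-anchor J gene; a
#' junction of i.i.d. random nucleotides (length ~ Normal(30, 10),
#' truncated at 0) joins them. Poisson(`shm_mean`) substitutions are
#' planted at distinct uniform positions of the V segment. The read is
#' V + junction + J, untruncated.
#'
#' @param genotype A `simulated_genotype`.
#' @param seed Integer seed.
#' @param n_reads Number of reads (> 0).
#' @param shm_mean Mean V mutation count (use ~1 for IgM-like, ~20 for
#'   IgG-like libraries).
#' @param junction_mean,junction_sd Junction length distribution
#'   parameters (defaults 30 and 10 nt).
#' @param non_anchor_j_rate Probability a read uses a non-anchor J gene
#'   (default 0.25).
#' @return List of class `simulated_repertoire`: `reads` (data frame
#'   `read_id`, `sequence`) and `truth` (per read: haplotype, true V and
#'   J alleles, `n_mutations`, comma-separated mutated V positions,
#'   junction string).
#' @export
simulate_repertoire <- function(genotype, seed, n_reads,
                                shm_mean = 1, junction_mean = 30,
                                junction_sd = 10,
                                non_anchor_j_rate = 0.25) {
  stopifnot(inherits(genotype, "simulated_genotype"))
  if (n_reads <= 0) stop("n_reads must be positive")
  locus <- genotype$locus
  vseq <- stats::setNames(locus$v_db$alleles$sequence,
                          locus$v_db$alleles$allele_id)
  jseq <- stats::setNames(locus$j_db$alleles$sequence,
                          locus$j_db$alleles$allele_id)
  non_anchor <- locus$j_db$alleles$allele_id[
    locus$j_db$alleles$gene_id != locus$anchor_gene]
  haps <- genotype$haplotypes
  if (any(vapply(haps, nrow, integer(1)) == 0))
    stop("each haplotype must express at least one V gene")
  with_seed(seed, {
    hap_idx <- sample(1:2, n_reads, replace = TRUE)
    jl <- pmax(0L, as.integer(round(stats::rnorm(n_reads, junction_mean,
                                                 junction_sd))))
    use_non_anchor <- stats::runif(n_reads) < non_anchor_j_rate &
      length(non_anchor) > 0
    rows <- vector("list", n_reads)
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      hap <- haps[[hap_idx[i]]]
      v_allele <- hap$allele_id[sample.int(nrow(hap), 1)]
      j_allele <- if (use_non_anchor[i])
        non_anchor[sample.int(length(non_anchor), 1)]
      else unname(genotype$anchor_alleles[hap_idx[i]])
      nmut <- stats::rpois(1, shm_mean)
      mut <- plant_substitutions(vseq[[v_allele]], nmut)
      junction <- if (jl[i] > 0) random_nt(jl[i]) else ""
      seqs[i] <- paste0(mut$sequence, junction, jseq[[j_allele]])
      rows[[i]] <- data.frame(
        read_id = sprintf("read_%06d", i),
        haplotype = hap_idx[i],
        v_allele = v_allele,
        j_allele = j_allele,
        n_mutations = length(mut$positions),
        positions = paste(mut$positions, collapse = ","),
        junction = junction,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    out <- list(reads = data.frame(read_id = truth$read_id,
                                   sequence = seqs,
                                   stringsAsFactors = FALSE),
                truth = truth,
                params = list(seed = seed, n_reads = n_reads,
                              shm_mean = shm_mean))
    class(out) <- "simulated_repertoire"
    out
  })
}

#' Write simulated reads to FASTA or FASTQ
#'
#' @param repertoire A `simulated_repertoire` (or any data frame with
#'   `read_id` and `sequence`).
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"` (FASTQ qualities are uniform
#'   `I`).
#' @return Invisibly, `path`.
#' @export
write_reads <- function(repertoire, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  reads <- if (inherits(repertoire, "simulated_repertoire"))
    repertoire$reads else repertoire
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  } else {
    q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
    qs <- Biostrings::QualityScaledDNAStringSet(
      set, Biostrings::PhredQuality(q))
    Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  }
  invisible(path)
}
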