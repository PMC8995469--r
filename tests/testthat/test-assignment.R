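# small fixture: a locus, a diploid genotype and IgM/IgG-like reads
make_fixture <- function(seed, n_reads = 200, shm_mean = 1, ...) {
  loc <- simulate_locus(seed, n_families = 2, genes_per_family = 3,
                        allele_counts = 2, between_targets = c(20, 30))
  gt <- simulate_genotype(loc, seed + 1, deletion_prob = 0)
  rep <- simulate_repertoire(gt, seed + 2, n_reads = n_reads,
                             shm_mean = shm_mean, ...)
  list(loc = loc, gt = gt, rep = rep)
}

test_that("a read equal to a germline allele assigns with zero errors", {
  fx <- make_fixture(101, n_reads = 1, shm_mean = 0)
  db <- fx$loc$v_db
  allele <- db$alleles$allele_id[4]
  read <- stats::setNames(db$alleles$sequence[4], "r1")
  tab <- assign_read(read, db)
  expect_equal(tab$v_call, allele)
  expect_equal(tab$v_errors, 0L)
  expect_equal(tab$v_aligned_length, unname(nchar(read)))
  expect_equal(tab$shm_pct, 0)
})

test_that("planted substitutions are counted exactly despite the junction", {
  set.seed(102)
  fx <- make_fixture(102)
  db <- fx$loc$v_db
  vseq <- db$alleles$sequence[1]
  # keep mutations clear of the V 3' boundary so the junction cannot
  # lure the alignment into a score-improving end detour
  mut <- plant_interior(vseq, 7, margin = 8)
  read <- stats::setNames(paste0(mut$sequence, rand_seq(30)), "r1")
  tab <- assign_read(read, db)
  expect_equal(tab$v_call, db$alleles$allele_id[1])
  expect_equal(tab$v_errors, 7L)
})

test_that("the planted-mutation audit holds across a library", {
  fx <- make_fixture(103, n_reads = 200, shm_mean = 5)
  tab <- assign_library(fx$rep$reads, fx$loc$v_db)
  m <- match(tab$read_id, fx$rep$truth$read_id)
  expect_equal(nrow(tab), 200)
  # the best-scoring call matches the source allele except where SHM has
  # genuinely pushed a read toward a sibling allele
  expect_gte(mean(tab$v_call == fx$rep$truth$v_allele[m]), 0.97)
  same <- tab$v_call == fx$rep$truth$v_allele[m]
  # errors can only be counted on top of the planted ones (a rare end
  # detour into the junction adds columns, never removes them)
  expect_true(all(tab$v_errors[same] >= fx$rep$truth$n_mutations[m][same]))
  expect_gte(mean(tab$v_errors[same] == fx$rep$truth$n_mutations[m][same]),
             0.95)
})

test_that("reads from a removed gene fall to the nearest remaining gene", {
  set.seed(104)
  base <- rand_seq(296)
  near <- plant_interior(base, 8)$sequence
  far <- lapply(1:6, function(i) plant_interior(base, 40)$sequence)
  seqs <- c("IGHV1-1*01" = base, "IGHV1-2*01" = near,
            stats::setNames(unlist(far), sprintf("IGHV2-%d*01", 1:6)))
  db <- germline_db(seqs, name = "loo")
  read <- stats::setNames(paste0(base, rand_seq(25)), "r1")
  full <- assign_read(read, db)
  expect_equal(full$v_call, "IGHV1-1*01")
  reduced <- assign_read(read, subset_db(db, drop_genes = "IGHV1-1"))
  expect_equal(reduced$v_call, "IGHV1-2*01")
  expect_equal(reduced$v_errors, 8L)
})

test_that("empty, short and low-coverage inputs are handled explicitly", {
  fx <- make_fixture(105)
  db <- fx$loc$v_db
  empty <- assign_library(data.frame(read_id = character(),
                                     sequence = character()), db)
  expect_equal(nrow(empty), 0)

  short <- stats::setNames(substr(db$alleles$sequence[1], 1, 60), "s1")
  tab <- assign_library(short, db)
  expect_equal(nrow(tab), 0)
  expect_equal(attr(tab, "dropped")$reason, "short_read")

  frag <- stats::setNames(substr(db$alleles$sequence[1], 1, 120), "f1")
  tab2 <- assign_library(frag, db)
  expect_equal(nrow(tab2), 0)
  expect_equal(attr(tab2, "dropped")$reason, "low_coverage")
})

test_that("assignment is deterministic and file input round-trips", {
  fx <- make_fixture(106, n_reads = 50)
  t1 <- assign_library(fx$rep$reads, fx$loc$v_db)
  t2 <- assign_library(fx$rep$reads, fx$loc$v_db)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  fq <- tempfile(fileext = ".fastq")
  write_reads(fx$rep, fq, format = "fastq")
  t3 <- assign_library(fq, fx$loc$v_db)
  expect_equal(t3$v_call, t1$v_call)
  expect_equal(t3$v_errors, t1$v_errors)
})

test_that("read tracing joins on identifiers and reports missing reads", {
  fx <- make_fixture(107, n_reads = 10)
  db <- fx$loc$v_db
  t1 <- assign_library(fx$rep$reads, db)
  tr <- trace_reads(t1, list(again = t1))
  expect_equal(nrow(tr$joined), 10)
  expect_equal(tr$joined$v_errors_again, tr$joined$v_errors_sim_locus)
  expect_equal(nrow(tr$missing), 0)

  t2 <- assign_library(fx$rep$reads[1:9, ], db)
  attr(t2, "database") <- "partial"
  tr2 <- trace_reads(t1, list(partial = t2))
  expect_equal(nrow(tr2$joined), 9)
  expect_equal(nrow(tr2$missing), 1)
  expect_equal(tr2$missing$read_id, fx$rep$reads$read_id[10])

  t3 <- t1
  t3$read_id[2] <- t3$read_id[1]
  expect_error(trace_reads(t1, list(bad = t3)), "duplicated read_id")
})

test_that("per-gene medians bin by the anchor run, lower-median for ties", {
  mk_tab <- function(v_call, v_errors, dbname) {
    tab <- data.frame(read_id = sprintf("r%02d", seq_along(v_call)),
                      v_call = v_call, v_errors = v_errors,
                      stringsAsFactors = FALSE)
    attr(tab, "database") <- dbname
    class(tab) <- c("assignment_table", "data.frame")
    tab
  }
  anchor <- mk_tab(rep(c("GA*01", "GB*01"), each = 4),
                   c(0, 1, 2, 3, 5, 6, 7, 8), "anchor")
  other <- mk_tab(rep(c("GA*01", "GB*01"), each = 4),
                  c(1, 2, 3, 4, 10, 11, 12, 13), "other")
  tr <- trace_reads(anchor, list(other = other))
  med <- per_gene_median_table(tr)
  # even-sized bins take the lower central value
  expect_equal(med$median_v_errors_anchor[med$gene_id == "GA"], 1)
  expect_equal(med$median_v_errors_other[med$gene_id == "GA"], 2)
  expect_equal(med$median_v_errors_anchor[med$gene_id == "GB"], 6)
  expect_equal(med$median_v_errors_other[med$gene_id == "GB"], 11)
  expect_equal(med$n_reads, c(4L, 4L))

  # all-zero errors give all-zero medians
  z <- mk_tab(rep("GA*01", 4), rep(0L, 4), "z")
  medz <- per_gene_median_table(trace_reads(z, list(b = z)))
  expect_equal(medz$median_v_errors_z, 0)
  expect_equal(medz$median_v_errors_b, 0)
})

test_that("leave-one-out reports inflation and reassignment", {
  set.seed(108)
  base <- rand_seq(296)
  near <- plant_interior(base, 8)$sequence
  far <- lapply(1:8, function(i) plant_interior(base, 45)$sequence)
  seqs <- c("IGHV1-1*01" = base, "IGHV1-2*01" = near,
            stats::setNames(unlist(far), sprintf("IGHV3-%d*01", 1:8)))
  db <- germline_db(seqs, name = "loo")
  reads <- data.frame(
    read_id = sprintf("r%03d", 1:300),
    sequence = vapply(1:300, function(i)
      paste0(plant_interior(base, stats::rpois(1, 5))$sequence,
             rand_seq(30)), ""),
    stringsAsFactors = FALSE)
  loo <- leave_one_out(db, "IGHV1-1", reads)
  expect_gt(loo$n_affected, 250)
  infl <- loo$median_after - loo$median_before
  expect_gte(infl, 8 - 2)
  expect_lte(infl, 8 + 2)
  frac_near <- loo$reassignment["IGHV1-2"] / sum(loo$reassignment)
  expect_gte(unname(frac_near), 0.95)

  # removing a gene no read uses affects nothing
  loo2 <- leave_one_out(db, "IGHV3-5", reads)
  expect_equal(loo2$n_affected, 0)
  expect_true(is.na(loo2$median_before) && is.na(loo2$median_after))
  expect_error(leave_one_out(db, "IGHV9-9", reads), "unknown gene")
})

test_that("v_errors never improve when the database shrinks", {
  fx <- make_fixture(109, n_reads = 150, shm_mean = 8)
  stats <- alignment_stats_matrix(fx$rep$reads, fx$loc$v_db)
  full <- best_under_subset(stats)
  set.seed(109)
  ids <- stats$allele_ids
  for (trial in 1:20) {
    sub <- sample(ids, sample(4:(length(ids) - 1), 1))
    res <- best_under_subset(stats, sub)
    ok <- !is.na(full$v_errors) & !is.na(res$v_errors)
    expect_true(all(full$v_errors[ok] <= res$v_errors[ok]))
  }
})

test_that("rearrangement tables serialize as AIRR-style TSV", {
  fx <- make_fixture(110, n_reads = 20)
  tab <- assign_library(fx$rep$reads, fx$loc$v_db, j_db = fx$loc$j_db)
  path <- tempfile(fileext = ".tsv")
  write_rearrangements(tab, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$sequence_id, tab$read_id)
  expect_equal(back$v_call, tab$v_call)
  expect_equal(back$v_errors, tab$v_errors)
  expect_equal(back$junction, tab$junction)
})
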