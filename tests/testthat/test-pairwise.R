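test_that("alignment matches brute-force enumeration on tiny pairs", {
  # the named example: one mismatch column is optimal
  or <- brute_align_oracle("ACGT", "ACAT")
  expect_equal(or$score, 3)
  expect_equal(or$distance, 1)
  r <- global_align("ACGT", "ACAT")
  expect_equal(r$score, or$score)
  expect_equal(r$distance_nt, or$distance)

  set.seed(41)
  for (trial in 1:25) {
    a <- rand_seq(sample(3:6, 1))
    b <- rand_seq(sample(3:6, 1))
    or <- brute_align_oracle(a, b)
    r <- global_align(a, b)
    expect_equal(r$score, or$score, info = paste(a, b))
    # the enumeration's best score is definitionally an upper bound; the
    # implementation must reach it, and never undercut the best distance
    expect_gte(r$distance_nt, or$distance)
  }
})

test_that("identity and substring containment give distance zero", {
  r <- global_align("ACGT", "ACGT")
  expect_equal(r$score, 4)
  expect_equal(r$distance_nt, 0)
  expect_true(all(r$aligned_columns == "match"))

  r2 <- global_align("ACGTACGT", "GTAC")
  expect_equal(r2$score, 4)
  expect_equal(r2$distance_nt, 0)
  expect_equal(sum(r2$aligned_columns == "terminal_overhang"), 4)

  set.seed(42)
  for (trial in 1:10) {
    tgt <- rand_seq(sample(80:200, 1))
    i0 <- sample(1:30, 1)
    qry <- substr(tgt, i0, i0 + sample(40:49, 1))
    expect_equal(global_align(qry, tgt)$distance_nt, 0)
    expect_equal(global_align(tgt, qry)$distance_nt, 0)
  }
})

test_that("score agrees with an independent overlap aligner", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  set.seed(43)
  for (trial in 1:30) {
    a <- rand_seq(sample(60:180, 1))
    b <- plant_interior(a, sample(0:10, 1), margin = 1)$sequence
    if (trial %% 3 == 0) { # also exercise indel-bearing pairs
      cut <- sample(10:(nchar(b) - 10), 1)
      b <- paste0(substr(b, 1, cut), substr(b, cut + sample(1:3, 1) + 1,
                                            nchar(b)))
    }
    ref <- Biostrings::pairwiseAlignment(
      pattern = a, subject = b, type = "overlap",
      substitutionMatrix = mat, gapOpening = 0.4, gapExtension = 0.1,
      scoreOnly = TRUE)
    expect_equal(global_align(a, b)$score, ref, tolerance = 1e-5,
                 info = paste("trial", trial))
  }
})

test_that("levenshtein wraps unit-cost edit distance", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0)
  expect_equal(levenshtein("ACGT", ""), 4)
  expect_equal(levenshtein("", ""), 0)
  expect_equal(levenshtein("ACGT", "AGT"), 1)
})

test_that("distance equals Hamming for equal-length mutated copies", {
  set.seed(44)
  for (trial in 1:20) {
    a <- rand_seq(100)
    k <- sample(0:8, 1)
    b <- plant_interior(a, k, margin = 4)$sequence
    r <- global_align(a, b)
    expect_equal(r$distance_nt, k)
    expect_equal(r$score, 100 - k)
  }
})

test_that("distance is symmetric in value", {
  set.seed(45)
  for (trial in 1:15) {
    a <- rand_seq(sample(50:120, 1))
    b <- plant_interior(a, sample(0:6, 1))$sequence
    if (trial %% 2 == 0)
      b <- paste0(substr(b, 1, 20), substr(b, 23, nchar(b))) # indel
    expect_equal(global_align(a, b)$distance_nt,
                 global_align(b, a)$distance_nt)
  }
})

test_that("score never increases as point mutations accumulate", {
  set.seed(46)
  for (trial in 1:100) {
    tgt <- rand_seq(60)
    q <- tgt
    prev <- global_align(q, tgt)$score
    pos <- sample(60, 3) # fresh positions: never revert a mutation
    for (step in 1:3) {
      q <- substitute_at(q, pos[step])
      sc <- global_align(q, tgt)$score
      expect_lte(sc, prev + 1e-9)
      prev <- sc
    }
  }
})

test_that("best_match picks the top score with deterministic tie-breaks", {
  set.seed(47)
  seqs <- vapply(1:8, function(i) rand_seq(90), "")
  names(seqs) <- sprintf("G%d*01", 1:8)
  db <- germline_db(seqs, name = "bm")
  hit <- best_match(c(q = seqs[[3]]), db)
  expect_equal(hit$allele_id, "G3*01")
  expect_equal(hit$distance_nt, 0)

  # equal-scoring duplicates resolve to the lexicographically first id
  db2 <- germline_db(c("B*01" = "TTTTGGGG", "A*01" = "TTTTGGGG"),
                     name = "tie")
  expect_equal(best_match(c(q = "TTTTGGGG"), db2)$allele_id, "A*01")

  # distance of the best match equals the Levenshtein minimum when no
  # truncation or indel is involved
  q <- plant_interior(seqs[[5]], 2, margin = 2)$sequence
  hit3 <- best_match(c(q = q), db)
  expect_equal(hit3$allele_id, "G5*01")
  expect_equal(hit3$distance_nt,
               min(utils::adist(q, unname(seqs))))
  expect_error(best_match(c(q = "ACGT"),
                          structure(list(name = "e",
                                         alleles = germline_db(
                                           c("x*01" = "ACGT"))$alleles[0, ]),
                                    class = "germline_db")),
               "empty")
})

test_that("distance distributions report per-family medians", {
  set.seed(49)
  a <- rand_seq(20) # random background so edit distance equals Hamming
  b <- substitute_at(a, 1:4)            # d(a,b) = 4
  # engineer d(a,c) = 6 and d(b,c) = 5 so the within set is {4, 5, 6}
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  cv <- av
  cv[1:2] <- bv[1:2]                    # share b's variants at 1, 2
  cv[3] <- setdiff(BASES, c(av[3], bv[3]))[1] # differ from both at 3
  for (p in c(5, 6, 9)) cv[p] <- setdiff(BASES, av[p])[1]
  cc <- paste(cv, collapse = "")
  expect_equal(as.integer(utils::adist(a, b)), 4)
  expect_equal(as.integer(utils::adist(a, cc)), 6)
  expect_equal(as.integer(utils::adist(b, cc)), 5)
  db <- germline_db(c("IGHV1-1*01" = a, "IGHV1-1*02" = b,
                      "IGHV1-1*03" = cc), name = "med")
  dd <- distance_distributions(db)
  expect_equal(dd$within_gene_median, 5)
  expect_true(is.na(dd$between_gene_median))

  # singleton genes only: within set empty
  db2 <- germline_db(c("IGHV1-1*01" = rand_seq(40),
                       "IGHV1-2*01" = rand_seq(40)), name = "sing")
  dd2 <- distance_distributions(db2)
  expect_equal(dd2$n_within, 0)
  expect_true(is.na(dd2$within_gene_median))
  expect_equal(dd2$n_between, 1)
})

test_that("generator loci reproduce their divergence targets", {
  loc <- simulate_locus(48, n_families = 1, genes_per_family = 5,
                        allele_counts = 3, within_target = 5,
                        between_targets = 20)
  dd <- distance_distributions(loc$v_db)
  expect_gte(dd$within_gene_median, 3)
  expect_lte(dd$within_gene_median, 7)
  expect_gte(dd$between_gene_median, 15)
  expect_lte(dd$between_gene_median, 25)
})

test_that("pairwise results export as a TSV table", {
  r <- global_align("ACGT", "ACAT", query_id = "q", target_id = "t")
  path <- tempfile(fileext = ".tsv")
  df <- pairwise_table(r, path)
  expect_true(file.exists(path))
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$query_id, "q")
  expect_equal(back$distance_nt, 1)
  expect_equal(df$columns, r$transcript)
})
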