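# Test helpers: sequence generators and independent alignment oracles.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute at given 1-based positions (each to a different base)
substitute_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

# plant k substitutions at distinct positions, at least `margin` from ends
plant_interior <- function(seq, k, margin = 0) {
  L <- nchar(seq)
  lo <- 1 + margin; hi <- L - margin
  pos <- if (k > 0) sample(lo:hi, k) else integer(0)
  list(sequence = substitute_at(seq, pos), positions = sort(pos))
}

# ---------------------------------------------------------------------------
# Brute-force enumeration oracle for tiny free-end-gap affine alignments.
# Enumerates every monotone alignment path; a leading/trailing pure run of
# one-sequence moves is a free terminal overhang; internal gap runs cost
# 0.5 + 0.1*(len-1); match +1, mismatch 0. Returns the maximum score and
# the minimum distance among maximum-score paths.
# ---------------------------------------------------------------------------
brute_align_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  best_score <- -Inf; best_dist <- Inf

  score_path <- function(mv) {
    L <- length(mv)
    lead <- 0L
    if (mv[1] != "M") {
      t <- mv[1]
      while (lead < L && mv[lead + 1] == t) lead <- lead + 1L
    }
    trail <- 0L
    if (mv[L] != "M" && lead < L) {
      t <- mv[L]
      while (trail < L - lead && mv[L - trail] == t) trail <- trail + 1L
    }
    i <- 0L; j <- 0L; sc <- 0; dist <- 0L; lastgap <- ""
    for (p in seq_len(L)) {
      v <- mv[p]
      internal <- p > lead && p <= L - trail
      if (v == "M") {
        i <- i + 1L; j <- j + 1L
        if (A[i] == B[j]) sc <- sc + 1 else dist <- dist + 1L
        lastgap <- ""
      } else {
        if (v == "D") i <- i + 1L else j <- j + 1L
        if (internal) {
          dist <- dist + 1L
          sc <- sc - (if (v == lastgap) 0.1 else 0.5)
          lastgap <- v
        } else lastgap <- ""
      }
    }
    c(sc, dist)
  }

  rec <- function(i, j, mv) {
    if (i == m && j == n) {
      r <- score_path(mv)
      if (r[1] > best_score + 1e-9) {
        best_score <<- r[1]; best_dist <<- r[2]
      } else if (abs(r[1] - best_score) < 1e-9 && r[2] < best_dist) {
        best_dist <<- r[2]
      }
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1, j + 1, c(mv, "M"))
    if (i < m) rec(i + 1, j, c(mv, "D"))
    if (j < n) rec(i, j + 1, c(mv, "I"))
  }
  rec(0L, 0L, character(0))
  list(score = best_score, distance = best_dist)
}

# ---------------------------------------------------------------------------
# Gap-free sliding oracle: over every relative offset of a against b,
# count matches/mismatches in the overlap; best = max matches, ties by
# fewer mismatches. Exact for substitution-only pairs where gaps cannot
# pay for themselves.
# ---------------------------------------------------------------------------
slide_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  best <- NULL
  for (c in (-(n - 1)):(m - 1)) {
    i0 <- max(0L, c); j0 <- i0 - c
    len <- min(m - i0, n - j0)
    if (len <= 0) next
    mt <- sum(A[(i0 + 1):(i0 + len)] == B[(j0 + 1):(j0 + len)])
    mm <- len - mt
    if (is.null(best) || mt > best$matches ||
        (mt == best$matches && mm < best$mismatches))
      best <- list(matches = mt, mismatches = mm)
  }
  best
}

# reverse complement without depending on package internals
rc <- function(s) {
  ch <- rev(strsplit(s, "")[[1]])
  paste(c(A = "T", C = "G", G = "C", T = "A")[ch], collapse = "")
}

# small helper: write a named character vector as a FASTA file
write_fa <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
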