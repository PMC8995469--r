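---
title: "Auditing IGHV germline reference databases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing IGHV germline reference databases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighvaudit)
```

## The problem

Antibody repertoire analysis starts by assigning each expressed VDJ read
to a germline V gene database; the number of nucleotide differences
between the read's V region and its assigned germline (`v_errors`) is
then read as somatic hypermutation (SHM). This makes every downstream
quantity hostage to the completeness of the database. Outbred species
such as rhesus macaques carry extensive structural variation at the IGH
locus: individual animals lack genes that other animals carry, so a
database compiled from one genome assembly (or from too few animals)
misses genes entirely. Reads from a missing gene do not disappear — they
are silently assigned to the *nearest remaining gene*, and the distance
between genes (typically 14–49 nt within a family) masquerades as extra
SHM. Alleles of one gene, by contrast, differ by only ~5 nt, so missing
an *allele* inflates SHM far less than missing a *gene*.

`ighvaudit` packages the components needed to quantify this effect and
to audit databases against each other and against genomic assemblies:

* database I/O and distance-based gene grouping (`parse_fasta_db`,
  `cluster_alleles_into_genes`),
* a free-end-gap pairwise aligner and nucleotide distance
  (`global_align`, `best_match`, `distance_distributions`),
* database-vs-database overlap and gene-content comparison
  (`exact_overlap`, `gene_content_compare`, `reciprocal_unmatched`),
* exact and approximate search of database sequences in assembly
  contigs (`exact_search`, `approximate_search`, `presence_matrix`),
* a deterministic repertoire assigner with per-gene SHM medians and a
  leave-one-gene-out experiment (`assign_library`, `trace_reads`,
  `per_gene_median_table`, `leave_one_out`),
* simplified individualized genotyping and heterozygous-J-anchored
  haplotype inference (`infer_genotype`, `haplotype_by_j_anchor`),
* a synthetic locus/genotype/repertoire generator with full ground
  truth (`simulate_locus`, `simulate_genotype`, `simulate_repertoire`).

## The aligner and its distance

Database comparison rests on one primitive: a global alignment of two
nucleotide sequences with *free end gaps*, scored

* match `+1`, mismatch `0`,
* internal gap: `-0.5` for the first position, `-0.1` for each further
  contiguous position,
* terminal gaps in either sequence: `0`, classed `terminal_overhang`.

The **nucleotide distance** of a pair is the number of mismatch plus
internal-gap columns in the maximum-score alignment; terminal overhangs
are excluded. Identical sequences, and sequences contained in a longer
partner (truncated database records), therefore sit at distance 0. A
perfect staggered suffix–prefix overlap also yields distance 0 — this is
a consequence of maximising the score under free end gaps and is
harmless at germline-database scale, where compared sequences are
near-full-length.

Mismatch at score 0 (rather than a penalty) is what makes the
substring-at-distance-0 behaviour exact, which the exact-overlap
analysis depends on. Because mismatches are free, many alignments can
tie at the maximum score; ties are resolved the same way best matches
are selected throughout the package — score primary, **distance
secondary**. The DP carries a co-optimal distance refinement (the
minimum distance among maximum-score paths into each cell), endpoint
ties resolve to the smallest such distance (then the longer alignment),
and the traceback follows a (score, distance)-co-optimal path,
preferring match > mismatch > gap in the second sequence > gap in the
first. Without this refinement an equal-scoring gap detour could
inflate the reported distance of a clean hit — e.g. past the 5-nt
assembly-presence filter. The core is implemented in C++ (integer
arithmetic in tenths of a score unit, so the gap costs are exact).

The unit-cost **Levenshtein distance** (via `utils::adist`) is kept as a
separate primitive; it drives allele-into-gene clustering and the
within/between-gene distance distributions, and serves as an independent
oracle for the aligner in the test-suite.

### Banded assignment

Aligning every read of a library against every database allele is the
assigner's contract (a full scan — no candidate pruning across alleles).
Within a pair, the DP is banded: a diagonal is chosen by exact 8-mer
seeding (falling back to an exhaustive gap-free diagonal scan when no
8-mer is shared), and the affine DP is computed exactly within ±24
diagonals of it. For any target within ~60 differences of the read —
every target that can win an assignment or materially shape a median —
seeds are abundant, the chosen diagonal is the true one and the banded
score equals the full-DP score; distant targets can only be
*under*-scored, which cannot change a best match. `global_align` and
`best_match` always run the full DP. `band = NULL` forces the full DP in
the assigner too.

## Gene grouping by distance

Alleles are grouped into putative genes by single-linkage clustering on
Levenshtein distance with a 5-nt threshold ("fewer than 6 differences"),
the same criterion used for gene presence in databases and assemblies
(`--max-allelic-distance` analogue: the `threshold` argument, one global
constant of 5 nt across `cluster_alleles_into_genes`,
`gene_content_compare` and `approximate_search`). Single linkage is the
right topology here because allelic variants radiate from a common
ancestral allele: chains through the hub connect variants that are
farther than the threshold from each other but within it of the hub.

## The assigner

`assign_library` aligns each read against every V allele; the call is
the best score (ties: fewer errors, then lexicographic id). `v_errors`
counts mismatch and internal-gap columns over the germline-covered span
only — the read's junction/CDR3 overhang is terminal and never counted.
Reads shorter than 100 nt or covering less than 50% of their best
germline are dropped with logged reasons. When a J database is supplied,
the best J allele is called at the 3' end and the junction (between the
V span end and the J span start) is extracted; junctions operationalise
independent VDJ recombination events.

Two properties matter downstream and are worth stating precisely:

* **Monotonicity.** Removing alleles from the database can only raise
  (or preserve) a read's `v_errors`: the best match over a subset is
  never better than over the full set. This is the mechanism by which a
  gene-restricted database inflates SHM. It holds as stated for scores;
  for error counts it holds empirically up to the junction-detour
  artefact below (fewer than ~0.1% of read × subset evaluations), since
  a detour on the full-database winner can leave a subset winner with a
  marginally lower count.
* **Near-exact mutation bookkeeping.** On simulated reads the assigned
  `v_errors` equals the planted mutation count for the overwhelming
  majority of reads, and never undercounts. Exact equality for *every*
  read is not attainable under this scoring: with mismatches at score 0,
  the optimal alignment occasionally (~1–2% of reads at IgM/IgG-like
  mutation loads) gains score by gap-skipping a mutated V-end position
  and re-matching the trailing germline bases against coincidentally
  matching junction bases, which adds error columns; and a heavily
  mutated read can genuinely score best against a sibling allele.
  Medians per gene — the quantities the audit reports — are unaffected.

The per-gene SHM comparison follows the read-tracing design:
`trace_reads` joins assignment tables from the same library on read
identifiers (reads missing from a run are reported, never dropped), and
`per_gene_median_table` bins reads by their call under the anchor run
(the individualized genotype) and reports the median `v_errors` under
each database per bin. Medians of even-sized bins use the *lower*
median, keeping integer counts integer and runs reproducible.
`leave_one_out` packages the single-gene dropout experiment: assign with
and without one gene, report how many reads are affected, where they go,
and both medians.

## Genotyping and haplotyping

`infer_genotype` is a deliberately simplified, fully specified
individualized-genotype step: an allele is called when the identical
germline-region sequence is observed in ≥ 5 reads spanning ≥ 3 distinct
junctions. IgM reads are near-germline, so each expressed allele leaves
a large group of exact observations while mutated reads scatter into
singletons; junction diversity separates independent recombination
events from clonal expansions. Candidates matching the starting database
keep their names; novel candidates are named `<gene>*S<number>`. An
allele observed *only* through mutated reads is not called — a
documented limitation of the exact-consensus rule.

`haplotype_by_j_anchor` exploits a heterozygous J gene: the V and J of
one read come from one chromosome, so the two J alleles partition the
near-germline reads (`v_errors ≤ 1`, tolerating one sequencing error
without cross-allele bleed) by haplotype. A V allele is exclusive to an
anchor when ≥ 90% of its reads carry it (`purity`); genes are then
called heterozygous (distinct alleles on opposite anchors), homozygous
(one allele on both), hemizygous (all alleles on one anchor), absent
(fewer than `min_count = 10` reads), or ambiguous for patterns outside
the model (e.g. same-anchor duplications).

## Assembly search

`exact_search` locates exact occurrences of every allele, forward and
reverse-complement, with 0-based half-open coordinates on the forward
strand. `approximate_search` is a seed-and-extend scan: exact 20-mer
seeds nominate candidate windows, each window is aligned to the query
with free end gaps on the window side, and the distance is the sum of
unaligned query residues plus differing aligned residues with gaps
counted — so an allele truncated at a contig edge pays for its
unaligned overhang. Hits above 5 nt are discarded as spurious;
overlapping hits of one allele merge keeping the smaller distance (the
audit reports gene *presence*, not copy number). With a 5-nt ceiling on
~300-nt queries any true hit necessarily contains an exact 20-mer
(5 edits cut a 300-mer into at least one clean ≥ 50-nt stretch), so
seeding costs no sensitivity at this filter. `presence_matrix` reduces
hits to a gene × assembly Boolean table with an any-assembly union.

## The synthetic generator

The generator emulates the statistical structure that the audit's
arguments rest on, not rhesus sequence composition:

* **Locus.** Five families by default; family ancestors are i.i.d.
  uniform sequences (296 nt); each gene plants ~half its family's
  between-gene target (defaults 42, 21, 49, 21, 14 nt) on the ancestor,
  so gene pairs differ by roughly the target. Allele `*01` is the gene's
  ancestral base; further alleles radiate from it with
  2 + Poisson(within/2 − 1) substitutions capped at the within-gene
  target (5 nt). The cap and the hub topology make the 5-nt grouping
  criterion well posed — every allele stays within the allelic-distance
  criterion of its `*01` — while allele pairs still differ by ~5 nt.
  Realized medians are validated (within ± 2 nt, between ± 5 nt per
  family) and the locus is resampled (up to 10 times) on violation. The
  J locus carries ≥ 2 genes, the last heterozygous with two alleles 2 nt
  apart — the anchor.
* **Genotype.** Per haplotype, each gene is deleted independently with
  probability 0.1 (the hemizygosity rate 2p(1−p) ≈ 0.18 matches the
  common-structural-variant picture); one uniformly chosen allele per
  retained gene; anchor-J alleles differ between haplotypes.
* **Repertoire.** Per read: haplotype by fair coin; V gene uniform over
  that haplotype; J is the haplotype's anchor allele (or, at rate 0.25,
  a non-anchor J gene); junction of i.i.d. random bases, length
  ~ Normal(30, 10) truncated at 0; Poisson(shm_mean) substitutions at
  distinct uniform V positions (IgM-like ≈ 1, IgG-like ≈ 20). Reads are
  full V + junction + J, untruncated; truth records carry the source
  haplotype, alleles, mutation count and positions.

Substitution-only SHM and uniform placement are deliberate: they keep
the planted-mutation audit sharp and reflect that the audit's arguments
depend only on mutation *counts*, not motifs. What passing tests on this
generator do **not** show: robustness to indel SHM, hotspot clustering,
sequencing error, primer/barcode artefacts, or real rhesus gene-usage
skew. The generator also makes no attempt at RSS sites or genomic gene
order.

## Numerical and design choices

* Match/mismatch weights are 1/0; only gap and end-gap costs deviate
  from that baseline. Integer scoring in tenths avoids floating-point
  ties.
* The 5-nt presence/grouping threshold is one global constant, used for
  database gene content, assembly presence and allele grouping alike.
* Lower median for even bins; integer outputs stay integer.
* Degenerate inputs: empty databases and empty subsets error; empty
  libraries return empty tables; a gene removed that no read uses gives
  an `n_affected` of 0 and `NA` medians.
* Desk-scale problem sizes used throughout the validation suite: 500
  oracle pairs, 20 clustering seeds, 5,000-read dropout libraries at
  three planted nearest-gene distances, 1,000 reads × 100 database
  subsets, 10 genotype-recovery animals at 200 reads/allele, 20
  haplotype animals, and one synthetic assembly per presence check.
  These sizes give binomial error well inside the asserted tolerances.
* Seeds: every simulator takes an explicit seed and restores the
  caller's RNG state; identical seeds give identical outputs.

## Limitations

* The assigner is a stand-in for IgBLAST/IgDiscover: deterministic,
  full-scan, and sufficient for best-match identity and error counts; it
  applies none of IgDiscover's internal quality filters beyond the
  length and coverage guards.
* Genotype inference requires exact repeated observations; rare alleles
  expressed only through mutated reads are missed.
* Haplotyping supports one heterozygous J anchor; multi-anchor (D-based)
  haplotyping and chromosomal gene ordering are out of scope.
* `exact_overlap` counts each allele of the first database at most once;
  with substring matches the shared count need not be symmetric between
  directions (it is symmetric for equality-only overlaps).
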