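test_that("low-identity and ambiguous blocks contribute no calls", {
  set.seed(40)
  a <- rand_seq(500)
  b <- mutate_positions(a, sample(500, 20))   # identity ~0.96 < 0.97
  bl <- align_genomes(dss(b, nm = "q"), dss(a, nm = "r"), min_anchor = 20)
  expect_lt(bl$identity[1], 0.97)
  calls <- call_variants(bl, dss(b, nm = "q"), dss(a, nm = "r"))
  expect_equal(nrow(calls), 0L)

  bl$ambiguous <- NA
  expect_error(call_variants(bl, dss(b, nm = "q"), dss(a, nm = "r")),
               "flag_ambiguity")
})

test_that("gap runs become single indel calls of the right length", {
  set.seed(41)
  a <- rand_seq(600)
  b <- paste0(substr(a, 1, 300), substr(a, 304, 600))  # 3 bp deletion
  bl <- align_genomes(dss(b, nm = "q"), dss(a, nm = "r"), min_anchor = 20)
  calls <- call_variants(bl, dss(b, nm = "q"), dss(a, nm = "r"))
  dels <- calls[calls$kind == "deletion", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$length, 3L)

  # a 120 bp deletion is excluded from small calls and logged as structural
  b2 <- paste0(substr(a, 1, 200), substr(a, 321, 600))
  bl2 <- align_genomes(dss(b2, nm = "q"), dss(a, nm = "r"), min_anchor = 20)
  calls2 <- call_variants(bl2, dss(b2, nm = "q"), dss(a, nm = "r"))
  expect_true(all(calls2$length <= 90))
  st <- attr(calls2, "structural")
  expect_equal(st$kind, "deletion")
  expect_equal(st$length, 120L)
})

test_that("indels are left-aligned within repeat context", {
  # deleting one "AC" from an AC-array is reported at the array start
  a <- paste0("GGTTT", strrep("AC", 6), "TTTGG")
  b <- paste0("GGTTT", strrep("AC", 5), "TTTGG")
  ctx <- paste0(rand_seq(200), a, rand_seq(200))
  qry <- paste0(substr(ctx, 1, 200), b, substr(ctx, 206 + nchar(a) - 5, nchar(ctx)))
  # direct normalization check
  norm <- normalize_indel(ctx, 200 + 5 + 8, "deletion", "AC")
  expect_equal(norm$pos, 205L)
  expect_identical(norm$seq, "AC")
})

test_that("tandem repeat detection matches direct expectations and an exhaustive oracle", {
  set.seed(42)
  bg1 <- rand_seq(50); bg2 <- rand_seq(50)
  s <- paste0(bg1, "ACGACGACG", bg2)
  tr <- detect_tandem_repeats(dss(s, nm = "c"), max_unit = 10)
  hit <- tr[tr$unit == 3 & tr$start <= 50 & tr$end >= 59, ]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$copies >= 3))

  s2 <- paste0("GTCGTC", strrep("A", 12), "CTGCTG")
  tr2 <- detect_tandem_repeats(dss(s2, nm = "c"), max_unit = 10)
  homo <- tr2[tr2$unit == 1, ]
  expect_true(any(homo$copies >= 12))

  # exhaustive oracle on a short random string: every reported locus is a
  # perfect array, and every maximal (start, unit) array >= 2 copies is
  # covered by some report
  x <- rand_seq(120)
  got <- detect_tandem_repeats(dss(x, nm = "c"), max_unit = 8)
  for (i in seq_len(nrow(got))) {
    span <- substr(x, got$start[i] + 1, got$end[i])
    u <- got$unit[i]
    unit <- substr(span, 1, u)
    full <- strrep(unit, ceiling(nchar(span) / u))
    expect_identical(span, substr(full, 1, nchar(span)))
  }
  xv <- strsplit(x, "")[[1]]
  for (u in 1:8) for (st in 0:(120 - 2 * u)) {
    if (all(xv[(st + 1):(st + u)] == xv[(st + u + 1):(st + 2 * u)])) {
      covered <- any(got$start <= st & got$end >= st + 2 * u)
      expect_true(covered)
    }
  }
})

test_that("planted simulator arrays are all recovered", {
  sim <- small_sim()
  tr <- detect_tandem_repeats(sim$ref$seqs)
  planted <- sim$ref$tandem_repeats
  for (i in seq_len(nrow(planted))) {
    hit <- tr[tr$seqid == planted$seqid[i] & tr$start <= planted$start[i] &
                tr$end >= planted$end[i] & tr$unit == planted$unit[i], ]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("gene-effect annotation follows the codon rules", {
  # gene: ATG | GGT | TAC | TAA on the forward strand at offset 10
  cds <- "ATGGGTTACTAA"
  chrom <- paste0("GGGGGCCCCC", cds, "GGGGGCCCCC")
  ref <- dss(chrom, nm = "chr")
  genes <- data.frame(gene_id = "G1", seqid = "chr", start = 10L, end = 22L,
                      strand = "+", stringsAsFactors = FALSE)
  mk_call <- function(pos, refb, altb) data.frame(
    seqid = "chr", pos = pos, kind = "snv", ref = refb, alt = altb,
    length = 1L, seq = NA_character_, block_id = "b1",
    in_tandem_repeat = NA, stringsAsFactors = FALSE)
  # GGT -> GGC at codon 2: synonymous -> sense
  ann <- annotate_variants(mk_call(15L, "T", "C"), genes, NULL, ref)
  expect_identical(ann$effect, "sense")
  # GGT -> GAT: missense
  ann2 <- annotate_variants(mk_call(14L, "G", "A"), genes, NULL, ref)
  expect_identical(ann2$effect, "missense")
  # TAC -> TAA: internal stop gained -> start/stop usage altered
  ann3 <- annotate_variants(mk_call(18L, "C", "A"), genes, NULL, ref)
  expect_identical(ann3$effect, "start_stop_altered")
  # ATG disrupted
  ann4 <- annotate_variants(mk_call(10L, "A", "G"), genes, NULL, ref)
  expect_identical(ann4$effect, "start_stop_altered")
  # intergenic SNV
  ann5 <- annotate_variants(mk_call(2L, "G", "A"), genes, NULL, ref)
  expect_identical(ann5$effect, "intergenic")

  # in-CDS deletion of length 3 away from first/last codon: in-frame
  del3 <- data.frame(seqid = "chr", pos = 13L, kind = "deletion",
                     ref = NA, alt = NA, length = 3L, seq = "GGT",
                     block_id = "b1", in_tandem_repeat = NA,
                     stringsAsFactors = FALSE)
  ann6 <- annotate_variants(del3, genes, NULL, ref)
  expect_identical(ann6$effect, "inframe_indel")
  expect_true(ann6$frame_preserved)
  # length 2: frameshift
  del2 <- del3; del2$length <- 2L; del2$seq <- "GG"
  ann7 <- annotate_variants(del2, genes, NULL, ref)
  expect_identical(ann7$effect, "frameshift")
  expect_false(ann7$frame_preserved)
})

test_that("minus-strand genes are annotated on the coding strand", {
  cds <- "ATGGGTTACTAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  chrom <- paste0("GGGGGCCCCC", rc, "GGGGGCCCCC")
  ref <- dss(chrom, nm = "chr")
  genes <- data.frame(gene_id = "G1", seqid = "chr", start = 10L, end = 22L,
                      strand = "-", stringsAsFactors = FALSE)
  # genomic ACC (offsets 16..18) is codon GGT; A->G at offset 18 makes GGC: sense
  call <- data.frame(seqid = "chr", pos = 16L, kind = "snv",
                     ref = substr(chrom, 17, 17),
                     alt = "G", length = 1L, seq = NA_character_,
                     block_id = "b1", in_tandem_repeat = NA,
                     stringsAsFactors = FALSE)
  ann <- annotate_variants(call, genes, NULL, ref)
  expect_identical(ann$effect, "sense")
})

test_that("calls overlapping tandem arrays are flagged", {
  chrom <- paste0(rand_seq(100), strrep("ACG", 10), rand_seq(100))
  ref <- dss(chrom, nm = "chr")
  reps <- detect_tandem_repeats(ref, max_unit = 10)
  call <- data.frame(seqid = "chr", pos = 110L, kind = "snv", ref = "A",
                     alt = "T", length = 1L, seq = NA_character_,
                     block_id = "b1", in_tandem_repeat = NA,
                     stringsAsFactors = FALSE)
  ann <- annotate_variants(call, data.frame(gene_id = character(0),
                                            seqid = character(0),
                                            start = integer(0), end = integer(0),
                                            strand = character(0)),
                           reps, ref)
  expect_true(ann$in_tandem_repeat)
})

test_that("genes with incomplete codons are skipped with a warning", {
  chrom <- paste0("AAAAA", "ATGGGTTACTAA", "AAAAA")
  ref <- dss(chrom, nm = "chr")
  genes <- data.frame(gene_id = "BAD", seqid = "chr", start = 5L, end = 15L,
                      strand = "+", stringsAsFactors = FALSE)  # length 10
  call <- data.frame(seqid = "chr", pos = 8L, kind = "snv", ref = "G",
                     alt = "A", length = 1L, seq = NA_character_,
                     block_id = "b1", in_tandem_repeat = NA,
                     stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_variants(call, genes, NULL, ref),
                 "not divisible by 3")
  expect_true(is.na(ann$effect))
})

test_that("applying called variants locally reconstructs the query", {
  set.seed(44)
  a <- rand_seq(2000)
  b <- mutate_positions(a, sample(2000, 8))
  b <- paste0(substr(b, 1, 700), "TTACG", substr(b, 701, nchar(b)))  # insertion
  b <- paste0(substr(b, 1, 1200), substr(b, 1205, nchar(b)))          # deletion
  bl <- align_genomes(dss(b, nm = "q"), dss(a, nm = "r"), min_anchor = 20)
  expect_equal(nrow(bl), 1L)
  calls <- call_variants(bl, dss(b, nm = "q"), dss(a, nm = "r"))
  # rebuild the query from the reference and the calls (right to left)
  calls <- calls[order(-calls$pos), ]
  rec <- a
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    if (v$kind == "snv") {
      substr(rec, v$pos + 1, v$pos + 1) <- v$alt
    } else if (v$kind == "deletion") {
      rec <- paste0(substr(rec, 1, v$pos), substr(rec, v$pos + v$length + 1, nchar(rec)))
    } else {
      rec <- paste0(substr(rec, 1, v$pos), v$seq, substr(rec, v$pos + 1, nchar(rec)))
    }
  }
  expect_identical(rec, b)
})
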