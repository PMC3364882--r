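test_that("MEM finding matches direct expectations", {
  set.seed(11)
  s <- rand_seq(500)
  m <- find_mems(dss(s, nm = "q"), dss(s, nm = "r"), min_length = 20,
                 both_strands = FALSE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$q_start, 0L)
  expect_equal(m$r_end, 500L)

  a <- rand_seq(200); b <- rand_seq(200)   # no shared 20-mer, w.h.p.
  m2 <- find_mems(dss(a, nm = "q"), dss(b, nm = "r"), min_length = 20)
  expect_equal(nrow(m2), 0L)

  expect_error(find_mems(dss(a, nm = "q"), dss(b, nm = "r"), min_length = 5),
               ">= 10")
})

test_that("MEM sets equal the brute-force oracle, both strands", {
  set.seed(12)
  for (rep in 1:15) {
    n <- sample(120:250, 1)
    anc <- rand_seq(n)
    b <- mutate_positions(anc, sample(n, round(0.04 * n)))
    m <- find_mems(dss(anc, nm = "q"), dss(b, nm = "r"), min_length = 12,
                   both_strands = TRUE)
    fwd <- m[m$strand == "+", ]
    oracle <- mems_bruteforce(anc, b, 12)
    expect_equal(fwd$q_start, oracle$q_start)
    expect_equal(fwd$r_start, oracle$r_start)
    expect_equal(fwd$length, oracle$length)
    # reverse strand against the oracle run on the reverse complement
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(anc)))
    orc <- mems_bruteforce(rc, b, 12)
    rev <- m[m$strand == "-", ]
    expect_equal(nrow(rev), nrow(orc))
  }
})

test_that("N bases never match, even against N", {
  a <- paste0(strrep("A", 30), "NNNN", strrep("C", 30))
  m <- find_mems(dss(a, nm = "q"), dss(a, nm = "r"), min_length = 10,
                 both_strands = FALSE)
  # the trivial self-match is split by the N run: no match crosses it
  expect_true(all(m$q_end <= 30 | m$q_start >= 34))
})

test_that("chaining produces the documented example blocks", {
  set.seed(13)
  s <- rand_seq(300)
  # one full-length anchor -> one block, identity 1, all-match path
  bl <- align_genomes(dss(s, nm = "q"), dss(s, nm = "r"), min_anchor = 20,
                      both_strands = FALSE)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$identity, 1.0)
  expect_identical(bl$cigar, "300=")

  # two 100bp anchors separated by 2 substitutions -> identity 202/204
  a <- rand_seq(204)
  b <- a
  substr(b, 101, 101) <- if (substr(a, 101, 101) == "A") "C" else "A"
  substr(b, 103, 103) <- if (substr(a, 103, 103) == "G") "T" else "G"
  bl2 <- align_genomes(dss(a, nm = "q"), dss(b, nm = "r"), min_anchor = 20,
                       both_strands = FALSE)
  expect_equal(nrow(bl2), 1L)
  expect_equal(bl2$identity, 202 / 204, tolerance = 1e-12)
  expect_equal(bl2$matches, 202L)
  # edit path agrees with an independent edit-distance computation
  runs <- straincomp:::cigar_runs(bl2$cigar)
  expect_equal(sum(runs$len[runs$op != "="]), as.integer(adist(a, b)))
})

test_that("anchors on opposite strands give separate blocks", {
  set.seed(14)
  left <- rand_seq(200)
  right <- rand_seq(200)
  rc_right <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(right)))
  q <- paste0(left, rc_right)
  r <- paste0(left, right)
  bl <- align_genomes(dss(q, nm = "q"), dss(r, nm = "r"), min_anchor = 50)
  expect_setequal(unique(bl$strand), c("+", "-"))
  expect_true(all(bl$q_end - bl$q_start <= 210))
})

test_that("block edit paths consume exactly their intervals and identity is recomputable", {
  sim <- small_sim()
  bl <- sim$blocks
  for (i in seq_len(nrow(bl))) {
    cons <- straincomp:::cigar_consumed(bl$cigar[i])
    expect_equal(cons$query, bl$q_end[i] - bl$q_start[i])
    expect_equal(cons$ref, bl$r_end[i] - bl$r_start[i])
    expect_equal(straincomp:::cigar_identity(bl$cigar[i]), bl$identity[i])
  }
})

test_that("pairwise alignment achieves optimal edit distance", {
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(100:300, 1)
    a <- rand_seq(n)
    b <- mutate_positions(a, sample(n, round(0.03 * n)))
    # add an indel
    p <- sample(40:(n - 45), 1)
    b <- paste0(substr(b, 1, p), substr(b, p + 4, nchar(b)))
    al <- align_pair(a, b)
    expect_equal(al$distance, as.integer(adist(a, b)))
  }
})

test_that("ambiguity is a query-side definition", {
  set.seed(16)
  seg <- rand_seq(800)
  # reference-side duplication: one query segment aligns to two reference
  # copies -> both blocks cover the same query interval -> ambiguous
  r <- paste0(rand_seq(400), seg, rand_seq(400), seg, rand_seq(400))
  q <- seg
  bl <- flag_ambiguity(align_genomes(dss(q, nm = "q"), dss(r, nm = "r"),
                                     min_anchor = 100))
  expect_gte(nrow(bl), 2L)
  expect_true(all(bl$ambiguous[bl$q_end - bl$q_start > 700]))

  # single block genome-wide -> not ambiguous
  bl1 <- align_genomes(dss(seg, nm = "q"), dss(seg, nm = "r"), min_anchor = 100)
  expect_false(any(bl1$ambiguous))

  # two blocks overlapping on the reference but not on the query -> not
  # ambiguous (query-side duplication)
  q2 <- paste0(rand_seq(300), seg, rand_seq(300), seg, rand_seq(300))
  bl2 <- flag_ambiguity(align_genomes(dss(q2, nm = "q"), dss(seg, nm = "r"),
                                      min_anchor = 100, max_join_gap = 100))
  big <- bl2[bl2$q_end - bl2$q_start > 700, ]
  expect_gte(nrow(big), 2L)
  expect_false(any(big$ambiguous))
})

test_that("self-alignment repeat detection brackets the identity threshold", {
  set.seed(17)
  seg <- rand_seq(1000)
  genome <- dss(paste0(rand_seq(2000), seg, rand_seq(2000), seg, rand_seq(2000)),
                nm = "chr")
  rr <- self_repeats(genome, min_length = 500)
  expect_gte(nrow(rr), 2L)  # both copies reported (symmetric output)
  starts <- sort(unique(rr$start))
  expect_true(any(abs(starts - 2000) <= 20) && any(abs(starts - 5000) <= 20))
  # symmetry: every (region, partner) has its mirror
  key <- paste(rr$seqid, rr$start, rr$end, rr$partner_start, rr$partner_end)
  mirror <- paste(rr$partner_seqid, rr$partner_start, rr$partner_end,
                  rr$start, rr$end)
  expect_true(all(mirror %in% key))

  # repeat-free genome -> empty
  expect_equal(nrow(self_repeats(dss(rand_seq(5000), nm = "c"), min_length = 500)), 0L)

  # a copy mutated to ~93% identity is not reported; at ~96.5% it is
  seg2 <- mutate_positions(seg, sample(1000, 70))
  g93 <- dss(paste0(rand_seq(2000), seg, rand_seq(2000), seg2, rand_seq(2000)), nm = "chr")
  expect_equal(nrow(self_repeats(g93, min_length = 500)), 0L)
  seg3 <- mutate_positions(seg, sample(1000, 35))
  g96 <- dss(paste0(rand_seq(2000), seg, rand_seq(2000), seg3, rand_seq(2000)), nm = "chr")
  expect_gte(nrow(self_repeats(g96, min_length = 500)), 2L)
})
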