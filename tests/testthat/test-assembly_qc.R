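test_that("contig tiling picks the best placement with a deterministic tie rule", {
  set.seed(50)
  chrom <- rand_seq(3000)
  bl <- align_genomes(dss(chrom, nm = "c1"), dss(chrom, nm = "chr"),
                      min_anchor = 50)
  pl <- tile_contigs(bl)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$r_start, 0L)
  expect_equal(pl$r_end, 3000L)

  # a contig matching two identical loci equally well takes the lower
  # reference coordinate
  seg <- rand_seq(900)
  r <- paste0(rand_seq(500), seg, rand_seq(500), seg, rand_seq(500))
  bl2 <- align_genomes(dss(seg, nm = "c1"), dss(r, nm = "chr"),
                       min_anchor = 100, max_join_gap = 200)
  pl2 <- tile_contigs(bl2)
  expect_equal(pl2$r_start, 500L)

  # simulated truth: every placed contig lands on its true interval
  sim <- small_sim()
  pl3 <- tile_contigs(sim$blocks)
  truth <- sim$asm$placements
  m <- merge(pl3, truth, by = "contig_id")
  # block coordinates are on the reference; truth is on the query
  # chromosome; with one chromosome and few edits, starts agree closely
  expect_true(all(abs(m$r_start - m$q_start) < 3000))
  expect_equal(order(m$r_start), order(m$q_start))
  expect_true(all(diff(pl3$order) == 1))
})

test_that("gap classification separates missing sequence from unassembled repeats", {
  placements <- data.frame(contig_id = c("c1", "c2", "c3", "c4"),
                           seqid = "chr",
                           r_start = c(0L, 1000L, 3000L, 6000L),
                           r_end = c(1000L, 2000L, 5000L, 7000L),
                           strand = "+", score = 1, order = 1:4,
                           stringsAsFactors = FALSE)
  # gap 1: 2000-3000 with a zero-coverage window; gap 2: 5000-6000 over a repeat
  depth <- data.frame(seqid = "chr",
                      start = seq(0L, 6900L, by = 100L),
                      end = seq(100L, 7000L, by = 100L))
  depth$count <- 50
  depth$count[depth$start >= 2300 & depth$end <= 2700] <- 0
  repeats <- data.frame(seqid = "chr", start = 5200L, end = 5900L,
                        partner_seqid = "chr", partner_start = 100L,
                        partner_end = 800L, strand = "+", identity = 0.99)
  gaps <- classify_gaps(placements, depth, repeats)
  expect_equal(nrow(gaps), 2L)   # adjacent placements (0-1000, 1000-2000) gap-free
  expect_identical(gaps$label[gaps$start == 2000], "missing_sequence")
  expect_identical(gaps$label[gaps$start == 5000], "unassembled")
  tally <- attr(gaps, "tally")
  expect_equal(tally$n[tally$label == "missing_sequence"], 1L)
  expect_equal(tally$n[tally$label == "unassembled"], 1L)

  # both criteria -> "both"; neither -> "unexplained"
  repeats2 <- rbind(repeats, data.frame(seqid = "chr", start = 2400L, end = 2600L,
                                        partner_seqid = "chr", partner_start = 100L,
                                        partner_end = 300L, strand = "+",
                                        identity = 0.99))
  gaps2 <- classify_gaps(placements, depth, repeats2)
  expect_identical(gaps2$label[gaps2$start == 2000], "both")
  depth3 <- depth; depth3$count <- 50
  gaps3 <- classify_gaps(placements, depth3, repeats[0, ])
  expect_true(all(gaps3$label == "unexplained"))
})

test_that("transposon loci classify as GA, CB or AS on constructed alignments", {
  set.seed(51)
  ltr <- rand_seq(300)
  body <- rand_seq(5400)
  elem <- paste0(ltr, body, ltr)
  flankL <- rand_seq(4000); flankR <- rand_seq(4000)
  r <- paste0(flankL, elem, flankR)
  loci <- data.frame(locus_id = "Ty1-1", family = "Ty1", seqid = "chr",
                     start = 4000L, end = 10000L, stringsAsFactors = FALSE)

  # AS: the element is present and crossed by one gapless contig
  q_as <- r
  bl <- align_genomes(dss(q_as, nm = "c1"), dss(r, nm = "chr"), min_anchor = 100)
  pl <- tile_contigs(bl)
  expect_identical(classify_transposons(loci, pl, bl)$label, "present_assembled")

  # GA: excision left a solo LTR; one contig spans with a ~5.7 kb gap
  q_ga <- paste0(flankL, ltr, flankR)
  bl2 <- align_genomes(dss(q_ga, nm = "c1"), dss(r, nm = "chr"), min_anchor = 100)
  pl2 <- tile_contigs(bl2)
  ty2 <- classify_transposons(loci, pl2, bl2)
  expect_identical(ty2$label, "absent_gapped")
  expect_true(abs(ty2$gap_size - 5700) <= 1200)

  # CB: the element is present but its interior was not assembled; two
  # contigs end on the flanks
  bl3 <- align_genomes(dss(c(c1 = flankL, c2 = flankR)), dss(r, nm = "chr"),
                       min_anchor = 100)
  pl3 <- tile_contigs(bl3)
  expect_identical(classify_transposons(loci, pl3, bl3)$label, "present_break")

  # precedence: an assembled locus stays AS even though flanking contigs
  # also exist
  bl4 <- rbind(bl, bl3)
  bl4$block_id <- sprintf("b%05d", seq_len(nrow(bl4)))
  pl4 <- tile_contigs(bl4)
  expect_identical(classify_transposons(loci, pl4, bl4)$label, "present_assembled")

  # a locus matching no pattern is conservatively present_break, with warning
  far <- align_genomes(dss(rand_seq(2000), nm = "c9"), dss(r, nm = "chr"),
                       min_anchor = 100)
  pl5 <- data.frame(contig_id = "c9", seqid = "chr", r_start = 0L, r_end = 100L,
                    strand = "+", score = 1, order = 1L)
  expect_warning(ty5 <- classify_transposons(loci, pl5, bl[0, ]), "no pattern")
  expect_identical(ty5$label, "present_break")
})

test_that("family copy estimates recover the depth ratio", {
  loci <- data.frame(locus_id = paste0("Ty1-", 1:4), family = "Ty1",
                     seqid = "chr", start = seq(0L, 30000L, by = 10000L),
                     end = seq(6000L, 36000L, by = 10000L),
                     stringsAsFactors = FALSE)
  win <- data.frame(seqid = "chr", start = seq(0L, 39900L, by = 100L),
                    end = seq(100L, 40000L, by = 100L))
  ref_track <- win; ref_track$count <- 100
  # equal depths -> estimate equals the reference count
  est <- ty_family_copy_estimate(loci, ref_track, ref_track)
  expect_equal(est$per_family$estimate, 4L)
  expect_true(all(abs(est$per_element$log2_ratio) < 1e-12))

  # half the elements excised (zero test depth) -> estimate half
  test_track <- ref_track
  drop <- test_track$start < 6000 | (test_track$start >= 10000 & test_track$start < 16000)
  test_track$count[drop] <- 0
  est2 <- ty_family_copy_estimate(loci, test_track, ref_track)
  # library scaling inflates the retained ratios; allow +-1 copy
  expect_lte(abs(est2$per_family$estimate - 2L), 1L)

  # doubling the test library leaves the estimate unchanged (scaling)
  test3 <- ref_track; test3$count <- 200
  est3 <- ty_family_copy_estimate(loci, test3, ref_track)
  expect_equal(est3$per_family$estimate, 4L)

  # zero reference depth -> element skipped with a warning
  ref0 <- ref_track; ref0$count[ref0$start < 6000] <- 0
  expect_warning(est4 <- ty_family_copy_estimate(loci, ref_track, ref0),
                 "skipped")
  expect_equal(nrow(est4$per_element), 3L)
})

test_that("placements and gaps partition the spanned reference", {
  sim <- small_sim()
  pl <- tile_contigs(sim$blocks)
  depth <- data.frame(seqid = "chrI", start = 0L,
                      end = sum(Biostrings::width(sim$ref$seqs)), count = 50)
  gaps <- classify_gaps(pl, depth,
                        data.frame(seqid = character(0), start = integer(0),
                                   end = integer(0)))
  span <- IRanges::IRanges(min(pl$r_start) + 1L, max(pl$r_end))
  covered <- IRanges::reduce(c(
    IRanges::IRanges(pl$r_start + 1L, pl$r_end),
    if (nrow(gaps)) IRanges::IRanges(gaps$start + 1L, gaps$end) else IRanges::IRanges()))
  expect_equal(sum(IRanges::width(IRanges::setdiff(span, covered))), 0L)
})
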