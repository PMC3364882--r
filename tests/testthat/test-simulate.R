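tiny_plan <- function(...) {
  defaults <- list(seed = 5, n_chromosomes = 1, chromosome_length = 40000,
                   n_genes = 10, n_transposons = c(Ty1 = 1),
                   n_tandem_repeat_loci = 4, n_snvs = 50, indel_count = 10,
                   delete_genes = 0, large_deletion_specs = list(),
                   duplication_specs = list(), excised_transposon_count = 0,
                   unique_insertion_specs = integer(0), dropout_specs = list())
  do.call(simulation_plan, utils::modifyList(defaults, list(...)))
}

test_that("reference generation is deterministic and honours feature counts", {
  plan <- tiny_plan()
  r1 <- generate_reference(plan)
  r2 <- generate_reference(plan)
  expect_identical(as.character(r1$seqs), as.character(r2$seqs))
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$transposons, r2$transposons)

  # zero transposons -> empty annotation
  r0 <- generate_reference(tiny_plan(n_transposons = c(Ty1 = 0)))
  expect_equal(nrow(r0$transposons), 0L)

  # ten elements -> exactly ten records of the configured length
  r10 <- generate_reference(simulation_plan(
    seed = 6, n_chromosomes = 2, chromosome_length = 200000, n_genes = 10,
    n_transposons = c(Ty1 = 6, Ty2 = 4), n_tandem_repeat_loci = 0,
    transposon_length = 6000))
  expect_equal(nrow(r10$transposons), 10L)
  expect_true(all(r10$transposons$end - r10$transposons$start == 6000L))

  # transposon copies are LTR-flanked: both termini identical within a family
  tp <- r10$transposons[1, ]
  chrom <- as.character(r10$seqs[[tp$seqid]])
  left <- substr(chrom, tp$start + 1, tp$start + 300)
  right <- substr(chrom, tp$end - 299, tp$end)
  expect_identical(left, right)
  expect_identical(left, unname(r10$ltr_seqs[tp$family]))

  # tandem loci are perfect arrays of the recorded unit
  tr <- generate_reference(plan)$tandem_repeats
  for (i in seq_len(nrow(tr))) {
    chrom <- as.character(generate_reference(plan)$seqs[[tr$seqid[i]]])
    arr <- substr(chrom, tr$start[i] + 1, tr$end[i])
    expect_identical(arr, strrep(tr$unit_seq[i], tr$copies[i]))
  }
})

test_that("an all-zero mutation plan returns the reference unchanged", {
  plan <- tiny_plan(n_snvs = 0, indel_count = 0)
  ref <- generate_reference(plan)
  mut <- mutate_genome(ref, plan)
  expect_identical(as.character(mut$seqs), as.character(ref$seqs))
  expect_equal(nrow(mut$truth$snvs), 0L)
  expect_equal(nrow(mut$truth$indels), 0L)
})

test_that("planted variant counts and coordinates are conserved", {
  plan <- tiny_plan(n_snvs = 100, indel_count = 15)
  ref <- generate_reference(plan)
  mut <- mutate_genome(ref, plan)
  tr <- mut$truth
  expect_equal(nrow(tr$snvs), 100L)
  expect_equal(nrow(tr$indels), 15L)
  # every SNV record matches the sequences it claims
  chrom_r <- as.character(ref$seqs[[1]])
  chrom_q <- as.character(mut$seqs[[1]])
  for (i in seq_len(nrow(tr$snvs))) {
    expect_identical(substr(chrom_r, tr$snvs$pos[i] + 1, tr$snvs$pos[i] + 1),
                     tr$snvs$ref[i])
    expect_identical(substr(chrom_q, tr$snvs$query_pos[i] + 1,
                            tr$snvs$query_pos[i] + 1), tr$snvs$alt[i])
  }
  # length bookkeeping reconciles reference and query exactly
  delta <- sum(tr$indels$length[tr$indels$kind == "insertion"]) -
    sum(tr$indels$length[tr$indels$kind == "deletion"])
  expect_equal(nchar(chrom_q), nchar(chrom_r) + delta)
})

test_that("transposon excision leaves exactly one solo terminal repeat", {
  plan <- tiny_plan(n_transposons = c(Ty1 = 2), excised_transposon_count = 1,
                    n_snvs = 0, indel_count = 0)
  ref <- generate_reference(plan)
  mut <- mutate_genome(ref, plan)
  exc <- mut$truth$transposons[mut$truth$transposons$state == "excised", ]
  expect_equal(nrow(exc), 1L)
  elem_len <- exc$end - exc$start
  # closed-form length bookkeeping: query loses element minus one LTR
  expect_equal(sum(Biostrings::width(mut$seqs)),
               sum(Biostrings::width(ref$seqs)) - (elem_len - plan$ltr_length))
  solo <- substr(as.character(mut$seqs[[exc$seqid]]), exc$query_start + 1,
                 exc$query_end)
  expect_identical(solo, unname(ref$ltr_seqs[exc$family]))
})

test_that("fragmentation policies behave and conserve sequence", {
  plan <- tiny_plan(n_transposons = c(Ty1 = 2), keep_assembled_count = 0,
                    contig_break_policy = "no-breaks")
  ref <- generate_reference(plan)
  mut <- mutate_genome(ref, plan)
  asm0 <- fragment_assembly(mut, plan)
  expect_equal(length(asm0$contigs), plan$n_chromosomes)

  plan2 <- tiny_plan(n_transposons = c(Ty1 = 2), keep_assembled_count = 0,
                     random_orientation = FALSE)
  ref2 <- generate_reference(plan2)
  mut2 <- mutate_genome(ref2, plan2)
  asm2 <- fragment_assembly(mut2, plan2)
  # break-and-drop: each retained locus breaks the genome around it
  expect_gte(length(asm2$contigs), 3L)
  # conservation: contigs + withheld = query genome length
  total <- sum(Biostrings::width(asm2$contigs)) +
    sum(asm2$withheld$end - asm2$withheld$start)
  expect_equal(total, sum(Biostrings::width(mut2$seqs)))
  # placements tile the query except withheld intervals
  for (i in seq_len(nrow(asm2$placements))) {
    p <- asm2$placements[i, ]
    seg <- substr(as.character(mut2$seqs[[p$seqid]]), p$q_start + 1, p$q_end)
    expect_identical(seg, as.character(asm2$contigs[[p$contig_id]]))
  }
})

test_that("depth simulation honours its Poisson contract", {
  set.seed(30)
  g <- dss(rand_seq(10000), nm = "chr")
  # flat bias, mean 50: sample mean within 3 standard errors
  d <- simulate_depth(g, 50, bias_strength = 0, seed = 9, window = 1)
  expect_lt(abs(mean(d$count) - 50), 3 * sqrt(50 / nrow(d)))
  # same seed -> identical counts; different seed -> different
  d2 <- simulate_depth(g, 50, bias_strength = 0, seed = 9, window = 1)
  expect_identical(d$count, d2$count)
  d3 <- simulate_depth(g, 50, bias_strength = 0, seed = 10, window = 1)
  expect_false(identical(d$count, d3$count))
  # deleted regions have zero counts in fully covered windows
  dd <- simulate_depth(g, 50, seed = 9, window = 100,
                       deleted = data.frame(seqid = "chr", start = 2000, end = 3000))
  expect_true(all(dd$count[dd$start >= 2000 & dd$end <= 3000] == 0))
  expect_error(simulate_depth(g, 0, seed = 1), "positive")
})

test_that("the whole simulator is a pure function of plan and seed", {
  plan <- tiny_plan(n_snvs = 30, indel_count = 5,
                    n_transposons = c(Ty1 = 1), excised_transposon_count = 1)
  run <- function() {
    ref <- generate_reference(plan)
    mut <- mutate_genome(ref, plan)
    asm <- fragment_assembly(mut, plan)
    list(r = as.character(ref$seqs), q = as.character(mut$seqs),
         c = as.character(asm$contigs), t = mut$truth$snvs)
  }
  expect_identical(run(), run())
})
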