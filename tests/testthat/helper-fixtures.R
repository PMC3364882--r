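# Shared fixtures and independent oracles used across the test files.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

dss <- function(..., nm = NULL) {
  x <- Biostrings::DNAStringSet(c(...))
  if (!is.null(nm)) names(x) <- nm
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("s", seq_along(x))
  x
}

# substitute n random positions (1-based, from `eligible`) with a different base
mutate_positions <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1)
  paste(v, collapse = "")
}

# brute-force MEM oracle: enumerate equal-run diagonals of the comparison
# matrix and keep maximal runs >= k (quadratic, independent of the k-mer
# index implementation)
mems_bruteforce <- function(a, b, k) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  out <- NULL
  for (d in -(length(av) - 1):(length(bv) - 1)) {
    i0 <- max(1, 1 - d); i1 <- min(length(av), length(bv) - d)
    if (i1 - i0 + 1 < k) next
    idx <- i0:i1
    eq <- av[idx] == bv[idx + d] & av[idx] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (h in which(r$values & r$lengths >= k)) {
      qs <- idx[starts[h]] - 1L
      out <- rbind(out, data.frame(q_start = qs, r_start = qs + d,
                                   length = r$lengths[h]))
    }
  }
  if (is.null(out)) return(data.frame(q_start = integer(0), r_start = integer(0),
                                      length = integer(0)))
  out[order(out$r_start, out$q_start), , drop = FALSE]
}

# a small simulated genome pair shared by several test files (built once)
.sim_cache <- new.env()
small_sim <- function() {
  if (!is.null(.sim_cache$sim)) return(.sim_cache$sim)
  plan <- simulation_plan(seed = 7, n_chromosomes = 1, chromosome_length = 60000,
                          n_genes = 20, n_transposons = c(Ty1 = 1),
                          n_tandem_repeat_loci = 5, n_snvs = 100,
                          indel_count = 20, delete_genes = 1,
                          large_deletion_specs = list(), duplication_specs = list(),
                          excised_transposon_count = 0,
                          unique_insertion_specs = c(2000),
                          dropout_specs = list(), keep_assembled_count = 1)
  ref <- generate_reference(plan)
  mut <- mutate_genome(ref, plan)
  asm <- fragment_assembly(mut, plan)
  blocks <- align_genomes(asm$contigs, ref$seqs)
  .sim_cache$sim <- list(plan = plan, ref = ref, mut = mut, asm = asm,
                         blocks = blocks)
  .sim_cache$sim
}

# map a contig-coordinate interval back to query-chromosome coordinates
contig_to_query <- function(placements, contig_id, start, end) {
  p <- placements[placements$contig_id == contig_id, ]
  if (p$orientation == "+") {
    c(p$q_start + start, p$q_start + end)
  } else {
    len <- p$q_end - p$q_start
    c(p$q_start + (len - end), p$q_start + (len - start))
  }
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- max(e1, e2) - min(s1, s2)
  inter / uni
}
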