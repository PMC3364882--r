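# Synthetic genome-pair simulator. Generates a multi-chromosome yeast-like
# reference (LTR-flanked retrotransposons in five families, perfect tandem
# repeat arrays, intronless gene models), derives a query genome with
# planted SNVs, small indels, gene/segment deletions, segmental
# duplications, transposon excisions (solo-LTR remnants) and novel unique
# insertions, fragments the query into contigs the way repeats fragment
# real assemblies, and simulates windowed read depth with a shared GC bias.
# Every planted event is recorded in a truth table so each pipeline stage
# can be scored against known ground truth.

#' Build a simulation plan
#'
#' The defaults describe the desk-scale study conditions used throughout
#' the package: a two-chromosome 500 kb genome carrying ~6 kb LTR
#' retrotransposons, an SNV rate of 0.2% (the density observed between
#' closely related laboratory strains), indels with mean length 3 bp capped
#' at 90 bp, and 50x-style Poisson read depth.
#'
#' @param seed integer seed; all stages derive their own sub-streams from it
#' @param n_chromosomes,chromosome_length genome shape
#' @param n_genes number of intronless gene models
#' @param n_transposons named counts per family (Ty1..Ty5)
#' @param transposon_length,ltr_length element and terminal-repeat sizes (bp)
#' @param n_tandem_repeat_loci number of perfect tandem arrays
#' @param tandem_unit_range,tandem_copies_range unit length (bp) and copy
#'   number ranges for tandem arrays
#' @param snv_rate per-bp substitution probability (sets `n_snvs` unless
#'   given explicitly)
#' @param n_snvs exact SNV count (overrides `snv_rate`)
#' @param indel_count,indel_mean_length,max_indel small-indel plan: count,
#'   geometric mean length, hard cap
#' @param frac_indel_in_repeat fraction of indels planted inside tandem
#'   arrays (as whole-unit expansions/contractions)
#' @param large_deletion_specs list of `list(length=, subtelomeric=)`
#' @param delete_genes number of whole genes to delete
#' @param duplication_specs list of `list(length=, copies=)` segmental
#'   duplications
#' @param excised_transposon_count transposon loci excised to a solo LTR
#' @param unique_insertion_specs lengths (bp) of novel unique insertions
#' @param dropout_specs list of `list(length=)`: regions present in both
#'   genomes but unsequenceable in the query strain (extreme nucleotide
#'   composition in real data) - their reads are absent and their sequence
#'   is withheld from contigs, producing zero-coverage assembly gaps
#' @param contig_break_policy "break-and-drop" (repeat interiors withheld),
#'   "break" (split at repeat edges, interior kept) or "no-breaks"
#' @param keep_assembled_count retained transposon loci left intact inside
#'   one contig (fully assembled loci)
#' @param random_break_rate extra per-bp contig break probability
#' @param drop_flank bp of flanking sequence withheld around dropped repeat
#'   interiors
#' @param min_contig_length contigs shorter than this are withheld
#' @param random_orientation emit contigs in random orientation
#' @param depth_mean expected reads per window under copy number 1
#' @param bias_strength strength of the GC depth bias shared by both strains
#' @param depth_window window size (bp) for simulated depth tracks
#' @param subtelomere_length chromosome-end span eligible for subtelomeric
#'   deletions
#' @return a list of class `sim_plan`
#' @export
simulation_plan <- function(seed = 1L,
                            n_chromosomes = 2L,
                            chromosome_length = 250000L,
                            n_genes = 200L,
                            n_transposons = c(Ty1 = 3L, Ty2 = 2L, Ty3 = 1L,
                                              Ty4 = 1L, Ty5 = 1L),
                            transposon_length = 6000L,
                            ltr_length = 300L,
                            n_tandem_repeat_loci = 30L,
                            tandem_unit_range = c(3L, 60L),
                            tandem_copies_range = c(5L, 40L),
                            snv_rate = 0.002,
                            n_snvs = NULL,
                            indel_count = 200L,
                            indel_mean_length = 3,
                            max_indel = 90L,
                            frac_indel_in_repeat = 0.4,
                            large_deletion_specs = list(list(length = 8000L,
                                                             subtelomeric = TRUE)),
                            delete_genes = 3L,
                            duplication_specs = list(list(length = 12000L,
                                                          copies = 1L)),
                            excised_transposon_count = 2L,
                            unique_insertion_specs = c(5000L),
                            dropout_specs = list(list(length = 2000L)),
                            contig_break_policy = "break-and-drop",
                            keep_assembled_count = 1L,
                            random_break_rate = 1e-5,
                            drop_flank = 0L,
                            min_contig_length = 1000L,
                            random_orientation = TRUE,
                            depth_mean = 50,
                            bias_strength = 0.6,
                            depth_window = 100L,
                            subtelomere_length = 25000L) {
  plan <- as.list(environment())
  stopifnot(plan$n_chromosomes >= 1, plan$chromosome_length > 0,
            all(plan$n_transposons >= 0), plan$transposon_length > 0,
            plan$ltr_length > 0, plan$snv_rate >= 0, plan$snv_rate <= 1,
            plan$indel_count >= 0, plan$max_indel >= 1,
            plan$frac_indel_in_repeat >= 0, plan$frac_indel_in_repeat <= 1,
            plan$contig_break_policy %in% c("break-and-drop", "break", "no-breaks"))
  if (is.null(names(plan$n_transposons)))
    names(plan$n_transposons) <- paste0("Ty", seq_along(plan$n_transposons))
  class(plan) <- "sim_plan"
  plan
}

# sample a placement start for a feature of length L on [lo, hi), at least
# `margin` away from intervals in `occ` (IRanges); NULL when impossible
sample_slot <- function(len, occ, L, margin = 150L, lo = 500L, hi = NULL,
                        tries = 2000L) {
  hi <- hi %||% (len - 500L)
  if (hi - L < lo) return(NULL)
  for (i in seq_len(tries)) {
    s <- sample.int(hi - L - lo + 1L, 1L) + lo - 1L
    cand <- IRanges::IRanges(s - margin + 1L, s + L + margin)
    if (length(occ) == 0 || !any(IRanges::overlapsAny(cand, occ))) return(s)
  }
  NULL
}

codon_pool <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Generate a synthetic annotated reference genome
#'
#' Transposon copies within a family are identical and flanked by the
#' family's terminal repeat; tandem loci are perfect k-mer arrays; genes are
#' intronless ATG..stop models placed clear of transposons. Deterministic
#' given the plan seed.
#'
#' @param plan a [simulation_plan()]
#' @return list of class `sim_reference`: `seqs` (DNAStringSet), `genes`,
#'   `transposons`, `tandem_repeats` (data.frames, 0-based half-open),
#'   `ltr_seqs`, `plan`
#' @export
generate_reference <- function(plan) {
  stopifnot(inherits(plan, "sim_plan"))
  with_subseed(plan$seed, 1L, {
    chroms <- paste0("chr", utils::as.roman(seq_len(plan$n_chromosomes)))
    seqs <- lapply(chroms, function(x) random_dna(plan$chromosome_length))
    names(seqs) <- chroms
    occ <- lapply(chroms, function(x) IRanges::IRanges())
    names(occ) <- chroms

    # family LTRs and bodies (identical within a family)
    fams <- names(plan$n_transposons)
    ltr_seqs <- setNames(vapply(fams, function(f) random_dna(plan$ltr_length),
                                character(1)), fams)
    body_len <- plan$transposon_length - 2L * plan$ltr_length
    stopifnot(body_len > 0)
    body_seqs <- setNames(vapply(fams, function(f) random_dna(body_len),
                                 character(1)), fams)

    place <- function(chrom, L, margin = 150L) {
      s <- sample_slot(plan$chromosome_length, occ[[chrom]], L, margin)
      if (is.null(s)) stop("placement error: feature of length ", L,
                           " does not fit on ", chrom)
      occ[[chrom]] <<- c(occ[[chrom]], IRanges::IRanges(s + 1L, s + L))
      s
    }

    transposons <- NULL
    k <- 0L
    for (f in fams) {
      nf <- plan$n_transposons[[f]]
      if (nf == 0) next
      elem <- paste0(ltr_seqs[f], body_seqs[f], ltr_seqs[f])
      for (i in seq_len(nf)) {
        k <- k + 1L
        chrom <- sample(chroms, 1L)
        s <- place(chrom, plan$transposon_length, margin = 300L)
        substr(seqs[[chrom]], s + 1L, s + plan$transposon_length) <- elem
        transposons <- rbind(transposons, data.frame(
          locus_id = sprintf("%s-%d", f, i), family = f, seqid = chrom,
          start = s, end = s + plan$transposon_length, stringsAsFactors = FALSE))
      }
    }
    transposons <- transposons %||% data.frame(
      locus_id = character(0), family = character(0), seqid = character(0),
      start = integer(0), end = integer(0), stringsAsFactors = FALSE)

    tandem <- NULL
    for (i in seq_len(plan$n_tandem_repeat_loci)) {
      for (try in seq_len(100L)) {
        unit_len <- sample(seq(plan$tandem_unit_range[1], plan$tandem_unit_range[2]), 1L)
        copies <- sample(seq(plan$tandem_copies_range[1], plan$tandem_copies_range[2]), 1L)
        unit <- random_dna(unit_len)
        # reject units that are themselves periodic, so the array's unit
        # length is unambiguous
        if (unit_len > 1) {
          prim <- vapply(seq_len(unit_len - 1), function(u) {
            all(substring(unit, 1:(unit_len - u), 1:(unit_len - u)) ==
                  substring(unit, (1 + u):unit_len, (1 + u):unit_len))
          }, logical(1))
          if (any(prim)) next
        }
        arr <- strrep(unit, copies)
        chrom <- sample(chroms, 1L)
        s <- place(chrom, nchar(arr))
        substr(seqs[[chrom]], s + 1L, s + nchar(arr)) <- arr
        tandem <- rbind(tandem, data.frame(
          seqid = chrom, start = s, end = s + nchar(arr), unit = unit_len,
          copies = copies, unit_seq = unit, stringsAsFactors = FALSE))
        break
      }
    }
    tandem <- tandem %||% data.frame(seqid = character(0), start = integer(0),
                                     end = integer(0), unit = integer(0),
                                     copies = numeric(0), unit_seq = character(0),
                                     stringsAsFactors = FALSE)

    pool <- codon_pool()
    genes <- NULL
    for (i in seq_len(plan$n_genes)) {
      n_codons <- sample(150:500, 1L)
      cds <- paste0("ATG", paste(sample(pool, n_codons - 2L, replace = TRUE),
                                 collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") cds else revcomp(cds)
      chrom <- sample(chroms, 1L)
      s <- place(chrom, nchar(ins), margin = 100L)
      substr(seqs[[chrom]], s + 1L, s + nchar(ins)) <- ins
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("GENE%04d", i), seqid = chrom, start = s,
        end = s + nchar(ins), strand = strand, stringsAsFactors = FALSE))
    }
    genes <- genes %||% data.frame(gene_id = character(0), seqid = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0), stringsAsFactors = FALSE)

    out <- list(seqs = Biostrings::DNAStringSet(unlist(seqs)),
                genes = genes, transposons = transposons,
                tandem_repeats = tandem, ltr_seqs = ltr_seqs, plan = plan)
    class(out) <- "sim_reference"
    out
  })
}

# cumulative ref->query offset mapping from an edit table (sorted,
# non-overlapping). Positions inside replaced intervals map to NA.
map_ref_to_query <- function(edits, pos) {
  if (nrow(edits) == 0) return(pos)
  edits <- edits[order(edits$start), , drop = FALSE]
  delta <- cumsum(nchar(edits$repl) - (edits$end - edits$start))
  before <- findInterval(pos, edits$end)         # edits fully left of pos
  d <- ifelse(before > 0, delta[pmax(before, 1L)], 0L)
  at <- findInterval(pos, edits$start)           # last edit starting <= pos
  inside <- at >= 1 & edits$start[pmax(at, 1L)] < pos & edits$end[pmax(at, 1L)] > pos
  out <- as.integer(pos + d)
  out[inside] <- NA_integer_
  out
}

apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  edits <- edits[order(edits$start, edits$end), , drop = FALSE]
  if (nrow(edits) > 1 &&
      any(edits$start[-1] < edits$end[-nrow(edits)])) {
    bad <- which(edits$start[-1] < edits$end[-nrow(edits)])[1]
    stop("plan conflict: overlapping edits at ", edits$start[bad + 1],
         " and [", edits$start[bad], ",", edits$end[bad], ")")
  }
  pieces <- character(0)
  cur <- 0L
  for (i in seq_len(nrow(edits))) {
    pieces <- c(pieces, substr(seq, cur + 1L, edits$start[i]), edits$repl[i])
    cur <- edits$end[i]
  }
  paste0(paste(pieces, collapse = ""), substr(seq, cur + 1L, nchar(seq)))
}

#' Derive a mutated query genome with a full truth table
#'
#' Plants, in order: transposon excisions (element replaced by one solo
#' LTR), whole-gene deletions, large (optionally subtelomeric) deletions,
#' segmental duplications, novel unique insertions, small indels (a
#' configurable fraction inside tandem arrays as whole-unit changes,
#' left-aligned), and SNVs. Edits never overlap; conflicts are an error.
#'
#' @param reference from [generate_reference()]
#' @param plan the simulation plan
#' @return list of class `sim_mutation`: `seqs` (query DNAStringSet),
#'   `truth` (class `sim_truth`)
#' @export
mutate_genome <- function(reference, plan = reference$plan) {
  stopifnot(inherits(reference, "sim_reference"))
  with_subseed(plan$seed, 2L, {
    chroms <- names(reference$seqs)
    seqlen <- setNames(Biostrings::width(reference$seqs), chroms)
    edits <- lapply(chroms, function(x)
      data.frame(start = integer(0), end = integer(0), repl = character(0),
                 stringsAsFactors = FALSE))
    names(edits) <- chroms
    # occupied = regions no later edit may touch (with margin)
    occ <- lapply(chroms, function(x) IRanges::IRanges())
    names(occ) <- chroms
    occupy <- function(chrom, s, e, margin = 0L) {
      occ[[chrom]] <<- c(occ[[chrom]],
                         IRanges::IRanges(max(s - margin, 0L) + 1L, e + margin))
    }
    is_free <- function(chrom, s, e, margin = 0L) {
      !any(IRanges::overlapsAny(
        IRanges::IRanges(max(s - margin, 0L) + 1L, e + margin), occ[[chrom]]))
    }
    add_edit <- function(chrom, s, e, repl) {
      edits[[chrom]] <<- rbind(edits[[chrom]],
                               data.frame(start = s, end = e, repl = repl,
                                          stringsAsFactors = FALSE))
    }
    # protect reference features from unrelated edits
    for (i in seq_len(nrow(reference$transposons)))
      occupy(reference$transposons$seqid[i], reference$transposons$start[i],
             reference$transposons$end[i], margin = 150L)
    for (i in seq_len(nrow(reference$tandem_repeats)))
      occupy(reference$tandem_repeats$seqid[i], reference$tandem_repeats$start[i],
             reference$tandem_repeats$end[i], margin = 10L)

    trans <- reference$transposons
    trans$state <- rep("retained", nrow(trans))
    n_exc <- min(plan$excised_transposon_count, nrow(trans))
    if (n_exc > 0) {
      exc <- sample(seq_len(nrow(trans)), n_exc)
      trans$state[exc] <- "excised"
      for (i in exc) {
        solo <- reference$ltr_seqs[[trans$family[i]]]
        add_edit(trans$seqid[i], trans$start[i], trans$end[i], solo)
      }
    }

    gene_dels <- NULL
    if (plan$delete_genes > 0 && nrow(reference$genes) > 0) {
      cand <- reference$genes
      pick <- integer(0)
      ord <- sample(seq_len(nrow(cand)))
      for (i in ord) {
        if (length(pick) >= plan$delete_genes) break
        if (is_free(cand$seqid[i], cand$start[i], cand$end[i], margin = 150L)) {
          pick <- c(pick, i)
          add_edit(cand$seqid[i], cand$start[i], cand$end[i], "")
          occupy(cand$seqid[i], cand$start[i], cand$end[i], margin = 150L)
        }
      }
      gene_dels <- cand[pick, c("gene_id", "seqid", "start", "end")]
    }

    deletions <- NULL
    for (spec in plan$large_deletion_specs %||% list()) {
      L <- spec$length
      placed <- FALSE
      for (try in seq_len(500L)) {
        chrom <- sample(chroms, 1L)
        if (isTRUE(spec$subtelomeric)) {
          side <- sample(c("L", "R"), 1L)
          lim <- min(plan$subtelomere_length, seqlen[[chrom]] %/% 4L)
          if (lim <= L + 400L) next
          s <- if (side == "L") sample(200:(lim - L), 1L) else
            sample((seqlen[[chrom]] - lim):(seqlen[[chrom]] - L - 200L), 1L)
        } else {
          s <- sample(500:(seqlen[[chrom]] - L - 500L), 1L)
        }
        # avoid transposons/tandem/edits, but genes inside are deleted too
        feat_occ <- c(
          IRanges::IRanges(reference$transposons$start[reference$transposons$seqid == chrom] + 1L,
                           reference$transposons$end[reference$transposons$seqid == chrom]),
          IRanges::IRanges(reference$tandem_repeats$start[reference$tandem_repeats$seqid == chrom] + 1L,
                           reference$tandem_repeats$end[reference$tandem_repeats$seqid == chrom]),
          if (nrow(edits[[chrom]]) > 0)
            IRanges::IRanges(edits[[chrom]]$start + 1L, pmax(edits[[chrom]]$end, edits[[chrom]]$start + 1L))
          else IRanges::IRanges())
        # genes must be wholly inside or wholly outside
        g <- reference$genes[reference$genes$seqid == chrom, ]
        straddle <- any((g$start < s & g$end > s) |
                          (g$start < s + L & g$end > s + L))
        if (straddle) next
        if (any(IRanges::overlapsAny(IRanges::IRanges(s - 150L + 1L, s + L + 150L), feat_occ)))
          next
        add_edit(chrom, s, s + L, "")
        occupy(chrom, s, s + L, margin = 150L)
        inside <- g[g$start >= s & g$end <= s + L, ]
        deletions <- rbind(deletions, data.frame(
          seqid = chrom, start = s, end = s + L,
          subtelomeric = isTRUE(spec$subtelomeric),
          genes = paste(inside$gene_id, collapse = ","), stringsAsFactors = FALSE))
        if (nrow(inside) > 0)
          gene_dels <- rbind(gene_dels, inside[, c("gene_id", "seqid", "start", "end")])
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: could not place deletion of length ", L)
    }
    deletions <- deletions %||% data.frame(seqid = character(0), start = integer(0),
                                           end = integer(0), subtelomeric = logical(0),
                                           genes = character(0), stringsAsFactors = FALSE)
    gene_dels <- gene_dels %||% data.frame(gene_id = character(0), seqid = character(0),
                                           start = integer(0), end = integer(0),
                                           stringsAsFactors = FALSE)

    duplications <- NULL
    for (spec in plan$duplication_specs %||% list()) {
      L <- spec$length; copies <- spec$copies %||% 1L
      placed <- FALSE
      for (try in seq_len(500L)) {
        chrom <- sample(chroms, 1L)
        s <- sample(500:(seqlen[[chrom]] - L - 500L), 1L)
        if (!is_free(chrom, s, s + L, margin = 150L)) next
        # source must not straddle genes (keeps per-gene copy number clean)
        g <- reference$genes[reference$genes$seqid == chrom, ]
        if (any((g$start < s & g$end > s) | (g$start < s + L & g$end > s + L))) next
        ichrom <- sample(chroms, 1L)
        ip <- sample_slot(seqlen[[ichrom]], occ[[ichrom]], 0L, margin = 200L)
        if (is.null(ip)) next
        src_seq <- substr(as.character(reference$seqs[[chrom]]), s + 1L, s + L)
        add_edit(ichrom, ip, ip, strrep(src_seq, copies))
        occupy(chrom, s, s + L, margin = 150L)   # keep source pristine
        occupy(ichrom, ip, ip, margin = 200L)
        duplications <- rbind(duplications, data.frame(
          seqid = chrom, src_start = s, src_end = s + L, copies = copies,
          insert_seqid = ichrom, insert_pos = ip, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: could not place duplication of length ", L)
    }
    duplications <- duplications %||% data.frame(
      seqid = character(0), src_start = integer(0), src_end = integer(0),
      copies = integer(0), insert_seqid = character(0), insert_pos = integer(0),
      stringsAsFactors = FALSE)

    uniques <- NULL
    for (L in plan$unique_insertion_specs %||% integer(0)) {
      novel <- NULL
      for (try in seq_len(25L)) {
        cand <- random_dna(L)
        hits <- find_mems(Biostrings::DNAStringSet(c(novel1 = cand)),
                          reference$seqs, min_length = 20L)
        if (nrow(hits) == 0) { novel <- cand; break }
      }
      if (is.null(novel)) stop("could not generate a unique insertion of length ", L)
      placed <- FALSE
      for (try in seq_len(500L)) {
        chrom <- sample(chroms, 1L)
        ip <- sample_slot(seqlen[[chrom]], occ[[chrom]], 0L, margin = 200L)
        if (is.null(ip)) next
        add_edit(chrom, ip, ip, novel)
        occupy(chrom, ip, ip, margin = 200L)
        uniques <- rbind(uniques, data.frame(
          seqid = chrom, insert_pos = ip, length = L, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: could not place unique insertion")
    }
    uniques <- uniques %||% data.frame(seqid = character(0), insert_pos = integer(0),
                                       length = integer(0), stringsAsFactors = FALSE)

    # sequencing dropouts: no edit, but the region is protected so its
    # query coordinates stay contiguous and later stages can withhold it
    dropouts <- NULL
    for (spec in plan$dropout_specs %||% list()) {
      L <- spec$length
      placed <- FALSE
      for (try in seq_len(500L)) {
        chrom <- sample(chroms, 1L)
        s <- sample_slot(seqlen[[chrom]], occ[[chrom]], L, margin = 200L)
        if (is.null(s)) next
        occupy(chrom, s, s + L, margin = 200L)
        dropouts <- rbind(dropouts, data.frame(
          seqid = chrom, start = s, end = s + L, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: could not place dropout of length ", L)
    }
    dropouts <- dropouts %||% data.frame(seqid = character(0), start = integer(0),
                                         end = integer(0), stringsAsFactors = FALSE)

    # small indels: tandem-repeat expansions/contractions first
    indels <- NULL
    n_rep <- round(plan$frac_indel_in_repeat * plan$indel_count)
    tr <- reference$tandem_repeats
    if (n_rep > 0 && nrow(tr) > 0) {
      ord <- sample(seq_len(nrow(tr)))
      done <- 0L
      for (i in ord) {
        if (done >= n_rep) break
        u <- tr$unit[i]
        if (u > plan$max_indel) next
        max_units <- min(plan$max_indel %/% u, tr$copies[i] - 2L)
        if (max_units < 1) next
        m <- sample.int(max_units, 1L)
        kind <- sample(c("insertion", "deletion"), 1L)
        s <- tr$start[i]
        seqtxt <- strrep(tr$unit_seq[i], m)
        if (kind == "deletion") add_edit(tr$seqid[i], s, s + m * u, "")
        else add_edit(tr$seqid[i], s, s, seqtxt)
        norm <- normalize_indel(as.character(reference$seqs[[tr$seqid[i]]]),
                                s, kind, seqtxt)
        indels <- rbind(indels, data.frame(
          seqid = tr$seqid[i], pos = norm$pos, kind = kind, length = m * u,
          seq = norm$seq, in_tandem_repeat = TRUE, stringsAsFactors = FALSE))
        done <- done + 1L
      }
      n_rep <- done
    } else n_rep <- 0L
    n_free <- plan$indel_count - n_rep
    p_geom <- 1 / max(plan$indel_mean_length, 1.01)
    for (i in seq_len(n_free)) {
      L <- min(1L + stats::rgeom(1, p_geom), plan$max_indel)
      placed <- FALSE
      for (try in seq_len(500L)) {
        chrom <- sample(chroms, 1L)
        s <- sample_slot(seqlen[[chrom]], occ[[chrom]], L, margin = 8L,
                         lo = 300L, hi = seqlen[[chrom]] - 300L)
        if (is.null(s)) next
        kind <- sample(c("insertion", "deletion"), 1L)
        refseq <- as.character(reference$seqs[[chrom]])
        if (kind == "deletion") {
          norm <- normalize_indel(refseq, s, "deletion",
                                  substr(refseq, s + 1L, s + L))
          add_edit(chrom, s, s + L, "")
        } else {
          seqtxt <- random_dna(L)
          norm <- normalize_indel(refseq, s, "insertion", seqtxt)
          add_edit(chrom, s, s, seqtxt)
        }
        occupy(chrom, s, s + max(L, 1L), margin = 8L)
        indels <- rbind(indels, data.frame(
          seqid = chrom, pos = norm$pos, kind = kind, length = L,
          seq = norm$seq, in_tandem_repeat = FALSE, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: could not place indel of length ", L)
    }
    indels <- indels %||% data.frame(seqid = character(0), pos = integer(0),
                                     kind = character(0), length = integer(0),
                                     seq = character(0), in_tandem_repeat = logical(0),
                                     stringsAsFactors = FALSE)

    # SNVs last, on remaining free positions
    n_snvs <- plan$n_snvs %||% round(plan$snv_rate * sum(seqlen))
    snvs <- NULL
    if (n_snvs > 0) {
      per_chrom <- table(sample(chroms, n_snvs, replace = TRUE,
                                prob = seqlen / sum(seqlen)))
      for (chrom in names(per_chrom)) {
        need <- per_chrom[[chrom]]
        free <- IRanges::setdiff(
          IRanges::IRanges(301L, seqlen[[chrom]] - 300L),
          IRanges::reduce(occ[[chrom]]))
        pos_pool <- unlist(lapply(seq_along(free), function(j)
          seq(IRanges::start(free)[j], IRanges::end(free)[j])), use.names = FALSE) - 1L
        if (length(pos_pool) < need)
          stop("placement error: not enough free positions for SNVs on ", chrom)
        pos <- sort(sample(pos_pool, need))
        refseq <- as.character(reference$seqs[[chrom]])
        refb <- substring(refseq, pos + 1L, pos + 1L)
        altb <- vapply(refb, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        for (j in seq_along(pos)) add_edit(chrom, pos[j], pos[j] + 1L, altb[j])
        snvs <- rbind(snvs, data.frame(seqid = chrom, pos = pos, ref = refb,
                                       alt = altb, stringsAsFactors = FALSE))
      }
    }
    snvs <- snvs %||% data.frame(seqid = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0),
                                 stringsAsFactors = FALSE)

    # apply edits and derive query coordinates
    qseqs <- setNames(vector("list", length(chroms)), chroms)
    for (chrom in chroms)
      qseqs[[chrom]] <- apply_edits(as.character(reference$seqs[[chrom]]),
                                    edits[[chrom]])
    snvs <- snvs[order(snvs$seqid, snvs$pos), , drop = FALSE]
    map1 <- function(chrom, pos) map_ref_to_query(edits[[chrom]], pos)
    snvs$query_pos <- if (nrow(snvs) > 0)
      vapply(seq_len(nrow(snvs)), function(i)
        map1(snvs$seqid[i], snvs$pos[i]), integer(1)) else integer(0)
    # ref->query mapping counts an edit once its end coordinate is passed,
    # so a zero-width insertion edit at pos shifts map1(pos) by its own
    # length; inserted material starts that many bases earlier
    if (nrow(indels) > 0)
      indels$query_pos <- vapply(seq_len(nrow(indels)), function(i)
        map1(indels$seqid[i], indels$pos[i]), integer(1)) -
        ifelse(indels$kind == "insertion", indels$length, 0L)
    trans$query_start <- rep(NA_integer_, nrow(trans))
    trans$query_end <- rep(NA_integer_, nrow(trans))
    for (i in seq_len(nrow(trans))) {
      qs <- map1(trans$seqid[i], trans$start[i])
      if (trans$state[i] == "retained") {
        trans$query_start[i] <- qs
        trans$query_end[i] <- qs + (trans$end[i] - trans$start[i])
      } else {
        trans$query_start[i] <- qs
        trans$query_end[i] <- qs + plan$ltr_length
      }
    }
    if (nrow(duplications) > 0) {
      dup_len <- duplications$copies * (duplications$src_end - duplications$src_start)
      duplications$query_start <- vapply(seq_len(nrow(duplications)), function(i)
        map1(duplications$insert_seqid[i], duplications$insert_pos[i]), integer(1)) -
        dup_len
      duplications$query_end <- duplications$query_start + dup_len
    } else {
      duplications$query_start <- integer(0); duplications$query_end <- integer(0)
    }
    if (nrow(uniques) > 0) {
      uniques$query_start <- vapply(seq_len(nrow(uniques)), function(i)
        map1(uniques$seqid[i], uniques$insert_pos[i]), integer(1)) - uniques$length
      uniques$query_end <- uniques$query_start + uniques$length
    } else {
      uniques$query_start <- integer(0); uniques$query_end <- integer(0)
    }

    if (nrow(dropouts) > 0) {
      dropouts$query_start <- vapply(seq_len(nrow(dropouts)), function(i)
        map1(dropouts$seqid[i], dropouts$start[i]), integer(1))
      dropouts$query_end <- dropouts$query_start + (dropouts$end - dropouts$start)
    } else {
      dropouts$query_start <- integer(0); dropouts$query_end <- integer(0)
    }

    truth <- list(snvs = snvs, indels = indels, deletions = deletions,
                  gene_deletions = gene_dels, duplications = duplications,
                  transposons = trans, unique_insertions = uniques,
                  dropouts = dropouts,
                  edits = edits,
                  ref_lengths = seqlen,
                  query_lengths = setNames(nchar(unlist(qseqs)), chroms))
    class(truth) <- "sim_truth"
    out <- list(seqs = Biostrings::DNAStringSet(unlist(qseqs)), truth = truth)
    class(out) <- "sim_mutation"
    out
  })
}

#' Fragment a query genome into assembly-like contigs
#'
#' Contigs break at retained transposon copies (whose interiors are
#' withheld under the "break-and-drop" policy, emulating repeat-induced
#' assembly failure), at deletion junctions, and at a low random rate
#' elsewhere. A configurable number of retained loci are left fully
#' assembled inside one contig. Contigs may be emitted in either
#' orientation.
#'
#' @param mutation from [mutate_genome()]
#' @param plan the simulation plan
#' @return list of class `sim_assembly`: `contigs` (DNAStringSet),
#'   `placements` (contig -> query interval + orientation), `withheld`
#'   (query intervals absent from contigs), `loci_assembly` (per-locus
#'   assembly fate)
#' @export
fragment_assembly <- function(mutation, plan) {
  stopifnot(inherits(mutation, "sim_mutation"))
  truth <- mutation$truth
  with_subseed(plan$seed, 3L, {
    chroms <- names(mutation$seqs)
    qlen <- setNames(Biostrings::width(mutation$seqs), chroms)
    policy <- plan$contig_break_policy
    retained <- truth$transposons[truth$transposons$state == "retained", , drop = FALSE]
    keep_n <- min(plan$keep_assembled_count, nrow(retained))
    keep_ids <- if (keep_n > 0 && policy != "no-breaks")
      sample(retained$locus_id, keep_n) else character(0)
    if (policy == "no-breaks") keep_ids <- retained$locus_id

    loci_assembly <- truth$transposons[, c("locus_id", "family", "seqid", "start", "end", "state")]
    loci_assembly$assembly <- ifelse(
      loci_assembly$state == "excised", "excised",
      ifelse(loci_assembly$locus_id %in% keep_ids, "assembled",
             if (policy == "break-and-drop") "dropped" else "split"))
    qs_all <- truth$transposons$query_start
    qe_all <- truth$transposons$query_end

    drops <- list(); points <- list()
    for (chrom in chroms) { drops[[chrom]] <- NULL; points[[chrom]] <- integer(0) }
    if (policy != "no-breaks") {
      for (i in seq_len(nrow(retained))) {
        if (retained$locus_id[i] %in% keep_ids) next
        chrom <- retained$seqid[i]
        qs <- retained$query_start[i]; qe <- retained$query_end[i]
        if (policy == "break-and-drop") {
          drops[[chrom]] <- rbind(drops[[chrom]], data.frame(
            start = max(qs - plan$drop_flank, 0L),
            end = min(qe + plan$drop_flank, qlen[[chrom]]),
            reason = "repeat", stringsAsFactors = FALSE))
        } else {
          points[[chrom]] <- c(points[[chrom]], qs, qe)
        }
      }
      for (i in seq_len(nrow(truth$dropouts))) {
        chrom <- truth$dropouts$seqid[i]
        drops[[chrom]] <- rbind(drops[[chrom]], data.frame(
          start = truth$dropouts$query_start[i],
          end = truth$dropouts$query_end[i],
          reason = "dropout", stringsAsFactors = FALSE))
      }
      for (chrom in chroms) {
        n_rand <- stats::rpois(1, plan$random_break_rate * qlen[[chrom]])
        if (n_rand > 0)
          points[[chrom]] <- c(points[[chrom]],
                               sample.int(qlen[[chrom]] - 1L, min(n_rand, qlen[[chrom]] - 1L)))
      }
      # a break landing inside an excised or fully-assembled locus changes
      # its realized assembly fate: the observable pattern becomes a
      # contig break, and the truth table must say so
      for (i in seq_len(nrow(loci_assembly))) {
        if (!(loci_assembly$assembly[i] %in% c("excised", "assembled"))) next
        chrom <- loci_assembly$seqid[i]
        qs <- qs_all[i] - 200L; qe <- qe_all[i] + 200L
        pt_hit <- any(points[[chrom]] > qs & points[[chrom]] < qe)
        dr <- drops[[chrom]]
        dr_hit <- !is.null(dr) && nrow(dr) > 0 && any(dr$start < qe & dr$end > qs)
        if (pt_hit || dr_hit) loci_assembly$assembly[i] <- "split"
      }
    }

    contigs <- character(0); cnames <- character(0)
    placements <- NULL; withheld <- NULL
    k <- 0L
    for (chrom in chroms) {
      dr <- drops[[chrom]]
      dr_ir <- if (!is.null(dr) && nrow(dr) > 0)
        IRanges::reduce(IRanges::IRanges(dr$start + 1L, dr$end)) else IRanges::IRanges()
      keep_ir <- IRanges::setdiff(IRanges::IRanges(1L, qlen[[chrom]]), dr_ir)
      segs <- data.frame(start = IRanges::start(keep_ir) - 1L,
                         end = IRanges::end(keep_ir))
      # split kept segments at point breaks
      pts <- sort(unique(points[[chrom]]))
      out_segs <- NULL
      for (i in seq_len(nrow(segs))) {
        cuts <- pts[pts > segs$start[i] & pts < segs$end[i]]
        bnds <- c(segs$start[i], cuts, segs$end[i])
        out_segs <- rbind(out_segs, data.frame(start = bnds[-length(bnds)],
                                               end = bnds[-1]))
      }
      if (!is.null(dr) && nrow(dr) > 0)
        withheld <- rbind(withheld, data.frame(seqid = chrom, start = dr$start,
                                               end = dr$end, reason = dr$reason,
                                               stringsAsFactors = FALSE))
      for (i in seq_len(nrow(out_segs) %||% 0L)) {
        s <- out_segs$start[i]; e <- out_segs$end[i]
        if (e - s < plan$min_contig_length) {
          withheld <- rbind(withheld, data.frame(seqid = chrom, start = s, end = e,
                                                 reason = "short", stringsAsFactors = FALSE))
          next
        }
        k <- k + 1L
        orient <- if (plan$random_orientation && stats::runif(1) < 0.5) "-" else "+"
        seqtxt <- substr(as.character(mutation$seqs[[chrom]]), s + 1L, e)
        if (orient == "-") seqtxt <- revcomp(seqtxt)
        contigs <- c(contigs, seqtxt)
        cnames <- c(cnames, sprintf("contig_%04d", k))
        placements <- rbind(placements, data.frame(
          contig_id = sprintf("contig_%04d", k), seqid = chrom,
          q_start = s, q_end = e, orientation = orient, stringsAsFactors = FALSE))
      }
    }
    names(contigs) <- cnames
    out <- list(contigs = Biostrings::DNAStringSet(contigs),
                placements = placements %||% data.frame(
                  contig_id = character(0), seqid = character(0),
                  q_start = integer(0), q_end = integer(0),
                  orientation = character(0), stringsAsFactors = FALSE),
                withheld = withheld %||% data.frame(
                  seqid = character(0), start = integer(0), end = integer(0),
                  reason = character(0), stringsAsFactors = FALSE),
                loci_assembly = loci_assembly)
    class(out) <- "sim_assembly"
    out
  })
}

#' Simulate a windowed read-depth track
#'
#' Per-window counts are Poisson with mean
#' `depth_mean * bias(GC) * copy_number * width/window`; the GC bias is a
#' deterministic function of window GC content, so two strains simulated on
#' the same coordinates share it and it cancels from depth ratios.
#' Intervals in `deleted` zero the local mean; intervals in `duplicated`
#' double it (proportionally for partial windows).
#'
#' @param genome DNAStringSet the track is computed over
#' @param depth_mean expected reads per full window at copy number 1 (> 0)
#' @param bias_strength linear GC-bias coefficient (0 = flat)
#' @param seed RNG seed for this track
#' @param window window width in bp (last window of a chromosome may be
#'   shorter; its true width is kept)
#' @param deleted,duplicated optional interval data.frames (seqid, start,
#'   end) of copy-number 0 and 2 regions
#' @param cn_intervals optional data.frame (seqid, start, end, cn) of
#'   arbitrary copy-number multipliers (e.g. 0.5 for a heterozygous-style
#'   loss)
#' @return data.frame (seqid, start, end, width, gc, count)
#' @export
simulate_depth <- function(genome, depth_mean, bias_strength = 0.6, seed = 1L,
                           window = 100L, deleted = NULL, duplicated = NULL,
                           cn_intervals = NULL) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (window < 1) stop("window must be >= 1")
  genome <- as_seq_set(genome)
  with_subseed(seed, 4L, {
    out <- lapply(names(genome), function(chrom) {
      len <- Biostrings::width(genome[names(genome) == chrom])[1]
      starts <- seq(0L, len - 1L, by = window)
      ends <- pmin(starts + window, len)
      v <- Biostrings::Views(genome[[chrom]], start = starts + 1L, end = ends)
      fr <- Biostrings::letterFrequency(v, c("G", "C"))
      gc <- (fr[, 1] + fr[, 2]) / (ends - starts)
      bias <- pmax(1 + bias_strength * (gc - 0.5), 0.05)
      cn <- rep(1, length(starts))
      ivl_frac <- function(tab) {
        f <- rep(0, length(starts))
        if (is.null(tab)) return(f)
        tab <- tab[tab$seqid == chrom, , drop = FALSE]
        for (i in seq_len(nrow(tab)))
          f <- f + overlap_len(starts, ends, tab$start[i], tab$end[i]) / (ends - starts)
        pmin(f, 1)
      }
      cn <- cn + ivl_frac(duplicated) - ivl_frac(deleted)
      if (!is.null(cn_intervals)) {
        tab <- cn_intervals[cn_intervals$seqid == chrom, , drop = FALSE]
        for (i in seq_len(nrow(tab)))
          cn <- cn + (tab$cn[i] - 1) *
            overlap_len(starts, ends, tab$start[i], tab$end[i]) / (ends - starts)
      }
      mu <- depth_mean * bias * cn * (ends - starts) / window
      data.frame(seqid = chrom, start = starts, end = ends,
                 width = ends - starts, gc = as.numeric(gc),
                 count = stats::rpois(length(starts), pmax(mu, 0)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
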