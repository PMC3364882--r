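# SNV and small-indel calling from non-ambiguous alignment blocks, tandem
# repeat detection, and gene-effect annotation.

#' Left-align an indel within its sequence context
#'
#' Shifts an insertion/deletion to its leftmost equivalent position (the
#' VCF normalization convention); insertions are rotated accordingly.
#'
#' @param refseq reference chromosome sequence (character)
#' @param pos 0-based position (first deleted base, or insertion point)
#' @param kind "insertion" or "deletion"
#' @param seq the inserted or deleted sequence
#' @return list(pos=, seq=)
#' @export
normalize_indel <- function(refseq, pos, kind, seq) {
  L <- nchar(seq)
  if (L == 0) return(list(pos = pos, seq = seq))
  repeat {
    if (pos <= 0) break
    prev <- substr(refseq, pos, pos)            # base at pos-1 (0-based)
    last <- substr(seq, L, L)
    if (prev != last) break
    seq <- paste0(prev, substr(seq, 1L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

empty_calls <- function() {
  data.frame(seqid = character(0), pos = integer(0), kind = character(0),
             ref = character(0), alt = character(0), length = integer(0),
             seq = character(0), block_id = character(0),
             in_tandem_repeat = logical(0), stringsAsFactors = FALSE)
}

#' Call SNVs and small indels from alignment blocks
#'
#' Only non-ambiguous blocks with identity at or above `min_identity`
#' contribute. Every mismatch column yields one SNV; every gap run of
#' length at most `max_indel` yields one indel (left-aligned); longer gap
#' runs are excluded from the small-variant set and reported as structural
#' events in the `structural` attribute. Calls are sorted and deduplicated.
#'
#' @param blocks alignment blocks from [align_genomes()] (ambiguity flags set)
#' @param query,reference the aligned sequence sets
#' @param min_identity minimum block identity (default 0.97)
#' @param max_indel largest indel length called (default 90 bp)
#' @return data.frame of calls (seqid/pos on the reference, 0-based; for
#'   insertions `pos` is the base the insertion precedes); attribute
#'   `structural` holds gap runs longer than `max_indel`
#' @export
call_variants <- function(blocks, query, reference, min_identity = 0.97,
                          max_indel = 90L) {
  query <- as_seq_set(query); reference <- as_seq_set(reference)
  if (any(is.na(blocks$ambiguous)))
    stop("blocks must pass flag_ambiguity() before variant calling")
  unknown <- setdiff(unique(blocks$r_id), names(reference))
  if (length(unknown)) stop("block references unknown sequence: ", unknown[1])
  use <- blocks[!blocks$ambiguous & blocks$identity >= min_identity, , drop = FALSE]
  calls <- list(); structural <- list()
  for (i in seq_len(nrow(use))) {
    b <- use[i, ]
    rseq <- as.character(reference[[b$r_id]])
    qseq <- as.character(query[[b$q_id]])
    qaln <- if (b$strand == "+") substr(qseq, b$q_start + 1L, b$q_end) else
      revcomp(substr(qseq, b$q_start + 1L, b$q_end))
    runs <- cigar_runs(b$cigar)
    qi <- 0L; ri <- b$r_start
    for (j in seq_len(nrow(runs))) {
      op <- runs$op[j]; n <- runs$len[j]
      if (op == "=") { qi <- qi + n; ri <- ri + n }
      else if (op == "X") {
        refb <- substring(rseq, ri + 1L, ri + n)
        altb <- substring(qaln, qi + 1L, qi + n)
        refv <- strsplit(refb, "")[[1]]; altv <- strsplit(altb, "")[[1]]
        calls[[length(calls) + 1L]] <- data.frame(
          seqid = b$r_id, pos = ri + seq_len(n) - 1L, kind = "snv",
          ref = refv, alt = altv, length = 1L, seq = NA_character_,
          block_id = b$block_id, in_tandem_repeat = NA, stringsAsFactors = FALSE)
        qi <- qi + n; ri <- ri + n
      } else if (op == "I") {
        ins <- substr(qaln, qi + 1L, qi + n)
        if (n <= max_indel) {
          norm <- normalize_indel(rseq, ri, "insertion", ins)
          calls[[length(calls) + 1L]] <- data.frame(
            seqid = b$r_id, pos = norm$pos, kind = "insertion",
            ref = NA_character_, alt = NA_character_, length = n,
            seq = norm$seq, block_id = b$block_id, in_tandem_repeat = NA,
            stringsAsFactors = FALSE)
        } else {
          structural[[length(structural) + 1L]] <- data.frame(
            seqid = b$r_id, pos = ri, kind = "insertion", length = n,
            block_id = b$block_id, stringsAsFactors = FALSE)
        }
        qi <- qi + n
      } else { # D
        del <- substr(rseq, ri + 1L, ri + n)
        if (n <= max_indel) {
          norm <- normalize_indel(rseq, ri, "deletion", del)
          calls[[length(calls) + 1L]] <- data.frame(
            seqid = b$r_id, pos = norm$pos, kind = "deletion",
            ref = NA_character_, alt = NA_character_, length = n,
            seq = norm$seq, block_id = b$block_id, in_tandem_repeat = NA,
            stringsAsFactors = FALSE)
        } else {
          structural[[length(structural) + 1L]] <- data.frame(
            seqid = b$r_id, pos = ri, kind = "deletion", length = n,
            block_id = b$block_id, stringsAsFactors = FALSE)
        }
        ri <- ri + n
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  if (nrow(out)) {
    key <- paste(out$seqid, out$pos, out$kind, out$ref, out$alt, out$seq)
    out <- out[!duplicated(key), , drop = FALSE]
    out <- out[order(out$seqid, out$pos, out$kind), , drop = FALSE]
    rownames(out) <- NULL
    stopifnot(all(out$length <= max_indel))
  }
  attr(out, "structural") <- if (length(structural))
    do.call(rbind, structural) else
      data.frame(seqid = character(0), pos = integer(0), kind = character(0),
                 length = integer(0), block_id = character(0),
                 stringsAsFactors = FALSE)
  out
}

#' Detect perfect tandem repeat arrays
#'
#' Reports every maximal perfect array with unit length at most `max_unit`
#' and span of at least two units (fractional copy numbers allowed).
#' Reports contained in a longer-span report are dropped; for identical
#' spans the smallest (primitive) unit wins.
#'
#' @param genome DNAStringSet or character sequences
#' @param max_unit largest unit length considered (default 60 bp)
#' @param min_copies minimum copy number (default 2)
#' @return data.frame (seqid, start, end, unit, copies)
#' @export
detect_tandem_repeats <- function(genome, max_unit = 60L, min_copies = 2) {
  genome <- as_seq_set(genome)
  out <- list()
  for (chrom in names(genome)) {
    s <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    n <- length(s)
    loci <- list()
    for (u in seq_len(min(max_unit, n - 1))) {
      eq <- s[seq_len(n - u)] == s[(u + 1):n] & s[seq_len(n - u)] != "N"
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- r$values & r$lengths >= u * (min_copies - 1)
      if (!any(hit)) next
      span_start <- starts[hit] - 1L           # 0-based
      span_end <- ends[hit] + u                # half-open
      loci[[length(loci) + 1L]] <- data.frame(
        start = span_start, end = span_end, unit = u,
        copies = (span_end - span_start) / u)
    }
    if (!length(loci)) next
    df <- do.call(rbind, loci)
    df <- df[df$copies >= min_copies, , drop = FALSE]
    if (!nrow(df)) next
    # identical spans: keep the smallest (primitive) unit
    df <- df[order(df$start, -df$end, df$unit), , drop = FALSE]
    df <- df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
    # drop reports contained in a longer-span report
    maxend <- cummax(c(0L, df$end))[seq_len(nrow(df))]
    df <- df[df$end > maxend, , drop = FALSE]
    df$seqid <- chrom
    out[[length(out) + 1L]] <- df[order(df$start),
                                  c("seqid", "start", "end", "unit", "copies"),
                                  drop = FALSE]
  }
  if (!length(out))
    return(data.frame(seqid = character(0), start = integer(0), end = integer(0),
                      unit = integer(0), copies = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# standard nuclear genetic code
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G")

translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# extract the coding sequence of a gene (coding-strand orientation)
gene_cds_seq <- function(gene, ref_seqs) {
  chrom <- as.character(ref_seqs[[gene$seqid]])
  cds_tab <- if (!is.null(gene$cds)) gene$cds[[1]] else
    data.frame(start = gene$start, end = gene$end)
  cds_tab <- cds_tab[order(cds_tab$start), , drop = FALSE]
  parts <- substring(chrom, cds_tab$start + 1L, cds_tab$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

# 0-based coding offset of a reference position within a gene's CDS
cds_offset <- function(gene, pos) {
  cds_tab <- if (!is.null(gene$cds)) gene$cds[[1]] else
    data.frame(start = gene$start, end = gene$end)
  cds_tab <- cds_tab[order(cds_tab$start), , drop = FALSE]
  inside <- which(pos >= cds_tab$start & pos < cds_tab$end)
  if (!length(inside)) return(NA_integer_)
  fwd <- sum(cds_tab$end[seq_len(inside - 1)] - cds_tab$start[seq_len(inside - 1)]) +
    (pos - cds_tab$start[inside])
  total <- sum(cds_tab$end - cds_tab$start)
  if (gene$strand == "-") total - 1L - fwd else as.integer(fwd)
}

#' Annotate variant calls with gene effects
#'
#' SNVs inside a CDS are classified by codon outcome: synonymous changes
#' are labelled `sense` (the vocabulary used in depth-of-variation plots of
#' lab-strain comparisons), amino-acid changes `missense`, and changes that
#' create or destroy a start/stop codon `start_stop_altered`. In-CDS indels
#' are `frameshift` when their length is not a multiple of three, otherwise
#' `inframe_indel` unless they touch the first/last codon or introduce a
#' premature stop (then `start_stop_altered`). `frame_preserved` is TRUE
#' when the indel neither shifts the frame nor alters start/stop usage.
#' Calls overlapping a tandem repeat locus get `in_tandem_repeat = TRUE`.
#'
#' @param calls from [call_variants()]
#' @param genes gene models (gene_id, seqid, start, end, strand, optional
#'   `cds` list-column)
#' @param repeats tandem repeat loci from [detect_tandem_repeats()] (or NULL)
#' @param ref_seqs reference DNAStringSet
#' @return `calls` with columns gene_id, effect, frame_preserved and the
#'   in_tandem_repeat flag filled in
#' @export
annotate_variants <- function(calls, genes, repeats, ref_seqs) {
  ref_seqs <- as_seq_set(ref_seqs)
  if (nrow(calls) == 0) {
    calls$gene_id <- character(0); calls$effect <- character(0)
    calls$frame_preserved <- logical(0)
    return(calls)
  }
  # tandem repeat context
  calls$in_tandem_repeat <- FALSE
  if (!is.null(repeats) && nrow(repeats) > 0) {
    for (chrom in unique(calls$seqid)) {
      sel <- calls$seqid == chrom
      rr <- repeats[repeats$seqid == chrom, , drop = FALSE]
      if (!nrow(rr)) next
      span_end <- ifelse(calls$kind[sel] == "deletion",
                         calls$pos[sel] + calls$length[sel], calls$pos[sel] + 1L)
      ir <- IRanges::IRanges(calls$pos[sel] + 1L, span_end)
      rir <- IRanges::IRanges(rr$start + 1L, rr$end)
      calls$in_tandem_repeat[sel] <- IRanges::overlapsAny(ir, rir)
    }
  }

  calls$gene_id <- NA_character_
  calls$effect <- "intergenic"
  calls$frame_preserved <- NA

  skip_warned <- character(0)
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    span_end <- if (v$kind == "deletion") v$pos + v$length else v$pos + 1L
    g <- genes[genes$seqid == v$seqid & genes$start < span_end & genes$end > v$pos, , drop = FALSE]
    if (nrow(g) == 0) next
    gene <- g[1, ]
    cds <- gene_cds_seq(gene, ref_seqs)
    if (nchar(cds) %% 3L != 0L) {
      if (!(gene$gene_id %in% skip_warned)) {
        warning("CDS length of ", gene$gene_id, " not divisible by 3; annotation skipped")
        skip_warned <- c(skip_warned, gene$gene_id)
      }
      calls$gene_id[i] <- gene$gene_id
      calls$effect[i] <- NA_character_
      next
    }
    calls$gene_id[i] <- gene$gene_id
    n_cod <- nchar(cds) %/% 3L
    if (v$kind == "snv") {
      off <- cds_offset(gene, v$pos)
      if (is.na(off)) { calls$effect[i] <- "intergenic"; next }
      cod_idx <- off %/% 3L
      base_in <- off %% 3L
      codon <- substr(cds, cod_idx * 3L + 1L, cod_idx * 3L + 3L)
      altb <- if (gene$strand == "-") chartr("ACGT", "TGCA", v$alt) else v$alt
      mut <- codon
      substr(mut, base_in + 1L, base_in + 1L) <- altb
      aa_ref <- unname(CODON_TABLE[codon]); if (is.na(aa_ref)) aa_ref <- "X"
      aa_mut <- unname(CODON_TABLE[mut]); if (is.na(aa_mut)) aa_mut <- "X"
      if (aa_ref == aa_mut) {
        calls$effect[i] <- "sense"
      } else if (cod_idx == 0L || cod_idx == n_cod - 1L || aa_mut == "*") {
        calls$effect[i] <- "start_stop_altered"
      } else {
        calls$effect[i] <- "missense"
      }
    } else {
      # indel
      off1 <- cds_offset(gene, v$pos)
      off2 <- cds_offset(gene, max(v$pos, span_end - 1L))
      in_cds <- !is.na(off1) || !is.na(off2)
      if (!in_cds) { calls$effect[i] <- "intergenic"; next }
      if (v$length %% 3L != 0L) {
        calls$effect[i] <- "frameshift"
        calls$frame_preserved[i] <- FALSE
        next
      }
      offs <- c(off1, off2)
      offs <- offs[!is.na(offs)]
      touches_edge <- any(offs %/% 3L == 0L) || any(offs %/% 3L == n_cod - 1L) ||
        v$pos < gene$start || span_end > gene$end
      # rebuild the mutated CDS and check start/stop usage
      chrom <- as.character(ref_seqs[[v$seqid]])
      mut_chrom <- if (v$kind == "deletion")
        paste0(substr(chrom, 1L, v$pos), substr(chrom, v$pos + v$length + 1L, nchar(chrom)))
      else
        paste0(substr(chrom, 1L, v$pos), v$seq, substr(chrom, v$pos + 1L, nchar(chrom)))
      shift <- if (v$kind == "deletion") -v$length else v$length
      gs <- gene$start; ge <- gene$end + shift
      mut_cds <- substr(mut_chrom, gs + 1L, ge)
      if (gene$strand == "-") mut_cds <- revcomp(mut_cds)
      prot <- translate_cds(mut_cds)
      np <- nchar(prot)
      ok <- substr(mut_cds, 1L, 3L) == "ATG" &&
        substr(prot, np, np) == "*" &&
        !grepl("\\*", substr(prot, 1L, np - 1L))
      if (touches_edge || !ok) {
        calls$effect[i] <- "start_stop_altered"
        calls$frame_preserved[i] <- FALSE
      } else {
        calls$effect[i] <- "inframe_indel"
        calls$frame_preserved[i] <- TRUE
      }
    }
  }
  calls
}
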