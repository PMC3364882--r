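# Gene presence/absence with high-confidence deletion calling (the
# intersection of "not in the assembly" and "depth says missing"), query
# unique-region detection under the best-alignment-per-reference-position
# rule, and a cross-strain conservation screen for unique regions.

# per-chromosome integer vector marking, for each reference base, the row
# index of the best block covering it (0 = none). "Best" = highest
# identity, ties to the earlier block.
paint_best_blocks <- function(blocks, seqlens) {
  paint <- lapply(seqlens, function(n) integer(n))
  ord <- order(-blocks$identity, blocks$block_id)
  for (i in ord) {
    b <- blocks[i, ]
    v <- paint[[b$r_id]]
    sel <- (b$r_start + 1L):b$r_end
    free <- v[sel] == 0L
    v[sel[free]] <- i
    paint[[b$r_id]] <- v
  }
  paint
}

#' Classify gene presence from assembly alignment and depth ratio
#'
#' A gene is "mapped" when some alignment block covers at least
#' `min_coverage` of its span with per-gene identity (matching columns /
#' aligned columns within the gene) of at least `min_identity`. Status:
#' `present` (mapped, normal depth), `low_depth` (mapped but mean log2
#' ratio below `depth_cut`), `absent_in_assembly` (unmapped, normal depth
#' - an assembly dropout, not a deletion), and `deleted_high_confidence`
#' (unmapped AND mean log2 below `depth_cut` - the intersection rule that
#' protects against false deletion calls at repeats).
#'
#' @param genes gene models
#' @param blocks alignment blocks
#' @param cnv_windows log2-ratio track from [log2_ratio_track()]
#' @param min_identity identity cut for a mapped gene (default 0.95)
#' @param depth_cut log2-ratio cut for "missing in the data" (default -0.6)
#' @param min_coverage aligned fraction required for a mapped gene
#' @return data.frame (gene_id, best_identity, coverage, mean_log2, status)
#' @export
gene_presence <- function(genes, blocks, cnv_windows, min_identity = 0.95,
                          depth_cut = -0.6, min_coverage = 0.8) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cand <- blocks[blocks$r_id == g$seqid & blocks$r_start < g$end &
                     blocks$r_end > g$start, , drop = FALSE]
    best_id <- NA_real_; best_cov <- 0
    for (j in seq_len(nrow(cand))) {
      b <- cand[j, ]
      cc <- cigar_columns(b$cigar)
      rpos <- b$r_start + cc$r_off
      in_gene <- !is.na(rpos) & rpos >= g$start & rpos < g$end
      aligned <- sum(in_gene & cc$op %in% c("=", "X"))
      matched <- sum(in_gene & cc$op == "=")
      cov <- aligned / (g$end - g$start)
      idn <- if (aligned > 0) matched / aligned else 0
      if (cov >= min_coverage && (is.na(best_id) || idn > best_id)) {
        best_id <- idn; best_cov <- cov
      } else if (cov > best_cov && is.na(best_id)) best_cov <- cov
    }
    w <- cnv_windows[cnv_windows$seqid == g$seqid &
                       cnv_windows$start < g$end & cnv_windows$end > g$start, , drop = FALSE]
    lg <- pmin(pmax(w$log2_ratio, -4), 4)
    mean_lg <- if (length(lg)) mean(lg, na.rm = TRUE) else NA_real_
    mapped <- !is.na(best_id) && best_id >= min_identity
    low <- !is.na(mean_lg) && mean_lg < depth_cut
    status <- if (mapped && !low) "present" else if (mapped) "low_depth"
    else if (low) "deleted_high_confidence" else "absent_in_assembly"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, best_identity = best_id, coverage = best_cov,
      mean_log2 = mean_lg, status = status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # invariant: high-confidence deletions are a subset of assembly-absent
  stopifnot(all(out$status != "deleted_high_confidence" |
                  is.na(out$best_identity) | out$best_identity < min_identity))
  out
}

#' Detect query regions unique with respect to the reference
#'
#' For every reference position only the best-identity alignment is kept;
#' query positions covered by no kept alignment of identity above
#' `min_identity`, merged into runs of at least `min_length`, are unique.
#' Extra copies of query duplications therefore surface as unique, because
#' only one copy can win its reference positions.
#'
#' @param query query sequences (contigs or chromosomes)
#' @param reference reference sequences
#' @param blocks alignment blocks of query vs reference
#' @param min_identity strict identity cut for a kept alignment
#' @param min_length minimum unique-region length (bp)
#' @return data.frame (seqid, start, end, length, best_ref_identity);
#'   seqid/start/end are query coordinates
#' @export
unique_regions <- function(query, reference, blocks, min_identity = 0.95,
                           min_length = 500L) {
  query <- as_seq_set(query); reference <- as_seq_set(reference)
  seqlens <- setNames(Biostrings::width(reference), names(reference))
  qlens <- setNames(Biostrings::width(query), names(query))
  use_idx <- which(blocks$identity > min_identity)
  covered <- lapply(qlens, function(n) logical(n))
  if (length(use_idx)) {
    use <- blocks[use_idx, , drop = FALSE]
    paint <- paint_best_blocks(use, seqlens)
    for (k in seq_len(nrow(use))) {
      b <- use[k, ]
      won <- which(paint[[b$r_id]][(b$r_start + 1L):b$r_end] == k)
      if (!length(won)) next
      r2q <- cigar_ref_to_query(b$cigar)     # per ref offset -> query offset
      qoff <- r2q[won]
      qoff <- qoff[!is.na(qoff)]
      if (!length(qoff)) next
      qpos <- if (b$strand == "+") b$q_start + qoff else b$q_end - 1L - qoff
      v <- covered[[b$q_id]]
      v[qpos + 1L] <- TRUE
      covered[[b$q_id]] <- v
    }
  }
  out <- list()
  for (qid in names(qlens)) {
    un <- !covered[[qid]]
    r <- rle(un)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_length)
    for (h in hit) {
      s <- starts[h] - 1L; e <- ends[h]
      ov <- blocks[blocks$q_id == qid & blocks$q_start < e & blocks$q_end > s, , drop = FALSE]
      best <- if (nrow(ov)) max(ov$identity) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        seqid = qid, start = s, end = e, length = e - s,
        best_ref_identity = best, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seqid = character(0), start = integer(0), end = integer(0),
               length = integer(0), best_ref_identity = numeric(0),
               stringsAsFactors = FALSE)
  attr(res, "covered") <- covered
  res
}

#' Filter conservation hits at the coverage/identity cuts
#'
#' Pure threshold rule (strict inequalities): a hit survives when query
#' coverage exceeds `min_coverage` and identity exceeds `min_identity`.
#'
#' @param hits data.frame with coverage and identity columns
#' @param min_coverage coverage cut (default 0.60)
#' @param min_identity identity cut (default 0.90)
#' @return the surviving rows
#' @export
screen_hits <- function(hits, min_coverage = 0.60, min_identity = 0.90) {
  hits[hits$coverage > min_coverage & hits$identity > min_identity, , drop = FALSE]
}

#' Screen unique regions for conservation in a strain panel
#'
#' Each region is aligned against every panel genome; the best local
#' alignment's query coverage and identity are recorded and hits below
#' either cut are dropped (coverage > 0.60 and identity > 0.90 by
#' default). Passing strains are reported per region, sorted by aligned
#' score.
#'
#' @param regions from [unique_regions()]
#' @param query_seqs the query sequences the regions live on
#' @param panel named list (or DNAStringSet list) of panel strain genomes
#' @param group_map optional data.frame (strain, group)
#' @param min_coverage,min_identity the screen cuts
#' @param min_mem MEM seed length for the local alignments
#' @return data.frame (region, strain, group, coverage, identity)
#' @export
conservation_screen <- function(regions, query_seqs, panel, group_map = NULL,
                                min_coverage = 0.60, min_identity = 0.90,
                                min_mem = 15L) {
  if (!length(panel)) stop("conservation panel is empty")
  query_seqs <- as_seq_set(query_seqs)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    rseq <- substr(as.character(query_seqs[[reg$seqid]]), reg$start + 1L, reg$end)
    L <- nchar(rseq)
    for (strain in names(panel)) {
      genome <- as_seq_set(panel[[strain]])
      mems <- find_mems(Biostrings::DNAStringSet(c(region = rseq)), genome,
                        min_length = min_mem)
      if (nrow(mems) == 0) next
      bl <- chain_and_extend(mems, Biostrings::DNAStringSet(c(region = rseq)),
                             genome, min_anchor = min_mem)
      if (nrow(bl) == 0) next
      best <- bl[which.max(bl$matches), ]
      cov <- (best$q_end - best$q_start) / L
      rows[[length(rows) + 1L]] <- data.frame(
        region = paste0(reg$seqid, ":", reg$start, "-", reg$end),
        strain = strain,
        group = if (!is.null(group_map))
          group_map$group[match(strain, group_map$strain)] else NA_character_,
        coverage = cov, identity = best$identity, score = best$matches,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(0), strain = character(0), group = character(0),
               coverage = numeric(0), identity = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  hits <- screen_hits(hits, min_coverage, min_identity)
  hits[order(hits$region, -hits$score), , drop = FALSE]
}
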