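# Contig tiling on the reference, classification of inter-contig gaps
# (missing sequence vs unassembled repeats), LTR-transposon locus
# classification (GA/CB/AS), and depth-ratio estimates of per-family
# retrotransposon copy number.

#' Assign each contig its best reference location
#'
#' Per contig the placement maximizing aligned reference length times
#' identity wins; ties go to the smallest reference coordinate. Contigs
#' whose best block falls below `min_identity` are reported in the
#' `unplaced` attribute.
#'
#' @param blocks alignment blocks
#' @param min_identity minimum block identity for a placement
#' @return data.frame (contig_id, seqid, r_start, r_end, strand, score,
#'   order) sorted by reference position; `order` increases along each
#'   chromosome
#' @export
tile_contigs <- function(blocks, min_identity = 0.9) {
  if (nrow(blocks) == 0) stop("no blocks to tile")
  rows <- list(); unplaced <- character(0)
  for (cid in unique(blocks$q_id)) {
    sub <- blocks[blocks$q_id == cid, , drop = FALSE]
    sub$score <- (sub$r_end - sub$r_start) * sub$identity
    sub <- sub[sub$identity >= min_identity, , drop = FALSE]
    if (nrow(sub) == 0) { unplaced <- c(unplaced, cid); next }
    sub <- sub[order(-sub$score, sub$r_id, sub$r_start), , drop = FALSE]
    best <- sub[1, ]
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = cid, seqid = best$r_id, r_start = best$r_start,
      r_end = best$r_end, strand = best$strand, score = best$score,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no contig could be placed")
  out <- do.call(rbind, rows)
  out <- out[order(out$seqid, out$r_start), , drop = FALSE]
  out$order <- as.integer(stats::ave(out$r_start, out$seqid, FUN = seq_along))
  rownames(out) <- NULL
  attr(out, "unplaced") <- unplaced
  out
}

#' Classify inter-contig reference gaps
#'
#' A gap is the reference interval between consecutive contig placements.
#' It is labelled `missing_sequence` when it contains at least one
#' zero-coverage stretch in the query-read depth track (the data are
#' absent), `unassembled` when it overlaps a repetitive region of the
#' reference (the data are present but the assembler could not place
#' them), `both` when both hold, else `unexplained`. Per-label counts and
#' total widths are attached as the `tally` attribute.
#'
#' @param placements from [tile_contigs()]
#' @param depth query-read depth track on the reference (from
#'   [simulate_depth()] or [read_depth_track()])
#' @param repeats repeat regions from [self_repeats()]
#' @return data.frame of gap calls
#' @export
classify_gaps <- function(placements, depth, repeats) {
  out <- list()
  for (chrom in unique(placements$seqid)) {
    pl <- placements[placements$seqid == chrom, , drop = FALSE]
    if (is.unsorted(pl$r_start)) stop("placements not sorted (internal error)")
    dw <- depth[depth$seqid == chrom, , drop = FALSE]
    rr <- repeats[repeats$seqid == chrom, , drop = FALSE]
    cur_end <- pl$r_end[1]
    for (i in seq_len(nrow(pl))[-1]) {
      gs <- cur_end; ge <- pl$r_start[i]
      cur_end <- max(cur_end, pl$r_end[i])
      if (ge <= gs) next
      zero <- any(dw$count == 0 & dw$start < ge & dw$end > gs)
      rep_hit <- nrow(rr) > 0 && any(rr$start < ge & rr$end > gs)
      label <- if (zero && rep_hit) "both" else if (zero) "missing_sequence"
      else if (rep_hit) "unassembled" else "unexplained"
      out[[length(out) + 1L]] <- data.frame(
        seqid = chrom, start = gs, end = ge,
        has_zero_coverage_base = zero, overlaps_repeat = rep_hit,
        label = label, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seqid = character(0), start = integer(0), end = integer(0),
               has_zero_coverage_base = logical(0), overlaps_repeat = logical(0),
               label = character(0), stringsAsFactors = FALSE)
  lv <- c("missing_sequence", "unassembled", "both", "unexplained")
  attr(res, "tally") <- data.frame(
    label = lv,
    n = vapply(lv, function(l) sum(res$label == l), integer(1)),
    total_bp = vapply(lv, function(l) sum(res$end[res$label == l] - res$start[res$label == l]),
                      numeric(1)), row.names = NULL)
  res
}

#' Classify annotated transposon loci from contig alignments
#'
#' Three locus states are distinguished: `absent_gapped` (GA) - a single
#' alignment block spans the locus with an internal deletion gap close to
#' the annotated element length (the element is absent from the query);
#' `present_break` (CB) - distinct contigs terminate on the two flanks (the
#' element is present but unassembled); `present_assembled` (AS) - one
#' block crosses the locus with no sizeable gap. Precedence AS > GA > CB;
#' loci matching no pattern are conservatively labelled `present_break`
#' with a warning.
#'
#' @param loci transposon annotation (locus_id, family, seqid, start, end)
#' @param placements from [tile_contigs()]
#' @param blocks alignment blocks (ambiguity flags set)
#' @param tolerance relative tolerance on the GA gap size (default 0.2)
#' @param flank_window bp window for CB flank detection (default 1000)
#' @param min_gap smallest gap (bp) that disqualifies AS (default 100)
#' @return data.frame (locus_id, family, label, gap_size)
#' @export
classify_transposons <- function(loci, placements, blocks, tolerance = 0.2,
                                 flank_window = 1000L, min_gap = 100L) {
  out <- list()
  # all blocks participate: the requirement that a spanning block extend
  # beyond both locus edges already excludes element-body-only alignments
  # from other loci (which end at the locus boundaries), and long genuine
  # spanning blocks may carry the ambiguity flag merely because their own
  # repeat content aligns elsewhere too
  use <- blocks
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    elem_len <- lc$end - lc$start
    cand <- use[use$r_id == lc$seqid &
                  use$r_start < lc$start - 50L &
                  use$r_end > lc$end + 50L, , drop = FALSE]
    label <- NA_character_; gap_size <- NA_integer_
    # deletion gap content of each spanning block within the locus
    if (nrow(cand) > 0) {
      for (j in seq_len(nrow(cand))) {
        runs <- cigar_runs(cand$cigar[j])
        rpos <- cand$r_start[j] + cumsum(c(0L, runs$len[-nrow(runs)] *
                                             (runs$op[-nrow(runs)] %in% c("=", "X", "D"))))
        rend <- rpos + runs$len * (runs$op %in% c("=", "X", "D"))
        din <- runs$op == "D" & rend > lc$start & rpos < lc$end
        gap_in_locus <- sum(pmin(rend[din], lc$end) - pmax(rpos[din], lc$start))
        ins_in_locus <- runs$op == "I" & runs$len >= min_gap &
          rpos >= lc$start & rpos <= lc$end
        big_gap <- any(din & runs$len >= min_gap) || any(ins_in_locus)
        if (gap_in_locus < min_gap && !big_gap) { label <- "present_assembled"; break }
        if (is.na(label) &&
            abs(gap_in_locus - elem_len) <= tolerance * elem_len) {
          label <- "absent_gapped"; gap_size <- as.integer(gap_in_locus)
        }
      }
    }
    if (is.na(label) || label == "absent_gapped") {
      # CB: contigs terminating on both flanks (only if not already GA/AS)
      pl <- placements[placements$seqid == lc$seqid, , drop = FALSE]
      left <- any(abs(pl$r_end - lc$start) <= flank_window)
      right <- any(abs(pl$r_start - lc$end) <= flank_window)
      if (is.na(label)) {
        if (left && right && sum(abs(pl$r_end - lc$start) <= flank_window |
                                   abs(pl$r_start - lc$end) <= flank_window) >= 2) {
          label <- "present_break"
        } else {
          warning("locus ", lc$locus_id, " matches no pattern; labelled present_break")
          label <- "present_break"
        }
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      locus_id = lc$locus_id, family = lc$family, label = label,
      gap_size = gap_size, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Estimate per-family transposon copy number from depth ratios
#'
#' For each annotated element the library-scaled query/reference depth
#' ratio is computed over its windows; the family estimate is the
#' annotated reference copy count times the mean per-element ratio,
#' rounded to the nearest integer. Elements with zero reference depth are
#' skipped with a warning.
#'
#' @param loci transposon annotation (locus_id, family, seqid, start, end)
#' @param depth_test,depth_ref depth tracks for the two strains on the
#'   reference coordinates
#' @return list with `per_element` (locus, family, ratio, log2_ratio) and
#'   `per_family` (family, ref_count, estimate)
#' @export
ty_family_copy_estimate <- function(loci, depth_test, depth_ref) {
  tot_t <- sum(depth_test$count); tot_r <- sum(depth_ref$count)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    sel_t <- depth_test$seqid == lc$seqid & depth_test$start < lc$end &
      depth_test$end > lc$start
    sel_r <- depth_ref$seqid == lc$seqid & depth_ref$start < lc$end &
      depth_ref$end > lc$start
    x <- sum(depth_test$count[sel_t]); y <- sum(depth_ref$count[sel_r])
    if (y == 0) {
      warning("zero reference depth over ", lc$locus_id, "; skipped")
      next
    }
    ratio <- (x / tot_t) / (y / tot_r)
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = lc$locus_id, family = lc$family, ratio = ratio,
      log2_ratio = log2(ratio), stringsAsFactors = FALSE)
  }
  per_element <- do.call(rbind, rows)
  fams <- unique(loci$family)
  per_family <- do.call(rbind, lapply(fams, function(f) {
    ref_count <- sum(loci$family == f)
    r <- per_element$ratio[per_element$family == f]
    data.frame(family = f, ref_count = ref_count,
               estimate = as.integer(round(ref_count * mean(r))),
               stringsAsFactors = FALSE)
  }))
  list(per_element = per_element, per_family = per_family)
}
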