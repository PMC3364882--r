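# Anchor-based whole-genome alignment: maximal-exact-match (MEM) seeding,
# collinear chaining with affine-ish gap costs, exact unit-cost closure of
# inter-anchor gaps, greedy end extension, and exact polishing of small
# blocks. This re-implements the seeding/chaining strategy of classical
# whole-genome aligners; it is not a suffix-tree MUM finder.

as_seq_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString")) x <- as.character(x)
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    if (any(!nzchar(names(out)))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  stop("expected DNAStringSet or character sequences")
}

empty_mems <- function() {
  data.frame(q_id = character(0), r_id = character(0),
             q_start = integer(0), q_end = integer(0),
             r_start = integer(0), r_end = integer(0),
             strand = character(0), length = integer(0),
             stringsAsFactors = FALSE)
}

#' Find maximal exact matches between two sequence sets
#'
#' A MEM is an exact match that cannot be extended on either side without a
#' mismatch (N never matches, including against N). Matches on the minus
#' strand pair the reverse complement of the query with the forward
#' reference; their query coordinates are reported on the original query.
#'
#' @param query,reference DNAStringSet (or character) sequences
#' @param min_length minimum match length in bp (>= 10)
#' @param both_strands also search the reverse complement of the query
#' @return data.frame (q_id, r_id, q_start, q_end, r_start, r_end, strand,
#'   length), 0-based half-open, sorted by reference position
#' @export
find_mems <- function(query, reference, min_length = 20L, both_strands = TRUE) {
  if (min_length < 10) stop("min_length must be >= 10")
  query <- as_seq_set(query); reference <- as_seq_set(reference)
  out <- list()
  for (qi in seq_along(query)) {
    qname <- names(query)[qi]
    qseq <- as.character(query[[qi]])
    qlen <- nchar(qseq)
    qrc <- if (both_strands) revcomp(qseq) else NULL
    for (ri in seq_along(reference)) {
      rname <- names(reference)[ri]
      rseq <- as.character(reference[[ri]])
      fwd <- .find_mems_cpp(qseq, rseq, as.integer(min_length))
      if (nrow(fwd)) {
        out[[length(out) + 1L]] <- data.frame(
          q_id = qname, r_id = rname,
          q_start = fwd$q_start, q_end = fwd$q_start + fwd$length,
          r_start = fwd$r_start, r_end = fwd$r_start + fwd$length,
          strand = "+", length = fwd$length, stringsAsFactors = FALSE)
      }
      if (both_strands) {
        rv <- .find_mems_cpp(qrc, rseq, as.integer(min_length))
        if (nrow(rv)) {
          out[[length(out) + 1L]] <- data.frame(
            q_id = qname, r_id = rname,
            q_start = qlen - (rv$q_start + rv$length),
            q_end = qlen - rv$q_start,
            r_start = rv$r_start, r_end = rv$r_start + rv$length,
            strand = "-", length = rv$length, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_mems())
  res <- do.call(rbind, out)
  res[order(res$r_id, res$r_start, res$q_id, res$q_start), , drop = FALSE]
}

# Greedy gap-free extension outward from a block edge. Walks up to the
# sequence boundaries scoring match +1 / mismatch -3, stops when the score
# drops `xdrop` below its running maximum, and trims back to the maximum.
# Returns the op characters ("=", "X") in walk order.
greedy_extend <- function(qseq, rseq, qpos, rpos, dir, xdrop = 12L) {
  qn <- nchar(qseq); rn <- nchar(rseq)
  steps <- if (dir > 0) min(qn - qpos, rn - rpos) else min(qpos, rpos)
  if (steps <= 0) return(character(0))
  steps <- min(steps, 2000L)
  if (dir > 0) {
    qs <- substr(qseq, qpos + 1L, qpos + steps)
    rs <- substr(rseq, rpos + 1L, rpos + steps)
  } else {
    qs <- substr(qseq, qpos - steps + 1L, qpos)
    rs <- substr(rseq, rpos - steps + 1L, rpos)
  }
  qv <- strsplit(qs, "")[[1]]; rv <- strsplit(rs, "")[[1]]
  if (dir < 0) { qv <- rev(qv); rv <- rev(rv) }
  eq <- qv == rv & qv %in% c("A", "C", "G", "T")
  sc <- cumsum(ifelse(eq, 1L, -3L))
  runmax <- cummax(sc)
  stop_at <- which(runmax - sc >= xdrop)
  lim <- if (length(stop_at)) stop_at[1] else length(eq)
  best <- which.max(sc[seq_len(lim)])
  if (!length(best) || sc[best] <= 0) return(character(0))
  ifelse(eq[seq_len(best)], "=", "X")
}

# Chain anchors and build gapped blocks for a single (query sequence,
# reference sequence, strand) combination. Anchors arrive in alignment
# space: for minus-strand matches the query coordinates refer to the
# reverse complement of the query sequence.
chain_one <- function(anchors, qseq_aln, rseq, max_join_gap, min_anchor,
                      gap_cells_max, polish_max, extend_ends, xdrop = 12L) {
  n <- nrow(anchors)
  if (n == 0) return(list())
  anchors <- anchors[order(anchors$aq_start, anchors$ar_start), , drop = FALSE]
  aqs <- anchors$aq_start; aqe <- anchors$aq_start + anchors$length
  ars <- anchors$ar_start; are <- anchors$ar_start + anchors$length
  len <- anchors$length
  # one chaining DP over all anchors; chains are then peeled off in order
  # of decreasing score, truncating at anchors already consumed
  dp <- as.numeric(len)
  prev <- rep(0L, n)
  if (n > 1) {
    for (k in 2:n) {
      js <- seq_len(k - 1)
      qg <- aqs[k] - aqe[js]
      rg <- ars[k] - are[js]
      ok <- aqe[k] > aqe[js] & are[k] > are[js] &
        qg <= max_join_gap & rg <= max_join_gap &
        qg > -len[k] & rg > -len[k]
      if (any(ok)) {
        # gap cost is kept subadditive in the asymmetric part so that two
        # nearby structural events (a deletion and an insertion separated
        # by anchored sequence) chain through the anchors between them
        # rather than skipping them into one smeared gap
        pen <- 4 + 0.05 * pmax(pmax(qg, 0), pmax(rg, 0)) +
          0.05 * abs(pmax(qg, 0) - pmax(rg, 0))
        cand <- dp[js] + len[k] - pen
        cand[!ok] <- -Inf
        best <- which.max(cand)
        if (cand[best] > dp[k]) { dp[k] <- cand[best]; prev[k] <- best }
      }
    }
  }
  used <- rep(FALSE, n)
  chains <- list()
  for (k in order(-dp, aqs)) {
    if (used[k]) next
    chain <- k
    while (prev[chain[1]] > 0L && !used[prev[chain[1]]])
      chain <- c(prev[chain[1]], chain)
    used[chain] <- TRUE
    if (sum(len[chain]) >= min_anchor)
      chains[[length(chains) + 1L]] <- chain
  }

  blocks <- list()
  for (chain in chains) {
    # trim anchor overlaps
    caqs <- aqs[chain]; caqe <- aqe[chain]; cars <- ars[chain]; care <- are[chain]
    if (length(chain) > 1) {
      for (k in 2:length(chain)) {
        t <- max(caqe[k - 1] - caqs[k], care[k - 1] - cars[k], 0L)
        caqs[k] <- caqs[k] + t; cars[k] <- cars[k] + t
      }
    }
    segs <- list()   # list of op character vectors
    seg_start_q <- caqs[1]; seg_start_r <- cars[1]
    cur_q <- caqs[1]; cur_r <- cars[1]
    flush_block <- function(end_q, end_r) {
      ops <- unlist(segs, use.names = FALSE)
      if (!length(ops)) return(NULL)
      list(aq_start = seg_start_q, aq_end = end_q,
           r_start = seg_start_r, r_end = end_r, ops = ops)
    }
    for (k in seq_along(chain)) {
      if (k > 1) {
        qgap <- caqs[k] - cur_q; rgap <- cars[k] - cur_r
        if (qgap == 0 && rgap == 0) {
          # nothing to fill
        } else if (qgap == 0) {
          segs[[length(segs) + 1L]] <- rep("D", rgap)
        } else if (rgap == 0) {
          segs[[length(segs) + 1L]] <- rep("I", qgap)
        } else if (as.double(qgap) * as.double(rgap) <= gap_cells_max) {
          al <- .edit_align_cpp(substr(qseq_aln, cur_q + 1L, cur_q + qgap),
                                substr(rseq, cur_r + 1L, cur_r + rgap))
          ops <- strsplit(al$ops, "")[[1]]
          # unrelated gap sides (random DNA aligns at ~0.56 matches per
          # position under unit cost) are represented as one clean
          # deletion+insertion instead of a smear of spurious matches
          if (min(qgap, rgap) > 50 &&
              sum(ops == "=") < 0.75 * min(qgap, rgap)) {
            ops <- c(rep("D", rgap), rep("I", qgap))
          }
          segs[[length(segs) + 1L]] <- ops
        } else {
          # band overflow: split the block at this junction
          b <- flush_block(cur_q, cur_r)
          if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
          segs <- list()
          seg_start_q <- caqs[k]; seg_start_r <- cars[k]
        }
      }
      segs[[length(segs) + 1L]] <- rep("=", caqe[k] - caqs[k])
      cur_q <- caqe[k]; cur_r <- care[k]
    }
    b <- flush_block(cur_q, cur_r)
    if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  }

  # end extension and polish
  qn <- nchar(qseq_aln); rn <- nchar(rseq)
  out <- list()
  for (b in blocks) {
    if (extend_ends) {
      left <- greedy_extend(qseq_aln, rseq, b$aq_start, b$r_start, -1L, xdrop)
      if (length(left)) {
        b$aq_start <- b$aq_start - length(left)
        b$r_start <- b$r_start - length(left)
        b$ops <- c(rev(left), b$ops)
      }
      right <- greedy_extend(qseq_aln, rseq, b$aq_end, b$r_end, +1L, xdrop)
      if (length(right)) {
        b$aq_end <- b$aq_end + length(right)
        b$r_end <- b$r_end + length(right)
        b$ops <- c(b$ops, right)
      }
    }
    qspan <- b$aq_end - b$aq_start; rspan <- b$r_end - b$r_start
    if (as.double(qspan) * as.double(rspan) <= polish_max && qspan > 0 && rspan > 0) {
      al <- .edit_align_cpp(substr(qseq_aln, b$aq_start + 1L, b$aq_end),
                            substr(rseq, b$r_start + 1L, b$r_end))
      b$ops <- strsplit(al$ops, "")[[1]]
    }
    out[[length(out) + 1L]] <- b
  }
  out
}

#' Chain exact matches into gapped alignment blocks
#'
#' Collinear same-strand matches within `max_join_gap` are chained
#' (maximizing anchored length under an affine-style gap penalty, ties
#' resolved deterministically by coordinate order); inter-anchor gaps are
#' closed by exact unit-cost alignment; block ends are extended by greedy
#' gap-free walks; blocks small enough are re-polished by full dynamic
#' programming so their edit paths are optimal. A gap too large to close
#' splits the block at that junction.
#'
#' @param mems data.frame from [find_mems()]
#' @param query,reference the sequences the matches were found on
#' @param max_join_gap largest query/reference gap joined within one block
#' @param min_anchor minimum total anchored length for a chain to be kept
#' @param gap_cells_max largest `qgap * rgap` closed exactly before the
#'   block is split instead
#' @param polish_max largest `qspan * rspan` for which the whole block edit
#'   path is recomputed by full dynamic programming
#' @param extend_ends extend block ends by greedy gap-free walks
#' @return data.frame of alignment blocks with CIGAR-style edit paths over
#'   `{=, X, I, D}` and identity = matches / aligned columns; the
#'   `ambiguous` flag is NA until [flag_ambiguity()] is applied
#' @export
chain_and_extend <- function(mems, query, reference, max_join_gap = 10000L,
                             min_anchor = 20L, gap_cells_max = 2.5e7,
                             polish_max = 4e6, extend_ends = TRUE,
                             struct_gap = 90L) {
  query <- as_seq_set(query); reference <- as_seq_set(reference)
  if (nrow(mems) == 0) return(empty_blocks())
  out <- list()
  combos <- unique(mems[, c("q_id", "r_id", "strand")])
  for (i in seq_len(nrow(combos))) {
    qid <- combos$q_id[i]; rid <- combos$r_id[i]; strand <- combos$strand[i]
    sub <- mems[mems$q_id == qid & mems$r_id == rid & mems$strand == strand, , drop = FALSE]
    qseq <- as.character(query[[qid]])
    rseq <- as.character(reference[[rid]])
    qlen <- nchar(qseq)
    if (strand == "+") {
      anchors <- data.frame(aq_start = sub$q_start, ar_start = sub$r_start,
                            length = sub$length)
      qseq_aln <- qseq
    } else {
      anchors <- data.frame(aq_start = qlen - sub$q_end, ar_start = sub$r_start,
                            length = sub$length)
      qseq_aln <- revcomp(qseq)
    }
    bl <- chain_one(anchors, qseq_aln, rseq, max_join_gap, min_anchor,
                    gap_cells_max, polish_max, extend_ends)
    for (b in bl) {
      cig <- ops_to_cigar(b$ops)
      nmatch <- sum(b$ops == "=")
      ncol <- length(b$ops)
      if (strand == "+") {
        qs <- b$aq_start; qe <- b$aq_end
      } else {
        qs <- qlen - b$aq_end; qe <- qlen - b$aq_start
      }
      out[[length(out) + 1L]] <- data.frame(
        q_id = qid, q_start = qs, q_end = qe,
        r_id = rid, r_start = b$r_start, r_end = b$r_end,
        strand = strand, cigar = cig,
        identity = cigar_identity(cig, struct_gap),
        matches = nmatch, columns = ncol,
        ambiguous = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_blocks())
  res <- do.call(rbind, out)
  # drop blocks whose query AND reference intervals both lie inside a
  # larger same-strand block: redundant re-alignments of self-similar
  # sequence (tandem arrays aligned at a unit shift and the like)
  keep <- rep(TRUE, nrow(res))
  for (gi in split(seq_len(nrow(res)),
                   paste(res$q_id, res$r_id, res$strand))) {
    if (length(gi) < 2) next
    gi <- gi[order(-res$columns[gi])]
    for (a in seq_along(gi)[-length(gi)]) {
      ia <- gi[a]
      if (!keep[ia]) next
      for (b2 in (a + 1):length(gi)) {
        ib <- gi[b2]
        if (!keep[ib]) next
        if (res$q_start[ib] >= res$q_start[ia] && res$q_end[ib] <= res$q_end[ia] &&
            res$r_start[ib] >= res$r_start[ia] && res$r_end[ib] <= res$r_end[ia])
          keep[ib] <- FALSE
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$r_id, res$r_start, res$q_id, res$q_start), , drop = FALSE]
  res$block_id <- sprintf("b%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  # invariant: edit path consumes exactly the two intervals
  for (i in seq_len(nrow(res))) {
    cons <- cigar_consumed(res$cigar[i])
    stopifnot(cons$query == res$q_end[i] - res$q_start[i],
              cons$ref == res$r_end[i] - res$r_start[i])
  }
  res
}

empty_blocks <- function() {
  data.frame(q_id = character(0), q_start = integer(0), q_end = integer(0),
             r_id = character(0), r_start = integer(0), r_end = integer(0),
             strand = character(0), cigar = character(0), identity = numeric(0),
             matches = integer(0), columns = integer(0), ambiguous = logical(0),
             block_id = character(0), stringsAsFactors = FALSE)
}

#' Flag alignment blocks with ambiguous query mapping
#'
#' A block is ambiguous when more than half of its query interval is also
#' covered by other blocks of identity at least `min_identity` (query-side
#' definition: competing placements of the same assembly sequence). Nothing
#' is removed; downstream callers decide what to do with ambiguous blocks.
#'
#' @param blocks data.frame from [chain_and_extend()]
#' @param min_identity competing blocks below this identity are ignored
#' @return `blocks` with the `ambiguous` flag filled in
#' @export
flag_ambiguity <- function(blocks, min_identity = 0.95) {
  if (nrow(blocks) == 0) return(blocks)
  blocks$ambiguous <- FALSE
  for (qid in unique(blocks$q_id)) {
    sel <- which(blocks$q_id == qid)
    if (length(sel) < 2) next
    ir <- IRanges::IRanges(start = blocks$q_start[sel] + 1L, end = blocks$q_end[sel])
    for (k in seq_along(sel)) {
      others <- sel[-k][blocks$identity[sel[-k]] >= min_identity]
      if (!length(others)) next
      oir <- IRanges::reduce(IRanges::IRanges(start = blocks$q_start[others] + 1L,
                                              end = blocks$q_end[others]))
      cov <- sum(IRanges::width(IRanges::intersect(ir[k], oir)))
      w <- blocks$q_end[sel[k]] - blocks$q_start[sel[k]]
      if (w > 0 && cov / w > 0.5) blocks$ambiguous[sel[k]] <- TRUE
    }
  }
  blocks
}

#' Align a query genome (or contig set) to a reference genome
#'
#' Runs [find_mems()], [chain_and_extend()] and [flag_ambiguity()] over all
#' sequence pairs and returns one table of alignment blocks.
#'
#' @inheritParams find_mems
#' @inheritParams chain_and_extend
#' @param ambiguity_identity identity threshold for [flag_ambiguity()]
#' @return alignment block data.frame
#' @export
align_genomes <- function(query, reference, min_length = 20L,
                          both_strands = TRUE, max_join_gap = 10000L,
                          min_anchor = 100L, gap_cells_max = 2.5e7,
                          polish_max = 4e6, extend_ends = TRUE,
                          ambiguity_identity = 0.95) {
  query <- as_seq_set(query); reference <- as_seq_set(reference)
  mems <- find_mems(query, reference, min_length, both_strands)
  blocks <- chain_and_extend(mems, query, reference, max_join_gap, min_anchor,
                             gap_cells_max, polish_max, extend_ends)
  flag_ambiguity(blocks, ambiguity_identity)
}

#' Globally align two sequences through the anchored pipeline
#'
#' Convenience wrapper for pairwise comparison: seeds with MEMs, chains,
#' and forces the resulting block to span both sequences end to end (the
#' ends are closed by exact dynamic programming). Small problems are
#' polished exactly, so the returned edit distance is the true optimum for
#' sequences whose size product is below `polish_max`.
#'
#' @param a,b sequences (character or DNAString)
#' @param min_mem MEM seed length
#' @param polish_max see [chain_and_extend()]
#' @return list with `cigar`, `identity`, `distance` (unit-cost edit
#'   distance of the path), `matches`, `columns`
#' @export
align_pair <- function(a, b, min_mem = 12L, polish_max = 4e6) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  na <- nchar(a); nb <- nchar(b)
  if (as.double(na) * as.double(nb) <= polish_max) {
    al <- .edit_align_cpp(a, b)
    ops <- strsplit(al$ops, "")[[1]]
    return(list(cigar = ops_to_cigar(ops),
                identity = sum(ops == "=") / length(ops),
                distance = al$distance,
                matches = sum(ops == "="), columns = length(ops)))
  }
  mems <- find_mems(a, b, min_length = max(10L, min_mem), both_strands = FALSE)
  blocks <- chain_and_extend(mems, Biostrings::DNAStringSet(c(seq1 = a)),
                             Biostrings::DNAStringSet(c(seq1 = b)),
                             min_anchor = max(10L, min_mem),
                             polish_max = polish_max)
  if (nrow(blocks) == 0) stop("sequences share no usable anchor")
  best <- blocks[which.max(blocks$matches), ]
  runs <- cigar_runs(best$cigar)
  dist <- sum(runs$len[runs$op != "="]) +
    best$q_start + (nchar(a) - best$q_end) +
    best$r_start + (nchar(b) - best$r_end)
  list(cigar = best$cigar, identity = best$identity, distance = dist,
       matches = best$matches, columns = best$columns)
}

#' Detect repetitive regions by genome self-alignment
#'
#' Aligns the genome against itself, discards the trivial self-match, and
#' reports region/partner pairs above the identity cut-off (the repeat
#' definition used for the unassembled-gap label). Output is symmetric: if
#' A partners B then B partners A.
#'
#' @param genome DNAStringSet
#' @param min_identity strict lower bound on pair identity (default 0.95)
#' @param min_length minimum repeat length in bp
#' @param min_mem MEM seed length
#' @return data.frame (seqid, start, end, partner_seqid, partner_start,
#'   partner_end, strand, identity)
#' @export
self_repeats <- function(genome, min_identity = 0.95, min_length = 500L,
                         min_mem = 20L) {
  genome <- as_seq_set(genome)
  mems <- find_mems(genome, genome, min_length = min_mem, both_strands = TRUE)
  # drop the trivial full-length self-diagonal
  trivial <- mems$q_id == mems$r_id & mems$strand == "+" &
    mems$q_start == mems$r_start
  mems <- mems[!trivial, , drop = FALSE]
  blocks <- chain_and_extend(mems, genome, genome, max_join_gap = 2000L,
                             min_anchor = min_mem)
  blocks <- blocks[blocks$identity > min_identity &
                     (blocks$r_end - blocks$r_start) >= min_length &
                     !(blocks$q_id == blocks$r_id & blocks$strand == "+" &
                         blocks$q_start == blocks$r_start), , drop = FALSE]
  if (nrow(blocks) == 0)
    return(data.frame(seqid = character(0), start = integer(0), end = integer(0),
                      partner_seqid = character(0), partner_start = integer(0),
                      partner_end = integer(0), strand = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  fwd <- data.frame(seqid = blocks$r_id, start = blocks$r_start, end = blocks$r_end,
                    partner_seqid = blocks$q_id, partner_start = blocks$q_start,
                    partner_end = blocks$q_end, strand = blocks$strand,
                    identity = blocks$identity, stringsAsFactors = FALSE)
  bwd <- data.frame(seqid = blocks$q_id, start = blocks$q_start, end = blocks$q_end,
                    partner_seqid = blocks$r_id, partner_start = blocks$r_start,
                    partner_end = blocks$r_end, strand = blocks$strand,
                    identity = blocks$identity, stringsAsFactors = FALSE)
  out <- rbind(fwd, bwd)
  out <- out[!(out$seqid == out$partner_seqid & out$start == out$partner_start &
                 out$end == out$partner_end), , drop = FALSE]
  out <- unique(out)
  out[order(out$seqid, out$start), , drop = FALSE]
}
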