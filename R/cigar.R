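# Edit-path (CIGAR) helpers. Paths are run-length encoded strings over
# {=, X, I, D}: '=' match, 'X' mismatch, 'I' insertion relative to the
# reference (consumes query), 'D' deletion (consumes reference).

#' Parse a CIGAR-style edit path into run lengths and operations
#' @param cigar character scalar like "120=1X45=3D"
#' @return data.frame with columns `len`, `op`
#' @keywords internal
cigar_runs <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  stopifnot(length(lens) == length(ops))
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

#' Run-length encode an expanded op vector into a CIGAR string
#' @keywords internal
ops_to_cigar <- function(ops) {
  if (length(ops) == 0) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Lengths consumed by an edit path
#' @return list(query=, ref=, columns=, matches=)
#' @keywords internal
cigar_consumed <- function(cigar) {
  r <- cigar_runs(cigar)
  q <- sum(r$len[r$op %in% c("=", "X", "I")])
  ref <- sum(r$len[r$op %in% c("=", "X", "D")])
  list(query = q, ref = ref, columns = sum(r$len),
       matches = sum(r$len[r$op == "="]))
}

#' Identity recomputed from an edit path
#'
#' Identity is matches / aligned columns, where gap runs longer than
#' `struct_gap` (structural events, not alignment noise) are excluded from
#' the denominator so that a block spanning, say, a transposon-sized
#' deletion is not dominated by it.
#' @keywords internal
cigar_identity <- function(cigar, struct_gap = 90L) {
  r <- cigar_runs(cigar)
  if (nrow(r) == 0) return(NA_real_)
  big <- r$op %in% c("I", "D") & r$len > struct_gap
  n <- sum(r$len[!big])
  if (n == 0) return(NA_real_)
  sum(r$len[r$op == "="]) / n
}

# Per-column table of an edit path: for each column its op, the 0-based
# offsets into the (alignment-orientation) query and reference intervals
# (NA where the op does not consume that side).
cigar_columns <- function(cigar) {
  r <- cigar_runs(cigar)
  op <- rep(r$op, r$len)
  dq <- op %in% c("=", "X", "I")
  dr <- op %in% c("=", "X", "D")
  qo <- rep(NA_integer_, length(op))
  ro <- rep(NA_integer_, length(op))
  qo[dq] <- seq_len(sum(dq)) - 1L
  ro[dr] <- seq_len(sum(dr)) - 1L
  data.frame(op = op, q_off = qo, r_off = ro, stringsAsFactors = FALSE)
}

# Reference offsets (0-based, within the block's reference interval) whose
# column is a match.
cigar_ref_match_offsets <- function(cigar) {
  cc <- cigar_columns(cigar)
  cc$r_off[cc$op == "="]
}

# Map reference offsets to query offsets within a block (both 0-based in
# alignment orientation). Deleted reference positions map to NA.
cigar_ref_to_query <- function(cigar) {
  cc <- cigar_columns(cigar)
  keep <- !is.na(cc$r_off)
  q <- cc$q_off[keep]
  names(q) <- NULL
  q # indexed by r_off + 1
}
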