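`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a derived random seed, restoring RNG state
#'
#' Each simulator stage draws from its own sub-stream derived from the plan
#' seed, so stages can be regenerated independently and determinism holds.
#'
#' @param seed integer base seed
#' @param offset integer stage offset
#' @param expr expression to evaluate
#' @keywords internal
with_subseed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483647L)
  expr
}

#' Sample random DNA
#' @param n length in bp
#' @return character scalar
#' @keywords internal
random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a character sequence
#' @keywords internal
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# fraction of interval [s1,e1) covered by [s2,e2), half-open
overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# merge sorted half-open intervals closer than max_gap; df with start/end
merge_intervals <- function(start, end, max_gap = 0L) {
  if (length(start) == 0) return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + max_gap) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
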