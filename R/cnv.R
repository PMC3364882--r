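# Windowed depth-of-coverage log2-ratio analysis between two strains:
# library-size scaling, per-chromosome normalization, a Geary-Hinkley
# ratio test per window, and segment calling above the |log2| = 0.6 cut.

#' Aggregate a depth track into fixed windows
#'
#' Windows tile each chromosome from its start; the last (partial) window
#' keeps its true width. Track mass overlapping a window is assigned
#' proportionally, so the total count is conserved exactly.
#'
#' @param track depth track (seqid, start, end, count)
#' @param seqlens named chromosome lengths
#' @param window window width in bp (>= 50)
#' @return data.frame (seqid, start, end, width, count)
#' @export
window_counts <- function(track, seqlens, window = 414L) {
  if (window < 50) stop("window must be >= 50")
  unknown <- setdiff(unique(track$seqid), names(seqlens))
  if (length(unknown)) stop("track names a sequence not in the genome: ", unknown[1])
  out <- lapply(names(seqlens), function(chrom) {
    len <- seqlens[[chrom]]
    starts <- seq(0L, len - 1L, by = window)
    ends <- pmin(starts + window, len)
    counts <- numeric(length(starts))
    tr <- track[track$seqid == chrom, , drop = FALSE]
    if (nrow(tr)) {
      for (i in seq_len(nrow(tr))) {
        w <- tr$end[i] - tr$start[i]
        if (w <= 0) next
        first <- tr$start[i] %/% window + 1L
        last <- min((tr$end[i] - 1L) %/% window + 1L, length(starts))
        idx <- first:last
        ov <- overlap_len(starts[idx], ends[idx], tr$start[i], tr$end[i])
        counts[idx] <- counts[idx] + tr$count[i] * ov / w
      }
    }
    data.frame(seqid = chrom, start = starts, end = ends,
               width = ends - starts, count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Geary-Hinkley two-sided p-value for a depth ratio window
#'
#' Tests the null that the scaled test/reference count ratio is `r0`,
#' treating both counts as Poisson (variance = mean) and applying the
#' Geary-Hinkley transformation of a Gaussian ratio to an approximately
#' standard normal statistic: `t = (x - r0 R y) / sqrt(x + r0^2 R^2 y)`,
#' with `R = total_test / total_ref`.
#'
#' @param x,y window counts for the test and reference strains
#' @param total_x,total_y library sizes
#' @param r0 null ratio (default 1)
#' @return list(p=, t=, flagged=) where `flagged` marks windows computed
#'   against a 0.5 pseudo-count because y was zero
#' @export
window_pvalue <- function(x, y, total_x, total_y, r0 = 1) {
  if (total_x <= 0 || total_y <= 0) stop("library totals must be positive")
  flagged <- y == 0
  y <- ifelse(flagged, 0.5, y)
  R <- total_x / total_y
  t <- (x - r0 * R * y) / sqrt(x + r0^2 * R^2 * y)
  t[x == 0 & y == 0] <- 0
  p <- 2 * (1 - stats::pnorm(abs(t)))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(p = p, t = t, flagged = flagged)
}

#' Compute the normalized log2 depth-ratio track
#'
#' Window ratios are computed after library-size scaling and then
#' normalized to an average ratio of 1 per chromosome. The default
#' (`"geometric"`) divides by the per-chromosome geometric mean ratio,
#' which keeps gain/loss symmetry exact: swapping the two tracks negates
#' every log2 ratio. `"arithmetic"` divides by the arithmetic mean ratio;
#' `"depth"` scales each depth track to a per-chromosome mean of 1 before
#' taking the ratio. Windows with a zero count on either side are flagged
#' and excluded from the normalization mean. A Geary-Hinkley p-value is
#' attached per window.
#'
#' @param test,ref window count tables on identical tilings (from
#'   [window_counts()] or [simulate_depth()])
#' @param normalization "geometric", "arithmetic" or "depth"
#' @return data.frame with ratio, log2_ratio, p_value, ref_zero columns
#' @export
log2_ratio_track <- function(test, ref,
                             normalization = c("geometric", "arithmetic", "depth")) {
  normalization <- match.arg(normalization)
  if (nrow(test) != nrow(ref) || any(test$start != ref$start) ||
      any(test$seqid != ref$seqid))
    stop("test and reference tracks must share one tiling")
  tot_t <- sum(test$count); tot_r <- sum(ref$count)
  out <- test[, c("seqid", "start", "end", "width")]
  out$count_test <- test$count
  out$count_ref <- ref$count
  out$ref_zero <- ref$count == 0
  out$ratio <- NA_real_
  for (chrom in unique(out$seqid)) {
    sel <- out$seqid == chrom
    x <- test$count[sel]; y <- ref$count[sel]
    if (all(y == 0)) {
      warning("all-zero reference depth on ", chrom, "; chromosome skipped")
      next
    }
    if (normalization %in% c("geometric", "arithmetic")) {
      raw <- (x / tot_t) / (y / tot_r)
      use <- x > 0 & y > 0
      m <- if (!any(use)) 1 else if (normalization == "geometric")
        exp(mean(log(raw[use]))) else mean(raw[use])
      out$ratio[sel] <- raw / m
    } else {
      xs <- x / mean(x)
      ys <- y / mean(y)
      out$ratio[sel] <- xs / ys
    }
  }
  out$log2_ratio <- log2(out$ratio)
  pv <- window_pvalue(out$count_test, out$count_ref, tot_t, tot_r)
  out$p_value <- pv$p
  out
}

#' Call copy-number segments from a log2-ratio track
#'
#' Maximal runs of at least `min_windows` consecutive windows with
#' `|log2| >= threshold` and consistent sign become segments; runs of the
#' same sign separated by at most `max_bridge` sub-threshold windows are
#' merged (window-level Poisson noise routinely drops single interior
#' windows below the cut). Window p-values are combined by Fisher's
#' method. Infinite log2 ratios (zero counts) enter the segment mean at
#' the display cap of -4/+4.
#'
#' @param windows from [log2_ratio_track()]
#' @param threshold absolute log2-ratio cut-off (default 0.6)
#' @param min_windows minimum qualifying run length (default 3)
#' @param max_bridge most sub-threshold windows bridged between same-sign
#'   runs (default 1; 0 restores strict runs)
#' @param genes optional gene table to annotate overlapping genes
#' @return data.frame of segments (seqid, start, end, n_windows, direction,
#'   mean_log2, p_value, genes)
#' @export
call_segments <- function(windows, threshold = 0.6, min_windows = 3L,
                          max_bridge = 1L, genes = NULL) {
  segs <- list()
  for (chrom in unique(windows$seqid)) {
    w <- windows[windows$seqid == chrom, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    lg <- w$log2_ratio
    state <- ifelse(is.na(lg), 0L, ifelse(lg >= threshold, 1L,
                                          ifelse(lg <= -threshold, -1L, 0L)))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hit <- which(r$values != 0L)
    if (!length(hit)) next
    # group same-sign runs across short neutral interruptions; a group
    # qualifies when its runs together hold >= min_windows windows
    groups <- list()
    cur <- hit[1]
    if (length(hit) > 1) {
      for (h in hit[-1]) {
        prev <- cur[length(cur)]
        between <- seq_len(length(r$values))
        between <- between[between > prev & between < h]
        gap_w <- sum(r$lengths[between])
        same <- r$values[h] == r$values[prev]
        neutral <- all(r$values[between] == 0L)
        if (same && neutral && gap_w <= max_bridge) cur <- c(cur, h)
        else { groups[[length(groups) + 1L]] <- cur; cur <- h }
      }
    }
    groups[[length(groups) + 1L]] <- cur
    groups <- Filter(function(g) sum(r$lengths[g]) >= min_windows, groups)
    for (grp in groups) {
      idx <- starts[grp[1]]:ends[grp[length(grp)]]
      lgc <- pmin(pmax(lg[idx], -4), 4)
      pc <- pmin(pmax(w$p_value[idx], .Machine$double.xmin), 1)
      fisher <- stats::pchisq(-2 * sum(log(pc)), df = 2 * length(pc),
                              lower.tail = FALSE)
      gs <- w$start[idx[1]]; ge <- w$end[idx[length(idx)]]
      glist <- ""
      if (!is.null(genes)) {
        gg <- genes[genes$seqid == chrom & genes$start < ge & genes$end > gs, ]
        glist <- paste(gg$gene_id, collapse = ",")
      }
      segs[[length(segs) + 1L]] <- data.frame(
        seqid = chrom, start = gs, end = ge, n_windows = length(idx),
        direction = if (r$values[grp[1]] > 0) "gain" else "loss",
        mean_log2 = mean(lgc), p_value = fisher, genes = glist,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(seqid = character(0), start = integer(0), end = integer(0),
                      n_windows = integer(0), direction = character(0),
                      mean_log2 = numeric(0), p_value = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

#' Write a log2-ratio track as TSV, capping displayed log2 ratios
#'
#' The -4 display cap applies only here, at serialization: in-memory
#' statistics are never capped.
#'
#' @param windows from [log2_ratio_track()]
#' @param path output path
#' @param cap display cap for |log2| (default 4)
#' @export
write_cnv_track <- function(windows, path, cap = 4) {
  w <- windows
  w$log2_ratio <- pmin(pmax(w$log2_ratio, -cap), cap)
  write_tsv(w, path)
}
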