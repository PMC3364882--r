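# Mosaic genome painting against grouped strain panels, whole-genome
# coverage distances, and UPGMA trees.

# per-query-base match indicator against one panel genome. Each query
# position takes its match status from the best (highest-identity) block
# covering it, so secondary self-similar alignments cannot inflate
# fragment identity.
query_match_vector <- function(query, genome, min_mem = 20L,
                               min_identity = 0, ...) {
  query <- as_seq_set(query)
  genome <- as_seq_set(genome)
  blocks <- align_genomes(query, genome, min_length = min_mem, ...)
  blocks <- blocks[blocks$identity >= min_identity, , drop = FALSE]
  out <- lapply(setNames(Biostrings::width(query), names(query)), logical)
  assigned <- lapply(setNames(Biostrings::width(query), names(query)), logical)
  if (nrow(blocks) == 0) return(out)
  for (i in order(-blocks$identity, blocks$block_id)) {
    b <- blocks[i, ]
    cc <- cigar_columns(b$cigar)
    cc <- cc[!is.na(cc$q_off), , drop = FALSE]
    qpos <- if (b$strand == "+") b$q_start + cc$q_off else b$q_end - 1L - cc$q_off
    a <- assigned[[b$q_id]]
    new <- !a[qpos + 1L]
    a[qpos + 1L] <- TRUE
    assigned[[b$q_id]] <- a
    v <- out[[b$q_id]]
    v[qpos[new] + 1L] <- cc$op[new] == "="
    out[[b$q_id]] <- v
  }
  out
}

#' Paint a query genome by identity against grouped strain panels
#'
#' The query is divided into non-overlapping fragments (1000 bp by
#' default). Per fragment and group, the best identity across the group's
#' genomes (matching positions / fragment width) becomes a colour channel
#' after linear scaling: identity at or below `lo` (0.97) maps to 0,
#' identity `hi` (1.00) maps to 1.
#'
#' @param query query genome (DNAStringSet)
#' @param panel named list of panel genomes
#' @param group_map data.frame (strain, group)
#' @param fragment fragment width in bp (>= 100)
#' @param lo,hi identity endpoints of the channel scaling
#' @param min_mem MEM seed length
#' @return data.frame with one row per fragment: identity_<group> and
#'   channel_<group> columns
#' @export
paint_mosaic <- function(query, panel, group_map, fragment = 1000L,
                         lo = 0.97, hi = 1.00, min_mem = 20L) {
  if (fragment < 100) stop("fragment size must be >= 100")
  if (!length(panel)) stop("panel must contain at least one genome")
  query <- as_seq_set(query)
  groups <- unique(group_map$group)
  frags <- do.call(rbind, lapply(names(query), function(chrom) {
    len <- Biostrings::width(query[names(query) == chrom])[1]
    starts <- seq(0L, len - 1L, by = fragment)
    data.frame(seqid = chrom, start = starts,
               end = pmin(starts + fragment, len), stringsAsFactors = FALSE)
  }))
  best <- matrix(0, nrow = nrow(frags), ncol = length(groups),
                 dimnames = list(NULL, groups))
  for (strain in names(panel)) {
    grp <- group_map$group[match(strain, group_map$strain)]
    if (is.na(grp)) next
    mv <- query_match_vector(query, panel[[strain]], min_mem = min_mem)
    ids <- vapply(seq_len(nrow(frags)), function(i) {
      v <- mv[[frags$seqid[i]]]
      sum(v[(frags$start[i] + 1L):frags$end[i]]) / (frags$end[i] - frags$start[i])
    }, numeric(1))
    best[, grp] <- pmax(best[, grp], ids)
  }
  for (g in groups) {
    frags[[paste0("identity_", g)]] <- best[, g]
    frags[[paste0("channel_", g)]] <- pmin(pmax((best[, g] - lo) / (hi - lo), 0), 1)
  }
  frags
}

#' Whole-genome coverage distance between two genomes
#'
#' `d = 1 - 2 C / (|A| + |B|)`, where C is the genome span that is
#' reciprocally alignable and identical: each genome is aligned against
#' the other, every position takes its state from the best block covering
#' it (blocks below `min_identity` are ignored), and C averages the two
#' matched-position totals. Identical genomes give 0; genomes sharing no
#' alignable segment give 1, and the distance grows smoothly with
#' substitution divergence in between. This is one concrete reading of a
#' coverage-based genome distance; the identity cut and seeding are
#' parameterizable so alternatives can be swapped in.
#'
#' @param a,b genomes (DNAStringSet)
#' @param min_identity minimum block identity counted as aligned
#' @param min_mem MEM seed length
#' @return distance in `[0, 1]`
#' @export
coverage_distance <- function(a, b, min_identity = 0.90, min_mem = 20L) {
  a <- as_seq_set(a); b <- as_seq_set(b)
  matched_len <- function(q, r) {
    mv <- query_match_vector(q, r, min_mem = min_mem, min_identity = min_identity)
    sum(vapply(mv, sum, numeric(1)))
  }
  la <- sum(Biostrings::width(a)); lb <- sum(Biostrings::width(b))
  C <- (matched_len(a, b) + matched_len(b, a)) / 2
  max(0, min(1, 1 - 2 * C / (la + lb)))
}

#' Pairwise coverage-distance matrix for a set of genomes
#'
#' @param genomes named list of genomes
#' @param ... passed to [coverage_distance()]
#' @return symmetric matrix with zero diagonal
#' @export
distance_matrix <- function(genomes, ...) {
  n <- length(genomes)
  ids <- names(genomes)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- coverage_distance(genomes[[i]], genomes[[j]], ...)
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' UPGMA hierarchical clustering of a distance matrix
#'
#' Standard size-weighted (proportional) averaging; merge ties are broken
#' by the lexicographically smallest pair of cluster labels, so the output
#' is deterministic. Leaf heights are half the merge distance, giving an
#' ultrametric rooted tree.
#'
#' @param D symmetric distance matrix with zero diagonal
#' @return an [ape::phylo] tree (ultrametric, with branch lengths)
#' @export
upgma <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (any(abs(D - t(D)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  if (any(diag(D) != 0)) stop("diagonal must be zero")
  n <- nrow(D)
  if (n < 2) stop("need at least two taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  rownames(D) <- colnames(D) <- labels
  clusters <- as.list(labels)          # member labels per active cluster
  newick <- labels                     # partial newick per active cluster
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  M <- D
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      key <- sort(c(min(unlist(clusters[[i]])), min(unlist(clusters[[j]]))))
      if (is.null(best) || M[i, j] < best$d - 1e-15 ||
          (abs(M[i, j] - best$d) <= 1e-15 &&
           (key[1] < best$key[1] || (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = M[i, j], key = key)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    bi <- h - heights[i]; bj <- h - heights[j]
    nwk <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], bi, newick[j], bj)
    si <- sizes[i]; sj <- sizes[j]
    newd <- (si * M[i, ] + sj * M[j, ]) / (si + sj)
    keep <- setdiff(seq_len(m), c(i, j))
    M2 <- matrix(0, m - 1, m - 1)
    if (length(keep)) {
      M2[seq_along(keep), seq_along(keep)] <- M[keep, keep, drop = FALSE]
      M2[m - 1, seq_along(keep)] <- newd[keep]
      M2[seq_along(keep), m - 1] <- newd[keep]
    }
    M <- M2
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    newick <- c(newick[keep], nwk)
    sizes <- c(sizes[keep], si + sj)
    heights <- c(heights[keep], h)
  }
  tree <- ape::read.tree(text = paste0(newick[1], ";"))
  attr(tree, "height") <- heights[1]
  tree
}
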