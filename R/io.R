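# Readers/writers for the standard formats used across the package and the
# shared coordinate conventions. All in-memory coordinates are 0-based
# half-open; conversion to 1-based (VCF, GFF3) happens only here, at the
# serialization boundary. BED stays 0-based half-open on disk.

#' Read a FASTA file into an uppercase DNAStringSet
#'
#' Sequences are validated line by line before parsing so that malformed
#' input is reported with its line number. Lowercase (soft-masked) input is
#' preserved as an interval annotation in the `softmask` attribute and the
#' returned sequences are uppercased.
#'
#' @param path path to a plain or gzipped FASTA file
#' @return a [Biostrings::DNAStringSet]; attribute `softmask` holds a
#'   data.frame (seqid, start, end) of soft-masked intervals
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) stop("not a FASTA file (line 1): ", path)
  bad_hdr <- which(hdr & !grepl("^>\\S", lines))
  if (length(bad_hdr)) stop("malformed FASTA header at line ", bad_hdr[1])
  seq_lines <- !hdr & nzchar(lines)
  bad <- which(seq_lines & grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv]", lines))
  if (length(bad)) stop("non-IUPAC character in FASTA at line ", bad[1])
  grp <- cumsum(hdr)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  seqs <- seqs[as.character(seq_along(ids))]
  seqs[is.na(seqs)] <- ""
  if (any(!nzchar(seqs))) {
    empty <- which(!nzchar(seqs))[1]
    stop("empty sequence for record '", ids[empty], "' (header line ",
         which(hdr)[empty], ")")
  }
  mask <- do.call(rbind, lapply(seq_along(ids), function(i) {
    low <- gregexpr("[a-z]+", seqs[i])[[1]]
    if (low[1] == -1) return(NULL)
    data.frame(seqid = ids[i], start = as.integer(low) - 1L,
               end = as.integer(low) + attr(low, "match.length") - 1L)
  }))
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- ids
  attr(out, "softmask") <- mask %||%
    data.frame(seqid = character(0), start = integer(0), end = integer(0))
  out
}

#' Write sequences to FASTA
#' @param x DNAStringSet or named character vector
#' @param path output path
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Validate a genomic interval table
#'
#' Checks the 0-based half-open invariants: `0 <= start <= end` and, when
#' sequence lengths are resolvable, `end <= seqlength`.
#'
#' @param x data.frame with seqid, start, end (and optionally strand)
#' @param seqlens named integer vector of sequence lengths, or NULL
#' @return x, invisibly; stops on violation
#' @export
validate_intervals <- function(x, seqlens = NULL) {
  stopifnot(all(c("seqid", "start", "end") %in% names(x)))
  if (any(x$start < 0) || any(x$end < x$start))
    stop("invalid interval: require 0 <= start <= end")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (!is.null(seqlens)) {
    unknown <- setdiff(unique(x$seqid), names(seqlens))
    if (length(unknown)) stop("unknown sequence id: ", unknown[1])
    if (any(x$end > seqlens[as.character(x$seqid)]))
      stop("interval end exceeds sequence length")
  }
  invisible(x)
}

#' Read a BED file (0-based half-open, as on disk)
#' @param path BED path
#' @param extra_cols names for columns beyond the first three
#' @export
read_bed <- function(path, extra_cols = NULL) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("seqid", "start", "end")
  if (!is.null(extra_cols) && ncol(x) >= 3 + length(extra_cols))
    names(x)[4:(3 + length(extra_cols))] <- extra_cols
  x
}

#' Write intervals as BED (0-based half-open)
#' @param x data.frame with seqid, start, end and optional extra columns
#' @param path output path
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  first <- c("seqid", "start", "end")
  x <- x[, c(first, setdiff(names(x), first)), drop = FALSE]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a generic TSV with header
#' @export
#' @param x data.frame
#' @param path output path
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a depth track (bedGraph-style TSV: seqid, start, end, count)
#' @param path input path
#' @export
read_depth_track <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:4] <- c("seqid", "start", "end", "count")
  x
}

#' Write a depth track as bedGraph (seqid, start, end, count)
#' @param x data.frame from [simulate_depth()] or [window_counts()]
#' @param path output path
#' @export
write_depth_track <- function(x, path) {
  write.table(x[, c("seqid", "start", "end", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models to GFF3 (1-based inclusive on disk)
#'
#' @param genes data.frame with gene_id, seqid, start, end, strand
#'   (0-based half-open); an optional `cds` list-column holds per-gene
#'   data.frames of CDS intervals, otherwise the gene interval is the CDS
#' @param path output path
#' @export
write_gff3_genes <- function(genes, path) {
  validate_intervals(genes)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cds <- if (!is.null(genes$cds)) genes$cds[[i]] else
      data.frame(start = g$start, end = g$end)
    rbind(
      data.frame(seqid = g$seqid, source = "straincomp", type = "gene",
                 start = g$start + 1L, end = g$end, score = ".",
                 strand = g$strand, phase = ".",
                 attr = paste0("ID=", g$gene_id)),
      data.frame(seqid = g$seqid, source = "straincomp", type = "CDS",
                 start = cds$start + 1L, end = cds$end, score = ".",
                 strand = g$strand, phase = ".",
                 attr = paste0("ID=", g$gene_id, ".cds;Parent=", g$gene_id))
    )
  })
  out <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 into the package's 0-based representation
#' @param path GFF3 path
#' @return data.frame (gene_id, seqid, start, end, strand) with a `cds`
#'   list-column of CDS intervals sorted 5'->3'
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gdf <- as.data.frame(gr)
  genes <- gdf[gdf$type == "gene", ]
  cds <- gdf[gdf$type == "CDS", ]
  out <- data.frame(gene_id = as.character(genes$ID),
                    seqid = as.character(genes$seqnames),
                    start = genes$start - 1L, end = genes$end,
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  parent <- vapply(cds$Parent, function(p) as.character(p)[1], character(1))
  out$cds <- lapply(out$gene_id, function(id) {
    ci <- cds[parent == id, , drop = FALSE]
    ci <- ci[order(ci$start), ]
    data.frame(start = ci$start - 1L, end = ci$end)
  })
  # 5'->3' order: reverse for minus-strand genes
  minus <- out$strand == "-"
  out$cds[minus] <- lapply(out$cds[minus], function(d) d[rev(seq_len(nrow(d))), , drop = FALSE])
  out
}

#' Write variant calls as VCF 4.2
#'
#' SNVs are written as-is; indels follow the VCF anchor-base convention
#' (POS is the base before the event). INFO carries KIND, BLOCK (source
#' alignment block), TRF (tandem-repeat context flag) and, when annotation
#' is attached, EFFECT and GENE.
#'
#' @param calls data.frame from [call_variants()] (optionally annotated)
#' @param ref_seqs reference DNAStringSet (for indel anchor bases)
#' @param path output path
#' @export
write_vcf <- function(calls, ref_seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=straincomp",
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"snv, insertion or deletion\">",
    "##INFO=<ID=BLOCK,Number=1,Type=String,Description=\"source alignment block\">",
    "##INFO=<ID=TRF,Number=0,Type=Flag,Description=\"overlaps a tandem repeat locus\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"gene effect\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"overlapping gene\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) == 0) return(invisible(path))
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, ]
    chrom <- as.character(ref_seqs[[as.character(v$seqid)]])
    if (v$kind == "snv") {
      pos1 <- v$pos + 1L; ref <- v$ref; alt <- v$alt
    } else if (v$kind == "deletion") {
      a <- max(v$pos - 1L, 0L)
      anchor <- substr(chrom, a + 1L, a + 1L)
      del <- substr(chrom, v$pos + 1L, v$pos + v$length)
      pos1 <- a + 1L
      if (v$pos == 0L) { ref <- paste0(del, anchor); alt <- anchor }
      else { ref <- paste0(anchor, del); alt <- anchor }
    } else { # insertion before v$pos
      a <- max(v$pos - 1L, 0L)
      anchor <- substr(chrom, a + 1L, a + 1L)
      pos1 <- a + 1L
      if (v$pos == 0L) { ref <- anchor; alt <- paste0(v$seq, anchor) }
      else { ref <- anchor; alt <- paste0(anchor, v$seq) }
    }
    info <- paste0("KIND=", v$kind,
                   if (!is.null(v$block_id) && !is.na(v$block_id))
                     paste0(";BLOCK=", v$block_id) else "",
                   if (isTRUE(v$in_tandem_repeat)) ";TRF" else "",
                   if (!is.null(v$effect) && !is.na(v$effect))
                     paste0(";EFFECT=", v$effect) else "",
                   if (!is.null(v$gene_id) && !is.na(v$gene_id))
                     paste0(";GENE=", v$gene_id) else "")
    paste(v$seqid, pos1, ".", ref, alt, ".", "PASS", info, sep = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Read a straincomp VCF back into a call table
#' @param path VCF path
#' @return data.frame in the [call_variants()] layout
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  if (!length(body))
    return(data.frame(seqid = character(0), pos = integer(0), kind = character(0),
                      ref = character(0), alt = character(0), length = integer(0),
                      seq = character(0), block_id = character(0),
                      in_tandem_repeat = logical(0), stringsAsFactors = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  out <- lapply(f, function(v) {
    pos1 <- as.integer(v[2]); ref <- v[4]; alt <- v[5]
    info <- v[8]
    kind <- sub(".*KIND=([a-z]+).*", "\\1", info)
    blk <- if (grepl("BLOCK=", info)) sub(".*BLOCK=([^;]+).*", "\\1", info) else NA_character_
    trf <- grepl("(^|;)TRF(;|$)", info)
    if (kind == "snv") {
      data.frame(seqid = v[1], pos = pos1 - 1L, kind = kind, ref = ref, alt = alt,
                 length = 1L, seq = NA_character_, block_id = blk,
                 in_tandem_repeat = trf, stringsAsFactors = FALSE)
    } else if (kind == "deletion") {
      edge <- nchar(alt) == 1L && substr(ref, nchar(ref), nchar(ref)) == alt &&
        pos1 == 1L && substr(ref, 1L, 1L) != alt
      if (edge) { # deletion at offset 0 (anchor after)
        del <- substr(ref, 1L, nchar(ref) - 1L)
        data.frame(seqid = v[1], pos = 0L, kind = kind, ref = NA_character_,
                   alt = NA_character_, length = nchar(del), seq = del,
                   block_id = blk, in_tandem_repeat = trf, stringsAsFactors = FALSE)
      } else {
        del <- substr(ref, 2L, nchar(ref))
        data.frame(seqid = v[1], pos = pos1, kind = kind, ref = NA_character_,
                   alt = NA_character_, length = nchar(del), seq = del,
                   block_id = blk, in_tandem_repeat = trf, stringsAsFactors = FALSE)
      }
    } else {
      edge <- pos1 == 1L && substr(alt, nchar(alt), nchar(alt)) == ref
      ins <- if (edge) substr(alt, 1L, nchar(alt) - 1L) else substr(alt, 2L, nchar(alt))
      data.frame(seqid = v[1], pos = if (edge) 0L else pos1, kind = "insertion",
                 ref = NA_character_, alt = NA_character_, length = nchar(ins),
                 seq = ins, block_id = blk, in_tandem_repeat = trf,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Serialize a call collection to disk
#'
#' Dispatches on `format`: variants to VCF, interval tables to BED, general
#' tables to TSV, trees to Newick. VCF/GFF3 are written 1-based, BED 0-based
#' half-open.
#'
#' @param calls the object to write
#' @param path output path
#' @param format one of "vcf", "bed", "tsv", "gff3", "newick"
#' @param ... extra arguments (e.g. `ref_seqs` for VCF)
#' @export
serialize_calls <- function(calls, path, format = c("tsv", "vcf", "bed", "gff3", "newick"), ...) {
  format <- match.arg(format)
  switch(format,
    vcf = write_vcf(calls, path = path, ...),
    bed = write_bed(calls, path),
    tsv = write_tsv(calls, path),
    gff3 = write_gff3_genes(calls, path),
    newick = { ape::write.tree(calls, file = path); invisible(path) },
    stop("unsupported format for this call type: ", format))
}
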