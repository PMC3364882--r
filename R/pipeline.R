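# End-to-end orchestration: chains the modules in dependency order
# (align -> variants / assembly QC / CNV -> presence -> compare / enrich),
# serializes every call set, and writes a JSON run manifest with
# parameters, seeds and per-stage record counts. Reruns with the same
# configuration are byte-identical apart from file timestamps.

#' Run the full comparative pipeline
#'
#' With no input files configured, a synthetic genome pair is simulated
#' from `config$plan` (see [simulation_plan()]) and analysed end to end;
#' alternatively `reference_fasta`, `query_fasta`, `genes_gff3` and depth
#' tracks can be supplied. All stage outputs are written under
#' `config$out_dir`.
#'
#' @param config a list (or path to a YAML file) with `out_dir`, optional
#'   `seed`, optional `plan` overrides, optional input paths
#'   (`reference_fasta`, `query_fasta`, `genes_gff3`, `transposons_bed`,
#'   `depth_test`, `depth_ref`), optional `panel` (named list of FASTA
#'   paths) with `group_map`, optional `categories_tsv`, and optional
#'   per-stage `params`
#' @return invisibly, a list with all in-memory results and the manifest
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  for (key in c("reference_fasta", "query_fasta", "genes_gff3",
                "transposons_bed", "depth_test", "depth_ref", "categories_tsv")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config$", key, " does not exist: ", p)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  params <- config$params %||% list()
  counts <- list()
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      writeLines(paste("failed at stage:", name),
                 file.path(out_dir, "PARTIAL_RESULTS"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  simulate <- is.null(config$reference_fasta)
  if (simulate) {
    plan <- do.call(simulation_plan, utils::modifyList(list(seed = seed),
                                                config$plan %||% list()))
    ref <- stage("simulate", {
      r <- generate_reference(plan)
      mut <- mutate_genome(r, plan)
      asm <- fragment_assembly(mut, plan)
      list(r = r, mut = mut, asm = asm)
    })
    reference <- ref$r$seqs; genes <- ref$r$genes
    transposons <- ref$r$transposons
    contigs <- ref$asm$contigs
    truth <- ref$mut$truth
    del_iv <- rbind(truth$deletions[, c("seqid", "start", "end")],
                    truth$gene_deletions[, c("seqid", "start", "end")],
                    truth$dropouts[, c("seqid", "start", "end")],
                    data.frame(seqid = truth$transposons$seqid[truth$transposons$state == "excised"],
                               start = truth$transposons$start[truth$transposons$state == "excised"] +
                                 plan$ltr_length,
                               end = truth$transposons$end[truth$transposons$state == "excised"]))
    dup_iv <- truth$duplications[, c("seqid", "src_start", "src_end")]
    names(dup_iv) <- c("seqid", "start", "end")
    depth_test <- simulate_depth(reference, plan$depth_mean, plan$bias_strength,
                                 seed = seed + 11L, window = plan$depth_window,
                                 deleted = del_iv, duplicated = dup_iv)
    depth_ref <- simulate_depth(reference, plan$depth_mean, plan$bias_strength,
                                seed = seed + 12L, window = plan$depth_window)
    write_fasta(reference, file.path(out_dir, "reference.fasta"))
    write_fasta(contigs, file.path(out_dir, "contigs.fasta"))
    write_gff3_genes(genes, file.path(out_dir, "genes.gff3"))
  } else {
    plan <- NULL; truth <- NULL
    reference <- stage("load", read_fasta(config$reference_fasta))
    contigs <- read_fasta(config$query_fasta)
    genes <- if (!is.null(config$genes_gff3)) read_gff3_genes(config$genes_gff3) else NULL
    transposons <- if (!is.null(config$transposons_bed))
      read_bed(config$transposons_bed, c("locus_id", "family")) else NULL
    depth_test <- if (!is.null(config$depth_test)) read_depth_track(config$depth_test) else NULL
    depth_ref <- if (!is.null(config$depth_ref)) read_depth_track(config$depth_ref) else NULL
  }
  seqlens <- setNames(Biostrings::width(reference), names(reference))

  blocks <- stage("align", align_genomes(
    contigs, reference,
    min_length = params$min_mem %||% 20L,
    ambiguity_identity = params$ambiguity_identity %||% 0.95))
  counts$alignment_blocks <- nrow(blocks)
  write_tsv(blocks[, setdiff(names(blocks), "cigar")],
            file.path(out_dir, "blocks.tsv"))

  repeats <- stage("self_repeats", self_repeats(reference))
  counts$repeat_regions <- nrow(repeats)
  write_tsv(repeats, file.path(out_dir, "repeats.tsv"))

  tr_loci <- stage("tandem_repeats", detect_tandem_repeats(reference))
  big_tr <- tr_loci[tr_loci$end - tr_loci$start >= 6, , drop = FALSE]
  counts$tandem_repeat_loci <- nrow(big_tr)
  write_bed(big_tr, file.path(out_dir, "tandem_repeats.bed"))

  calls <- stage("variants", {
    v <- call_variants(blocks, contigs, reference,
                       min_identity = params$min_identity %||% 0.97,
                       max_indel = params$max_indel %||% 90L)
    annotate_variants(v, genes, big_tr, reference)
  })
  counts$snvs <- sum(calls$kind == "snv")
  counts$indels <- sum(calls$kind != "snv")
  counts$structural <- nrow(attr(calls, "structural"))
  write_vcf(calls, reference, file.path(out_dir, "variants.vcf"))

  placements <- stage("tile", tile_contigs(blocks))
  write_tsv(placements, file.path(out_dir, "placements.tsv"))
  gaps <- if (!is.null(depth_test))
    stage("gaps", classify_gaps(placements, depth_test, repeats)) else NULL
  if (!is.null(gaps)) {
    counts$gaps <- nrow(gaps)
    write_tsv(gaps, file.path(out_dir, "gaps.tsv"))
  }
  ty <- if (!is.null(transposons) && nrow(transposons))
    stage("transposons", classify_transposons(transposons, placements, blocks)) else NULL
  if (!is.null(ty)) {
    counts$transposon_calls <- nrow(ty)
    write_tsv(ty, file.path(out_dir, "transposons.tsv"))
  }

  cnv <- NULL
  if (!is.null(depth_test) && !is.null(depth_ref)) {
    cnv <- stage("cnv", {
      wt <- window_counts(depth_test, seqlens, params$cnv_window %||% 414L)
      wr <- window_counts(depth_ref, seqlens, params$cnv_window %||% 414L)
      win <- log2_ratio_track(wt, wr)
      segs <- call_segments(win, threshold = params$log2_threshold %||% 0.6,
                            genes = genes)
      list(windows = win, segments = segs)
    })
    counts$cnv_segments <- nrow(cnv$segments)
    write_cnv_track(cnv$windows, file.path(out_dir, "cnv_windows.tsv"))
    write_tsv(cnv$segments, file.path(out_dir, "cnv_segments.tsv"))
  }

  presence <- NULL
  if (!is.null(genes) && !is.null(cnv)) {
    presence <- stage("presence", gene_presence(genes, blocks, cnv$windows))
    counts$genes_present <- sum(presence$status == "present")
    counts$genes_deleted_high_confidence <-
      sum(presence$status == "deleted_high_confidence")
    write_tsv(presence, file.path(out_dir, "gene_presence.tsv"))
  }
  uniq <- stage("unique_regions", unique_regions(contigs, reference, blocks))
  counts$unique_regions <- nrow(uniq)
  write_bed(uniq, file.path(out_dir, "unique_regions.bed"))

  panel <- NULL
  if (!is.null(config$panel)) {
    panel <- lapply(config$panel, function(p)
      if (is.character(p) && length(p) == 1 && file.exists(p)) read_fasta(p) else as_seq_set(p))
    gm <- config$group_map
    if (is.list(gm) && !is.data.frame(gm)) gm <- as.data.frame(gm)
    mosaic <- stage("mosaic", paint_mosaic(contigs, panel, gm))
    write_tsv(mosaic, file.path(out_dir, "mosaic.tsv"))
    counts$mosaic_fragments <- nrow(mosaic)
    genomes <- c(list(query = contigs), panel)
    D <- stage("phylo", distance_matrix(genomes))
    tree <- upgma(D)
    write_tsv(as.data.frame(D), file.path(out_dir, "distances.tsv"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  }

  enrich <- NULL
  if (!is.null(config$categories_tsv) && !is.null(calls$gene_id)) {
    cats <- read_tsv(config$categories_tsv)
    hit_genes <- unique(calls$gene_id[!is.na(calls$gene_id)])
    hit_genes <- intersect(hit_genes, cats$gene)
    if (length(hit_genes)) {
      enrich <- stage("enrich", enrich_gene_list(hit_genes, cats))
      write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
      counts$enriched_categories <- sum(enrich$significant)
    }
  }

  manifest <- list(
    package = "straincomp",
    version = as.character(utils::packageVersion("straincomp")),
    seed = seed,
    simulated = simulate,
    parameters = params,
    plan = if (simulate) unclass(plan)[!vapply(unclass(plan), is.list, logical(1))] else NULL,
    record_counts = counts,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  json <- jsonlite::toJSON(manifest[setdiff(names(manifest), "elapsed_sec")],
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, file.path(out_dir, "manifest.json"))

  invisible(list(blocks = blocks, calls = calls, placements = placements,
                 gaps = gaps, transposon_calls = ty, cnv = cnv,
                 presence = presence, unique_regions = uniq,
                 repeats = repeats, tandem_repeats = big_tr,
                 truth = truth, manifest = manifest))
}
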