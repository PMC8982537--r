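# End-to-end per-tissue pipeline: read inputs, integrate binding sites and
# target evidence, derive edges, test regulator pairs, assemble loops,
# write deterministic TSV outputs plus a flat-text run manifest.

#' Pipeline run configuration
#'
#' Parameter defaults are the identification settings used throughout:
#' 100 kb enhancer flank, 10 kb/1 kb miRNA and 5 kb/1 kb gene promoter
#' windows, strict target score > 1, strict conserved-track score > 500,
#' q < 0.05, and the printed form of the joint-target tail.
#'
#' @param tissue Tissue/cell-line label for this run.
#' @param enhancer_flank,mirna_promoter_up,mirna_promoter_down,gene_promoter_up,gene_promoter_down
#'   Window sizes in bp.
#' @param min_target_score Strict lower bound on the miRNA-target score S.
#' @param conserved_min_score Strict lower bound on conserved-track scores.
#' @param alpha q-value threshold (strict; `alpha >= 1` disables).
#' @param pvalue_mode `"printed"` or `"ge"` (see [hypergeom_pvalue()]).
#' @param universe_rule `"intersection"` or `"union"` universe for M.
#' @param tfbs_mode `"chipseq_intersection"` or `"conserved_track"`.
#' @param test_enhancer_mirna_gene Also subject enhancer-miRNA pairs to the
#'   joint-target test (off by default; the test is defined for
#'   TF-enhancer pairs).
#' @param curated_replaces_proximity When a curated enhancer-miRNA table is
#'   present it replaces the proximity rule (default); `FALSE` takes the
#'   union of both.
#' @param conservation_filter Optional conservation label restricting
#'   enhancer-miRNA-gene loops.
#' @param lenient Downgrade malformed-record errors to warnings.
#' @return Configuration list.
#' @export
run_config <- function(tissue = "synthetic",
                       enhancer_flank = 100000,
                       mirna_promoter_up = 10000, mirna_promoter_down = 1000,
                       gene_promoter_up = 5000, gene_promoter_down = 1000,
                       min_target_score = 1.0, conserved_min_score = 500,
                       alpha = 0.05,
                       pvalue_mode = c("printed", "ge"),
                       universe_rule = c("intersection", "union"),
                       tfbs_mode = c("chipseq_intersection", "conserved_track"),
                       test_enhancer_mirna_gene = FALSE,
                       curated_replaces_proximity = TRUE,
                       conservation_filter = NULL,
                       lenient = FALSE) {
  cfg <- list(tissue = tissue,
              enhancer_flank = enhancer_flank,
              mirna_promoter_up = mirna_promoter_up,
              mirna_promoter_down = mirna_promoter_down,
              gene_promoter_up = gene_promoter_up,
              gene_promoter_down = gene_promoter_down,
              min_target_score = min_target_score,
              conserved_min_score = conserved_min_score,
              alpha = alpha,
              pvalue_mode = match.arg(pvalue_mode),
              universe_rule = match.arg(universe_rule),
              tfbs_mode = match.arg(tfbs_mode),
              test_enhancer_mirna_gene = isTRUE(test_enhancer_mirna_gene),
              curated_replaces_proximity = isTRUE(curated_replaces_proximity),
              conservation_filter = conservation_filter,
              lenient = isTRUE(lenient))
  dists <- unlist(cfg[c("enhancer_flank", "mirna_promoter_up",
                        "mirna_promoter_down", "gene_promoter_up",
                        "gene_promoter_down")])
  if (anyNA(dists) || any(dists < 0))
    stop("window distances must be non-negative", call. = FALSE)
  if (cfg$min_target_score < 0 || cfg$conserved_min_score < 0)
    stop("score thresholds must be non-negative", call. = FALSE)
  cfg
}

#' Read a landscape-format input directory
#'
#' Reads the file layout written by [write_landscape_files()]:
#' `enhancers_*.bed`, `tfbs_<tf>.bed`, `mirna_tss.tsv`, `gene_tss.tsv`,
#' `evidence_<source>.tsv` with `sources.tsv`, `tf_gene_map.tsv` and an
#' optional `curated_enhancer_mirna.tsv`.
#'
#' @param dir Input directory.
#' @param tissue Tissue label stamped on the records.
#' @param lenient Passed to the readers.
#' @return Input list (`enhancers`, `tfbs`, `mirna_tss`, `gene_tss`,
#'   `evidence`, `source_map`, `tf_gene_map`, `curated`, `tissue`).
#' @export
read_landscape_inputs <- function(dir, tissue = "synthetic", lenient = FALSE) {
  enh_files <- list.files(dir, pattern = "^enhancers_.*\\.bed$",
                          full.names = TRUE)
  if (!length(enh_files))
    stop("no enhancers_*.bed found in ", dir, call. = FALSE)
  enhancers <- do.call(rbind, lapply(enh_files, read_enhancer_bed,
                                     tissue = tissue, lenient = lenient))
  dup <- enhancers$enhancer_id[duplicated(enhancers$enhancer_id)]
  if (length(dup))
    stop("duplicate enhancer ids across files: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  tf_files <- list.files(dir, pattern = "^tfbs_.*\\.bed$", full.names = TRUE)
  tfbs <- do.call(rbind, lapply(tf_files, function(f) {
    tf <- sub("^tfbs_", "", sub("\\.bed$", "", basename(f)))
    read_tfbs_bed(stats::setNames(f, "sim"), tf = tf, tissue = tissue,
                  lenient = lenient)
  }))
  if (is.null(tfbs))
    tfbs <- data.frame(tf = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       dataset_id = character(0), tissue = character(0),
                       score = numeric(0))
  mirna_tss <- read_tss_table(file.path(dir, "mirna_tss.tsv"), "mirna")
  gene_tss <- read_tss_table(file.path(dir, "gene_tss.tsv"), "gene")
  src <- utils::read.table(file.path(dir, "sources.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  source_map <- stats::setNames(src$evidence_class, src$source_db)
  ev_paths <- stats::setNames(
    file.path(dir, paste0("evidence_", src$source_db, ".tsv")), src$source_db)
  evidence <- read_target_evidence(ev_paths, source_map)
  map_path <- file.path(dir, "tf_gene_map.tsv")
  tf_gene_map <- character(0)
  if (file.exists(map_path)) {
    m <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
    tf_gene_map <- stats::setNames(m$gene_id, m$tf)
  }
  cur_path <- file.path(dir, "curated_enhancer_mirna.tsv")
  curated <- if (file.exists(cur_path))
    utils::read.table(cur_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character")
  else NULL
  list(enhancers = enhancers, tfbs = tfbs, mirna_tss = mirna_tss,
       gene_tss = gene_tss, evidence = evidence, source_map = source_map,
       tf_gene_map = tf_gene_map, curated = curated, tissue = tissue)
}

#' Derive every edge type for one tissue
#'
#' Integrates the binding sites per TF, scores and filters the miRNA-target
#' evidence, and applies all edge rules.  When a curated enhancer-miRNA
#' table is present it replaces (or, per config, is unioned with) the
#' proximity-derived `enhancer_mirna` edges.
#'
#' @param inputs Input list from [read_landscape_inputs()].
#' @param config From [run_config()].
#' @return Deduplicated edge table covering all seven edge types.
#' @export
derive_all_edges <- function(inputs, config = run_config()) {
  tfbs <- inputs$tfbs
  if (nrow(tfbs)) {
    tfbs <- do.call(rbind, lapply(split(tfbs, tfbs$tf), integrate_tfbs,
                                  mode = config$tfbs_mode,
                                  min_score = config$conserved_min_score))
    rownames(tfbs) <- NULL
  }
  tss <- rbind(inputs$mirna_tss, inputs$gene_tss)
  prox <- derive_enhancer_target_edges(inputs$enhancers, tss,
                                       flank = config$enhancer_flank)
  enh_gene <- prox[prox$edge_type == "enhancer_gene", , drop = FALSE]
  enh_mirna <- prox[prox$edge_type == "enhancer_mirna", , drop = FALSE]
  if (!is.null(inputs$curated)) {
    cur <- load_curated_enhancer_mirna_edges_df(inputs$curated,
                                                inputs$enhancers)
    enh_mirna <- if (config$curated_replaces_proximity) cur
                 else dedup_edges(rbind(enh_mirna, cur))
  }
  edges <- rbind(
    derive_tf_enhancer_edges(tfbs, inputs$enhancers),
    derive_tf_promoter_edges(tfbs, inputs$mirna_tss,
                             config$mirna_promoter_up,
                             config$mirna_promoter_down,
                             "tf_mirna", tissue = inputs$tissue),
    derive_tf_promoter_edges(tfbs, inputs$gene_tss,
                             config$gene_promoter_up,
                             config$gene_promoter_down,
                             "tf_gene", tissue = inputs$tissue),
    enh_gene, enh_mirna,
    derive_enhancer_tf_edges(enh_gene, inputs$tf_gene_map),
    target_scores_to_edges(
      filter_target_scores(compute_target_scores(inputs$evidence),
                           config$min_target_score),
      tissue = inputs$tissue))
  dedup_edges(edges)
}

#' Run the full loop-identification pipeline on one input directory
#'
#' Reads the inputs, derives all edges, builds and adjusts the pair tests,
#' assembles the four loop classes, and writes `edges.tsv`, `pairs.tsv`,
#' `loops.tsv`, `mirna_summary.tsv` and `manifest.txt` under `output_dir`.
#' Record counts at every filter step are logged with [message()].
#'
#' @param input_dir Landscape-format input directory.
#' @param output_dir Output directory (created if needed).
#' @param config From [run_config()].
#' @return Invisibly, a list with the edge, pair and loop tables and the
#'   output paths.
#' @export
run_pipeline <- function(input_dir, output_dir, config = run_config()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- read_landscape_inputs(input_dir, tissue = config$tissue,
                                  lenient = config$lenient)
  message("inputs: ", nrow(inputs$enhancers), " enhancers, ",
          nrow(inputs$tfbs), " peaks, ", nrow(inputs$mirna_tss), " miRNAs, ",
          nrow(inputs$gene_tss), " genes, ", nrow(inputs$evidence),
          " evidence rows")
  scores <- compute_target_scores(inputs$evidence)
  scores_f <- filter_target_scores(scores, config$min_target_score)
  message("target scores: ", nrow(scores), " pairs in, ", nrow(scores_f),
          " pass S > ", config$min_target_score)
  edges <- derive_all_edges(inputs, config)
  message("edges: ", nrow(edges), " after deduplication")
  fams <- c("tf_enhancer_over_mirna", "tf_enhancer_over_gene")
  if (config$test_enhancer_mirna_gene)
    fams <- c(fams, "enhancer_mirna_over_gene")
  pairs <- do.call(rbind, lapply(fams, function(f)
    build_pair_tests(edges, f, mode = config$pvalue_mode,
                     universe_rule = config$universe_rule)))
  if (is.null(pairs)) pairs <- empty_pairs()
  pairs <- adjust_pair_tests(pairs)
  sig <- qvalue_filter(pairs, config$alpha)
  message("pair tests: ", nrow(pairs), " tested, ", nrow(sig),
          " significant at q < ", config$alpha)
  ecls <- stats::setNames(inputs$enhancers$enhancer_class,
                          inputs$enhancers$enhancer_id)
  pick <- function(fam) sig[sig$family == fam, , drop = FALSE]
  et <- function(tp) edges[edges$edge_type == tp, , drop = FALSE]
  loops <- rbind(
    assemble_ffl_tf_enhancer_mirna(et("tf_enhancer"), et("tf_mirna"),
                                   et("enhancer_mirna"),
                                   pick("tf_enhancer_over_mirna"), ecls),
    assemble_ffl_tf_enhancer_gene(et("tf_enhancer"), et("tf_gene"),
                                  et("enhancer_gene"),
                                  pick("tf_enhancer_over_gene"), ecls),
    assemble_ffl_enhancer_mirna_gene(et("enhancer_mirna"), et("enhancer_gene"),
                                     scores_f,
                                     tested_pairs = if
                                       (config$test_enhancer_mirna_gene)
                                       pick("enhancer_mirna_over_gene")
                                     else NULL,
                                     enhancer_class = ecls),
    assemble_fbl_tf_enhancer(et("tf_enhancer"), et("enhancer_tf"), ecls))
  loops <- filter_loops(loops, conservation = config$conservation_filter)
  loops <- sort_loops(loops)
  message("loops: ", nrow(loops), " assembled (",
          paste(vapply(unique(loops$loop_type), function(t)
            paste0(t, "=", sum(loops$loop_type == t)), character(1)),
            collapse = ", "), ")")
  paths <- list(edges = file.path(output_dir, "edges.tsv"),
                pairs = file.path(output_dir, "pairs.tsv"),
                loops = file.path(output_dir, "loops.tsv"),
                summary = file.path(output_dir, "mirna_summary.tsv"),
                manifest = file.path(output_dir, "manifest.txt"))
  write_edges(edges, paths$edges)
  write_pairs(pairs, paths$pairs)
  write_loops(loops, paths$loops)
  summary <- mirna_participation_summary(loops)
  write_tsv_stable(summary, paths$summary)
  write_manifest(paths$manifest, input_dir, config,
                 counts = c(enhancers = nrow(inputs$enhancers),
                            peaks = nrow(inputs$tfbs),
                            evidence = nrow(inputs$evidence),
                            scores = nrow(scores),
                            scores_filtered = nrow(scores_f),
                            edges = nrow(edges), pairs = nrow(pairs),
                            significant_pairs = nrow(sig),
                            loops = nrow(loops)))
  invisible(list(edges = edges, pairs = pairs, significant_pairs = sig,
                 loops = loops, scores = scores_f, summary = summary,
                 paths = paths))
}

write_manifest <- function(path, input_dir, config, counts) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  keys <- setdiff(names(config), "conservation_filter")
  lines <- c(
    paste0("param.", keys, "=",
           vapply(config[keys], function(v)
             paste(as.character(v), collapse = ","), character(1))),
    paste0("param.conservation_filter=",
           if (is.null(config$conservation_filter)) "none"
           else config$conservation_filter))
  files <- sort(list.files(input_dir, full.names = TRUE))
  sums <- tools::md5sum(files)
  lines <- c(lines, paste0("input.", basename(files), "=", unname(sums)))
  lines <- c(lines, paste0("count.", names(counts), "=", unname(counts)))
  writeLines(lines, con)
  invisible(path)
}

# Curated table supplied as an in-memory data.frame (the file-reading
# variant is load_curated_enhancer_mirna_edges()).
load_curated_enhancer_mirna_edges_df <- function(d, enhancers,
                                                 strict = FALSE) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_curated_enhancer_mirna_edges(tmp, enhancers, strict = strict)
}
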