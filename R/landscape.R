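# Seeded synthetic regulatory landscapes with a truth ledger of planted
# loops, so the whole pipeline can be exercised end to end without any
# external download.
#
# Geometry: each chromosome is split into a feature half, holding
# enhancers, TSS and the planted-loop slots, and a reserved region where
# background TF peaks land when `background_edge_density` is 0.  Because
# the reserved region is disjoint from every enhancer and promoter window,
# a zero-density, zero-noise, zero-planting landscape provably yields no
# regulatory loops of any class.  With density > 0, each background peak is
# placed inside a random enhancer or promoter with that probability.
#
# Planting is constructive: each planted loop occupies its own 400 kb slot
# and places exactly the features the edge rules require (e.g. a planted
# TF-enhancer-miRNA loop puts one TF peak inside the enhancer, the miRNA
# TSS 30 kb from the enhancer center, and a second TF peak inside the
# miRNA promoter window).  Planted ids carry the reserved prefix
# "planted_" so recall can be measured without joins.

SLOT <- 400000L

#' Synthetic landscape configuration
#'
#' Element counts, geometry and noise levels for [generate_landscape()].
#' Defaults are desk-scale: tens of elements per class, a super-enhancer
#' fraction of 0.12 (approximately the genome-wide typical/super ratio in
#' large enhancer catalogs), and a handful of planted loops per class.
#'
#' @param seed Integer seed driving the single pseudo-random stream.
#' @param n_chroms,chrom_length Number of chromosomes and their length (bp).
#' @param n_enhancers Total enhancers (planted ones included).
#' @param super_fraction Probability an enhancer is class `super`.
#' @param n_tfs,peaks_per_tf TFs and background peaks per TF.
#' @param n_mirnas,n_genes miRNA and gene counts.
#' @param planted_tf_enhancer_mirna,planted_tf_enhancer_gene,planted_enhancer_mirna_gene,planted_fbl
#'   Planted loop counts per class.
#' @param background_edge_density Probability a background TF peak is placed
#'   inside a random enhancer or promoter rather than the reserved region.
#' @param target_evidence_noise Per-source probability that a random
#'   (miRNA, gene) pair is recorded as evidence.
#' @param evidence_sources Named character vector source -> class
#'   (`predicted`/`validated`); default two of each.
#' @param tissue Tissue label stamped on the landscape.
#' @param curated_enhancer_mirna Also write a curated enhancer-miRNA table
#'   covering the planted pairs.
#' @return Validated configuration list.
#' @export
landscape_config <- function(seed = 1L, n_chroms = 3L, chrom_length = 4000000L,
                             n_enhancers = 40L, super_fraction = 0.12,
                             n_tfs = 12L, peaks_per_tf = 6L,
                             n_mirnas = 25L, n_genes = 50L,
                             planted_tf_enhancer_mirna = 3L,
                             planted_tf_enhancer_gene = 3L,
                             planted_enhancer_mirna_gene = 3L,
                             planted_fbl = 2L,
                             background_edge_density = 0.02,
                             target_evidence_noise = 0.02,
                             evidence_sources = c(pred_db_a = "predicted",
                                                  pred_db_b = "predicted",
                                                  valid_db_a = "validated",
                                                  valid_db_b = "validated"),
                             tissue = "synthetic",
                             curated_enhancer_mirna = FALSE) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_enhancers = as.integer(n_enhancers),
              super_fraction = super_fraction, n_tfs = as.integer(n_tfs),
              peaks_per_tf = as.integer(peaks_per_tf),
              n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
              planted_tf_enhancer_mirna = as.integer(planted_tf_enhancer_mirna),
              planted_tf_enhancer_gene = as.integer(planted_tf_enhancer_gene),
              planted_enhancer_mirna_gene = as.integer(planted_enhancer_mirna_gene),
              planted_fbl = as.integer(planted_fbl),
              background_edge_density = background_edge_density,
              target_evidence_noise = target_evidence_noise,
              evidence_sources = evidence_sources, tissue = tissue,
              curated_enhancer_mirna = isTRUE(curated_enhancer_mirna))
  probs <- c(cfg$super_fraction, cfg$background_edge_density,
             cfg$target_evidence_noise)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("fractions and probabilities must lie in [0, 1]", call. = FALSE)
  if (!all(cfg$evidence_sources %in% c("predicted", "validated")))
    stop("evidence source classes must be predicted/validated", call. = FALSE)
  n_planted <- cfg$planted_tf_enhancer_mirna + cfg$planted_tf_enhancer_gene +
    cfg$planted_enhancer_mirna_gene + cfg$planted_fbl
  feature_half <- cfg$chrom_length %/% 2L
  slots <- (feature_half %/% SLOT) * cfg$n_chroms
  if (n_planted > slots || feature_half < SLOT)
    stop("infeasible geometry: ", n_planted, " planted loops need ",
         "more slot space than ", cfg$n_chroms, " x ", cfg$chrom_length,
         " bp provides", call. = FALSE)
  if (cfg$planted_tf_enhancer_mirna + cfg$planted_tf_enhancer_gene +
        cfg$planted_fbl > cfg$n_tfs ||
      n_planted > cfg$n_enhancers ||
      cfg$planted_tf_enhancer_mirna + cfg$planted_enhancer_mirna_gene >
        cfg$n_mirnas ||
      cfg$planted_tf_enhancer_gene + cfg$planted_enhancer_mirna_gene +
        cfg$planted_fbl > cfg$n_genes)
    stop("planted loop counts exceed the configured element counts",
         call. = FALSE)
  cfg
}

# Runs expr under a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

write_bed <- function(d, path, cols) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(d)) {
    cells <- vapply(d[cols], as.character, character(nrow(d)))
    if (nrow(d) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a landscape input set to a directory
#'
#' Emits the exact file layout the pipeline reads: split typical/super
#' enhancer BEDs, one peak BED per TF, TSS TSVs, one evidence TSV per
#' source plus `sources.tsv`, the TF-coding-gene map, and an optional
#' curated enhancer-miRNA table.  Deterministic given identical inputs.
#'
#' @param inputs Input list as produced by [generate_landscape()] /
#'   [read_landscape_inputs()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_landscape_files <- function(inputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enh <- inputs$enhancers[order(inputs$enhancers$chrom,
                                inputs$enhancers$start,
                                inputs$enhancers$enhancer_id), ]
  enh$chrom_out <- paste0("chr", enh$chrom)
  for (cls in c("typical", "super"))
    write_bed(enh[enh$enhancer_class == cls, , drop = FALSE],
              file.path(dir, paste0("enhancers_", cls, ".bed")),
              c("chrom_out", "start", "end", "enhancer_id", "enhancer_class"))
  tfbs <- inputs$tfbs
  tfbs$chrom_out <- paste0("chr", tfbs$chrom)
  tfbs$name <- paste0("peak", seq_len(nrow(tfbs)))
  for (tf in sort(unique(c(tfbs$tf, names(inputs$tf_gene_map))))) {
    d <- tfbs[tfbs$tf == tf, , drop = FALSE]
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    write_bed(d, file.path(dir, paste0("tfbs_", tf, ".bed")),
              c("chrom_out", "start", "end", "name"))
  }
  for (ft in c("mirna", "gene")) {
    d <- inputs[[paste0(ft, "_tss")]]
    d <- d[order(d$feature_id), c("feature_id", "chrom", "tss", "strand")]
    d$chrom <- paste0("chr", d$chrom)
    write_tsv_stable(d, file.path(dir, paste0(ft, "_tss.tsv")))
  }
  src <- data.frame(source_db = names(inputs$source_map),
                    evidence_class = unname(inputs$source_map))
  write_tsv_stable(src[order(src$source_db), ], file.path(dir, "sources.tsv"))
  for (s in names(inputs$source_map)) {
    d <- inputs$evidence[inputs$evidence$source_db == s,
                         c("mirna_id", "gene_id", "conservation"), drop = FALSE]
    d <- d[order(d$mirna_id, d$gene_id), , drop = FALSE]
    write_tsv_stable(d, file.path(dir, paste0("evidence_", s, ".tsv")))
  }
  map <- data.frame(tf = as.character(names(inputs$tf_gene_map)),
                    gene_id = as.character(unname(inputs$tf_gene_map)))
  write_tsv_stable(map[order(map$tf), , drop = FALSE],
                   file.path(dir, "tf_gene_map.tsv"))
  if (!is.null(inputs$curated)) {
    d <- inputs$curated[order(inputs$curated$enhancer_id,
                              inputs$curated$mirna_id), , drop = FALSE]
    write_tsv_stable(d, file.path(dir, "curated_enhancer_mirna.tsv"))
  }
  invisible(dir)
}

#' Generate a synthetic regulatory landscape
#'
#' Writes a complete, internally consistent input set (see
#' [write_landscape_files()] for the layout) plus a truth ledger:
#' `truth_loops.tsv` listing every planted loop and `truth_pairs.tsv`
#' giving the realized (M, N, k, x) of each planted TF-enhancer pair.
#' Identical seeds produce byte-identical files.
#'
#' @param config From [landscape_config()].
#' @param dir Output directory.
#' @return Invisibly, a list with `dir`, `config`, the in-memory `inputs`,
#'   and the `truth_loops` / `truth_pairs` ledgers.
#' @export
generate_landscape <- function(config = landscape_config(), dir) {
  with_seed(config$seed, generate_landscape_impl(config, dir))
}

generate_landscape_impl <- function(config, dir) {
  chroms <- as.character(seq_len(config$n_chroms))
  feature_half <- config$chrom_length %/% 2L
  tissue <- config$tissue

  n_tem <- config$planted_tf_enhancer_mirna
  n_teg <- config$planted_tf_enhancer_gene
  n_emg <- config$planted_enhancer_mirna_gene
  n_fbl <- config$planted_fbl
  plan <- data.frame(
    type = rep(c("tem", "teg", "emg", "fbl"), c(n_tem, n_teg, n_emg, n_fbl)),
    idx = c(seq_len(n_tem), seq_len(n_teg), seq_len(n_emg), seq_len(n_fbl)))
  n_planted <- nrow(plan)
  if (n_planted) {
    j <- seq_len(n_planted) - 1L
    plan$chrom <- chroms[(j %% config$n_chroms) + 1L]
    plan$offset <- (j %/% config$n_chroms) * SLOT
    plan$enh <- paste0("planted_enh_", plan$type, plan$idx)
    plan$tf <- ifelse(plan$type %in% c("tem", "teg", "fbl"),
                      paste0("planted_tf_", plan$type, plan$idx), NA)
    plan$mir <- ifelse(plan$type %in% c("tem", "emg"),
                       paste0("planted_mir_", plan$type, plan$idx), NA)
    plan$gene <- ifelse(plan$type %in% c("teg", "emg", "fbl"),
                        paste0("planted_gene_", plan$type, plan$idx), NA)
  }

  # --- enhancers -----------------------------------------------------------
  n_bg_enh <- config$n_enhancers - n_planted
  cls <- ifelse(stats::runif(config$n_enhancers) < config$super_fraction,
                "super", "typical")
  enh_rows <- list()
  if (n_planted)
    enh_rows$planted <- data.frame(
      enhancer_id = plan$enh, chrom = plan$chrom,
      start = plan$offset + 150000L, end = plan$offset + 152000L,
      enhancer_class = cls[seq_len(n_planted)], tissue = tissue)
  if (n_bg_enh > 0) {
    bcls <- cls[n_planted + seq_len(n_bg_enh)]
    width <- ifelse(bcls == "super",
                    sample(8000:20000, n_bg_enh, replace = TRUE),
                    sample(600:2500, n_bg_enh, replace = TRUE))
    start <- vapply(width, function(w)
      sample.int(feature_half - w, 1L) - 1L, integer(1))
    enh_rows$background <- data.frame(
      enhancer_id = sprintf("enh%03d", seq_len(n_bg_enh)),
      chrom = sample(chroms, n_bg_enh, replace = TRUE),
      start = start, end = start + width,
      enhancer_class = bcls, tissue = tissue)
  }
  enhancers <- do.call(rbind, enh_rows)
  rownames(enhancers) <- NULL

  # --- TSS tables ----------------------------------------------------------
  mk_tss <- function(planted_ids, planted_chrom, planted_pos, n_total,
                     prefix, feature_type) {
    n_bg <- n_total - length(planted_ids)
    rows <- list()
    if (length(planted_ids))
      rows$p <- data.frame(feature_id = planted_ids,
                           feature_type = feature_type,
                           chrom = planted_chrom, tss = planted_pos,
                           strand = "+")
    if (n_bg > 0)
      rows$b <- data.frame(
        feature_id = sprintf("%s%03d", prefix, seq_len(n_bg)),
        feature_type = feature_type,
        chrom = sample(chroms, n_bg, replace = TRUE),
        tss = sample(12000:(feature_half - 1L), n_bg, replace = TRUE),
        strand = sample(c("+", "-"), n_bg, replace = TRUE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  mir_plan <- plan[!is.na(plan$mir), , drop = FALSE]
  gene_plan <- plan[!is.na(plan$gene), , drop = FALSE]
  mirna_tss <- mk_tss(mir_plan$mir, mir_plan$chrom,
                      mir_plan$offset + 181000L, config$n_mirnas,
                      "mir", "mirna")
  gene_tss <- mk_tss(gene_plan$gene, gene_plan$chrom,
                     gene_plan$offset + 111000L, config$n_genes,
                     "gene", "gene")

  # --- TF peaks ------------------------------------------------------------
  tfs <- unique(c(plan$tf[!is.na(plan$tf)],
                  sprintf("tf%02d", seq_len(config$n_tfs -
                                              sum(!is.na(plan$tf))))))
  peak_rows <- list()
  # planted peaks: one inside the enhancer, one inside the promoter of the
  # planted target (tem: miRNA promoter; teg: gene promoter; fbl: enhancer
  # only, the return edge comes from the TF-coding gene)
  tf_plan <- plan[!is.na(plan$tf), , drop = FALSE]
  for (r in seq_len(nrow(tf_plan))) {
    pr <- tf_plan[r, ]
    peak_rows[[length(peak_rows) + 1L]] <- data.frame(
      tf = pr$tf, chrom = pr$chrom,
      start = pr$offset + 150600L, end = pr$offset + 150800L,
      dataset_id = "sim", tissue = tissue, score = NA_real_)
    if (pr$type == "tem")
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        tf = pr$tf, chrom = pr$chrom,
        start = pr$offset + 175000L, end = pr$offset + 175200L,
        dataset_id = "sim", tissue = tissue, score = NA_real_)
    if (pr$type == "teg")
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        tf = pr$tf, chrom = pr$chrom,
        start = pr$offset + 107000L, end = pr$offset + 107200L,
        dataset_id = "sim", tissue = tissue, score = NA_real_)
  }
  # background peaks
  mir_win <- promoter_window(mirna_tss$tss, mirna_tss$strand, 10000, 1000)
  gene_win <- promoter_window(gene_tss$tss, gene_tss$strand, 5000, 1000)
  targets <- rbind(
    data.frame(chrom = enhancers$chrom, start = enhancers$start,
               end = enhancers$end),
    data.frame(chrom = mirna_tss$chrom, start = mir_win$start,
               end = mir_win$end),
    data.frame(chrom = gene_tss$chrom, start = gene_win$start,
               end = gene_win$end))
  reserved_lo <- feature_half + 100000L
  reserved_hi <- config$chrom_length - 1000L
  for (tf in tfs) {
    for (p in seq_len(config$peaks_per_tf)) {
      if (stats::runif(1) < config$background_edge_density) {
        t <- targets[sample.int(nrow(targets), 1L), ]
        w <- min(200L, t$end - t$start)
        s <- t$start + sample.int(t$end - t$start - w + 1L, 1L) - 1L
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          tf = tf, chrom = t$chrom, start = s, end = s + w,
          dataset_id = "sim", tissue = tissue, score = NA_real_)
      } else {
        s <- reserved_lo + sample.int(reserved_hi - reserved_lo - 300L, 1L) - 1L
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          tf = tf, chrom = sample(chroms, 1L), start = s, end = s + 300L,
          dataset_id = "sim", tissue = tissue, score = NA_real_)
      }
    }
  }
  tfbs <- do.call(rbind, peak_rows)
  rownames(tfbs) <- NULL

  # --- target evidence -----------------------------------------------------
  sources <- config$evidence_sources
  pred_sources <- names(sources)[sources == "predicted"]
  valid_sources <- names(sources)[sources == "validated"]
  ev_rows <- list()
  emg_plan <- plan[plan$type == "emg", , drop = FALSE]
  for (r in seq_len(nrow(emg_plan))) {
    # one predicted + one validated source: S = 1.5 > 1
    if (length(pred_sources))
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        mirna_id = emg_plan$mir[r], gene_id = emg_plan$gene[r],
        source_db = pred_sources[1L], evidence_class = "predicted",
        conservation = "conserved")
    if (length(valid_sources))
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        mirna_id = emg_plan$mir[r], gene_id = emg_plan$gene[r],
        source_db = valid_sources[1L], evidence_class = "validated",
        conservation = NA_character_)
  }
  if (config$target_evidence_noise > 0) {
    grid <- expand.grid(mirna_id = mirna_tss$feature_id,
                        gene_id = gene_tss$feature_id,
                        stringsAsFactors = FALSE)
    for (s in names(sources)) {
      pick <- stats::runif(nrow(grid)) < config$target_evidence_noise
      if (!any(pick)) next
      g <- grid[pick, , drop = FALSE]
      cons <- if (sources[[s]] == "predicted")
        sample(c("conserved", "poorly_conserved"), nrow(g), replace = TRUE)
      else NA_character_
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        mirna_id = g$mirna_id, gene_id = g$gene_id, source_db = s,
        evidence_class = unname(sources[[s]]), conservation = cons)
    }
  }
  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows)
    else data.frame(mirna_id = character(0), gene_id = character(0),
                    source_db = character(0), evidence_class = character(0),
                    conservation = character(0))
  evidence <- evidence[!duplicated(evidence[c("mirna_id", "gene_id",
                                              "source_db")]), , drop = FALSE]
  rownames(evidence) <- NULL

  # --- TF-coding-gene map (closes the planted feedback loops) --------------
  fbl_plan <- plan[plan$type == "fbl", , drop = FALSE]
  tf_gene_map <- stats::setNames(as.character(fbl_plan$gene),
                                 as.character(fbl_plan$tf))

  curated <- NULL
  if (config$curated_enhancer_mirna) {
    cur_plan <- plan[!is.na(plan$mir), , drop = FALSE]
    curated <- data.frame(enhancer_id = cur_plan$enh, mirna_id = cur_plan$mir)
  }

  inputs <- list(enhancers = enhancers, tfbs = tfbs, mirna_tss = mirna_tss,
                 gene_tss = gene_tss, evidence = evidence,
                 source_map = sources, tf_gene_map = tf_gene_map,
                 curated = curated, tissue = tissue)
  write_landscape_files(inputs, dir)

  # --- truth ledger --------------------------------------------------------
  truth_loops <- if (n_planted) data.frame(
    loop_type = c(tem = "tf_enhancer_mirna", teg = "tf_enhancer_gene",
                  emg = "enhancer_mirna_gene", fbl = "tf_enhancer_fbl")[plan$type],
    tf = plan$tf, enhancer = plan$enh, mirna = plan$mir, gene = plan$gene)
  else data.frame(loop_type = character(0), tf = character(0),
                  enhancer = character(0), mirna = character(0),
                  gene = character(0))
  rownames(truth_loops) <- NULL
  truth_pairs <- planted_pair_stats(inputs)
  write_tsv_stable(truth_loops[order(truth_loops$loop_type,
                                     truth_loops$enhancer), , drop = FALSE],
                   file.path(dir, "truth_loops.tsv"))
  write_tsv_stable(truth_pairs, file.path(dir, "truth_pairs.tsv"),
                   numeric_cols = character(0))
  invisible(list(dir = dir, config = config, inputs = inputs,
                 truth_loops = truth_loops, truth_pairs = truth_pairs))
}

# Realized (M, N, k, x) of every planted regulator pair, obtained by
# running the edge rules on the generated inputs.
planted_pair_stats <- function(inputs) {
  edges <- derive_all_edges(inputs, run_config(tissue = inputs$tissue))
  out <- list()
  for (fam in c("tf_enhancer_over_mirna", "tf_enhancer_over_gene")) {
    p <- build_pair_tests(edges, fam, mode = "ge")
    p <- p[startsWith(p$regulator_a, "planted_") &
             startsWith(p$regulator_b, "planted_") &
             sub("^planted_tf_", "", p$regulator_a) ==
               sub("^planted_enh_", "", p$regulator_b), , drop = FALSE]
    out[[fam]] <- p[c("family", "regulator_a", "regulator_b",
                      "M", "N", "k", "x")]
  }
  out <- do.call(rbind, out)
  out <- out[order(out$family, out$regulator_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ablate one edge type from a landscape
#'
#' Rewrites a generated landscape with the inputs responsible for one edge
#' type removed, for necessary-edge ablation tests: removing any required
#' edge type must empty the corresponding loop class downstream.
#'
#' @param dir Generated landscape directory.
#' @param edge_type One of the seven edge types, or `"none"` for an
#'   unmodified copy.
#' @param out_dir Destination directory.
#' @param config Pipeline parameters defining the windows (defaults match
#'   the pipeline defaults).
#' @return `out_dir`, invisibly.
#' @export
ablate <- function(dir, edge_type, out_dir, config = run_config()) {
  inputs <- read_landscape_inputs(dir, tissue = config$tissue)
  drop_tfbs_in <- function(regions) {
    if (nrow(regions) == 0L || nrow(inputs$tfbs) == 0L) return(inputs$tfbs)
    hits <- overlap_pairs(inputs$tfbs[c("chrom", "start", "end")], regions)
    if (nrow(hits) == 0L) return(inputs$tfbs)
    inputs$tfbs[-unique(hits$a_idx), , drop = FALSE]
  }
  drop_tss_near_enh <- function(tss) {
    if (nrow(tss) == 0L) return(tss)
    ctr <- data.frame(chrom = inputs$enhancers$chrom,
                      center = interval_center(inputs$enhancers$start,
                                               inputs$enhancers$end))
    near <- vapply(seq_len(nrow(tss)), function(i)
      any(ctr$chrom == tss$chrom[i] &
            abs(tss$tss[i] - ctr$center) <= config$enhancer_flank),
      logical(1))
    tss[!near, , drop = FALSE]
  }
  switch(edge_type,
    none = NULL,
    tf_enhancer = {
      inputs$tfbs <- drop_tfbs_in(inputs$enhancers[c("chrom", "start", "end")])
    },
    tf_mirna = {
      w <- promoter_window(inputs$mirna_tss$tss, inputs$mirna_tss$strand,
                           config$mirna_promoter_up, config$mirna_promoter_down)
      inputs$tfbs <- drop_tfbs_in(data.frame(chrom = inputs$mirna_tss$chrom,
                                             start = w$start, end = w$end))
    },
    tf_gene = {
      w <- promoter_window(inputs$gene_tss$tss, inputs$gene_tss$strand,
                           config$gene_promoter_up, config$gene_promoter_down)
      inputs$tfbs <- drop_tfbs_in(data.frame(chrom = inputs$gene_tss$chrom,
                                             start = w$start, end = w$end))
    },
    enhancer_gene = {
      inputs$gene_tss <- drop_tss_near_enh(inputs$gene_tss)
    },
    enhancer_mirna = {
      inputs$mirna_tss <- drop_tss_near_enh(inputs$mirna_tss)
      inputs$curated <- NULL
    },
    enhancer_tf = {
      inputs$tf_gene_map <- character(0)
    },
    mirna_gene = {
      inputs$evidence <- inputs$evidence[0, , drop = FALSE]
    },
    stop("unknown edge_type: ", edge_type, call. = FALSE))
  write_landscape_files(inputs, out_dir)
  invisible(out_dir)
}
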