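# Derivation of typed regulator -> target edges, per tissue.
#
# Rules:
#   enhancer -> gene/miRNA : TSS within +/- `flank` bp (default 100 kb,
#                            inclusive) of the enhancer center
#   tf -> enhancer         : integrated binding site overlaps the enhancer
#   tf -> miRNA/gene       : binding site overlaps the strand-aware promoter
#                            window (10 kb/1 kb for miRNA, 5 kb/1 kb for gene)
#   enhancer -> tf         : the enhancer's target genes include the gene
#                            encoding that TF
#   mirna -> gene          : score-filtered miRNA-target evidence
# Edges are deduplicated on (regulator, target, edge_type, tissue) with
# provenance tags concatenated.

new_edges <- function(tissue = character(0), edge_type = character(0),
                      regulator_class = character(0),
                      regulator_id = character(0),
                      target_class = character(0), target_id = character(0),
                      provenance = character(0)) {
  data.frame(tissue = tissue, edge_type = edge_type,
             regulator_class = regulator_class, regulator_id = regulator_id,
             target_class = target_class, target_id = target_id,
             provenance = provenance)
}

#' Deduplicate an edge table
#'
#' Collapses rows sharing (regulator_id, target_id, edge_type, tissue);
#' provenance tags of the collapsed rows are concatenated (sorted, unique,
#' comma-separated).
#'
#' @param edges Edge table.
#' @return Deduplicated edge table in canonical sort.
#' @export
dedup_edges <- function(edges) {
  if (nrow(edges) == 0L) return(sort_edges(edges))
  key <- paste(edges$tissue, edges$edge_type, edges$regulator_id,
               edges$target_id, sep = "\t")
  first <- !duplicated(key)
  prov <- vapply(split(edges$provenance, key), function(p)
    paste(sort(unique(p)), collapse = ","), character(1))
  out <- edges[first, , drop = FALSE]
  out$provenance <- unname(prov[key[first]])
  sort_edges(out)
}

#' Default edge-derivation parameters
#'
#' All window sizes in bp.  Defaults: 100 kb enhancer flank, 10 kb/1 kb
#' miRNA promoter, 5 kb/1 kb gene promoter.
#'
#' @param enhancer_flank Distance from enhancer center within which a TSS is
#'   called a target (inclusive).
#' @param mirna_promoter_up,mirna_promoter_down miRNA promoter extents.
#' @param gene_promoter_up,gene_promoter_down Gene promoter extents.
#' @param tf_gene_map Named character vector mapping TF symbol to the
#'   gene id encoding it.
#' @return List of validated parameters.
#' @export
edge_config <- function(enhancer_flank = 100000,
                        mirna_promoter_up = 10000, mirna_promoter_down = 1000,
                        gene_promoter_up = 5000, gene_promoter_down = 1000,
                        tf_gene_map = character(0)) {
  vals <- c(enhancer_flank, mirna_promoter_up, mirna_promoter_down,
            gene_promoter_up, gene_promoter_down)
  if (anyNA(vals) || any(vals < 0))
    stop("window distances must be non-negative", call. = FALSE)
  if (length(tf_gene_map) && anyDuplicated(names(tf_gene_map)))
    stop("tf_gene_map must map each TF to a single gene", call. = FALSE)
  list(enhancer_flank = enhancer_flank,
       mirna_promoter_up = mirna_promoter_up,
       mirna_promoter_down = mirna_promoter_down,
       gene_promoter_up = gene_promoter_up,
       gene_promoter_down = gene_promoter_down,
       tf_gene_map = tf_gene_map)
}

#' Derive enhancer -> gene / enhancer -> miRNA edges by proximity
#'
#' A TSS is a target of an enhancer when it lies on the same chromosome
#' within `flank` bp (inclusive) of the enhancer center
#' (`floor((start+end)/2)`).  Gene TSS yield `enhancer_gene` edges; miRNA
#' TSS yield `enhancer_mirna` edges with provenance `"proximity"` (used when
#' no curated enhancer-miRNA table is supplied).
#'
#' @param enhancers Enhancer table ([read_enhancer_bed()]).
#' @param tss TSS table ([read_tss_table()]); may mix feature types.
#' @param flank Inclusive distance in bp (default 100000).
#' @return Deduplicated edge table.
#' @export
derive_enhancer_target_edges <- function(enhancers, tss, flank = 100000) {
  if (flank < 0) stop("flank must be non-negative", call. = FALSE)
  if (nrow(enhancers) == 0L || nrow(tss) == 0L) return(new_edges())
  centers <- data.frame(eidx = seq_len(nrow(enhancers)),
                        chrom = enhancers$chrom,
                        center = interval_center(enhancers$start, enhancers$end))
  feats <- data.frame(tidx = seq_len(nrow(tss)), chrom = tss$chrom,
                      tss = tss$tss)
  m <- merge(centers, feats, by = "chrom")
  m <- m[abs(m$tss - m$center) <= flank, , drop = FALSE]
  if (nrow(m) == 0L) return(new_edges())
  ft <- tss$feature_type[m$tidx]
  dedup_edges(new_edges(
    tissue = enhancers$tissue[m$eidx],
    edge_type = ifelse(ft == "gene", "enhancer_gene", "enhancer_mirna"),
    regulator_class = "enhancer",
    regulator_id = enhancers$enhancer_id[m$eidx],
    target_class = ft,
    target_id = tss$feature_id[m$tidx],
    provenance = "proximity"))
}

#' Derive TF -> enhancer edges from binding-site overlap
#'
#' A TF regulates an enhancer when at least one of its (integrated) binding
#' sites overlaps the enhancer interval; multiple overlapping peaks yield a
#' single edge.
#'
#' @param tfbs Integrated peak table (may contain several TFs).
#' @param enhancers Enhancer table.
#' @return Deduplicated `tf_enhancer` edge table.
#' @export
derive_tf_enhancer_edges <- function(tfbs, enhancers) {
  if (nrow(tfbs) == 0L || nrow(enhancers) == 0L) return(new_edges())
  hits <- overlap_pairs(tfbs[c("chrom", "start", "end")],
                        enhancers[c("chrom", "start", "end")])
  if (nrow(hits) == 0L) return(new_edges())
  dedup_edges(new_edges(
    tissue = enhancers$tissue[hits$b_idx],
    edge_type = "tf_enhancer",
    regulator_class = "tf",
    regulator_id = tfbs$tf[hits$a_idx],
    target_class = "enhancer",
    target_id = enhancers$enhancer_id[hits$b_idx],
    provenance = "tfbs_overlap"))
}

#' Derive TF -> miRNA / TF -> gene edges via promoter windows
#'
#' A TF regulates a miRNA or gene when a binding site overlaps the
#' strand-aware promoter window around the TSS.
#'
#' @param tfbs Integrated peak table.
#' @param tss TSS table of a single feature type.
#' @param up,down Promoter extents in bp.
#' @param edge_type `"tf_mirna"` or `"tf_gene"`.
#' @param tissue Tissue label for the emitted edges.
#' @return Deduplicated edge table.
#' @export
derive_tf_promoter_edges <- function(tfbs, tss, up, down,
                                     edge_type = c("tf_mirna", "tf_gene"),
                                     tissue) {
  edge_type <- match.arg(edge_type)
  if (nrow(tfbs) == 0L || nrow(tss) == 0L) return(new_edges())
  win <- promoter_window(tss$tss, tss$strand, up, down)
  win <- data.frame(chrom = tss$chrom, start = win$start, end = win$end)
  keep_win <- win$end > win$start
  hits <- overlap_pairs(tfbs[c("chrom", "start", "end")],
                        win[keep_win, , drop = FALSE])
  if (nrow(hits) == 0L) return(new_edges())
  tidx <- which(keep_win)[hits$b_idx]
  dedup_edges(new_edges(
    tissue = tissue,
    edge_type = edge_type,
    regulator_class = "tf",
    regulator_id = tfbs$tf[hits$a_idx],
    target_class = tss$feature_type[tidx],
    target_id = tss$feature_id[tidx],
    provenance = "promoter_overlap"))
}

#' Derive enhancer -> TF edges from enhancer-gene edges
#'
#' Screens the enhancer target genes for genes encoding TFs: every
#' `enhancer_gene` edge whose gene appears in `tf_gene_map` projects to an
#' `enhancer_tf` edge toward the encoded TF.  These edges close the
#' TF-enhancer feedback loops.
#'
#' @param enhancer_gene_edges `enhancer_gene` edge table.
#' @param tf_gene_map Named character vector, TF symbol -> gene id.
#' @return Deduplicated `enhancer_tf` edge table.
#' @export
derive_enhancer_tf_edges <- function(enhancer_gene_edges, tf_gene_map) {
  eg <- enhancer_gene_edges[enhancer_gene_edges$edge_type == "enhancer_gene", ,
                            drop = FALSE]
  if (nrow(eg) == 0L || length(tf_gene_map) == 0L) return(new_edges())
  gene_to_tf <- stats::setNames(names(tf_gene_map), unname(tf_gene_map))
  hit <- eg$target_id %in% names(gene_to_tf)
  if (!any(hit)) return(new_edges())
  eg <- eg[hit, , drop = FALSE]
  dedup_edges(new_edges(
    tissue = eg$tissue,
    edge_type = "enhancer_tf",
    regulator_class = "enhancer",
    regulator_id = eg$regulator_id,
    target_class = "tf",
    target_id = unname(gene_to_tf[eg$target_id]),
    provenance = "tf_coding_target"))
}

#' Load a curated enhancer -> miRNA edge table
#'
#' Reads a two-column TSV (`enhancer_id`, `mirna_id`) of externally curated
#' enhancer-miRNA relationships and resolves it against the enhancer set.
#' Unresolvable enhancer ids are reported; more than 50% unresolvable
#' aborts (a likely id-space mismatch).  When supplied to the pipeline this
#' table replaces the proximity rule for `enhancer_mirna` edges.
#'
#' @param path TSV path with header `enhancer_id`, `mirna_id`.
#' @param enhancers Enhancer table used to resolve ids.
#' @param strict Abort on any unresolvable id (default `FALSE`: warn and
#'   drop, abort above 50%).
#' @return Deduplicated `enhancer_mirna` edge table, provenance `"curated"`.
#' @export
load_curated_enhancer_mirna_edges <- function(path, enhancers, strict = FALSE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  if (length(setdiff(c("enhancer_id", "mirna_id"), names(d))))
    stop("curated table needs enhancer_id and mirna_id columns", call. = FALSE)
  d <- unique(d[c("enhancer_id", "mirna_id")])
  known <- d$enhancer_id %in% enhancers$enhancer_id
  if (any(!known)) {
    missing <- unique(d$enhancer_id[!known])
    if (strict || mean(!known) > 0.5)
      stop("unresolvable enhancer id(s) in curated table: ",
           paste(utils::head(missing, 10L), collapse = ", "), call. = FALSE)
    warning(length(missing), " unresolvable enhancer id(s) dropped",
            call. = FALSE)
    d <- d[known, , drop = FALSE]
  }
  if (nrow(d) == 0L) return(new_edges())
  tiss <- enhancers$tissue[match(d$enhancer_id, enhancers$enhancer_id)]
  dedup_edges(new_edges(
    tissue = tiss,
    edge_type = "enhancer_mirna",
    regulator_class = "enhancer",
    regulator_id = d$enhancer_id,
    target_class = "mirna",
    target_id = d$mirna_id,
    provenance = "curated"))
}

#' Convert filtered target scores to miRNA -> gene edges
#'
#' @param scores Score table, normally after [filter_target_scores()].
#' @param tissue Tissue label for the emitted edges.
#' @return Deduplicated `mirna_gene` edge table with provenance
#'   `"target_score"`.
#' @export
target_scores_to_edges <- function(scores, tissue) {
  if (nrow(scores) == 0L) return(new_edges())
  dedup_edges(new_edges(
    tissue = tissue,
    edge_type = "mirna_gene",
    regulator_class = "mirna",
    regulator_id = scores$mirna_id,
    target_class = "gene",
    target_id = scores$gene_id,
    provenance = "target_score"))
}
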