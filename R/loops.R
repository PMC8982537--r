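# Assembly of the four enhancer-mediated loop classes from derived edges
# and significant regulator pairs.
#
#   TF-enhancer-miRNA FFL : TF -> enhancer, and TF and enhancer jointly
#                           regulate at least one miRNA; one row per joint
#                           miRNA; the (TF, enhancer) pair must survive the
#                           q-value filter.
#   TF-enhancer-gene FFL  : same construction over gene targets.
#   enhancer-miRNA-gene FFL : enhancer -> miRNA, enhancer -> gene, and the
#                           miRNA targets the gene with score S > 1.
#   TF-enhancer FBL       : TF -> enhancer and enhancer -> TF (the enhancer
#                           targets the TF-coding gene).  FBLs carry no
#                           enrichment statistic: the joint-target test is
#                           undefined for a two-node motif.

new_loops <- function(n = 0L) {
  data.frame(tissue = character(n), loop_type = character(n),
             tf = character(n), enhancer = character(n),
             enhancer_class = character(n), mirna = character(n),
             gene = character(n), x_joint_targets = integer(n),
             p_value = numeric(n), q_value = numeric(n),
             min_target_score = numeric(n), conservation = character(n))
}

lookup_class <- function(ids, enhancer_class) {
  if (is.null(enhancer_class)) return(rep(NA_character_, length(ids)))
  unname(enhancer_class[ids])
}

edge_key <- function(edges) paste(edges$regulator_id, edges$target_id, sep = "\t")

assemble_ffl_regulator_pair <- function(tf_enh, tf_target, enh_target,
                                        tested_pairs, loop_type, target_col,
                                        enhancer_class) {
  if (nrow(tested_pairs) == 0L || nrow(tf_enh) == 0L) return(new_loops())
  te <- edge_key(tf_enh)
  rows <- list()
  for (r in seq_len(nrow(tested_pairs))) {
    t <- tested_pairs$regulator_a[r]
    e <- tested_pairs$regulator_b[r]
    tis <- tested_pairs$tissue[r]
    if (!paste(t, e, sep = "\t") %in% te[tf_enh$tissue == tis]) next
    joint <- intersect(
      tf_target$target_id[tf_target$regulator_id == t & tf_target$tissue == tis],
      enh_target$target_id[enh_target$regulator_id == e & enh_target$tissue == tis])
    if (length(joint) == 0L) next
    l <- new_loops(length(joint))
    l$tissue <- tis
    l$loop_type <- loop_type
    l$tf <- t
    l$enhancer <- e
    l$enhancer_class <- lookup_class(rep(e, length(joint)), enhancer_class)
    l[[target_col]] <- joint
    other <- setdiff(c("mirna", "gene"), target_col)
    l[[other]] <- NA_character_
    l$x_joint_targets <- tested_pairs$x[r]
    l$p_value <- tested_pairs$p_value[r]
    l$q_value <- tested_pairs$q_value[r]
    l$min_target_score <- NA_real_
    l$conservation <- NA_character_
    rows[[length(rows) + 1L]] <- l
  }
  out <- if (length(rows)) do.call(rbind, rows) else new_loops()
  sort_loops(out)
}

#' Assemble TF-enhancer-miRNA feed-forward loops
#'
#' Emits one loop per (TF, enhancer, miRNA) triple such that the TF binds
#' the enhancer, both the TF and the enhancer regulate the miRNA, and the
#' (TF, enhancer) pair passed the joint-target significance filter.
#'
#' @param tf_enh `tf_enhancer` edges.
#' @param tf_mirna `tf_mirna` edges.
#' @param enh_mirna `enhancer_mirna` edges.
#' @param tested_pairs Significant pairs from [qvalue_filter()] (family
#'   `tf_enhancer_over_mirna`).
#' @param enhancer_class Optional named vector enhancer id -> class label.
#' @return Loop table in canonical sort.
#' @export
assemble_ffl_tf_enhancer_mirna <- function(tf_enh, tf_mirna, enh_mirna,
                                           tested_pairs,
                                           enhancer_class = NULL) {
  assemble_ffl_regulator_pair(tf_enh, tf_mirna, enh_mirna, tested_pairs,
                              "tf_enhancer_mirna", "mirna", enhancer_class)
}

#' Assemble TF-enhancer-gene feed-forward loops
#'
#' Same construction as [assemble_ffl_tf_enhancer_mirna()], over joint gene
#' targets (family `tf_enhancer_over_gene`).
#'
#' @param tf_enh,tf_gene,enh_gene Edge tables.
#' @param tested_pairs Significant pairs.
#' @param enhancer_class Optional named class vector.
#' @return Loop table.
#' @export
assemble_ffl_tf_enhancer_gene <- function(tf_enh, tf_gene, enh_gene,
                                          tested_pairs,
                                          enhancer_class = NULL) {
  assemble_ffl_regulator_pair(tf_enh, tf_gene, enh_gene, tested_pairs,
                              "tf_enhancer_gene", "gene", enhancer_class)
}

#' Assemble enhancer-miRNA-gene feed-forward loops
#'
#' Emits one loop per (enhancer, miRNA, gene) triple such that the enhancer
#' regulates both the miRNA and the gene, and the miRNA targets the gene in
#' the score-filtered evidence.  The loop carries the pair's target score
#' and conservation label.  When `tested_pairs` is supplied (optional
#' enrichment family `enhancer_mirna_over_gene`), only (enhancer, miRNA)
#' pairs present there form loops.
#'
#' @param enh_mirna,enh_gene Edge tables.
#' @param scores Filtered target scores ([filter_target_scores()]).
#' @param tested_pairs Optional significant pair table.
#' @param enhancer_class Optional named class vector.
#' @return Loop table.
#' @export
assemble_ffl_enhancer_mirna_gene <- function(enh_mirna, enh_gene, scores,
                                             tested_pairs = NULL,
                                             enhancer_class = NULL) {
  if (nrow(enh_mirna) == 0L || nrow(enh_gene) == 0L || nrow(scores) == 0L)
    return(new_loops())
  score_key <- paste(scores$mirna_id, scores$gene_id, sep = "\t")
  pair_info <- NULL
  if (!is.null(tested_pairs))
    pair_info <- tested_pairs[tested_pairs$family == "enhancer_mirna_over_gene", ,
                              drop = FALSE]
  rows <- list()
  for (e in unique(enh_mirna$regulator_id)) {
    em <- enh_mirna[enh_mirna$regulator_id == e, , drop = FALSE]
    eg <- enh_gene[enh_gene$regulator_id == e, , drop = FALSE]
    if (nrow(eg) == 0L) next
    for (r in seq_len(nrow(em))) {
      m <- em$target_id[r]
      tis <- em$tissue[r]
      p_row <- NULL
      if (!is.null(pair_info)) {
        p_row <- pair_info[pair_info$regulator_a == e &
                             pair_info$regulator_b == m &
                             pair_info$tissue == tis, , drop = FALSE]
        if (nrow(p_row) == 0L) next
      }
      hit <- match(paste(m, eg$target_id, sep = "\t"), score_key)
      ok <- which(!is.na(hit))
      if (length(ok) == 0L) next
      l <- new_loops(length(ok))
      l$tissue <- tis
      l$loop_type <- "enhancer_mirna_gene"
      l$tf <- NA_character_
      l$enhancer <- e
      l$enhancer_class <- lookup_class(rep(e, length(ok)), enhancer_class)
      l$mirna <- m
      l$gene <- eg$target_id[ok]
      l$x_joint_targets <- if (!is.null(p_row) && nrow(p_row))
        p_row$x[1L] else NA_integer_
      l$p_value <- if (!is.null(p_row) && nrow(p_row)) p_row$p_value[1L] else NA_real_
      l$q_value <- if (!is.null(p_row) && nrow(p_row)) p_row$q_value[1L] else NA_real_
      l$min_target_score <- scores$S[hit[ok]]
      l$conservation <- scores$conservation[hit[ok]]
      rows[[length(rows) + 1L]] <- l
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else new_loops()
  sort_loops(out)
}

#' Assemble TF-enhancer feedback loops
#'
#' A feedback loop exists when a TF binds an enhancer whose target genes
#' include the gene encoding that TF (mutual `tf_enhancer` /
#' `enhancer_tf` edges).  No enrichment statistic is attached.
#'
#' @param tf_enh `tf_enhancer` edges.
#' @param enh_tf `enhancer_tf` edges.
#' @param enhancer_class Optional named class vector.
#' @return Loop table (`loop_type = "tf_enhancer_fbl"`).
#' @export
assemble_fbl_tf_enhancer <- function(tf_enh, enh_tf, enhancer_class = NULL) {
  if (nrow(tf_enh) == 0L || nrow(enh_tf) == 0L) return(new_loops())
  fwd <- paste(tf_enh$tissue, tf_enh$regulator_id, tf_enh$target_id, sep = "\t")
  rev_ <- paste(enh_tf$tissue, enh_tf$target_id, enh_tf$regulator_id, sep = "\t")
  hit <- which(fwd %in% rev_)
  if (length(hit) == 0L) return(new_loops())
  l <- new_loops(length(hit))
  l$tissue <- tf_enh$tissue[hit]
  l$loop_type <- "tf_enhancer_fbl"
  l$tf <- tf_enh$regulator_id[hit]
  l$enhancer <- tf_enh$target_id[hit]
  l$enhancer_class <- lookup_class(l$enhancer, enhancer_class)
  l$mirna <- NA_character_
  l$gene <- NA_character_
  l$x_joint_targets <- NA_integer_
  l$p_value <- NA_real_
  l$q_value <- NA_real_
  l$min_target_score <- NA_real_
  l$conservation <- NA_character_
  sort_loops(unique(l))
}

#' Apply browse-style post-assembly filters to loops
#'
#' Optional user-facing refinements mirroring interactive screening of the
#' loop tables: a conservation restriction and a strict minimum target
#' score for loops that carry one.
#'
#' @param loops Loop table.
#' @param conservation Optional: keep only loops whose target conservation
#'   equals this label (loops without a label are dropped).
#' @param min_target_score Optional strict lower bound applied to
#'   `min_target_score` where present.
#' @return Filtered loop table.
#' @export
filter_loops <- function(loops, conservation = NULL, min_target_score = NULL) {
  out <- loops
  if (!is.null(conservation))
    out <- out[!is.na(out$conservation) & out$conservation == conservation, ,
               drop = FALSE]
  if (!is.null(min_target_score))
    out <- out[is.na(out$min_target_score) |
                 out$min_target_score > min_target_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-miRNA participation across samples
#'
#' Counts, for every miRNA appearing in TF-enhancer-miRNA or
#' enhancer-miRNA-gene loops, the number of distinct samples
#' (tissues/cell lines) with at least one such loop, and flags "master"
#' miRNAs engaged in at least `min_samples` samples (default 14, the cut
#' used with 16 cancer samples).
#'
#' @param loops Loop table pooled across samples.
#' @param min_samples Minimum distinct samples for master status.
#' @return `data.frame(mirna, n_samples, is_master)` sorted by descending
#'   `n_samples` then miRNA id.
#' @export
mirna_participation_summary <- function(loops, min_samples = 14L) {
  rel <- loops[loops$loop_type %in% c("tf_enhancer_mirna", "enhancer_mirna_gene") &
                 !is.na(loops$mirna), , drop = FALSE]
  if (nrow(rel) == 0L)
    return(data.frame(mirna = character(0), n_samples = integer(0),
                      is_master = logical(0)))
  n <- vapply(split(rel$tissue, rel$mirna),
              function(t) length(unique(t)), integer(1))
  out <- data.frame(mirna = names(n), n_samples = unname(n),
                    is_master = unname(n) >= min_samples)
  out <- out[order(-out$n_samples, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
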