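# miRNA-target evidence integration and TF binding-site integration.
#
# A miRNA-gene pair's confidence is S = 0.5 * Ni + Nc, where Ni is the
# number of distinct prediction databases supporting the pair and Nc the
# number of distinct experimentally validated databases.  With the default
# two prediction plus two validation sources, S ranges over
# {0.5, 1, 1.5, 2, 2.5, 3} for any pair present in at least one source;
# only pairs with S strictly greater than 1 survive the default filter.

#' Integrate miRNA-target evidence into confidence scores
#'
#' Counts, for every distinct (miRNA, gene) pair present in at least one
#' source, the number of distinct prediction databases (`Ni`) and distinct
#' validated databases (`Nc`) supporting it, and scores the pair
#' `S = 0.5 * Ni + Nc`.  Multiple records of the same pair within one
#' database count once: the score counts databases, not rows.
#'
#' The conservation label is carried through for filtering only:
#' `"conserved"` if any supporting predicted record is conserved, else
#' `"poorly_conserved"` if any record says so, else `NA`.
#'
#' @param evidence Evidence table from [read_target_evidence()].
#' @return `data.frame(mirna_id, gene_id, Ni, Nc, S, conservation)`, one row
#'   per distinct pair, sorted by (mirna_id, gene_id).
#' @export
compute_target_scores <- function(evidence) {
  cols <- c("mirna_id", "gene_id", "source_db", "evidence_class", "conservation")
  stopifnot(all(cols %in% names(evidence)))
  if (nrow(evidence) == 0L)
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      Ni = integer(0), Nc = integer(0), S = numeric(0),
                      conservation = character(0)))
  ev <- unique(evidence[cols])
  key <- paste(ev$mirna_id, ev$gene_id, sep = "\t")
  groups <- split(seq_len(nrow(ev)), key)
  rows <- lapply(groups, function(idx) {
    g <- ev[idx, , drop = FALSE]
    ni <- length(unique(g$source_db[g$evidence_class == "predicted"]))
    nc <- length(unique(g$source_db[g$evidence_class == "validated"]))
    pred_cons <- g$conservation[g$evidence_class == "predicted"]
    cons <- if (any(pred_cons %in% "conserved")) "conserved"
            else if (any(g$conservation %in% "conserved")) "conserved"
            else if (any(g$conservation %in% "poorly_conserved")) "poorly_conserved"
            else NA_character_
    data.frame(mirna_id = g$mirna_id[1L], gene_id = g$gene_id[1L],
               Ni = ni, Nc = nc, S = 0.5 * ni + nc, conservation = cons)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter target scores
#'
#' Keeps pairs with `S` strictly greater than `min_score` (default 1), the
#' strict cut that discards single-source and prediction-only-pair support
#' patterns under the default 2+2 source configuration.
#'
#' @param scores Table from [compute_target_scores()].
#' @param min_score Strict lower bound on `S`; non-negative.
#' @return Filtered score table.  Idempotent.
#' @export
filter_target_scores <- function(scores, min_score = 1.0) {
  if (length(min_score) != 1L || is.na(min_score) || min_score < 0)
    stop("min_score must be a non-negative scalar", call. = FALSE)
  out <- scores[scores$S > min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate TF binding sites across datasets
#'
#' For a single (TF, tissue): when several ChIP-seq datasets are available,
#' the final binding regions are the basepair intersection of the
#' per-dataset merged coverages — a region counts only if every dataset
#' shows a peak over it.  A single dataset is returned as its merged peaks.
#' In `conserved_track` mode the peaks come from a cross-tissue conserved
#' track and are filtered by score instead (see [filter_conserved_tfbs()]).
#'
#' @param peaks Peak table for one TF in one tissue (from
#'   [read_tfbs_bed()]).
#' @param mode `"chipseq_intersection"` or `"conserved_track"`.
#' @param min_score Strict score cut used in `conserved_track` mode.
#' @return Peak table with `dataset_id` set to `"integrated"` (intersection
#'   mode) or the filtered conserved peaks.
#' @export
integrate_tfbs <- function(peaks, mode = c("chipseq_intersection", "conserved_track"),
                           min_score = 500) {
  mode <- match.arg(mode)
  if (nrow(peaks) == 0L)
    stop("integrate_tfbs: empty peak set", call. = FALSE)
  tf <- unique(peaks$tf)
  tissue <- unique(peaks$tissue)
  if (length(tf) != 1L || length(tissue) != 1L)
    stop("integrate_tfbs operates on one (tf, tissue) at a time", call. = FALSE)
  if (mode == "conserved_track")
    return(filter_conserved_tfbs(peaks, min_score))
  by_ds <- split(peaks[c("chrom", "start", "end")], peaks$dataset_id)
  cov <- Reduce(intersect_intervals, lapply(by_ds, merge_intervals))
  if (nrow(cov) == 0L)
    return(data.frame(tf = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      dataset_id = character(0), tissue = character(0),
                      score = numeric(0)))
  data.frame(tf = tf, chrom = cov$chrom, start = cov$start, end = cov$end,
             dataset_id = if (length(by_ds) > 1L) "integrated"
                          else names(by_ds)[1L],
             tissue = tissue, score = NA_real_)
}

#' Filter conserved-track binding sites by score
#'
#' Keeps peaks whose conserved-track score is strictly greater than
#' `min_score` (default 500), the cut used to retain highly conserved
#' binding sites when no tissue-matched ChIP-seq data exist.
#'
#' @param peaks Peak table; every row must carry a score.
#' @param min_score Strict lower bound.
#' @return Filtered peak table.  Idempotent.
#' @export
filter_conserved_tfbs <- function(peaks, min_score = 500) {
  if (nrow(peaks) == 0L) return(peaks)
  if (anyNA(peaks$score))
    stop("conserved-track filtering requires a score on every peak",
         call. = FALSE)
  out <- peaks[peaks$score > min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}
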