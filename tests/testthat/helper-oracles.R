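# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (per-basepair sets, exhaustive enumeration, triple
# loops) and never share code with the implementation they check.

# Per-basepair overlap oracle for half-open intervals on one chromosome.
bp_overlap_oracle <- function(s1, e1, s2, e2) {
  length(intersect(seq.int(s1, e1 - 1L), seq.int(s2, e2 - 1L))) > 0L
}

# Per-basepair coverage set of an interval table (single chromosome space:
# basepairs are tagged with their chromosome).
bp_coverage <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  unlist(lapply(seq_len(nrow(df)), function(i)
    paste(df$chrom[i], seq.int(df$start[i], df$end[i] - 1L))))
}

# Exhaustive hypergeometric tail: enumerate all N-subsets of 1..M, fix the
# k-set as {1..k}, and count draws whose overlap exceeds (or reaches) x.
hyper_tail_oracle <- function(M, N, k, x, mode) {
  if (N == 0L) return(if (mode == "ge" && x == 0L) 1 else 0)
  draws <- utils::combn(M, N)
  overlap <- colSums(draws <= k)
  if (mode == "printed") mean(overlap > x) else mean(overlap >= x)
}

# Textbook step-up BH: q_(i) = min_{j >= i} p_(j) * m / j, via a double
# loop over the sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) ps[j] * m / j, numeric(1))
    qs[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- qs
  out
}

# Brute-force loop assembly: triple loop over all candidate triples,
# checking edge membership directly in the edge table.
loop_oracle <- function(edges, sig_pairs, scores_f) {
  has <- function(type, r, t)
    any(edges$edge_type == type & edges$regulator_id == r &
          edges$target_id == t)
  ids <- function(type, col)
    unique(edges[[col]][edges$edge_type == type])
  out <- list()
  sig_key <- function(fam) {
    p <- sig_pairs[sig_pairs$family == fam, , drop = FALSE]
    paste(p$regulator_a, p$regulator_b)
  }
  tem_sig <- sig_key("tf_enhancer_over_mirna")
  teg_sig <- sig_key("tf_enhancer_over_gene")
  for (t in ids("tf_enhancer", "regulator_id"))
    for (e in ids("tf_enhancer", "target_id")) {
      if (!has("tf_enhancer", t, e)) next
      if (paste(t, e) %in% tem_sig)
        for (m in ids("enhancer_mirna", "target_id"))
          if (has("tf_mirna", t, m) && has("enhancer_mirna", e, m))
            out[[length(out) + 1L]] <- c("tf_enhancer_mirna", t, e, m, NA)
      if (paste(t, e) %in% teg_sig)
        for (g in ids("enhancer_gene", "target_id"))
          if (has("tf_gene", t, g) && has("enhancer_gene", e, g))
            out[[length(out) + 1L]] <- c("tf_enhancer_gene", t, e, NA, g)
      if (has("enhancer_tf", e, t))
        out[[length(out) + 1L]] <- c("tf_enhancer_fbl", t, e, NA, NA)
    }
  skey <- paste(scores_f$mirna_id, scores_f$gene_id)
  for (e in ids("enhancer_mirna", "regulator_id"))
    for (m in ids("enhancer_mirna", "target_id")) {
      if (!has("enhancer_mirna", e, m)) next
      for (g in ids("enhancer_gene", "target_id"))
        if (has("enhancer_gene", e, g) && paste(m, g) %in% skey)
          out[[length(out) + 1L]] <- c("enhancer_mirna_gene", NA, e, m, g)
    }
  if (!length(out))
    return(data.frame(loop_type = character(0), tf = character(0),
                      enhancer = character(0), mirna = character(0),
                      gene = character(0)))
  d <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(d) <- c("loop_type", "tf", "enhancer", "mirna", "gene")
  unique(d)
}

loop_key <- function(d) {
  sort(paste(d$loop_type,
             ifelse(is.na(d$tf), "", d$tf), d$enhancer,
             ifelse(is.na(d$mirna), "", d$mirna),
             ifelse(is.na(d$gene), "", d$gene)))
}

# Key for matching assembled loops against the generator's truth ledger:
# feedback loops are identified by (tf, enhancer) alone, since the ledger
# additionally records the TF-coding gene that closes them.
truth_key <- function(d) {
  fbl <- d$loop_type == "tf_enhancer_fbl"
  sort(c(if (any(fbl)) paste("fbl", d$tf[fbl], d$enhancer[fbl]),
         loop_key(d[!fbl, , drop = FALSE])))
}

# Small edge-table builder for hand-constructed cases.
mk_edges <- function(type, from, to, tissue = "t1") {
  cls <- list(tf_enhancer = c("tf", "enhancer"),
              tf_mirna = c("tf", "mirna"), tf_gene = c("tf", "gene"),
              enhancer_mirna = c("enhancer", "mirna"),
              enhancer_gene = c("enhancer", "gene"),
              enhancer_tf = c("enhancer", "tf"),
              mirna_gene = c("mirna", "gene"))[[type]]
  data.frame(tissue = tissue, edge_type = type, regulator_class = cls[1],
             regulator_id = from, target_class = cls[2], target_id = to,
             provenance = "test")
}

mk_evidence <- function(mirna, gene, source, class, conservation = NA) {
  data.frame(mirna_id = mirna, gene_id = gene, source_db = source,
             evidence_class = class, conservation = conservation)
}
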