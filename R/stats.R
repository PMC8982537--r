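# Hypergeometric joint-target enrichment for regulator pairs, with
# Benjamini-Hochberg FDR control per (tissue, family).
#
# For a pair (A, B) sharing x targets out of a universe of M co-regulatable
# targets, with N = |targets(A)| and k = |targets(B)|, the printed form of
# the test is
#     P = 1 - sum_{i=0}^{x} C(k,i) C(M-k, N-i) / C(M,N)
# i.e. the tail P(X > x).  The conventional enrichment tail P(X >= x)
# ("ge" mode) is the same sum truncated at x-1.  The printed form is the
# default; note it equals P(X >= x+1) and therefore understates the
# conventional tail — in particular it is exactly 0 whenever x = min(N,k).
# Both modes are exposed and the choice is recorded in the output.

#' Hypergeometric joint-target tail probability
#'
#' @param M Universe size (targets regulated by both regulator classes).
#' @param N Target count of the first regulator within the universe.
#' @param k Target count of the second regulator within the universe.
#' @param x Observed joint target count.
#' @param mode `"printed"` for `P(X > x)` (the default), `"ge"` for
#'   `P(X >= x)`.
#' @return Numeric vector of tail probabilities in `[0, 1]`.  Computed by
#'   log-space summation of the upper tail, so small tails lose no
#'   precision to cancellation.
#' @export
hypergeom_pvalue <- function(M, N, k, x, mode = c("printed", "ge")) {
  mode <- match.arg(mode)
  n <- max(length(M), length(N), length(k), length(x))
  M <- rep_len(as.numeric(M), n); N <- rep_len(as.numeric(N), n)
  k <- rep_len(as.numeric(k), n); x <- rep_len(as.numeric(x), n)
  if (anyNA(c(M, N, k, x)) || any(c(M, N, k, x) < 0) ||
      any(c(M, N, k, x) != floor(c(M, N, k, x))))
    stop("M, N, k, x must be non-negative integers", call. = FALSE)
  if (any(N > M) || any(k > M))
    stop("N and k must not exceed M", call. = FALSE)
  if (any(x > pmin(N, k)))
    stop("x must not exceed min(N, k)", call. = FALSE)
  lo <- if (mode == "printed") x + 1 else x
  vapply(seq_len(n), function(j) {
    hi <- min(N[j], k[j])
    if (lo[j] > hi) return(0)
    i <- lo[j]:hi
    p <- sum(exp(lchoose(k[j], i) + lchoose(M[j] - k[j], N[j] - i) -
                   lchoose(M[j], N[j])))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up q-values: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clamped at 1, returned in the
#' input order.  Tied p-values share a q.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

family_edge_types <- function(family) {
  switch(family,
    tf_enhancer_over_mirna = list(a = "tf_mirna", b = "enhancer_mirna",
                                  a_class = "tf", b_class = "enhancer"),
    tf_enhancer_over_gene = list(a = "tf_gene", b = "enhancer_gene",
                                 a_class = "tf", b_class = "enhancer"),
    enhancer_mirna_over_gene = list(a = "enhancer_gene", b = "mirna_gene",
                                    a_class = "enhancer", b_class = "mirna"),
    stop("unknown enrichment family: ", family, call. = FALSE))
}

empty_pairs <- function() {
  data.frame(tissue = character(0), family = character(0),
             regulator_a = character(0), regulator_b = character(0),
             M = integer(0), N = integer(0), k = integer(0), x = integer(0),
             p_value = numeric(0), q_value = numeric(0))
}

#' Build the pair-enrichment tests for one family
#'
#' For a family (e.g. TF + enhancer over joint miRNA targets), the universe
#' is the set of targets of the family's target class that have at least
#' one regulator of class A **and** at least one of class B in the tissue
#' (`universe_rule = "intersection"`, the default; `"union"` requires only
#' one of the two).  One test is emitted per (A, B) pair sharing at least
#' one joint target; pairs with no joint target cannot form loops and are
#' never tested.  q-values are left `NA`; fill them with
#' [adjust_pair_tests()] or filter directly with [qvalue_filter()].
#'
#' @param edges Edge table holding the family's two edge types.
#' @param family One of `"tf_enhancer_over_mirna"`, `"tf_enhancer_over_gene"`,
#'   `"enhancer_mirna_over_gene"`.
#' @param tissue Optional tissue restriction; default: every tissue present.
#' @param mode p-value mode, see [hypergeom_pvalue()].
#' @param universe_rule `"intersection"` (default) or `"union"`.
#' @return Pair table (`tissue, family, regulator_a, regulator_b, M, N, k,
#'   x, p_value, q_value`).
#' @export
build_pair_tests <- function(edges, family, tissue = NULL,
                             mode = c("printed", "ge"),
                             universe_rule = c("intersection", "union")) {
  mode <- match.arg(mode)
  universe_rule <- match.arg(universe_rule)
  ft <- family_edge_types(family)
  tissues <- if (is.null(tissue)) unique(edges$tissue) else tissue
  res <- list()
  for (tis in tissues) {
    ea <- edges[edges$edge_type == ft$a & edges$tissue == tis, , drop = FALSE]
    eb <- edges[edges$edge_type == ft$b & edges$tissue == tis, , drop = FALSE]
    if (nrow(ea) == 0L || nrow(eb) == 0L) next
    ta <- lapply(split(ea$target_id, ea$regulator_id), unique)
    tb <- lapply(split(eb$target_id, eb$regulator_id), unique)
    ua <- unique(unlist(ta)); ub <- unique(unlist(tb))
    universe <- if (universe_rule == "intersection") intersect(ua, ub)
                else union(ua, ub)
    M <- length(universe)
    if (M == 0L) {
      message("build_pair_tests: empty universe for ", family, " in ", tis)
      next
    }
    ta <- lapply(ta, intersect, universe)
    tb <- lapply(tb, intersect, universe)
    for (a in names(ta)) {
      if (length(ta[[a]]) == 0L) next
      for (b in names(tb)) {
        x <- length(intersect(ta[[a]], tb[[b]]))
        if (x == 0L) next
        res[[length(res) + 1L]] <- data.frame(
          tissue = tis, family = family, regulator_a = a, regulator_b = b,
          M = M, N = length(ta[[a]]), k = length(tb[[b]]), x = x,
          p_value = NA_real_, q_value = NA_real_)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty_pairs()
  if (nrow(out))
    out$p_value <- hypergeom_pvalue(out$M, out$N, out$k, out$x, mode)
  rownames(out) <- NULL
  out
}

#' Fill in q-values per (tissue, family)
#'
#' Applies [bh_adjust()] within every (tissue, family) set of tests; the
#' two loop families and the tissues are corrected independently, mirroring
#' per-sample, per-loop-type identification.
#'
#' @param pairs Pair table with p-values filled.
#' @return The pair table with `q_value` filled.
#' @export
adjust_pair_tests <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  if (anyNA(pairs$p_value))
    stop("p_value must be filled before adjustment", call. = FALSE)
  key <- paste(pairs$tissue, pairs$family, sep = "\t")
  for (kk in unique(key)) {
    idx <- which(key == kk)
    pairs$q_value[idx] <- bh_adjust(pairs$p_value[idx])
  }
  pairs
}

#' Keep non-random regulator pairs
#'
#' Fills q-values if needed and keeps pairs with `q` strictly less than
#' `alpha` (default 0.05).  `alpha >= 1` disables the filter entirely
#' (every tested pair is kept, including `q == 1`), which is the permissive
#' setting used to inspect all candidate loops.
#'
#' @param pairs Pair table.
#' @param alpha Significance threshold.
#' @return Filtered pair table with q filled.
#' @export
qvalue_filter <- function(pairs, alpha = 0.05) {
  if (nrow(pairs) == 0L) return(pairs)
  if (anyNA(pairs$q_value)) pairs <- adjust_pair_tests(pairs)
  keep <- if (alpha >= 1) rep(TRUE, nrow(pairs)) else pairs$q_value < alpha
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
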