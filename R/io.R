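# Readers and writers for every on-disk format the pipeline touches.
# Readers are strict by default: malformed records abort with the offending
# line number rather than being skipped; lenient = TRUE downgrades to a
# warning and drops the record.  Writers emit deterministic, byte-stable
# files: fixed column order, canonical row sort, fixed float formatting.

# Fixed numeric formatting for TSV output: 6 significant digits, scientific
# notation below 1e-4, so q-value diffs are stable across runs.
fmt_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) return("NA")
    if (v == 0) return("0")
    if (abs(v) < 1e-4) sprintf("%.5e", v)
    else format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
}

read_ws_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  strsplit(trimws(lines), "[ \t]+")
}

bad_line <- function(path, i, msg, lenient) {
  full <- sprintf("%s at line %d of %s", msg, i, path)
  if (lenient) {
    warning(full, call. = FALSE)
    FALSE
  } else {
    stop(full, call. = FALSE)
  }
}

#' Read an enhancer BED file
#'
#' Expects >= 4 whitespace-separated columns (chrom, start, end, name); the
#' enhancer class comes from column 5 (values `typical`/`super`) or, when
#' the source publishes typical and super enhancers as separate files, from
#' the `enhancer_class` argument, which overrides column 5.
#'
#' @param path BED file path.
#' @param tissue Tissue/cell-line label attached to every record.
#' @param enhancer_class Optional class label (`"typical"` or `"super"`)
#'   applied to the whole file.
#' @param lenient Drop malformed lines with a warning instead of stopping.
#' @param strip_chr Normalize chromosome names by stripping `"chr"`.
#' @return `data.frame(enhancer_id, chrom, start, end, enhancer_class, tissue)`,
#'   deduplicated; duplicate ids with conflicting coordinates are an error.
#' @export
read_enhancer_bed <- function(path, tissue, enhancer_class = NULL,
                              lenient = FALSE, strip_chr = TRUE) {
  if (!is.null(enhancer_class) && !enhancer_class %in% c("typical", "super"))
    stop("enhancer_class must be 'typical' or 'super'", call. = FALSE)
  fields <- read_ws_table(path)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L) {
      bad_line(path, i, "expected >= 4 columns", lenient)
      next
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end) || start < 0) {
      bad_line(path, i, "non-numeric or negative coordinates", lenient)
      next
    }
    if (end <= start) {
      bad_line(path, i, "end <= start", lenient)
      next
    }
    cls <- if (!is.null(enhancer_class)) enhancer_class
           else if (length(f) >= 5L) f[5L] else NA_character_
    if (is.na(cls) || !cls %in% c("typical", "super")) {
      bad_line(path, i, sprintf("unknown enhancer class '%s'", cls), lenient)
      next
    }
    rows[[i]] <- data.frame(enhancer_id = f[4L],
                            chrom = normalize_chrom(f[1L], strip_chr),
                            start = start, end = end,
                            enhancer_class = cls, tissue = tissue)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(enhancer_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      enhancer_class = character(0), tissue = character(0))
  out <- unique(out)
  dup <- out$enhancer_id[duplicated(out$enhancer_id)]
  if (length(dup))
    stop("conflicting duplicate enhancer id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read TF binding-site BED files
#'
#' Reads one or more peak BED files for a single TF in a single tissue.
#' Columns: chrom, start, end, optional name (col 4) and numeric score
#' (col 5, used for the conserved cross-tissue track).  An empty file gives
#' an empty peak set, not an error.
#'
#' @param paths Character vector of BED paths; names give the dataset ids,
#'   unnamed paths use the file stem.
#' @param tf TF symbol.
#' @param tissue Tissue label.
#' @param lenient,strip_chr See [read_enhancer_bed()].
#' @return `data.frame(tf, chrom, start, end, dataset_id, tissue, score)`
#'   with `score = NA` where absent.
#' @export
read_tfbs_bed <- function(paths, tf, tissue, lenient = FALSE, strip_chr = TRUE) {
  ids <- names(paths)
  if (is.null(ids)) ids <- rep(NA_character_, length(paths))
  ids[is.na(ids) | !nzchar(ids)] <-
    sub("\\.bed$", "", basename(paths[is.na(ids) | !nzchar(ids)]))
  all_rows <- list()
  for (p in seq_along(paths)) {
    fields <- read_ws_table(paths[[p]])
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 3L) {
        bad_line(paths[[p]], i, "expected >= 3 columns", lenient)
        next
      }
      start <- suppressWarnings(as.integer(f[2L]))
      end <- suppressWarnings(as.integer(f[3L]))
      if (is.na(start) || is.na(end) || start < 0 || end <= start) {
        bad_line(paths[[p]], i, "invalid coordinates", lenient)
        next
      }
      score <- NA_real_
      if (length(f) >= 5L) {
        score <- suppressWarnings(as.numeric(f[5L]))
        if (is.na(score)) {
          bad_line(paths[[p]], i, "non-numeric score column", lenient)
          next
        }
      }
      all_rows[[length(all_rows) + 1L]] <-
        data.frame(tf = tf, chrom = normalize_chrom(f[1L], strip_chr),
                   start = start, end = end, dataset_id = ids[p],
                   tissue = tissue, score = score)
    }
  }
  out <- do.call(rbind, all_rows)
  if (is.null(out))
    out <- data.frame(tf = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      dataset_id = character(0), tissue = character(0),
                      score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Read a TSS table
#'
#' Tab-separated with header columns `feature_id`, `chrom`, `tss`, `strand`.
#' Strand is mandatory (`+`/`-`) because promoter windows are asymmetric.
#' Duplicate ids with identical coordinates collapse to one record;
#' conflicting duplicates are an error.
#'
#' @param path TSV path.
#' @param feature_type `"mirna"` or `"gene"`.
#' @param strip_chr Normalize chromosome names.
#' @return `data.frame(feature_id, feature_type, chrom, tss, strand)`.
#' @export
read_tss_table <- function(path, feature_type = c("mirna", "gene"),
                           strip_chr = TRUE) {
  feature_type <- match.arg(feature_type)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("feature_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path,
         call. = FALSE)
  if (anyNA(d$tss) || any(d$tss < 0))
    stop("negative or missing tss in ", path, call. = FALSE)
  if (!all(d$strand %in% c("+", "-")))
    stop("strand outside {+,-} in ", path, call. = FALSE)
  out <- unique(data.frame(feature_id = as.character(d$feature_id),
                           feature_type = feature_type,
                           chrom = normalize_chrom(d$chrom, strip_chr),
                           tss = as.integer(d$tss),
                           strand = as.character(d$strand)))
  dup <- out$feature_id[duplicated(out$feature_id)]
  if (length(dup))
    stop("duplicate feature id(s) with conflicting coordinates in ", path,
         ": ", paste(unique(dup), collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read miRNA-target evidence tables
#'
#' One TSV per source database, each with header columns `mirna_id`,
#' `gene_id` and an optional `conservation` column
#' (`conserved`/`poorly_conserved`).  Every source must be assigned to an
#' evidence class through `source_class_map`; a source without a mapping is
#' an error.  Rows are deduplicated within each source so a pair recorded
#' twice by one database still counts once toward the target score.
#'
#' @param paths_by_source Named character vector: source db name -> path.
#' @param source_class_map Named character vector: source db name ->
#'   `"predicted"` or `"validated"`.
#' @return `data.frame(mirna_id, gene_id, source_db, evidence_class,
#'   conservation)`.
#' @export
read_target_evidence <- function(paths_by_source, source_class_map) {
  if (is.null(names(paths_by_source)) || any(!nzchar(names(paths_by_source))))
    stop("paths_by_source must be named by source database", call. = FALSE)
  miss <- setdiff(names(paths_by_source), names(source_class_map))
  if (length(miss))
    stop("source(s) missing from source_class_map: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(source_class_map %in% c("predicted", "validated")))
    stop("source classes must be 'predicted' or 'validated'", call. = FALSE)
  out <- list()
  for (src in names(paths_by_source)) {
    d <- utils::read.table(paths_by_source[[src]], header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
    need <- c("mirna_id", "gene_id")
    if (length(setdiff(need, names(d))))
      stop("missing mirna_id/gene_id columns in ", paths_by_source[[src]],
           call. = FALSE)
    cons <- if ("conservation" %in% names(d)) as.character(d$conservation)
            else rep(NA_character_, nrow(d))
    cons[!is.na(cons) & !nzchar(cons)] <- NA_character_
    if (!all(is.na(cons) | cons %in% c("conserved", "poorly_conserved")))
      stop("unknown conservation label in ", paths_by_source[[src]],
           call. = FALSE)
    r <- data.frame(mirna_id = as.character(d$mirna_id),
                    gene_id = as.character(d$gene_id),
                    source_db = rep(src, nrow(d)),
                    evidence_class = rep(unname(source_class_map[[src]]),
                                         nrow(d)),
                    conservation = cons)
    out[[src]] <- r[!duplicated(r[c("mirna_id", "gene_id")]), , drop = FALSE]
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(mirna_id = character(0), gene_id = character(0),
                      source_db = character(0), evidence_class = character(0),
                      conservation = character(0))
  rownames(out) <- NULL
  out
}

edge_columns <- c("tissue", "edge_type", "regulator_class", "regulator_id",
                  "target_class", "target_id", "provenance")
pair_columns <- c("tissue", "family", "regulator_a", "regulator_b",
                  "M", "N", "k", "x", "p_value", "q_value")
loop_columns <- c("tissue", "loop_type", "tf", "enhancer", "enhancer_class",
                  "mirna", "gene", "x_joint_targets", "p_value", "q_value",
                  "min_target_score", "conservation")

sort_edges <- function(edges) {
  edges[order(edges$tissue, edges$edge_type, edges$regulator_id,
              edges$target_id), edge_columns, drop = FALSE]
}

sort_loops <- function(loops) {
  q <- loops$q_value
  q[is.na(q)] <- Inf
  loops[order(loops$tissue, loops$loop_type, q,
              ifelse(is.na(loops$tf), "", loops$tf), loops$enhancer,
              ifelse(is.na(loops$mirna), "", loops$mirna),
              ifelse(is.na(loops$gene), "", loops$gene)),
        loop_columns, drop = FALSE]
}

sort_pairs <- function(pairs) {
  pairs[order(pairs$tissue, pairs$family, pairs$regulator_a,
              pairs$regulator_b), pair_columns, drop = FALSE]
}

write_tsv_stable <- function(d, path, numeric_cols = character(0)) {
  for (nc in numeric_cols) d[[nc]] <- fmt_num(d[[nc]])
  con <- file(path, open = "wb")  # binary mode: LF line endings everywhere
  on.exit(close(con))
  writeLines(paste(names(d), collapse = "\t"), con)
  if (nrow(d)) {
    cells <- vapply(d, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- "NA"
      col
    }, character(nrow(d)))
    if (nrow(d) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write and read edge tables
#'
#' Edges are written in canonical sort (tissue, edge_type, regulator_id,
#' target_id) with the fixed column order, so identical edge sets produce
#' byte-identical files.
#'
#' @param edges Edge `data.frame` (see [derive_enhancer_target_edges()]).
#' @param path Output TSV path.
#' @return `write_edges` the path, invisibly; `read_edges` the edge table.
#' @export
write_edges <- function(edges, path) {
  stopifnot(all(edge_columns %in% names(edges)))
  write_tsv_stable(sort_edges(edges), path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  stopifnot(identical(names(d), edge_columns))
  d
}

#' Write and read pair-enrichment tables
#'
#' Columns on disk follow the fixed interface (`tf`, `enhancer`, counts,
#' p/q); internally the regulators are the generic `regulator_a` /
#' `regulator_b`, since one test family pairs an enhancer with a miRNA.
#'
#' @param pairs Pair table from [build_pair_tests()].
#' @param path TSV path.
#' @return `write_pairs` the path invisibly; `read_pairs` the pair table.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(all(pair_columns %in% names(pairs)))
  d <- sort_pairs(pairs)
  names(d)[names(d) == "regulator_a"] <- "tf"
  names(d)[names(d) == "regulator_b"] <- "enhancer"
  write_tsv_stable(d, path, numeric_cols = c("p_value", "q_value"))
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  names(d)[names(d) == "tf"] <- "regulator_a"
  names(d)[names(d) == "enhancer"] <- "regulator_b"
  stopifnot(identical(names(d), pair_columns))
  for (ic in c("M", "N", "k", "x")) d[[ic]] <- as.integer(d[[ic]])
  d
}

#' Write and read loop tables
#'
#' Loops are sorted by (tissue, loop_type, q ascending, element ids); p/q
#' and target scores use the stable 6-significant-digit format.
#'
#' @param loops Loop table from the `assemble_*` functions.
#' @param path TSV path.
#' @return `write_loops` the path invisibly; `read_loops` the loop table.
#' @export
write_loops <- function(loops, path) {
  stopifnot(all(loop_columns %in% names(loops)))
  write_tsv_stable(sort_loops(loops), path,
                   numeric_cols = c("p_value", "q_value", "min_target_score"))
}

#' @rdname write_loops
#' @export
read_loops <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         na.strings = "NA")
  stopifnot(identical(names(d), loop_columns))
  for (cc in c("tf", "enhancer", "mirna", "gene", "conservation"))
    d[[cc]] <- as.character(d[[cc]])
  d$x_joint_targets <- as.integer(d$x_joint_targets)
  for (nc in c("p_value", "q_value", "min_target_score"))
    d[[nc]] <- as.numeric(d[[nc]])
  d
}
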