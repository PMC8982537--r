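mk_enh <- function(id, chrom, start, end = start + 1000,
                   tissue = "t1", class = "typical") {
  data.frame(enhancer_id = id, chrom = chrom, start = start, end = end,
             enhancer_class = class, tissue = tissue)
}

mk_tss <- function(id, chrom, tss, strand = "+", type = "gene") {
  data.frame(feature_id = id, feature_type = type, chrom = chrom, tss = tss,
             strand = strand)
}

mk_peak <- function(tf, chrom, start, end = start + 300, tissue = "t1") {
  data.frame(tf = tf, chrom = chrom, start = start, end = end,
             dataset_id = "ds", tissue = tissue, score = NA_real_)
}

test_that("enhancer targets are TSS within an inclusive 100 kb of the center", {
  enh <- mk_enh("e1", "1", 100000, 200000)       # center 150000
  tss <- rbind(mk_tss("gin", "1", 249999), mk_tss("gout", "1", 250001),
               mk_tss("gedge", "1", 250000), mk_tss("gother", "2", 150000),
               mk_tss("m1", "1", 140000, type = "mirna"))
  e <- derive_enhancer_target_edges(enh, tss)
  expect_setequal(e$target_id, c("gin", "gedge", "m1"))
  expect_equal(sort(unique(e$edge_type)), c("enhancer_gene", "enhancer_mirna"))
  expect_equal(unique(e$provenance), "proximity")
  # flank = 0 keeps only a TSS exactly at the center
  e0 <- derive_enhancer_target_edges(enh, rbind(tss, mk_tss("gc", "1", 150000)),
                                     flank = 0)
  expect_equal(e0$target_id, "gc")
})

test_that("TF-enhancer edges require binding-site overlap and deduplicate", {
  enh <- mk_enh("e1", "1", 1000, 2000)
  peaks <- rbind(mk_peak("tfA", "1", 1500, 1600),
                 mk_peak("tfA", "1", 1200, 1300),   # second peak, same pair
                 mk_peak("tfB", "1", 2000, 2100))   # book-ended: no overlap
  e <- derive_tf_enhancer_edges(peaks, enh)
  expect_equal(nrow(e), 1L)
  expect_equal(e$regulator_id, "tfA")
})

test_that("TF-promoter edges honour the per-feature windows and strand", {
  peaks <- mk_peak("tfA", "1", 41000, 42000)
  mir <- mk_tss("m1", "1", 50000, "+", "mirna")
  gene <- mk_tss("g1", "1", 50000, "+", "gene")
  expect_equal(derive_tf_promoter_edges(peaks, mir, 10000, 1000, "tf_mirna",
                                        "t1")$target_id, "m1")
  expect_equal(nrow(derive_tf_promoter_edges(peaks, gene, 5000, 1000,
                                             "tf_gene", "t1")), 0L)
  minus <- mk_tss("m2", "1", 50000, "-", "mirna")
  expect_equal(derive_tf_promoter_edges(mk_peak("tfA", "1", 58000, 59000),
                                        minus, 10000, 1000, "tf_mirna",
                                        "t1")$target_id, "m2")
})

test_that("enhancer-TF edges project enhancer-gene edges through the coding map", {
  eg <- rbind(mk_edges("enhancer_gene", "e1", "gFOXA1"),
              mk_edges("enhancer_gene", "e1", "g2"))
  e <- derive_enhancer_tf_edges(eg, c(FOXA1 = "gFOXA1"))
  expect_equal(e$target_id, "FOXA1")
  expect_equal(e$regulator_id, "e1")
  expect_equal(nrow(derive_enhancer_tf_edges(eg, character(0))), 0L)
  # every enhancer_tf edge has a witnessing enhancer_gene edge
  map <- c(FOXA1 = "gFOXA1", T2 = "g2")
  et <- derive_enhancer_tf_edges(eg, map)
  expect_true(all(paste(et$regulator_id, unname(map[et$target_id])) %in%
                    paste(eg$regulator_id, eg$target_id)))
})

test_that("curated enhancer-miRNA tables name unresolvable ids in strict mode", {
  enh <- mk_enh("e1", "1", 0, 100)
  f <- tempfile()
  writeLines(c("enhancer_id\tmirna_id", "e1\tm1", "e1\tm1", "eX\tm2"), f)
  expect_error(load_curated_enhancer_mirna_edges(f, enh, strict = TRUE), "eX")
})

test_that("curated tables warn below and abort above the resolution threshold", {
  enh <- mk_enh("e1", "1", 0, 100)
  f <- tempfile()
  writeLines(c("enhancer_id\tmirna_id", "e1\tm1", "e1\tm1", "e1\tm2", "eX\tm2"), f)
  expect_warning(e <- load_curated_enhancer_mirna_edges(f, enh),
                 "unresolvable")
  expect_equal(nrow(e), 2L)
  expect_equal(unique(e$provenance), "curated")
  f2 <- tempfile()
  writeLines(c("enhancer_id\tmirna_id", "eX\tm1", "eY\tm2", "e1\tm1"), f2)
  expect_error(load_curated_enhancer_mirna_edges(f2, enh), "unresolvable")
})

test_that("derived edges match a naive all-pairs oracle on a random landscape", {
  set.seed(21)
  enh <- mk_enh(sprintf("e%02d", 1:30), sample(c("1", "2"), 30, replace = TRUE),
                start = sample(seq(0, 900000, by = 1000), 30))
  enh$end <- enh$start + sample(500:3000, 30, replace = TRUE)
  tss <- rbind(
    mk_tss(sprintf("g%02d", 1:40), sample(c("1", "2"), 40, replace = TRUE),
           sample(0:1000000, 40), sample(c("+", "-"), 40, replace = TRUE)),
    mk_tss(sprintf("m%02d", 1:20), sample(c("1", "2"), 20, replace = TRUE),
           sample(0:1000000, 20), sample(c("+", "-"), 20, replace = TRUE),
           type = "mirna"))
  peaks <- mk_peak(sample(c("tfA", "tfB", "tfC"), 60, replace = TRUE),
                   sample(c("1", "2"), 60, replace = TRUE),
                   start = sample(0:1000000, 60))
  peaks$end <- peaks$start + sample(100:400, 60, replace = TRUE)

  flank <- 100000
  e_tgt <- derive_enhancer_target_edges(enh, tss, flank)
  want <- character(0)
  for (i in seq_len(nrow(enh))) for (j in seq_len(nrow(tss))) {
    ctr <- (enh$start[i] + enh$end[i]) %/% 2
    if (enh$chrom[i] == tss$chrom[j] && abs(tss$tss[j] - ctr) <= flank)
      want <- c(want, paste(enh$enhancer_id[i], tss$feature_id[j]))
  }
  expect_setequal(paste(e_tgt$regulator_id, e_tgt$target_id), want)

  e_te <- derive_tf_enhancer_edges(peaks, enh)
  want <- character(0)
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(enh)))
    if (peaks$chrom[i] == enh$chrom[j] &&
        max(peaks$start[i], enh$start[j]) < min(peaks$end[i], enh$end[j]))
      want <- c(want, paste(peaks$tf[i], enh$enhancer_id[j]))
  expect_setequal(paste(e_te$regulator_id, e_te$target_id), unique(want))

  mir <- tss[tss$feature_type == "mirna", ]
  e_tm <- derive_tf_promoter_edges(peaks, mir, 10000, 1000, "tf_mirna", "t1")
  want <- character(0)
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(mir))) {
    w <- if (mir$strand[j] == "+") c(mir$tss[j] - 10000, mir$tss[j] + 1000)
         else c(mir$tss[j] - 1000, mir$tss[j] + 10000)
    w[1] <- max(0, w[1])
    if (peaks$chrom[i] == mir$chrom[j] &&
        max(peaks$start[i], w[1]) < min(peaks$end[i], w[2]))
      want <- c(want, paste(peaks$tf[i], mir$feature_id[j]))
  }
  expect_setequal(paste(e_tm$regulator_id, e_tm$target_id), unique(want))
})

test_that("shrinking any window parameter never adds edges", {
  set.seed(22)
  enh <- mk_enh(sprintf("e%02d", 1:15), "1",
                start = sample(seq(0, 500000, by = 500), 15))
  enh$end <- enh$start + 1500
  tss <- mk_tss(sprintf("g%02d", 1:30), "1", sample(0:600000, 30),
                sample(c("+", "-"), 30, replace = TRUE))
  peaks <- mk_peak("tfA", "1", sample(0:600000, 25))
  peaks$end <- peaks$start + 300
  key <- function(e) paste(e$regulator_id, e$target_id)
  flanks <- c(200000, 100000, 50000, 10000, 0)
  prev <- NULL
  for (fl in flanks) {
    cur <- key(derive_enhancer_target_edges(enh, tss, fl))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (up in c(20000, 10000, 2000, 0)) {
    cur <- key(derive_tf_promoter_edges(peaks, tss, up, 1000, "tf_gene", "t1"))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})
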