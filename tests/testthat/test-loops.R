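sig_pair <- function(a, b, family = "tf_enhancer_over_mirna", tissue = "t1",
                     x = 1L) {
  data.frame(tissue = tissue, family = family, regulator_a = a,
             regulator_b = b, M = 5L, N = 2L, k = 2L, x = x,
             p_value = 0.01, q_value = 0.02)
}

test_that("TF-enhancer-miRNA loops need the full edge triangle and a surviving pair", {
  tf_enh <- mk_edges("tf_enhancer", "t1", "e1")
  tf_mir <- mk_edges("tf_mirna", "t1", c("m1", "m2"))
  enh_mir <- mk_edges("enhancer_mirna", "e1", "m1")
  loops <- assemble_ffl_tf_enhancer_mirna(tf_enh, tf_mir, enh_mir,
                                          sig_pair("t1", "e1"),
                                          c(e1 = "super"))
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$mirna, "m1")
  expect_equal(loops$enhancer_class, "super")
  expect_equal(loops$q_value, 0.02)
  # broken triangle: no enhancer->miRNA edge
  expect_equal(nrow(assemble_ffl_tf_enhancer_mirna(
    tf_enh, tf_mir, enh_mir[0, ], sig_pair("t1", "e1"))), 0L)
  # pair not significant: no loops for any target
  expect_equal(nrow(assemble_ffl_tf_enhancer_mirna(
    tf_enh, tf_mir, enh_mir, sig_pair("t1", "e1")[0, ])), 0L)
  # no TF->enhancer edge
  expect_equal(nrow(assemble_ffl_tf_enhancer_mirna(
    tf_enh[0, ], tf_mir, enh_mir, sig_pair("t1", "e1"))), 0L)
})

test_that("TF-enhancer-gene loops follow the same construction over genes", {
  tf_enh <- mk_edges("tf_enhancer", "t1", "e1")
  tf_gene <- mk_edges("tf_gene", "t1", "g1")
  enh_gene <- mk_edges("enhancer_gene", "e1", c("g1", "g2"))
  pair <- sig_pair("t1", "e1", "tf_enhancer_over_gene")
  loops <- assemble_ffl_tf_enhancer_gene(tf_enh, tf_gene, enh_gene, pair)
  expect_equal(loops$gene, "g1")
  expect_true(is.na(loops$mirna))
  expect_equal(nrow(assemble_ffl_tf_enhancer_gene(
    tf_enh, tf_gene[0, ], enh_gene, pair)), 0L)
})

test_that("enhancer-miRNA-gene loops carry the target score and honour filters", {
  enh_mir <- mk_edges("enhancer_mirna", "e1", "m1")
  enh_gene <- mk_edges("enhancer_gene", "e1", c("g1", "g2"))
  scores <- data.frame(mirna_id = c("m1", "m1"), gene_id = c("g1", "g3"),
                       Ni = 1L, Nc = 1L, S = 1.5,
                       conservation = c("conserved", NA))
  loops <- assemble_ffl_enhancer_mirna_gene(enh_mir, enh_gene,
                                            filter_target_scores(scores))
  expect_equal(loops$gene, "g1")           # g2 not targeted, g3 not near
  expect_equal(loops$min_target_score, 1.5)
  expect_equal(loops$conservation, "conserved")
  # a pair at exactly S = 1 is filtered out upstream
  s1 <- transform(scores, S = 1.0)
  expect_equal(nrow(assemble_ffl_enhancer_mirna_gene(
    enh_mir, enh_gene, filter_target_scores(s1))), 0L)
  # conservation filter drops unlabeled/poorly conserved loops
  scores2 <- data.frame(mirna_id = "m1", gene_id = c("g1", "g2"),
                        Ni = 1L, Nc = 1L, S = 1.5,
                        conservation = c("conserved", "poorly_conserved"))
  all_loops <- assemble_ffl_enhancer_mirna_gene(enh_mir, enh_gene, scores2)
  expect_equal(nrow(all_loops), 2L)
  kept <- filter_loops(all_loops, conservation = "conserved")
  expect_equal(kept$gene, "g1")
})

test_that("feedback loops require mutual TF-enhancer wiring", {
  tf_enh <- mk_edges("tf_enhancer", c("t1", "t2", "t3"), "e1")
  enh_tf <- mk_edges("enhancer_tf", "e1", c("t1", "t2"))
  fbl <- assemble_fbl_tf_enhancer(tf_enh, enh_tf)
  expect_equal(sort(fbl$tf), c("t1", "t2"))
  expect_true(all(is.na(fbl$p_value)))
  expect_equal(nrow(assemble_fbl_tf_enhancer(tf_enh, enh_tf[0, ])), 0L)
})

test_that("assembly equals the brute-force triple-loop oracle on random edges", {
  set.seed(31)
  for (rep in 1:5) {
    tfs <- sprintf("t%02d", 1:6)
    enhs <- sprintf("e%02d", 1:6)
    mirs <- sprintf("m%02d", 1:8)
    genes <- sprintf("g%02d", 1:8)
    rnd <- function(type, from, to, p = 0.3) {
      g <- expand.grid(f = from, t = to, stringsAsFactors = FALSE)
      g <- g[stats::runif(nrow(g)) < p, ]
      if (!nrow(g)) return(mk_edges(type, character(0), character(0)))
      mk_edges(type, g$f, g$t)
    }
    edges <- rbind(rnd("tf_enhancer", tfs, enhs),
                   rnd("tf_mirna", tfs, mirs),
                   rnd("tf_gene", tfs, genes),
                   rnd("enhancer_mirna", enhs, mirs),
                   rnd("enhancer_gene", enhs, genes),
                   rnd("enhancer_tf", enhs, tfs, 0.15))
    scores_f <- do.call(rbind, lapply(mirs, function(m)
      data.frame(mirna_id = m, gene_id = sample(genes, 3), Ni = 1L, Nc = 1L,
                 S = 1.5, conservation = NA_character_)))
    sig <- rbind(
      qvalue_filter(build_pair_tests(edges, "tf_enhancer_over_mirna",
                                     mode = "ge"), alpha = 1.0),
      qvalue_filter(build_pair_tests(edges, "tf_enhancer_over_gene",
                                     mode = "ge"), alpha = 1.0))
    et <- function(tp) edges[edges$edge_type == tp, , drop = FALSE]
    got <- rbind(
      assemble_ffl_tf_enhancer_mirna(et("tf_enhancer"), et("tf_mirna"),
                                     et("enhancer_mirna"),
                                     sig[sig$family == "tf_enhancer_over_mirna", ]),
      assemble_ffl_tf_enhancer_gene(et("tf_enhancer"), et("tf_gene"),
                                    et("enhancer_gene"),
                                    sig[sig$family == "tf_enhancer_over_gene", ]),
      assemble_ffl_enhancer_mirna_gene(et("enhancer_mirna"),
                                       et("enhancer_gene"), scores_f),
      assemble_fbl_tf_enhancer(et("tf_enhancer"), et("enhancer_tf")))
    want <- loop_oracle(edges, sig, scores_f)
    expect_identical(loop_key(got), loop_key(want))
    # row order of the inputs does not change the loop set
    perm <- edges[sample(nrow(edges)), ]
    got2 <- assemble_fbl_tf_enhancer(
      perm[perm$edge_type == "tf_enhancer", ],
      perm[perm$edge_type == "enhancer_tf", ])
    expect_identical(loop_key(got2),
                     loop_key(got[got$loop_type == "tf_enhancer_fbl", ]))
    # referential integrity: every loop's witnessing edges exist
    ek <- paste(edges$edge_type, edges$regulator_id, edges$target_id)
    tem <- got[got$loop_type == "tf_enhancer_mirna", ]
    expect_true(all(paste("tf_enhancer", tem$tf, tem$enhancer) %in% ek))
    expect_true(all(paste("tf_mirna", tem$tf, tem$mirna) %in% ek))
    expect_true(all(paste("enhancer_mirna", tem$enhancer, tem$mirna) %in% ek))
  }
})

test_that("miRNA participation counts distinct samples and flags masters", {
  loop_row <- function(tissue, mirna, type = "tf_enhancer_mirna") {
    l <- enhloops:::new_loops(1L)
    l$tissue <- tissue; l$loop_type <- type; l$mirna <- mirna
    l$enhancer <- "e1"
    l
  }
  loops <- rbind(
    do.call(rbind, lapply(sprintf("s%02d", 1:14), loop_row, mirna = "mirA")),
    do.call(rbind, lapply(sprintf("s%02d", 1:16), loop_row, mirna = "mirB",
                          type = "enhancer_mirna_gene")),
    loop_row("s01", "mirC"),
    loop_row("s01", "mirC"),                       # same sample twice
    loop_row("s01", "mirD", type = "tf_enhancer_gene"))  # wrong loop type
  s <- mirna_participation_summary(loops, min_samples = 14)
  expect_equal(s$n_samples[s$mirna == "mirA"], 14L)
  expect_true(s$is_master[s$mirna == "mirA"])
  expect_equal(s$n_samples[s$mirna == "mirB"], 16L)
  expect_equal(s$n_samples[s$mirna == "mirC"], 1L)
  expect_false(s$is_master[s$mirna == "mirC"])
  expect_false("mirD" %in% s$mirna)
})
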