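# Hypergeometric joint-target tail and BH adjustment, checked against
# exhaustive enumeration, base R's phyper, and a double-loop step-up oracle.

test_that("hypergeometric tails reproduce the enumerated M=10 draws", {
  # all C(10,5) = 252 equally likely draws; 6 of them overlap the 4-set fully
  expect_equal(hypergeom_pvalue(10, 5, 4, 4, mode = "ge"), 6 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(10, 5, 4, 3, mode = "printed"), 6 / 252,
               tolerance = 1e-12)
  # the printed sum over i = 0..x covers the whole support at x = min(N,k)
  expect_equal(hypergeom_pvalue(10, 5, 4, 4, mode = "printed"), 0)
  # regulator A targets the whole universe: overlap is deterministically k
  expect_equal(hypergeom_pvalue(10, 10, 4, 4, mode = "ge"), 1)
  expect_error(hypergeom_pvalue(10, 11, 4, 4), "exceed")
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "exceed")
})

test_that("both modes agree with exhaustive subset enumeration and phyper", {
  for (M in c(4L, 7L, 9L)) {
    for (N in 1:M) for (k in 1:M) for (x in 0:min(N, k)) {
      for (mode in c("printed", "ge")) {
        got <- hypergeom_pvalue(M, N, k, x, mode)
        expect_equal(got, hyper_tail_oracle(M, N, k, x, mode),
                     tolerance = 1e-12,
                     label = sprintf("M=%d N=%d k=%d x=%d %s", M, N, k, x, mode))
      }
      expect_equal(hypergeom_pvalue(M, N, k, x, "ge"),
                   stats::phyper(x - 1, k, M - k, N, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("the printed mode equals the ge mode evaluated at x + 1", {
  set.seed(5)
  for (i in 1:100) {
    M <- sample(2:60, 1)
    N <- sample(1:M, 1); k <- sample(1:M, 1)
    x <- sample(0:min(N, k), 1)
    p_printed <- hypergeom_pvalue(M, N, k, x, "printed")
    if (x + 1 <= min(N, k))
      expect_equal(p_printed, hypergeom_pvalue(M, N, k, x + 1, "ge"),
                   tolerance = 1e-12)
    else
      expect_equal(p_printed, 0)
  }
})

test_that("ge-mode p is non-increasing in x for fixed margins", {
  for (M in c(8L, 15L)) for (N in c(3L, 6L)) for (k in c(4L, 7L)) {
    p <- hypergeom_pvalue(rep(M, min(N, k) + 1), N, k, 0:min(N, k), "ge")
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("BH step-up matches the hand example and the double-loop oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (i in 1:200) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    # permutation invariance up to reordering
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
  }
})

test_that("pair tests count N, k, x within the co-regulated universe", {
  edges <- rbind(
    mk_edges("tf_mirna", "tfA", c("m1", "m2", "m5")),
    mk_edges("tf_mirna", "tfB", "m1"),
    mk_edges("enhancer_mirna", "e1", c("m1", "m2")),
    mk_edges("enhancer_mirna", "e2", c("m3", "m4")))
  p <- build_pair_tests(edges, "tf_enhancer_over_mirna", mode = "ge")
  # universe = targets with >= 1 TF and >= 1 enhancer regulator = {m1, m2}
  expect_equal(nrow(p), 2L)
  a <- p[p$regulator_a == "tfA", ]
  expect_equal(c(a$M, a$N, a$k, a$x), c(2L, 2L, 2L, 2L))
  expect_equal(a$p_value, 1)   # overlap is forced when N = k = M
  b <- p[p$regulator_b == "e1" & p$regulator_a == "tfB", ]
  expect_equal(c(b$M, b$N, b$k, b$x), c(2L, 1L, 2L, 1L))
  # no joint target, no test
  edges2 <- rbind(mk_edges("tf_mirna", "tfA", "m1"),
                  mk_edges("enhancer_mirna", "e1", "m2"))
  expect_equal(nrow(build_pair_tests(edges2, "tf_enhancer_over_mirna")), 0L)
  # union universe includes singly-regulated targets
  pu <- build_pair_tests(edges, "tf_enhancer_over_mirna", mode = "ge",
                         universe_rule = "union")
  expect_equal(unique(pu$M), 5L)
})

test_that("a planted co-regulated pair attains the minimum p among random pairs", {
  set.seed(9)
  targets <- sprintf("m%02d", 1:30)
  edges <- rbind(
    mk_edges("tf_mirna", "tfP", targets[1:8]),
    mk_edges("enhancer_mirna", "eP", targets[1:8]),
    do.call(rbind, lapply(sprintf("tf%02d", 1:5), function(tf)
      mk_edges("tf_mirna", tf, sample(targets, 8)))),
    do.call(rbind, lapply(sprintf("e%02d", 1:5), function(e)
      mk_edges("enhancer_mirna", e, sample(targets, 8)))))
  p <- build_pair_tests(edges, "tf_enhancer_over_mirna", mode = "ge")
  best <- p[which.min(p$p_value), ]
  expect_equal(best$regulator_a, "tfP")
  expect_equal(best$regulator_b, "eP")
  expect_equal(best$p_value,
               hyper_tail_oracle(best$M, best$N, best$k, best$x, "ge"),
               tolerance = 1e-10)
})

test_that("q-filtering is strict at alpha and disabled at alpha = 1", {
  pairs <- data.frame(tissue = "t1", family = "tf_enhancer_over_mirna",
                      regulator_a = c("a1", "a2", "a3"), regulator_b = "e1",
                      M = 20L, N = 5L, k = 5L, x = c(5L, 3L, 1L),
                      p_value = NA_real_, q_value = NA_real_)
  pairs$p_value <- hypergeom_pvalue(pairs$M, pairs$N, pairs$k, pairs$x, "ge")
  kept <- qvalue_filter(pairs, alpha = 0.05)
  expect_true(all(kept$q_value < 0.05))
  expect_equal(nrow(qvalue_filter(pairs, alpha = 1.0)), 3L)
  # a single test with p = 0.05 has q = 0.05 and is excluded
  one <- pairs[1, ]
  one$p_value <- 0.05
  expect_equal(nrow(qvalue_filter(one, alpha = 0.05)), 0L)
  expect_equal(nrow(qvalue_filter(pairs[0, ])), 0L)
  # BH families are corrected independently per (tissue, family)
  two_fam <- rbind(pairs, transform(pairs, family = "tf_enhancer_over_gene"))
  adj <- adjust_pair_tests(two_fam)
  expect_equal(adj$q_value[1:3], bh_adjust(pairs$p_value))
})
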