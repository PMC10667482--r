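test_that("Kruskal-Wallis H matches the tie-corrected rank formula", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis(v, g)
  expect_equal(res$statistic, oracle_kruskal_H(v, g), tolerance = 1e-12)

  same <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  set.seed(3)
  for (i in 1:10) {
    v <- sample(1:6, 12, replace = TRUE)  # ties on purpose
    g <- rep(c("a", "b", "c"), each = 4)
    expect_equal(kruskal_wallis(v, g)$statistic, oracle_kruskal_H(v, g),
                 tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(1:3, factor(c("a", "a", "a"), levels = c("a", "b"))),
               "2 groups")
})

test_that("Dunn z-statistics match an explicit mean-rank oracle", {
  set.seed(5)
  for (i in 1:10) {
    v <- c(rnorm(5), rnorm(6) + (i %% 3), sample(1:4, 7, replace = TRUE))
    g <- rep(c("a", "b", "c"), c(5, 6, 7))
    res <- dunn_posthoc(v, g)
    expect_equal(res$z[res$comparison == "a vs b"], oracle_dunn_z(v, g, "a", "b"),
                 tolerance = 1e-9)
    expect_equal(res$z[res$comparison == "b vs c"], oracle_dunn_z(v, g, "b", "c"),
                 tolerance = 1e-9)
    expect_true(all(res$q >= 0 & res$q <= 1))
  }
  # identical groups: all z = 0, p = 1
  res0 <- dunn_posthoc(rep(c(1, 2), 3), rep(c("a", "b", "c"), each = 2))
  expect_true(all(res0$z == 0))
  expect_true(all(res0$p == 1))
  # tie-free data: tie term vanishes, matches the same oracle
  v <- c(10, 20, 30, 40, 50, 60)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(dunn_posthoc(v, g)$z[1], oracle_dunn_z(v, g, "a", "b"),
               tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum uses exact enumeration for tiny tie-free samples", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, oracle_wilcoxon_exact(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)
  expect_equal(res$p, 0.1)   # 2/20 arrangements

  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:100, 4); b <- sample(101:200, 5) - 100 + runif(5)
    expect_equal(wilcoxon_rank_sum(a, b)$p, oracle_wilcoxon_exact(a, b),
                 tolerance = 1e-9)
    expect_equal(wilcoxon_rank_sum(a, b)$p, wilcoxon_rank_sum(b, a)$p,
                 tolerance = 1e-12)
  }
  expect_gt(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Fisher 2x2 p sums hypergeometric probabilities below observed", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p, 1)
  res <- fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))
  expect_equal(res$p, 2 / 252, tolerance = 1e-9)
  set.seed(11)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisher_exact_2x2(tab)$p, oracle_fisher_p(tab), tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tab)$p, fisher_exact_2x2(t(tab))$p,
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(fisher_exact_2x2(rbind(c(0.5, 2), c(3, 4))), "integer")
})

test_that("Benjamini-Hochberg step-up matches the hand oracle", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q <= 1 + 1e-12))
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p[perm]), q[perm], tolerance = 1e-12)
  }
  expect_error(benjamini_hochberg(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("Cohen's d uses n-1 pooled variance with preserved sign", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(0, 0), c(1, 1)), "zero")
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 1)
    expect_equal(cohens_d(a, b), oracle_cohens_d(a, b), tolerance = 1e-12)
  }
})

test_that("alpha diversity matches closed forms and the formula oracle", {
  t <- abundance_table(rbind(s1 = c(1, 1, 1, 1), s2 = c(4, 0, 0, 0),
                             s3 = c(2, 1, 1, 0)))
  expect_equal(unname(alpha_diversity(t, "shannon")),
               c(log(4), 0, 1.0397), tolerance = 1e-4)
  expect_equal(unname(alpha_diversity(t, "simpson")),
               c(0.75, 0, 1 - (0.25 + 2 * 0.0625)), tolerance = 1e-9)
  for (seed in 1:10) {
    m <- random_counts(6, 8, seed = seed)
    sh <- alpha_diversity(abundance_table(m), "shannon")
    si <- alpha_diversity(abundance_table(m), "simpson")
    for (i in 1:6) {
      expect_equal(unname(sh[i]), oracle_shannon(m[i, ]), tolerance = 1e-9)
      expect_equal(unname(si[i]), oracle_simpson(m[i, ]), tolerance = 1e-9)
    }
  }
  # Shannon maximal iff uniform over observed genera
  expect_lt(oracle_shannon(c(5, 2, 1, 0)), log(3))
})

test_that("compare_groups dispatches Wilcoxon for 2 and KW+Dunn for 3 groups", {
  v <- c(rnorm(5), rnorm(5) + 3)
  g2 <- rep(c("a", "b"), each = 5)
  out2 <- compare_groups(v, g2)
  expect_null(out2$omnibus)
  expect_equal(nrow(out2$pairwise), 1)

  v3 <- c(rnorm(5), rnorm(5), rnorm(5) + 3)
  g3 <- rep(c("a", "b", "c"), each = 5)
  out3 <- compare_groups(v3, g3)
  expect_equal(out3$omnibus$comparison, "omnibus")
  expect_equal(nrow(out3$pairwise), 3)
})
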